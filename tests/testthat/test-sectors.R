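test_that("sector map has 36 sectors, 12 per region, partitioning the gland", {
  an <- fixture_case()$anatomy
  map <- build_sector_map(an)
  expect_equal(nrow(map$sectors), 36L)
  expect_equal(as.integer(table(map$sectors$region)), rep(12L, 3))
  expect_setequal(map$sectors$segment[map$sectors$region == "mid"], 1:12)

  # exact partition: every gland voxel in exactly one sector, none outside
  expect_true(all((map$assignment > 0) == an$mask))
  expect_equal(sum(map$sectors$n_voxels), sum(an$mask))
  counted <- tabulate(map$assignment[map$assignment > 0], 36)
  expect_equal(counted, map$sectors$n_voxels)

  # degenerate anatomy (single-slice mask: only one region) is rejected
  flat <- an$mask
  flat[, , -8] <- FALSE
  expect_error(build_sector_map(anatomy_from_mask(flat, an$spacing)),
               "empty")
})

test_that("schematic polygons tile each region plane without gaps or overlap", {
  map <- build_sector_map(fixture_symmetric_anatomy())
  for (rg in c("apex", "mid", "base")) {
    pl <- map$polygons[[rg]]
    expect_length(pl$sectors, 12L)
    # probe points across the disc fall in exactly one polygon each
    set.seed(3)
    th <- runif(400, 0, 2 * pi)
    rr <- sqrt(runif(400)) * pl$radius_mm * 0.995
    px <- rr * cos(th)
    py <- rr * sin(th)
    hits <- vapply(pl$sectors, function(p)
      iplconcord:::points_in_polygon(px, py, p), logical(length(px)))
    n_hit <- rowSums(hits)
    expect_gte(mean(n_hit == 1), 0.99)  # edge-grazing probes may double-count
    expect_true(all(n_hit >= 1))
  }
})

test_that("mirror-symmetric anatomy gives balanced left/right sectors", {
  map <- build_sector_map(fixture_symmetric_anatomy())
  lr <- tapply(map$sectors$n_voxels, map$sectors$side, sum)
  expect_lt(abs(lr[["left"]] - lr[["right"]]) / sum(lr), 0.01)
})

test_that("deterministic detection marks exactly the traversed lesion sectors", {
  an <- fixture_symmetric_anatomy()
  map <- build_sector_map(an)
  # a small lesion confined to one sector
  target_sector <- 16L  # mid region
  vox <- which(map$assignment == target_sector, arr.ind = TRUE)
  centre_vox <- vox[which.min(rowSums(sweep(vox, 2, colMeans(vox))^2)), ]
  les_mask <- array(FALSE, dim(an$mask))
  sel <- abs(vox[, 1] - centre_vox[1]) <= 1 & abs(vox[, 2] - centre_vox[2]) <= 1 &
    vox[, 3] == centre_vox[3]
  les_mask[vox[sel, , drop = FALSE]] <- TRUE
  lesion <- list(mask = les_mask,
                 center_mm = (centre_vox - 1) * an$spacing,
                 gleason = "7a", id = 1L)

  always <- biopsy_scheme(detect = function(L) 1)
  lab <- simulate_biopsy(map, an, list(lesion), always, seed = 1)
  pos <- lab$sectors$sector_id[lab$sectors$biopsy_status == "positive"]
  expect_identical(pos, target_sector)
  expect_identical(lab$sectors$gleason[target_sector], "7a")

  never <- biopsy_scheme(detect = function(L) 0)
  lab0 <- simulate_biopsy(map, an, list(lesion), never, seed = 1)
  expect_equal(sum(lab0$sectors$biopsy_status == "positive"), 0L)
  expect_gt(sum(lab0$sectors$biopsy_status == "negative"), 0L)
})

test_that("empirical detection frequency matches the closed-form hit probability", {
  case <- fixture_case()
  an <- case$anatomy
  map <- build_sector_map(an)
  lesion <- case$lesions[[1]]

  # log the in-core tumour path lengths with a zero-probability probe scheme
  logged <- new.env()
  logged$L <- numeric(0)
  probe <- biopsy_scheme(detect = function(L) {
    logged$L <- c(logged$L, L)
    0
  })
  simulate_biopsy(map, an, list(lesion), probe, seed = 1)
  lambda <- 3
  p_closed <- 1 - prod(exp(-logged$L / lambda))
  expect_gt(p_closed, 0.2)

  hits <- vapply(1:400, function(s) {
    lab <- simulate_biopsy(map, an, list(lesion),
                           biopsy_scheme(lambda_mm = lambda), seed = s)
    1L %in% lab$detected_lesions
  }, logical(1))
  se <- sqrt(p_closed * (1 - p_closed) / 400)
  expect_lt(abs(mean(hits) - p_closed), 3 * max(se, 0.005))
})

test_that("adding targeted cores never loses detections", {
  case <- fixture_case()
  an <- case$anatomy
  map <- build_sector_map(an)
  lesions <- case$lesions
  n_with <- n_without <- integer(200)
  for (s in 1:200) {
    with_t <- simulate_biopsy(map, an, lesions,
                              biopsy_scheme(targeted = TRUE), seed = s)
    without <- simulate_biopsy(map, an, lesions,
                               biopsy_scheme(targeted = FALSE), seed = s)
    n_with[s] <- length(with_t$detected_lesions)
    n_without[s] <- length(without$detected_lesions)
  }
  expect_true(all(n_with >= n_without))
  expect_gte(mean(n_with), mean(n_without))
})

test_that("labelled sector tables round-trip through CSV", {
  case <- fixture_case()
  map <- build_sector_map(case$anatomy)
  lab <- simulate_biopsy(map, case$anatomy, case$lesions, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sector_csv(lab, path, case_id = 1L)
  back <- read_sector_csv(path)
  orig <- dplyr::mutate(lab$sectors,
                        dplyr::across(where(is.factor), as.character))
  expect_equal(back$sector_id, orig$sector_id)
  expect_equal(back$biopsy_status, orig$biopsy_status)
  expect_equal(back$gleason, orig$gleason)
  expect_equal(back$n_voxels, orig$n_voxels)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_sector_polygons_json(lab, jpath)
  parsed <- jsonlite::read_json(jpath)
  expect_length(parsed, 3L)
  expect_length(parsed[[1]]$sectors, 12L)
})
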