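test_that("confusion metrics match hand arithmetic and the brute-force oracle", {
  m <- confusion_metrics(3, 1, 2, 30)
  expect_equal(m$dsc, 6 / 9)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 30 / 31)
  expect_equal(m$yi, 0.6 + 30 / 31 - 1)
  expect_equal(m$yi, m$sensitivity + m$specificity - 1, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:50) {
    tu <- as.integer(rmultinom(1, sample(0:36, 1), rep(1, 4)))
    got <- confusion_metrics(tu[1], tu[2], tu[3], tu[4])
    ref <- brute_confusion(tu[1], tu[2], tu[3], tu[4])
    expect_equal(got$dsc, unname(ref["dsc"]), tolerance = 1e-12)
    expect_equal(got$yi, unname(ref["yi"]), tolerance = 1e-12)
  }
})

test_that("sector prediction respects the overlap fraction tau", {
  d <- c(10, 10, 3)
  assignment <- array(0L, d)
  assignment[3:6, 3:6, 2] <- 1L   # sector 1: 16 voxels
  assignment[7:8, 3:6, 2] <- 2L   # sector 2: 8 voxels
  map <- structure(list(
    assignment = assignment,
    spacing = c(1, 1, 1),
    sectors = tibble::tibble(sector_id = 1:2, n_voxels = c(16L, 8L))
  ), class = "sector_map")

  contour <- array(FALSE, d)
  contour[3:6, 3:4, 2] <- TRUE   # half of sector 1, none of sector 2
  expect_identical(sectorize_contour(contour, map, margin_mm = 0, tau = 0), 1L)
  expect_identical(sectorize_contour(contour, map, margin_mm = 0, tau = 0.6),
                   integer(0))
  expect_identical(sectorize_contour(array(FALSE, d), map, 0, 0), integer(0))
})

test_that("scoring handles perfect, disjoint, and degenerate references", {
  map <- fake_scored_map(positive = c(2, 5, 9))
  perfect <- score_sectors(c(2, 5, 9), map)
  expect_equal(perfect$dsc, 1)
  expect_equal(perfect$yi, 1)

  disjoint <- score_sectors(c(1, 3), map)
  expect_equal(disjoint$dsc, 0)
  expect_equal(disjoint$sensitivity, 0)

  none <- score_sectors(c(1, 3), fake_scored_map(positive = integer(0)))
  expect_true(is.na(none$sensitivity))
  expect_true(none$flag_no_positive)

  # unsampled sectors: negative by default, droppable on request
  part <- fake_scored_map(positive = 1, unsampled = 30:36)
  neg_mode <- score_sectors(1, part, unsampled = "negative")
  exc_mode <- score_sectors(1, part, unsampled = "exclude")
  expect_equal(neg_mode$n_scored, 36L)
  expect_equal(exc_mode$n_scored, 29L)
  expect_equal(exc_mode$tn, 28L)
})

test_that("aggregation reproduces textbook mean/SD and ignores record order", {
  rec <- tibble::tibble(method = c("a", "a", "b"),
                        dsc = c(0.4, 0.8, 0.5),
                        yi = c(0.2, 0.4, 0.1),
                        sensitivity = c(1, 0.5, 0.7),
                        specificity = c(0.3, 0.9, 0.8))
  agg <- aggregate_metrics(rec)
  a <- dplyr::filter(agg, method == "a")
  expect_equal(a$dsc_mean, 0.6)
  expect_equal(a$dsc_sd, sd(c(0.4, 0.8)))
  b <- dplyr::filter(agg, method == "b")
  expect_equal(b$n, 1L)
  expect_equal(b$dsc_sd, 0)

  shuffled <- aggregate_metrics(rec[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(agg, method), dplyr::arrange(shuffled, method))
})

test_that("best-threshold selection maximises DSC with YI tie-breaking", {
  expect_equal(as.numeric(best_threshold(c(0.4, 0.5, 0.6),
                                         c(0.2, 0.5, 0.7),
                                         c(0.1, 0.2, 0.3))), 0.6)
  tied <- suppressWarnings(
    best_threshold(c(0.4, 0.5), c(0.6, 0.6), yi = c(0.2, 0.5)))
  expect_equal(as.numeric(tied), 0.5)
  expect_true(attr(tied, "tie"))
  expect_warning(
    best_threshold(c(0.4, 0.5), c(0.7, 0.6), yi = c(0.2, 0.5)),
    "disagree")
})

test_that("wider margins trade specificity for sensitivity on a fixed case", {
  case <- fixture_case()
  map <- build_sector_map(case$anatomy)
  map <- simulate_biopsy(map, case$anatomy, case$lesions, seed = 9)
  cts <- auto_contour(case$volumes$pet, case$anatomy, 0.7)
  um <- Reduce(`|`, lapply(cts, `[[`, "mask"))
  prev <- integer(0)
  prev_sc <- NULL
  for (m in c(0, 3, 5, 8)) {
    pred <- sectorize_contour(um, map, margin_mm = m)
    expect_true(all(prev %in% pred))
    sc <- score_sectors(pred, map)
    if (!is.null(prev_sc)) {
      expect_gte(sc$sensitivity, prev_sc$sensitivity)
      expect_lte(sc$specificity, prev_sc$specificity)
    }
    prev <- pred
    prev_sc <- sc
  }
})

test_that("voxel-level Dice mode is bounded and margin-sensitive", {
  case <- fixture_case()
  map <- build_sector_map(case$anatomy)
  map <- simulate_biopsy(map, case$anatomy, case$lesions, seed = 9)
  cts <- auto_contour(case$volumes$pet, case$anatomy, 0.7)
  d_both <- voxel_dice(cts[[1]], map, margin_mm = 5, margin_both = TRUE)
  d_one <- voxel_dice(cts[[1]], map, margin_mm = 5, margin_both = FALSE)
  expect_true(d_both >= 0 && d_both <= 1)
  expect_true(d_one >= 0 && d_one <= 1)
})
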