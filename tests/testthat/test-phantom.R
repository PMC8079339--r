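noiseless_spec <- function(...) {
  cohort_spec(
    n_patients = 2,
    noise_sd = 0,
    psf_fwhm_mm = c(PET_GA68 = 0, PET_F18 = 0, T2W = 0, ADC = 0, DCE = 0),
    lesion_count_probs = c(`1` = 1),
    satellite_count_probs = c(`0` = 1),
    lesion_suvmax = list(median = 10, sdlog = 0, range = c(1.9, 21.4)),
    lesion_relvol = list(median = 0.15, sdlog = 0, range = c(0.06, 0.75)),
    seed = 7,
    ...
  )
}

test_that("zero-blur, zero-noise case reproduces the assigned SUVmax and conserves uptake", {
  case <- generate_case(noiseless_spec(), 1)
  pet <- case$volumes$pet$data
  inside <- case$anatomy$mask
  expect_identical(max(pet[inside]), 10)
  expect_true(all(pet >= 0))

  # integrated excess uptake over background = lesion volume x (SUV - bg)
  l <- case$lesions[[1]]
  vox_cc <- voxel_volume_cc(case$anatomy$spacing)
  excess <- sum(pet[inside] - 0.7) * vox_cc
  expect_equal(excess, l$volume_cc * (10 - 0.7) / 1, tolerance = 1e-9)

  # realized relative volume matches the requested fraction to one voxel
  expect_lt(abs(l$relvol - 0.15), 2 / sum(inside))
  expect_true(all(l$mask | !l$mask))          # logical mask
  expect_true(all(!(l$mask & !inside)))       # lesion inside the gland
})

test_that("prostate volume hits the target to within one voxel volume", {
  for (seed in c(1, 9)) {
    spec <- cohort_spec(
      n_patients = 1, seed = seed,
      prostate_volume = list(median_cc = 31, sdlog = 0, range_cc = c(21, 54)))
    case <- generate_case(spec, 1)
    vox_cc <- voxel_volume_cc(spec$spacing)
    expect_lte(abs(case$anatomy$prostate_volume_cc - 31), vox_cc + 1e-12)
    expect_equal(case$anatomy$prostate_volume_cc,
                 sum(case$anatomy$mask) * vox_cc)
  }
})

test_that("identical spec and seed reproduce a case bit-for-bit", {
  spec <- cohort_spec(n_patients = 3, seed = 5)
  a <- generate_case(spec, 2)
  b <- generate_case(spec, 2)
  expect_identical(a$volumes$pet$data, b$volumes$pet$data)
  expect_identical(a$lesion_table, b$lesion_table)
  expect_identical(a$covariates, b$covariates)
  # and a different case index gives a different draw
  c3 <- generate_case(spec, 3)
  expect_false(identical(a$volumes$pet$data, c3$volumes$pet$data))
})

test_that("anatomy labels are consistent: regions partition the gland, zones nest inside it", {
  an <- fixture_case()$anatomy
  expect_true(all((an$region > 0) == an$mask))
  expect_true(all((an$zone > 0) == an$mask))
  for (r in 1:3) expect_gt(sum(an$region == r), 0)
  # regions split the cranio-caudal extent in order
  z <- slice.index(an$mask, 3)
  expect_lte(max(z[an$region == 1]), min(z[an$region == 3]))
})

test_that("widening the PSF strictly lowers the observed peak of a small lesion", {
  d <- c(31, 31, 15)
  sp <- c(1.5, 1.5, 3)
  co <- expand.grid(x = (0:30) * 1.5, y = (0:30) * 1.5, z = (0:14) * 3)
  r <- sqrt((co$x - 22.5)^2 + (co$y - 22.5)^2 + (co$z - 21)^2)
  arr <- array(ifelse(r <= 4, 10, 0.5), d)
  peaks <- vapply(c(0, 2, 4, 6, 8),
                  function(fw) max(gaussian_blur_mm(arr, fw, sp)), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("default cohort statistics land inside the reported ranges", {
  spec <- cohort_spec(n_patients = 30, seed = 11)
  coh <- generate_cohort(spec)
  vols <- coh$covariates$prostate_volume_cc
  expect_true(all(vols >= 21 - 0.1 & vols <= 54 + 0.1))
  expect_gt(median(vols), 25)
  expect_lt(median(vols), 38)
  main <- dplyr::filter(coh$lesions, !satellite)
  expect_true(all(main$suvmax_assigned >= 1.9 & main$suvmax_assigned <= 21.4))
  expect_true(all(main$relvol >= 0.05 & main$relvol <= 0.76))
  expect_true(all(coh$lesions$gleason %in% c("6", "7a", "7b", "8", "9")))
})

test_that("manual contour perturbation behaves like observer noise", {
  les <- fixture_case()$lesions[[1]]
  id <- simulate_manual_contour(les, 0)
  expect_identical(id$mask, les$mask)

  c1 <- simulate_manual_contour(les, 2, seed = 1)
  c2 <- simulate_manual_contour(les, 2, seed = 2)
  mutual <- dice(c1$mask, c2$mask)
  expect_gt(mutual, 0)
  expect_lt(mutual, 1)

  d1 <- vapply(1:20, function(s)
    dice(simulate_manual_contour(les, 1, seed = s)$mask, les$mask), numeric(1))
  d2 <- vapply(1:20, function(s)
    dice(simulate_manual_contour(les, 2, seed = s)$mask, les$mask), numeric(1))
  expect_lt(mean(d2), mean(d1))
})

test_that("volumes round-trip through NIfTI with spacing intact", {
  case <- fixture_case()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(case$volumes$pet, path)
  back <- read_volume_nifti(path)
  expect_equal(back$spacing, case$volumes$pet$spacing, tolerance = 1e-6)
  expect_equal(back$data, case$volumes$pet$data, tolerance = 1e-6)
})
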