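#' Cohort specification for the digital prostate phantom
#'
#' Bundles every tunable of the synthetic cohort generator. The defaults emulate
#' the published validation cohort this package is designed to stress:
#' 35 patients in three imaging arms (68Ga-PSMA-PET/CT + mpMRI, 18F-PSMA-PET/CT
#' + mpMRI, 68Ga-PSMA-PET/MRI), prostate volumes with median 31 cc on 21-54 cc,
#' lesion SUVmax spanning roughly 1.9-21.4 with median about 8, lesions
#' occupying 6-75% of the gland, PSA with median 15.4 ng/mL, and Gleason grades
#' 6 to 9. Distributions are truncated log-normals parameterised by their median
#' and `sdlog`; `sdlog = 0` makes a quantity degenerate at its median, which the
#' oracle tests exploit.
#'
#' @param n_patients cohort size.
#' @param dim,spacing voxel grid (all modalities share it; `spacing` in mm,
#'   axial = third axis).
#' @param prostate_volume list `median_cc`, `sdlog`, `range_cc`.
#' @param lesion_count_probs named probabilities for the number of lesions.
#' @param lesion_relvol lesion volume as a fraction of prostate volume:
#'   `median`, `sdlog`, `range`.
#' @param lesion_suvmax assigned lesion SUVmax distribution.
#' @param gleason_probs named probabilities over `6, 7a, 7b, 8, 9`.
#' @param satellite_count_probs,satellite_relvol,satellite_suvmax small
#'   low-uptake satellite carcinoma foci accompanying the index lesions:
#'   biopsy can hit them, but their uptake sits near background so
#'   SUV-threshold contours usually miss them. They emulate the multifocality
#'   that makes positive biopsy locations exceed the imaged lesions, and they
#'   never meet the dominant-lesion criterion themselves.
#' @param psa,age patient covariate distributions.
#' @param background_suv uniform uptake inside the gland; must sit below every
#'   admissible lesion SUVmax.
#' @param outside_suv pelvic background outside the gland.
#' @param psf_fwhm_mm named per-modality Gaussian PSF FWHM (mm). PET defaults
#'   reflect clinical scanner resolution (18F slightly sharper than 68Ga);
#'   MRI-like channels are not blurred.
#' @param noise_sd additive noise SD (SUV), Gaussian truncated at zero after
#'   blurring.
#' @param arm_probs named probabilities of the three imaging arms.
#' @param lesion_profile `"ellipsoid"` (uniform uptake; default) or
#'   `"gaussian"` (radially decaying uptake).
#' @param seed integer; fixes the full cohort byte-for-byte.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_patients = 35,
    dim = c(56L, 56L, 24L),
    spacing = c(1.5, 1.5, 3.0),
    prostate_volume = list(median_cc = 31, sdlog = 0.25, range_cc = c(21, 54)),
    lesion_count_probs = c(`1` = 0.7, `2` = 0.3),
    lesion_relvol = list(median = 0.18, sdlog = 0.55, range = c(0.06, 0.75)),
    lesion_suvmax = list(median = 8.2, sdlog = 0.5, range = c(1.9, 21.4)),
    gleason_probs = c(`6` = 0.23, `7a` = 0.17, `7b` = 0.14, `8` = 0.28, `9` = 0.18),
    satellite_count_probs = c(`0` = 0.3, `1` = 0.4, `2` = 0.3),
    satellite_relvol = list(median = 0.02, sdlog = 0.5, range = c(0.005, 0.045)),
    satellite_suvmax = list(median = 2.0, sdlog = 0.3, range = c(1.0, 3.2)),
    psa = list(median = 15.4, sdlog = 0.9, range = c(0.6, 57.9)),
    age = list(median = 68, sd = 5, range = c(58, 77)),
    background_suv = 0.7,
    outside_suv = 0.2,
    psf_fwhm_mm = c(PET_GA68 = 6, PET_F18 = 5.5, T2W = 0, ADC = 0, DCE = 0),
    noise_sd = 0.1,
    arm_probs = c(ga_petct = 10 / 35, f18_petct = 16 / 35, ga_petmri = 9 / 35),
    lesion_profile = c("ellipsoid", "gaussian"),
    seed = 1L) {
  lesion_profile <- match.arg(lesion_profile)
  spec <- list(
    n_patients = as.integer(n_patients), dim = as.integer(dim),
    spacing = as.numeric(spacing), prostate_volume = prostate_volume,
    lesion_count_probs = lesion_count_probs, lesion_relvol = lesion_relvol,
    lesion_suvmax = lesion_suvmax, gleason_probs = gleason_probs,
    satellite_count_probs = satellite_count_probs,
    satellite_relvol = satellite_relvol, satellite_suvmax = satellite_suvmax,
    psa = psa, age = age, background_suv = background_suv,
    outside_suv = outside_suv, psf_fwhm_mm = psf_fwhm_mm,
    noise_sd = noise_sd, arm_probs = arm_probs,
    lesion_profile = lesion_profile, seed = as.integer(seed)
  )
  nums <- unlist(spec[c("spacing", "prostate_volume", "lesion_relvol",
                        "lesion_suvmax", "psa", "age", "background_suv",
                        "outside_suv", "psf_fwhm_mm", "noise_sd")])
  if (any(!is.finite(nums))) abort("all distribution parameters must be finite")
  if (any(spec$spacing <= 0)) abort("voxel spacing must be positive")
  if (spec$background_suv >= spec$lesion_suvmax$range[1])
    abort("background SUV must lie below the smallest admissible lesion SUVmax")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients, grid %s @ (%g, %g, %g) mm, seed %d\n",
              x$n_patients, paste(x$dim, collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3], x$seed))
  invisible(x)
}

# Deterministic per-case RNG stream seed, kept inside 32-bit integer range.
case_seed <- function(seed, case_index) {
  as.integer((abs(as.numeric(seed)) %% 50021) * 40013 +
               as.numeric(case_index) * 7919) %% 2147483629L + 1L
}

# Truncated log-normal draws parameterised by median; sdlog = 0 is degenerate.
rtrunc_lnorm <- function(n, median, sdlog, range) {
  if (sdlog <= 0) return(rep(min(max(median, range[1]), range[2]), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n * 2 + 8, meanlog = log(median), sdlog = sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

rtrunc_norm <- function(n, mean, sd, range) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n * 2 + 8, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Construct prostate anatomy on a voxel grid
#'
#' Builds an ellipsoidal gland whose discretized mask hits the target volume to
#' sub-voxel accuracy: the normalized-radius field is thresholded at the order
#' statistic matching the target voxel count, so `prostate_volume_cc` equals
#' `target_cc` within one voxel volume. Regions (apex/mid/base) split the mask
#' into equal thirds of its cranio-caudal extent (apex caudal); the transition
#' zone is a co-centred inner ellipsoid (62% in-plane, 95% axially), the
#' peripheral zone the remainder.
#'
#' @param dim,spacing voxel grid.
#' @param target_cc target gland volume (cc).
#' @param center_mm gland centre; defaults to the grid centre plus a small
#'   sub-voxel jitter (breaks grid-aligned discretization ties).
#' @param axis_ratios relative semi-axes (lateral, antero-posterior, axial).
#' @return An object of class `prostate_anatomy`: `mask`, `region` (1 apex,
#'   2 mid, 3 base), `zone` (1 peripheral, 2 transition), `spacing`,
#'   `center_mm`, `semi_axes_mm`, `prostate_volume_cc`.
#' @export
make_anatomy <- function(dim, spacing, target_cc, center_mm = NULL,
                         axis_ratios = c(1, 0.85, 1.1)) {
  dim <- as.integer(dim)
  co <- coord_arrays(dim, spacing)
  if (is.null(center_mm))
    center_mm <- (dim - 1) * spacing / 2 + runif(3, -0.45, 0.45) * spacing
  vox_cc <- voxel_volume_cc(spacing)
  target_vox <- max(27L, as.integer(round(target_cc / vox_cc)))
  a0 <- (3 * target_cc * 1000 / (4 * pi * prod(axis_ratios)))^(1 / 3)
  semi <- a0 * axis_ratios
  rho <- sqrt(((co$x - center_mm[1]) / semi[1])^2 +
                ((co$y - center_mm[2]) / semi[2])^2 +
                ((co$z - center_mm[3]) / semi[3])^2)
  if (target_vox > length(rho)) abort("grid too small for the requested gland volume")
  th <- sort(rho, partial = target_vox)[target_vox]
  mask <- array(rho <= th, dim)
  semi_eff <- semi * th

  zv <- co$z[mask]
  zr <- range(zv)
  b <- zr[1] + diff(zr) * c(1, 2) / 3
  region <- array(0L, dim)
  region[mask] <- ifelse(co$z[mask] <= b[1], 1L, ifelse(co$z[mask] <= b[2], 2L, 3L))

  rho_t <- sqrt(((co$x - center_mm[1]) / (0.62 * semi_eff[1]))^2 +
                  ((co$y - center_mm[2]) / (0.62 * semi_eff[2]))^2 +
                  ((co$z - center_mm[3]) / (0.95 * semi_eff[3]))^2)
  zone <- array(0L, dim)
  zone[mask] <- ifelse(rho_t[mask] <= 1, 2L, 1L)

  structure(
    list(mask = mask, region = region, zone = zone, spacing = spacing,
         center_mm = center_mm, semi_axes_mm = semi_eff,
         prostate_volume_cc = sum(mask) * vox_cc, rho = rho),
    class = "prostate_anatomy"
  )
}

#' @export
print.prostate_anatomy <- function(x, ...) {
  cat(sprintf("<prostate_anatomy> %.1f cc (%d voxels), semi-axes (%.1f, %.1f, %.1f) mm\n",
              x$prostate_volume_cc, sum(x$mask),
              x$semi_axes_mm[1], x$semi_axes_mm[2], x$semi_axes_mm[3]))
  invisible(x)
}

#' Derive anatomy labels from an existing prostate mask
#'
#' For user-supplied or hand-built masks: estimates the centre and semi-axes
#' from the mask extents, then applies the same region/zone recipe as
#' [make_anatomy()].
#' @param mask 3D logical array.
#' @param spacing voxel spacing (mm).
#' @export
anatomy_from_mask <- function(mask, spacing) {
  if (!any(mask)) abort("empty prostate mask")
  dim <- dim(mask)
  co <- coord_arrays(dim, spacing)
  center <- c(mean(co$x[mask]), mean(co$y[mask]), mean(co$z[mask]))
  semi <- c(diff(range(co$x[mask])), diff(range(co$y[mask])),
            diff(range(co$z[mask]))) / 2
  semi <- pmax(semi, spacing)
  rho <- sqrt(((co$x - center[1]) / semi[1])^2 +
                ((co$y - center[2]) / semi[2])^2 +
                ((co$z - center[3]) / semi[3])^2)
  zv <- co$z[mask]
  zr <- range(zv)
  b <- zr[1] + diff(zr) * c(1, 2) / 3
  region <- array(0L, dim)
  region[mask] <- ifelse(co$z[mask] <= b[1], 1L, ifelse(co$z[mask] <= b[2], 2L, 3L))
  rho_t <- sqrt(((co$x - center[1]) / (0.62 * semi[1]))^2 +
                  ((co$y - center[2]) / (0.62 * semi[2]))^2 +
                  ((co$z - center[3]) / (0.95 * semi[3]))^2)
  zone <- array(0L, dim)
  zone[mask] <- ifelse(rho_t[mask] <= 1, 2L, 1L)
  structure(
    list(mask = mask, region = region, zone = zone, spacing = spacing,
         center_mm = center, semi_axes_mm = semi,
         prostate_volume_cc = sum(mask) * voxel_volume_cc(spacing), rho = rho),
    class = "prostate_anatomy"
  )
}

region_names <- c("apex", "mid", "base")
zone_names <- c("peripheral", "transition")
gleason_levels <- c("6", "7a", "7b", "8", "9")

# Place one lesion: ellipsoid-of-target-volume intersected with the gland, with
# the iso-level chosen by order statistics so the voxel count is exact. Retries
# re-draw the centre when the iso-level has to inflate too far (lesion would be
# badly truncated) or when it would overlap an earlier lesion.
place_lesion <- function(anatomy, relvol, occupied, max_tries = 200) {
  dim <- dim(anatomy$mask)
  spacing <- anatomy$spacing
  co <- coord_arrays(dim, spacing)
  n_prost <- sum(anatomy$mask)
  target_vox <- max(4L, as.integer(round(relvol * n_prost)))
  target_cc <- target_vox * voxel_volume_cc(spacing)
  max_inflate <- if (relvol > 0.5) 2.0 else if (relvol > 0.25) 1.6 else 1.35
  cand <- which(anatomy$mask & anatomy$rho <= (if (relvol > 0.35) 0.45 else 0.8))
  if (length(cand) == 0) cand <- which(anatomy$mask)
  for (try in seq_len(max_tries)) {
    ratios <- runif(3, 0.75, 1.3)
    ratios <- ratios / prod(ratios)^(1 / 3)
    a0 <- (3 * target_cc * 1000 / (4 * pi))^(1 / 3)
    semi <- a0 * ratios
    idx <- arrayInd(sample(cand, 1), dim)
    center <- (idx - 1) * spacing + runif(3, -0.4, 0.4) * spacing
    rho_l <- sqrt(((co$x - center[1]) / semi[1])^2 +
                    ((co$y - center[2]) / semi[2])^2 +
                    ((co$z - center[3]) / semi[3])^2)
    vals <- rho_l[anatomy$mask]
    if (target_vox > length(vals)) next
    th <- sort(vals, partial = target_vox)[target_vox]
    if (th > max_inflate) next
    mask_l <- anatomy$mask & rho_l <= th
    if (sum(mask_l) != target_vox) next  # order-statistic tie; re-draw centre
    if (any(mask_l & occupied)) next
    return(list(mask = mask_l, center_mm = center, semi_axes_mm = semi * th,
                rho = rho_l, iso = th, n_voxels = target_vox))
  }
  abort("could not place a lesion inside the prostate: infeasible cohort spec")
}

#' Generate one synthetic patient case
#'
#' Draws anatomy, ground-truth lesions and covariates for case `case_index` of
#' the cohort, then renders the imaging channels: the PET volume is background
#' plus lesion uptake (pre-blur lesion peak equals the assigned SUVmax),
#' convolved with the per-modality Gaussian PSF and degraded with zero-truncated
#' Gaussian noise; T2W/ADC show lesions hypo-intense and DCE hyper-intense.
#' Identical `(spec, case_index)` reproduce the case bit-for-bit regardless of
#' the caller's RNG state.
#'
#' @param spec a [cohort_spec()].
#' @param case_index 1-based case number, at most `spec$n_patients`.
#' @return An object of class `phantom_case`: `case_id`, `arm`, `tracer`,
#'   `volumes` (named `image_volume` list: `pet`, `t2w`, `adc`, `dce`),
#'   `anatomy`, `lesions` (list with per-lesion `mask` and parameters),
#'   `lesion_table` (tibble, one row per lesion), `covariates` (1-row tibble).
#' @export
generate_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (case_index < 1 || case_index > spec$n_patients)
    abort("`case_index` must be in 1..n_patients")
  withr::with_seed(case_seed(spec$seed, case_index), {
    dim <- spec$dim
    spacing <- spec$spacing
    vol_cc <- rtrunc_lnorm(1, spec$prostate_volume$median_cc,
                           spec$prostate_volume$sdlog,
                           spec$prostate_volume$range_cc)
    anatomy <- make_anatomy(dim, spacing, vol_cc)
    arm <- sample(names(spec$arm_probs), 1, prob = spec$arm_probs)
    tracer <- if (grepl("^f18", arm)) "PET_F18" else "PET_GA68"
    psa <- rtrunc_lnorm(1, spec$psa$median, spec$psa$sdlog, spec$psa$range)
    age <- round(rtrunc_norm(1, spec$age$median, spec$age$sd, spec$age$range))

    n_les <- as.integer(sample(names(spec$lesion_count_probs), 1,
                               prob = spec$lesion_count_probs))
    occupied <- array(FALSE, dim)
    lesions <- list()
    for (li in seq_len(n_les)) {
      rv <- rtrunc_lnorm(1, spec$lesion_relvol$median, spec$lesion_relvol$sdlog,
                         spec$lesion_relvol$range)
      if (li == 2L) {
        first_rv <- lesions[[1]]$relvol
        if (first_rv > 0.55) break
        rv <- min(rv, max(0.06, 0.75 - first_rv - 0.1))
      }
      pl <- if (li == 1L) place_lesion(anatomy, rv, occupied) else
        tryCatch(place_lesion(anatomy, rv, occupied), error = function(e) NULL)
      if (is.null(pl)) break
      occupied <- occupied | pl$mask
      suv <- rtrunc_lnorm(1, spec$lesion_suvmax$median, spec$lesion_suvmax$sdlog,
                          spec$lesion_suvmax$range)
      gs <- sample(gleason_levels, 1, prob = spec$gleason_probs)
      cidx <- pmin(pmax(round(pl$center_mm / spacing) + 1, 1), dim)
      pl$relvol <- pl$n_voxels / sum(anatomy$mask)
      pl$volume_cc <- pl$n_voxels * voxel_volume_cc(spacing)
      pl$suvmax <- suv
      pl$gleason <- gs
      pl$region <- region_names[anatomy$region[cidx[1], cidx[2], cidx[3]]]
      pl$zone <- zone_names[anatomy$zone[cidx[1], cidx[2], cidx[3]]]
      pl$id <- li
      pl$spacing <- spacing
      pl$satellite <- FALSE
      lesions[[li]] <- pl
    }

    n_sat <- as.integer(sample(names(spec$satellite_count_probs), 1,
                               prob = spec$satellite_count_probs))
    for (si in seq_len(n_sat)) {
      rv <- rtrunc_lnorm(1, spec$satellite_relvol$median,
                         spec$satellite_relvol$sdlog, spec$satellite_relvol$range)
      pl <- tryCatch(place_lesion(anatomy, rv, occupied),
                     error = function(e) NULL)
      if (is.null(pl)) next
      occupied <- occupied | pl$mask
      cidx <- pmin(pmax(round(pl$center_mm / spacing) + 1, 1), dim)
      pl$relvol <- pl$n_voxels / sum(anatomy$mask)
      pl$volume_cc <- pl$n_voxels * voxel_volume_cc(spacing)
      pl$suvmax <- rtrunc_lnorm(1, spec$satellite_suvmax$median,
                                spec$satellite_suvmax$sdlog,
                                spec$satellite_suvmax$range)
      pl$gleason <- sample(gleason_levels, 1,
                           prob = c(0.5, 0.3, 0.1, 0.07, 0.03))
      pl$region <- region_names[anatomy$region[cidx[1], cidx[2], cidx[3]]]
      pl$zone <- zone_names[anatomy$zone[cidx[1], cidx[2], cidx[3]]]
      pl$id <- length(lesions) + 1L
      pl$spacing <- spacing
      pl$satellite <- TRUE
      lesions[[pl$id]] <- pl
    }

    # PET: uniform background inside the gland, lesion uptake overlaid with
    # max() semantics so the pre-blur peak is the assigned SUVmax exactly.
    pet_arr <- array(spec$outside_suv, dim)
    pet_arr[anatomy$mask] <- spec$background_suv
    for (l in lesions) {
      if (spec$lesion_profile == "ellipsoid") {
        pet_arr[l$mask] <- pmax(pet_arr[l$mask], l$suvmax)
      } else {
        up <- l$suvmax * exp(-0.5 * (2 * l$rho / l$iso)^2)
        pet_arr <- pmax(pet_arr, up * (l$rho <= l$iso * 1.5))
      }
    }
    pet_arr <- gaussian_blur_mm(pet_arr, spec$psf_fwhm_mm[[tracer]], spacing)
    if (spec$noise_sd > 0)
      pet_arr <- pmax(pet_arr + rnorm(length(pet_arr), 0, spec$noise_sd), 0)
    pet <- image_volume(pet_arr, spacing, tracer)

    lesion_union <- occupied
    mri <- function(outside, gland, trans_shift, lesion_val, noise, modality) {
      a <- array(outside, dim)
      a[anatomy$mask] <- gland
      a[anatomy$zone == 2L] <- gland + trans_shift
      a[lesion_union] <- lesion_val
      fw <- spec$psf_fwhm_mm[[modality]]
      if (fw > 0) a <- gaussian_blur_mm(a, fw, spacing)
      if (noise > 0) a <- pmax(a + rnorm(length(a), 0, noise), 0)
      image_volume(a, spacing, modality)
    }
    t2w <- mri(30, 100, -20, 55, 4, "T2W")
    adc <- mri(600, 1300, -150, 750, 30, "ADC")
    dce <- mri(15, 40, 5, 85, 2, "DCE")

    lesion_table <- purrr::map_dfr(lesions, function(l) {
      tibble::tibble(
        case_id = case_index, lesion_id = l$id,
        center_x_mm = l$center_mm[1], center_y_mm = l$center_mm[2],
        center_z_mm = l$center_mm[3],
        volume_cc = l$volume_cc, relvol = l$relvol,
        suvmax_assigned = l$suvmax, gleason = l$gleason,
        region = l$region, zone = l$zone, satellite = l$satellite,
        dominant = l$volume_cc >= 1 & l$suvmax >= 3 & !l$satellite
      )
    })
    covariates <- tibble::tibble(
      case_id = case_index, arm = arm, tracer = tracer, age = age, psa = psa,
      prostate_volume_cc = anatomy$prostate_volume_cc,
      n_lesions = length(lesions),
      suvmax_observed = max(pet_arr[anatomy$mask])
    )
    structure(
      list(case_id = case_index, arm = arm, tracer = tracer,
           volumes = list(pet = pet, t2w = t2w, adc = adc, dce = dce),
           anatomy = anatomy, lesions = lesions, lesion_table = lesion_table,
           covariates = covariates),
      class = "phantom_case"
    )
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> #%d arm=%s, prostate %.1f cc, %d lesion(s)\n",
              x$case_id, x$arm, x$anatomy$prostate_volume_cc, length(x$lesions)))
  invisible(x)
}

#' Generate a full cohort
#'
#' @param spec a [cohort_spec()].
#' @param cases which case indices to generate (default all).
#' @return List with `cases` (list of `phantom_case`), `covariates` and
#'   `lesions` tibbles bound across cases.
#' @export
generate_cohort <- function(spec, cases = seq_len(spec$n_patients)) {
  cs <- lapply(cases, function(i) generate_case(spec, i))
  list(cases = cs,
       covariates = purrr::map_dfr(cs, "covariates"),
       lesions = purrr::map_dfr(cs, "lesion_table"))
}

#' Simulate a manual contour of a lesion
#'
#' Emulates a human reader delineating a known lesion: the true mask is warped
#' by a smooth random displacement field whose root-mean-square magnitude is
#' `observer_noise_mm` (correlation length `correlation_mm`), standing in for
#' interobserver variability. Zero noise returns the true mask unchanged.
#'
#' @param lesion a lesion from [generate_case()] (uses its `mask`/`spacing`), or
#'   a bare logical array with `spacing` supplied.
#' @param observer_noise_mm RMS boundary displacement (mm), non-negative.
#' @param spacing voxel spacing (mm), required for bare arrays.
#' @param seed optional integer; when given, the perturbation is drawn from an
#'   isolated RNG stream.
#' @param correlation_mm smoothness of the displacement field.
#' @param modality modality tag recorded on the returned contour.
#' @return An `ipl_contour` with `method = "manual_sim"`.
#' @export
simulate_manual_contour <- function(lesion, observer_noise_mm, spacing = NULL,
                                    seed = NULL, correlation_mm = 6,
                                    modality = "PET_GA68") {
  if (is.list(lesion) && !is.null(lesion$mask)) {
    mask <- lesion$mask
    if (is.null(spacing)) spacing <- lesion$spacing
  } else {
    mask <- lesion
  }
  if (is.null(spacing)) abort("`spacing` required")
  if (observer_noise_mm < 0) abort("`observer_noise_mm` must be >= 0")
  if (observer_noise_mm == 0)
    return(new_contour(mask, spacing, modality, "manual_sim", NA_real_))
  draw <- function() {
    d <- dim(mask)
    comp <- lapply(1:3, function(a) {
      w <- array(rnorm(prod(d)), d)
      s <- gaussian_blur_mm(w, correlation_mm, spacing)
      s / sqrt(mean(s^2))
    })
    scl <- observer_noise_mm / sqrt(3)
    si <- pmin(pmax(slice.index(mask, 1) - round(comp[[1]] * scl / spacing[1]), 1L), d[1])
    sj <- pmin(pmax(slice.index(mask, 2) - round(comp[[2]] * scl / spacing[2]), 1L), d[2])
    sk <- pmin(pmax(slice.index(mask, 3) - round(comp[[3]] * scl / spacing[3]), 1L), d[3])
    array(mask[cbind(as.vector(si), as.vector(sj), as.vector(sk))], d)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  new_contour(out, spacing, modality, "manual_sim", NA_real_)
}

#' Write one phantom case to disk
#'
#' Volumes and label maps go out as NIfTI, the lesion ground truth and
#' covariates as CSV.
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case_nifti <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(dir, sprintf("case%03d", case$case_id))
  for (nm in names(case$volumes))
    write_volume_nifti(case$volumes[[nm]], paste0(pre, "_", nm, ".nii.gz"))
  sp <- case$anatomy$spacing
  write_volume_nifti(array(as.integer(case$anatomy$mask), dim(case$anatomy$mask)),
                     paste0(pre, "_prostate_mask.nii.gz"), spacing = sp)
  write_volume_nifti(case$anatomy$region, paste0(pre, "_region.nii.gz"), spacing = sp)
  write_volume_nifti(case$anatomy$zone, paste0(pre, "_zone.nii.gz"), spacing = sp)
  readr::write_csv(case$lesion_table, paste0(pre, "_lesions.csv"))
  readr::write_csv(case$covariates, paste0(pre, "_covariates.csv"))
  invisible(dir)
}
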