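# Radial outline of a 2D mask slice: max radius per angular bin around the
# gland axis, giving a closed polygon suitable for outline registration.
slice_outline <- function(mask2d, spacing, center_xy, n_angles = 48) {
  sel <- which(mask2d, arr.ind = TRUE)
  if (nrow(sel) < 8) abort("slice mask too small for an outline")
  px <- (sel[, 1] - 1) * spacing[1] - center_xy[1]
  py <- (sel[, 2] - 1) * spacing[2] - center_xy[2]
  th <- atan2(py, px)
  r <- sqrt(px^2 + py^2)
  breaks <- seq(-pi, pi, length.out = n_angles + 1)
  bin <- cut(th, breaks, include.lowest = TRUE, labels = FALSE)
  rad <- vapply(seq_len(n_angles), function(b) {
    rb <- r[bin == b]
    if (length(rb) == 0) NA_real_ else max(rb) + 0.5 * mean(spacing[1:2])
  }, numeric(1))
  if (anyNA(rad)) {  # fill empty bins by circular interpolation
    idx <- which(!is.na(rad))
    rad <- approx(c(idx, idx + n_angles), rep(rad[idx], 2),
                  xout = seq_len(n_angles) + n_angles, rule = 2)$y
  }
  mid <- (breaks[-1] + breaks[-(n_angles + 1)]) / 2
  cbind(x = center_xy[1] + rad * cos(mid), y = center_xy[2] + rad * sin(mid))
}

threshold_label <- function(value, type) {
  if (type == "absolute") sprintf("SUV%.1f", value) else
    sprintf("SUV%d%%", round(100 * value))
}

# Union of contour-component masks that touch a given ground-truth lesion.
components_for_lesion <- function(contours, lesion_mask) {
  hit <- purrr::keep(contours, function(ct) any(ct$mask & lesion_mask))
  if (length(hit) == 0) return(NULL)
  out <- hit[[1]]$mask
  for (ct in hit[-1]) out <- out | ct$mask
  out
}

#' Run the full validation study on a synthetic cohort
#'
#' Executes, per case: phantom generation, sector-map construction, biopsy
#' simulation, automatic SUV-threshold and simulated manual contouring,
#' margin-expanded sector-level scoring, and (optionally) a per-region
#' outline-registration quality check. Scoring unit is the dominant
#' ground-truth lesion (true volume >= 1 cc and assigned SUVmax >= 3); a case
#' without one is excluded, mirroring the study inclusion rule. The manual
#' mpMRI arm additionally misses small lesions with probability
#' `exp(-relvol / mpmri_detect_scale)` before contouring, standing in for the
#' lower sensitivity of mpMRI reading.
#'
#' @param spec a [cohort_spec()].
#' @param thresholds fractional SUVmax thresholds (default 40-80%).
#' @param abs_thresholds absolute SUV thresholds (default 3.0).
#' @param margin_mm margin added to contours before sector overlap.
#' @param tau minimum sector overlap fraction (see [sectorize_contour()]).
#' @param scheme a [biopsy_scheme()].
#' @param manual_noise_mm named RMS observer noise: `pet_man`, `petmri_man`,
#'   `mpmri_man` (mpMRI readers are noisier).
#' @param mpmri_detect_scale relative-volume scale of the mpMRI miss model.
#' @param unsampled scoring policy for unsampled sectors.
#' @param cases case indices to run.
#' @param registration_check fit the schematic outline to each region's
#'   central slice (rigid + thin-plate-spline) and record residuals.
#' @return An object of class `ipl_study`.
#' @export
run_study <- function(spec = cohort_spec(),
                      thresholds = c(0.4, 0.5, 0.6, 0.7, 0.8),
                      abs_thresholds = 3.0, margin_mm = 5, tau = 0,
                      scheme = biopsy_scheme(),
                      manual_noise_mm = c(pet_man = 1.5, petmri_man = 1.2,
                                          mpmri_man = 3.0),
                      mpmri_detect_scale = 0.15,
                      unsampled = c("negative", "exclude"),
                      cases = seq_len(spec$n_patients),
                      registration_check = TRUE) {
  unsampled <- match.arg(unsampled)
  records <- list()
  registration <- list()
  excluded <- integer(0)

  for (ci in cases) {
    case <- generate_case(spec, ci)
    dom <- dplyr::filter(case$lesion_table, .data$dominant)
    if (nrow(dom) == 0) {
      excluded <- c(excluded, ci)
      next
    }
    map <- build_sector_map(case$anatomy)
    map <- simulate_biopsy(map, case$anatomy, case$lesions, scheme,
                           seed = case_seed(spec$seed + 101L, ci))

    add_record <- function(lesion, method, contour_type, threshold, predicted) {
      sc <- score_sectors(predicted, map, unsampled)
      records[[length(records) + 1]] <<- dplyr::bind_cols(
        tibble::tibble(case_id = ci, lesion_id = lesion$id, arm = case$arm,
                       tracer = case$tracer, method = method,
                       contour_type = contour_type, threshold = threshold),
        sc,
        tibble::tibble(region = lesion$region, zone = lesion$zone,
                       relvol = lesion$relvol, gleason = lesion$gleason,
                       psa = case$covariates$psa,
                       suvmax = lesion$suvmax,
                       prostate_volume_cc = case$anatomy$prostate_volume_cc))
    }
    dom_lesions <- case$lesions[dom$lesion_id]

    thr_tbl <- dplyr::bind_rows(
      tibble::tibble(value = abs_thresholds, type = "absolute"),
      tibble::tibble(value = thresholds, type = "fraction"))
    for (ti in seq_len(nrow(thr_tbl))) {
      tv <- thr_tbl$value[ti]
      ty <- thr_tbl$type[ti]
      cts <- auto_contour(case$volumes$pet, case$anatomy, tv, ty)
      for (lesion in dom_lesions) {
        um <- components_for_lesion(cts, lesion$mask)
        predicted <- if (is.null(um)) integer(0) else
          sectorize_contour(um, map, margin_mm, tau)
        add_record(lesion, threshold_label(tv, ty), "auto", tv, predicted)
      }
    }

    seed_m <- case_seed(spec$seed + 202L, ci)
    withr::with_seed(seed_m, {
      pet_noise <- if (case$arm == "ga_petmri") manual_noise_mm[["petmri_man"]]
        else manual_noise_mm[["pet_man"]]
      for (lesion in dom_lesions) {
        mc <- simulate_manual_contour(lesion, pet_noise,
                                      modality = case$tracer)
        add_record(lesion, "PET_man", "manual", NA_real_,
                   sectorize_contour(mc, map, margin_mm, tau))
      }
      if (case$arm != "ga_petmri") {
        for (lesion in dom_lesions) {
          detected <- runif(1) >= exp(-lesion$relvol / mpmri_detect_scale)
          predicted <- integer(0)
          if (detected) {
            mc <- simulate_manual_contour(lesion,
                                          manual_noise_mm[["mpmri_man"]],
                                          modality = "T2W")
            predicted <- sectorize_contour(mc, map, margin_mm, tau)
          }
          add_record(lesion, "mpMRI_man", "manual", NA_real_, predicted)
        }
      }
    })

    if (registration_check) {
      for (r in 1:3) {
        zs <- which(apply(case$anatomy$region == r, 3, any))
        sl <- zs[ceiling(length(zs) / 2)]
        m2 <- case$anatomy$mask[, , sl] & case$anatomy$region[, , sl] == r
        reg <- tryCatch({
          pat <- slice_outline(m2, spec$spacing, c(0, 0))
          sch <- map$polygons[[region_names[r]]]$outline
          sch_pat <- sweep(sch, 2, case$anatomy$center_mm[1:2], "+")
          rg <- fit_rigid(sch_pat, pat, allow_scale = TRUE)
          wp <- fit_deformation(apply_rigid(rg, sch_pat), pat, n_control = 16)
          dense <- warp_points(wp, apply_rigid(rg, resample_closed(sch_pat, 96)))
          resid <- mean(point_to_ring_dist(dense[, 1], dense[, 2], pat))
          tibble::tibble(case_id = ci, region = region_names[r],
                         rigid_rmsd_mm = rg$rmsd, warp_residual_mm = resid)
        }, error = function(e) {
          tibble::tibble(case_id = ci, region = region_names[r],
                         rigid_rmsd_mm = NA_real_, warp_residual_mm = NA_real_)
        })
        registration[[length(registration) + 1]] <- reg
      }
    }
  }

  records <- dplyr::bind_rows(records)
  if (nrow(records) == 0) abort("no scorable lesions in the requested cases")
  summary_method <- aggregate_metrics(records, by = "method")
  summary_arm <- aggregate_metrics(records, by = c("arm", "method"))

  frac <- records |>
    dplyr::filter(.data$contour_type == "auto", !is.na(.data$threshold),
                  .data$threshold <= 1) |>
    aggregate_metrics(by = "threshold") |>
    dplyr::arrange(.data$threshold)
  best <- best_threshold(frac$threshold, frac$dsc_mean, frac$yi_mean,
                         frac$specificity_mean)

  ft <- factor_table(dplyr::filter(records, .data$contour_type == "auto",
                                   .data$threshold %in% as.numeric(best)))
  factors <- factor_correlation(ft)
  comparisons <- tryCatch(
    compare_methods(dplyr::filter(records, .data$contour_type == "auto")),
    error = function(e) NULL)

  structure(
    list(records = records, summary_by_method = summary_method,
         summary_by_arm = summary_arm, threshold_profile = frac,
         best_threshold = best, factor_records = ft, factors = factors,
         comparisons = comparisons,
         registration = dplyr::bind_rows(registration),
         excluded_cases = excluded, spec = spec, margin_mm = margin_mm),
    class = "ipl_study"
  )
}

#' @export
print.ipl_study <- function(x, ...) {
  cat(sprintf("<ipl_study> %d records, %d cases scored (%d excluded)\n",
              nrow(x$records), dplyr::n_distinct(x$records$case_id),
              length(x$excluded_cases)))
  cat(sprintf("  best automatic threshold: SUV%d%% (mean DSC %.3f)\n",
              round(100 * as.numeric(x$best_threshold)),
              max(x$threshold_profile$dsc_mean)))
  invisible(x)
}

#' Write study reports to disk
#'
#' Tidy per-lesion records, per-method and per-arm summaries, the
#' factor-correlation table and a JSON manifest (seed + configuration hash).
#' Output is byte-deterministic for a fixed spec and seed.
#'
#' @param study an `ipl_study`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study_reports <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$records, file.path(dir, "records.csv"))
  readr::write_csv(study$summary_by_method, file.path(dir, "summary_by_method.csv"))
  readr::write_csv(study$summary_by_arm, file.path(dir, "summary_by_arm.csv"))
  readr::write_csv(study$threshold_profile, file.path(dir, "threshold_profile.csv"))
  readr::write_csv(study$factors, file.path(dir, "factor_correlations.csv"))
  if (nrow(study$registration) > 0)
    readr::write_csv(study$registration, file.path(dir, "registration_quality.csv"))
  manifest <- list(
    seed = study$spec$seed,
    n_patients = study$spec$n_patients,
    margin_mm = study$margin_mm,
    best_threshold = as.numeric(study$best_threshold),
    excluded_cases = study$excluded_cases,
    spec_hash = rlang::hash(study$spec)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
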