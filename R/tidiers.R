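#' Tidy and glance methods for study objects
#'
#' `tidy()` returns the per-lesion, per-method record table; `glance()` a
#' one-row cohort summary.
#'
#' @param x an `ipl_study`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.ipl_study <- function(x, ...) x$records

#' @rdname tidy.ipl_study
#' @export
glance.ipl_study <- function(x, ...) {
  best <- as.numeric(x$best_threshold)
  at_best <- dplyr::filter(x$threshold_profile, .data$threshold == best)
  tibble::tibble(
    n_cases = dplyr::n_distinct(x$records$case_id),
    n_excluded = length(x$excluded_cases),
    n_lesions = dplyr::n_distinct(paste(x$records$case_id, x$records$lesion_id)),
    best_threshold = best,
    best_concordant = isTRUE(attr(x$best_threshold, "concordant")),
    dsc_at_best = at_best$dsc_mean,
    yi_at_best = at_best$yi_mean,
    sensitivity_at_best = at_best$sensitivity_mean,
    specificity_at_best = at_best$specificity_mean
  )
}

#' @rdname tidy.ipl_study
#' @export
tidy.rigid2d <- function(x, ...) {
  tibble::tibble(term = c("tx_mm", "ty_mm", "theta_rad", "scale"),
                 estimate = c(x$tx, x$ty, x$theta, x$scale))
}

#' @rdname tidy.ipl_study
#' @export
tidy.tps_warp <- function(x, ...) {
  tibble::tibble(control = seq_len(nrow(x$src)),
                 src_x = x$src[, 1], src_y = x$src[, 2],
                 dst_x = x$dst[, 1], dst_y = x$dst[, 2],
                 displacement_mm = sqrt(rowSums((x$dst - x$src)^2)))
}
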