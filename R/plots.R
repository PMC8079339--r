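#' Threshold trade-off plot
#'
#' Mean DSC, Youden index, sensitivity and specificity as a function of the
#' fractional SUVmax threshold, the operating-point picture behind
#' best-threshold selection.
#'
#' @param profile the `threshold_profile` tibble of an `ipl_study` (or any
#'   tibble from [aggregate_metrics()] grouped by `threshold`).
#' @return A ggplot object.
#' @export
plot_threshold_profile <- function(profile) {
  long <- profile |>
    dplyr::select("threshold", dplyr::ends_with("_mean")) |>
    tidyr::pivot_longer(-"threshold", names_to = "metric",
                        values_to = "mean") |>
    dplyr::mutate(metric = sub("_mean$", "", .data$metric))
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$mean,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "fraction of prostate SUVmax", y = "cohort mean",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ipl_study <- function(object, ...) {
  plot_threshold_profile(object$threshold_profile)
}

#' Factor-correlation plot
#'
#' Point-biserial correlation of each factor stratum with per-lesion DSC.
#' @param factors tibble from [factor_correlation()].
#' @return A ggplot object.
#' @export
plot_factor_correlation <- function(factors) {
  df <- dplyr::filter(factors, !is.na(.data$r))
  ggplot2::ggplot(df, ggplot2::aes(.data$stratum, .data$r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Pearson r with DSC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Schematic sector map plot
#'
#' Draws the twelve schematic polygons of one region, coloured by biopsy
#' status when the map is labelled.
#' @param object a `sector_map`.
#' @param region which schematic plane to draw.
#' @param ... unused.
#' @export
autoplot.sector_map <- function(object, region = "mid", ...) {
  region <- match.arg(region, region_names)
  ridx <- match(region, region_names)
  polys <- object$polygons[[region]]$sectors
  df <- purrr::imap_dfr(polys, function(p, seg) {
    sid <- (ridx - 1L) * 12L + seg
    tibble::tibble(x = p[, 1], y = p[, 2], segment = seg,
                   status = as.character(object$sectors$biopsy_status[sid]))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$segment,
                                   fill = .data$status)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(positive = "firebrick",
                                          negative = "palegreen3",
                                          unsampled = "grey85"),
                               na.value = "grey85") +
    ggplot2::labs(title = paste0(region, " sector plane"), x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}
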