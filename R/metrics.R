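#' Sector-level classification metrics from confusion counts
#'
#' Standard formulas over the 36 sectors of one case: Dice similarity
#' coefficient `2TP / (2TP + FP + FN)`, sensitivity `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)` and Youden index
#' `sensitivity + specificity - 1`. Undefined ratios (zero denominators) are
#' reported as `NA` rather than an error; a case with no biopsy-positive
#' sector has undefined sensitivity and is flagged downstream.
#'
#' @param tp,fp,fn,tn non-negative integer vectors (vectorised).
#' @return Tibble with columns `tp, fp, fn, tn, dsc, sensitivity, specificity,
#'   yi`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  dsc <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn, dsc = dsc,
                 sensitivity = sens, specificity = spec, yi = sens + spec - 1)
}

#' Predicted-positive sectors of a contour
#'
#' A sector is predicted positive when the margin-expanded contour overlaps its
#' voxel set by at least the fraction `tau` (default `tau = 0`: any overlap).
#' This is the sector-level projection of an image-defined lesion, the step
#' that makes a contour comparable with the biopsy reference.
#'
#' @param contour an `ipl_contour` or bare logical mask on the sector map's
#'   grid.
#' @param map a `sector_map`.
#' @param margin_mm isotropic margin added to the contour before overlap
#'   (default 5 mm, matching the margin added to image-defined lesions).
#' @param tau minimum overlapped voxel fraction of a sector.
#' @return Integer vector of predicted-positive sector ids (possibly empty).
#' @export
sectorize_contour <- function(contour, map, margin_mm = 5, tau = 0) {
  mask <- if (inherits(contour, "ipl_contour")) contour$mask else contour
  if (!any(mask)) return(integer(0))
  ex <- expand_margin(mask, margin_mm, map$spacing)
  hit <- map$assignment[ex & map$assignment > 0]
  if (length(hit) == 0) return(integer(0))
  counts <- table(hit)
  ids <- as.integer(names(counts))
  size <- map$sectors$n_voxels[ids]
  frac <- as.integer(counts) / pmax(size, 1L)
  sort(ids[as.integer(counts) >= 1 & frac >= tau])
}

#' Score predicted sectors against the biopsy reference
#'
#' Sectors predicted by the contour are compared with the biopsy-labelled
#' sector map: TP are predicted biopsy-positive sectors, FP predicted
#' negatives, and so on. Unsampled sectors count as negative by default (the
#' absence of a positive biopsy counts against the contour); set
#' `unsampled = "exclude"` to score only sampled sectors.
#'
#' @param predicted integer vector of predicted-positive sector ids.
#' @param map a labelled `sector_map`.
#' @param unsampled `"negative"` or `"exclude"`.
#' @return One-row tibble of confusion counts and metrics, plus
#'   `n_scored` and `flag_no_positive`.
#' @export
score_sectors <- function(predicted, map, unsampled = c("negative", "exclude")) {
  unsampled <- match.arg(unsampled)
  st <- as.character(map$sectors$biopsy_status)
  ids <- map$sectors$sector_id
  if (unsampled == "exclude") {
    keep <- st != "unsampled"
    ids <- ids[keep]
    st <- st[keep]
    predicted <- intersect(predicted, ids)
  }
  pos <- ids[st == "positive"]
  neg <- setdiff(ids, pos)
  tp <- length(intersect(predicted, pos))
  fp <- length(intersect(predicted, neg))
  fn <- length(setdiff(pos, predicted))
  tn <- length(setdiff(neg, predicted))
  out <- confusion_metrics(tp, fp, fn, tn)
  out$n_scored <- length(ids)
  out$flag_no_positive <- length(pos) == 0
  out
}

#' Voxel-level Dice between a contour and the positive-sector volume
#'
#' Secondary scoring mode: the margin-expanded contour against the
#' margin-expanded union of biopsy-positive sector voxel sets.
#'
#' @param contour `ipl_contour` or logical mask.
#' @param map labelled `sector_map`.
#' @param margin_mm margin applied to both structures (`margin_both = FALSE`
#'   expands only the contour).
#' @param margin_both expand the reference too (default, mirroring the margin
#'   added to both the image-defined lesion and the biopsy landmark).
#' @export
voxel_dice <- function(contour, map, margin_mm = 5, margin_both = TRUE) {
  mask <- if (inherits(contour, "ipl_contour")) contour$mask else contour
  pos <- map$sectors$sector_id[map$sectors$biopsy_status == "positive"]
  ref <- array(map$assignment %in% pos, dim(map$assignment))
  a <- expand_margin(mask, margin_mm, map$spacing)
  b <- if (margin_both) expand_margin(ref, margin_mm, map$spacing) else ref
  dice(a, b)
}

#' Aggregate per-lesion metric records by method
#'
#' Arithmetic mean and sample SD of each metric per method label, the layout of
#' a per-threshold summary table. Missing metric values (undefined ratios) are
#' excluded pairwise and counted.
#'
#' @param records tibble with a `method` column and metric columns
#'   `dsc`, `yi`, `sensitivity`, `specificity`.
#' @param by grouping column name (default `"method"`).
#' @return Tibble, one row per group: `n`, then `<metric>_mean`, `<metric>_sd`,
#'   `<metric>_n_missing` for each metric.
#' @export
aggregate_metrics <- function(records, by = "method") {
  metrics <- intersect(c("dsc", "yi", "sensitivity", "specificity"),
                       names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~ifelse(sum(!is.na(.x)) > 1, sd(.x, na.rm = TRUE), 0),
                         n_missing = ~sum(is.na(.x)))),
      .groups = "drop"
    )
}

#' Select the best automatic contouring threshold
#'
#' Returns the threshold maximising mean DSC; by definition the best automatic
#' contouring method is the one with the highest DSC and Youden index, so the
#' function checks that the same threshold maximises mean YI and flags
#' discordance otherwise (the DSC maximiser is still returned). Ties on DSC are
#' broken by YI, then by higher specificity, then by position.
#'
#' @param thresholds vector of threshold labels or fractions.
#' @param dsc mean DSC per threshold.
#' @param yi optional mean Youden index per threshold.
#' @param specificity optional mean specificity per threshold.
#' @return The winning element of `thresholds`, with attributes `concordant`
#'   (did YI agree?) and `tie` (was a tie broken?).
#' @export
best_threshold <- function(thresholds, dsc, yi = NULL, specificity = NULL) {
  stopifnot(length(thresholds) >= 2, length(dsc) == length(thresholds))
  tol <- 1e-12
  cand <- which(dsc >= max(dsc, na.rm = TRUE) - tol)
  tie <- length(cand) > 1
  if (tie && !is.null(yi)) {
    cand <- cand[yi[cand] >= max(yi[cand], na.rm = TRUE) - tol]
  }
  if (length(cand) > 1 && !is.null(specificity)) {
    cand <- cand[specificity[cand] >= max(specificity[cand], na.rm = TRUE) - tol]
  }
  pick <- cand[1]
  concordant <- if (is.null(yi)) NA else which.max(yi) == pick
  if (tie) warn("tie on mean DSC broken by YI/specificity")
  if (isFALSE(concordant))
    warn("DSC and YI disagree on the best threshold; returning the DSC maximiser")
  structure(thresholds[pick], concordant = concordant, tie = tie)
}

#' Printed per-threshold summary table of the reference study
#'
#' The published mean +/- SD correlation indices per contouring method
#' (worked-example input data, shipped as `printed_summary_table.csv`).
#' @return Tibble with columns `method`, `tracer`, `threshold`, `dsc_mean`,
#'   `dsc_sd`, `yi_mean`, `yi_sd`, `sensitivity_mean`, `sensitivity_sd`,
#'   `specificity_mean`, `specificity_sd` (sensitivity/specificity in %).
#' @export
printed_summary_table <- function() {
  path <- system.file("extdata", "printed_summary_table.csv",
                      package = "iplconcord", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
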