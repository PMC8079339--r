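#' Lesion contour container
#'
#' @param mask 3D logical array.
#' @param spacing voxel spacing (mm).
#' @param modality imaging modality tag.
#' @param method `"manual_sim"`, `"SUV_abs"` or `"SUV_frac"`.
#' @param threshold SUV for absolute thresholds, fraction of SUVmax for
#'   fractional ones, `NA` for manual contours.
#' @param suvmax observed SUVmax within the contour, if known.
#' @param lesion_id optional ground-truth lesion association.
#' @return An object of class `ipl_contour`.
#' @export
new_contour <- function(mask, spacing, modality, method, threshold,
                        suvmax = NA_real_, lesion_id = NA_integer_) {
  structure(
    list(mask = mask, spacing = spacing, modality = modality, method = method,
         threshold = threshold, suvmax = suvmax, lesion_id = lesion_id,
         volume_cc = sum(mask) * voxel_volume_cc(spacing)),
    class = "ipl_contour"
  )
}

#' @export
print.ipl_contour <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "" else sprintf(" thr=%g", x$threshold)
  cat(sprintf("<ipl_contour> %s/%s%s: %.2f cc, SUVmax %.3g\n",
              x$modality, x$method, thr, x$volume_cc, x$suvmax))
  invisible(x)
}

#' Manifest tibble for a list of contours
#' @param contours list of `ipl_contour`.
#' @export
contour_manifest <- function(contours) {
  purrr::map_dfr(contours, function(ct) {
    tibble::tibble(modality = ct$modality, method = ct$method,
                   threshold = ct$threshold, lesion_id = ct$lesion_id,
                   volume_cc = ct$volume_cc, suvmax = ct$suvmax)
  })
}

#' Automatic SUV-threshold contouring of a PET volume
#'
#' Computes SUVmax within the prostate mask only, thresholds the volume at an
#' absolute SUV or at a fraction of that SUVmax, restricts to the gland and
#' returns one contour per connected component. An absolute threshold above
#' SUVmax yields an empty list (not an error). The fractional thresholds of
#' interest run from 40 to 80% of SUVmax.
#'
#' @param pet an `image_volume` in SUV units (or a bare array with `spacing`).
#' @param anatomy a `prostate_anatomy` (or a bare prostate mask).
#' @param threshold numeric threshold value.
#' @param type `"fraction"` (of prostate SUVmax) or `"absolute"` (SUV).
#' @param connectivity component connectivity, 26 (default) or 6.
#' @param min_voxels drop components smaller than this many voxels.
#' @param per_lesion_suvmax if `TRUE`, fractional thresholds are applied per
#'   connected focus of the absolute-SUV>=3 support rather than to the single
#'   gland-wide SUVmax (multi-focal variant; default `FALSE`).
#' @return List of `ipl_contour` objects (possibly empty).
#' @export
auto_contour <- function(pet, anatomy, threshold,
                         type = c("fraction", "absolute"),
                         connectivity = 26, min_voxels = 1L,
                         per_lesion_suvmax = FALSE) {
  type <- match.arg(type)
  if (inherits(pet, "image_volume")) {
    arr <- pet$data; spacing <- pet$spacing; modality <- pet$modality
  } else {
    arr <- pet; spacing <- attr(pet, "spacing"); modality <- "PET_GA68"
    if (is.null(spacing)) abort("supply `pet` as an image_volume")
  }
  pmask <- if (inherits(anatomy, "prostate_anatomy")) anatomy$mask else anatomy
  if (!any(pmask)) abort("prostate mask is empty")
  method <- if (type == "fraction") "SUV_frac" else "SUV_abs"

  threshold_regions <- function(sel_mask, thr) {
    lab <- label_components(sel_mask, connectivity)
    ids <- setdiff(unique(as.vector(lab)), 0L)
    out <- list()
    for (id in ids) {
      m <- lab == id
      if (sum(m) < min_voxels) next
      out[[length(out) + 1]] <-
        new_contour(m, spacing, modality, method, thr, suvmax = max(arr[m]))
    }
    out
  }

  if (type == "absolute") {
    sel <- arr >= threshold & pmask
    if (!any(sel)) return(list())
    return(threshold_regions(sel, threshold))
  }

  if (!per_lesion_suvmax) {
    suvmax <- max(arr[pmask])
    sel <- arr >= threshold * suvmax & pmask
    if (!any(sel)) return(list())
    return(threshold_regions(sel, threshold))
  }

  # per-focus variant: fractional threshold relative to each SUV>=3 focus
  foci <- label_components(arr >= 3 & pmask, connectivity)
  ids <- setdiff(unique(as.vector(foci)), 0L)
  out <- list()
  for (id in ids) {
    fm <- foci == id
    smax <- max(arr[fm])
    sel <- fm & arr >= threshold * smax
    out <- c(out, threshold_regions(sel, threshold))
  }
  out
}

#' Select dominant lesions
#'
#' Keeps contours with volume at least 1 cc and observed SUVmax at least 3
#' (both bounds inclusive), the criterion defining dominant intraprostatic
#' lesions. Input order is preserved.
#'
#' @param contours list of `ipl_contour`.
#' @param min_volume_cc volume criterion (cc).
#' @param min_suv SUV criterion.
#' @export
select_dominant <- function(contours, min_volume_cc = 1, min_suv = 3) {
  purrr::keep(contours, function(ct) {
    isTRUE(ct$volume_cc >= min_volume_cc) &&
      (is.na(ct$suvmax) || ct$suvmax >= min_suv)
  })
}
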