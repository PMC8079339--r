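#' Euclidean distance transform with anisotropic spacing
#'
#' Distance (mm) from every voxel to the nearest voxel of a binary mask,
#' computed exactly on voxel centres via a separable lower-envelope transform.
#'
#' @param mask 3D logical array.
#' @param spacing voxel spacing (mm).
#' @return 3D numeric array of distances; `Inf` everywhere if the mask is empty.
#' @export
distance_to_mask <- function(mask, spacing) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d2 <- edt_squared_cpp(as.logical(mask), dim(mask), as.numeric(spacing))
  d2[d2 > 1e29] <- Inf
  array(sqrt(d2), dim(mask))
}

#' Label connected components of a 3D mask
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (default, vertex-adjacent) or 6 (face-adjacent).
#' @return Integer array; components numbered 1..K, background 0.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  array(label_components_cpp(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim(mask))
}

#' Expand a binary mask by a physical margin
#'
#' Morphological dilation by a Euclidean ball of radius `margin_mm`, respecting
#' anisotropic voxel spacing: a voxel belongs to the output iff its centre lies
#' within `margin_mm` of some mask voxel centre. `margin_mm = 0` is the
#' identity. Mirrors the isotropic external margin added to image-defined
#' lesions and biopsy landmarks before overlap scoring.
#'
#' @param mask 3D logical array (or an `ipl_contour`, whose mask is expanded and
#'   volume updated).
#' @param margin_mm non-negative margin in mm.
#' @param spacing voxel spacing (mm); taken from the contour if given one.
#' @return Expanded mask (or contour).
#' @export
expand_margin <- function(mask, margin_mm, spacing = NULL) {
  if (inherits(mask, "ipl_contour")) {
    out <- mask
    out$mask <- expand_margin(mask$mask, margin_mm, mask$spacing)
    out$volume_cc <- sum(out$mask) * voxel_volume_cc(mask$spacing)
    return(out)
  }
  stopifnot(margin_mm >= 0, !is.null(spacing))
  if (margin_mm == 0 || !any(mask)) return(mask)
  d <- distance_to_mask(mask, spacing)
  d <= margin_mm + 1e-9
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns `NA` when both masks are empty.
#' @param a,b logical arrays of identical dimension.
#' @export
dice <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}
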