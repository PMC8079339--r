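#' 3D scalar image volume
#'
#' Container for a 3D scalar grid with anisotropic voxel spacing and a modality
#' tag. PET volumes are in SUV units and must be non-negative. The coordinate
#' convention used throughout the package: array index `(i, j, k)` (1-based, as
#' in R) has its voxel centre at world position `((i-1)*dx, (j-1)*dy, (k-1)*dz)`
#' millimetres; the third axis is axial (cranio-caudal).
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm; all > 0.
#' @param modality one of `"PET_GA68"`, `"PET_F18"`, `"T2W"`, `"ADC"`, `"DCE"`.
#' @param slice_thickness_mm nominal axial acquisition thickness in mm
#'   (5 for PET-attached volumes, 3 for MRI by default).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, modality, slice_thickness_mm = NULL) {
  modality <- match.arg(modality, c("PET_GA68", "PET_F18", "T2W", "ADC", "DCE"))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three positive finite numbers (mm).")
  if (startsWith(modality, "PET") && any(data < 0))
    abort("PET volumes are in SUV units and must be non-negative.")
  if (is.null(slice_thickness_mm))
    slice_thickness_mm <- if (startsWith(modality, "PET")) 5 else 3
  structure(
    list(data = data, spacing = spacing, modality = modality,
         slice_thickness_mm = slice_thickness_mm),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels @ (%.2g, %.2g, %.2g) mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.3g, %.3g], axial slice thickness %g mm\n",
              min(x$data), max(x$data), x$slice_thickness_mm))
  invisible(x)
}

#' Voxel volume in cubic centimetres
#' @param spacing voxel spacing in mm.
#' @export
voxel_volume_cc <- function(spacing) prod(spacing) / 1000

# World coordinates (mm) of voxel centres along each axis.
axis_coords <- function(dim, spacing) {
  lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a])
}

# Dense world-coordinate arrays for a grid (each same dim as the volume).
coord_arrays <- function(dim, spacing) {
  cs <- axis_coords(dim, spacing)
  list(
    x = array(rep(cs[[1]], times = dim[2] * dim[3]), dim),
    y = array(rep(rep(cs[[2]], each = dim[1]), times = dim[3]), dim),
    z = array(rep(cs[[3]], each = dim[1] * dim[2]), dim)
  )
}

# Apply a linear operator K (n_ax x n_ax) along axis `ax` of a 3D array.
apply_along_axis <- function(arr, ax, K) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, d[ax])
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

#' Separable Gaussian blur with a physical FWHM
#'
#' Convolves a 3D array with an axis-aligned Gaussian point-spread function
#' specified by its full width at half maximum in millimetres, respecting
#' anisotropic voxel spacing. The discrete kernel is truncated at 3 sigma and
#' mass-renormalised at the array edges, so total uptake of interior objects is
#' conserved.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm scalar or length-3 FWHM in mm; 0 returns `arr` unchanged.
#' @param spacing voxel spacing (mm).
#' @return Blurred array of the same dimension.
#' @export
gaussian_blur_mm <- function(arr, fwhm_mm, spacing) {
  fwhm <- rep(as.numeric(fwhm_mm), length.out = 3)
  if (all(fwhm <= 0)) return(arr)
  sig_vox <- fwhm / (2 * sqrt(2 * log(2))) / spacing
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sig_vox[ax]
    if (s <= 1e-8) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- dnorm(seq(-r, r) / s)
    w <- w / sum(w)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (o in seq(-r, r)) {
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1 & j <= n
      K[cbind(j[ok], idx[ok])] <- K[cbind(j[ok], idx[ok])] + w[o + r + 1]
    }
    K <- sweep(K, 2, colSums(K), "/")  # conserve mass at edges
    arr <- apply_along_axis(arr, ax, K)
  }
  arr
}

#' Write / read a volume as NIfTI
#'
#' Thin wrappers over [RNifti::writeNifti()] carrying the voxel spacing in the
#' NIfTI pixdim. Label arrays (integer) round-trip unchanged.
#'
#' @param vol an `image_volume`, or a bare 3D array with `spacing` supplied.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param spacing required when `vol` is a bare array.
#' @return `write_volume_nifti()` returns `path` invisibly; `read_volume_nifti()`
#'   returns a list with `data` and `spacing`.
#' @export
write_volume_nifti <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "image_volume")) {
    arr <- vol$data
    spacing <- vol$spacing
  } else {
    arr <- vol
    if (is.null(spacing)) abort("`spacing` needed for a bare array.")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}
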