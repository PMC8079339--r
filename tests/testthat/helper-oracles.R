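# Shared fixtures and independent oracle implementations. Everything here is
# deliberately naive (brute force / closed form) and independent of the code
# paths it checks.

fixture_env <- new.env(parent = emptyenv())

# A small cached phantom case (default study conditions, small cohort).
fixture_case <- function() {
  if (is.null(fixture_env$case)) {
    fixture_env$spec <- cohort_spec(n_patients = 2, seed = 42)
    fixture_env$case <- generate_case(fixture_env$spec, 1)
  }
  fixture_env$case
}

# Symmetric ellipsoidal anatomy on a coarse grid (centre exactly between
# voxel columns so the left/right split is mirror-exact).
fixture_symmetric_anatomy <- function() {
  if (is.null(fixture_env$sym_anat)) {
    dims <- c(40L, 40L, 16L)
    sp <- c(2, 2, 3)
    co <- expand.grid(x = (0:39) * 2, y = (0:39) * 2, z = (0:15) * 3)
    rho <- sqrt(((co$x - 39) / 18)^2 + ((co$y - 39) / 16)^2 +
                  ((co$z - 22.5) / 14)^2)
    fixture_env$sym_anat <- anatomy_from_mask(array(rho <= 1, dims), sp)
  }
  fixture_env$sym_anat
}

# Brute-force dilation: voxel centre within margin of any mask voxel centre.
brute_dilate <- function(mask, margin_mm, spacing) {
  d <- dim(mask)
  all_pts <- (arrayInd(seq_len(prod(d)), d) - 1) %*% diag(spacing)
  pts <- all_pts[which(mask), , drop = FALSE]
  out <- vapply(seq_len(prod(d)), function(i) {
    dd <- sqrt((pts[, 1] - all_pts[i, 1])^2 + (pts[, 2] - all_pts[i, 2])^2 +
                 (pts[, 3] - all_pts[i, 3])^2)
    any(dd <= margin_mm + 1e-9)
  }, logical(1))
  array(out, d)
}

# Definitional confusion-matrix metrics from reconstructed label vectors.
brute_confusion <- function(tp, fp, fn, tn) {
  truth <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
  pred <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, fn), rep(FALSE, tn))
  TP <- sum(pred & truth); FP <- sum(pred & !truth)
  FN <- sum(!pred & truth); TN <- sum(!pred & !truth)
  dsc <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  c(dsc = dsc, sensitivity = sens, specificity = spec, yi = sens + spec - 1)
}

# Kruskal-Wallis H from the textbook rank-sum formula (no tie correction;
# only use with distinct values).
brute_kruskal_h <- function(values, groups) {
  rk <- rank(values)
  N <- length(values)
  rbar <- tapply(rk, groups, mean)
  ni <- tapply(rk, groups, length)
  12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
}

# Smooth closed prostate-like outline via a low-order Fourier radial profile.
smooth_shape <- function(seed, n = 100, R = 20) {
  set.seed(seed)
  a <- runif(3, -0.12, 0.12)
  ph <- runif(3, 0, 2 * pi)
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  rad <- R * (1 + a[1] * cos(ang + ph[1]) + a[2] * cos(2 * ang + ph[2]) +
                a[3] * cos(3 * ang + ph[3]))
  cbind(rad * cos(ang), rad * sin(ang))
}

# Minimal labelled sector map for pure scoring tests.
fake_scored_map <- function(positive, n_sectors = 36, unsampled = integer(0)) {
  status <- rep("negative", n_sectors)
  status[positive] <- "positive"
  status[unsampled] <- "unsampled"
  structure(list(sectors = tibble::tibble(
    sector_id = seq_len(n_sectors),
    biopsy_status = factor(status, levels = c("positive", "negative", "unsampled"))
  )), class = "sector_map")
}
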