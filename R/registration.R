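# --- closed-polyline utilities ------------------------------------------------

# Drop a repeated closing vertex, if present.
open_ring <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n > 1 && all(abs(pts[1, ] - pts[n, ]) < 1e-12)) pts <- pts[-n, , drop = FALSE]
  pts
}

# Resample a closed polyline at n points equally spaced in arc length,
# starting from the first vertex.
resample_closed <- function(pts, n) {
  pts <- open_ring(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) abort("degenerate contour: zero length")
  s <- seq(0, total, length.out = n + 1)[seq_len(n)]
  x <- approx(cum, closed[, 1], xout = s, ties = "ordered")$y
  y <- approx(cum, closed[, 2], xout = s, ties = "ordered")$y
  cbind(x, y)
}

polyline_self_intersects <- function(pts) {
  pts <- open_ring(pts)
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  a <- pts
  b <- pts[c(2:n, 1), ]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) next
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

# --- rigid (similarity) fit ---------------------------------------------------

#' Least-squares rigid alignment of two closed contours
#'
#' Two-dimensional rigid registration (translation + rotation, optionally a
#' single isotropic scale to absorb a difference in image size) between a
#' source and a target contour. Correspondence, which manual matching leaves
#' undefined, is resolved by arc-length resampling of both contours and a
#' circular-shift search over the starting point (optionally also the reversed
#' orientation); the transform minimising mean squared correspondence distance
#' wins.
#'
#' @param source,target closed polylines (n x 2 matrices, mm), at least 3
#'   non-collinear points each.
#' @param allow_scale include an isotropic scale factor.
#' @param n_samples arc-length resampling density for the correspondence
#'   search.
#' @param search_reverse also try the orientation-reversed target.
#' @param correspondence `"resample_search"` (default; arc-length resampling
#'   plus circular-shift search) or `"paired"` (rows of `source` and `target`
#'   are already corresponding landmarks).
#' @return An object of class `rigid2d`: `tx`, `ty` (mm), `theta` (radians),
#'   `scale`, `rmsd` (mm).
#' @export
fit_rigid <- function(source, target, allow_scale = FALSE, n_samples = 128,
                      search_reverse = TRUE,
                      correspondence = c("resample_search", "paired")) {
  correspondence <- match.arg(correspondence)
  source <- open_ring(source)
  target <- open_ring(target)
  if (nrow(source) < 3 || nrow(target) < 3)
    abort("need at least 3 points per contour")
  sv <- svd(scale(source, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-12))
    abort("collinear source contour: rotation unidentifiable")

  if (correspondence == "paired") {
    if (nrow(source) != nrow(target))
      abort("paired correspondence needs equally many source and target points")
    S <- source
    Tt <- target
    n_samples <- nrow(S)
    search_reverse <- FALSE
    shifts <- 0L
  } else {
    S <- resample_closed(source, n_samples)
    Tt <- resample_closed(target, n_samples)
    shifts <- 0:(n_samples - 1)
  }
  cs <- colMeans(S)
  Sc <- sweep(S, 2, cs)
  ss <- sum(Sc^2)

  best <- NULL
  orientations <- if (search_reverse) list(Tt, Tt[c(1, n_samples:2), ]) else list(Tt)
  for (To in orientations) {
    ct <- colMeans(To)
    Tc <- sweep(To, 2, ct)
    for (shift in shifts) {
      idx <- ((seq_len(n_samples) - 1 + shift) %% n_samples) + 1
      Ts <- Tc[idx, , drop = FALSE]
      a <- sum(Sc[, 1] * Ts[, 1] + Sc[, 2] * Ts[, 2])
      b <- sum(Sc[, 1] * Ts[, 2] - Sc[, 2] * Ts[, 1])
      theta <- atan2(b, a)
      s <- if (allow_scale) sqrt(a^2 + b^2) / ss else 1
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
      res <- Ts - s * Sc %*% t(R)
      rmsd <- sqrt(mean(rowSums(res^2)))
      if (is.null(best) || rmsd < best$rmsd) {
        tvec <- unname(ct - s * as.vector(R %*% cs))
        best <- list(tx = tvec[1], ty = tvec[2], theta = theta, scale = s,
                     rmsd = rmsd, shift = shift)
      }
    }
  }
  structure(best, class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> t = (%.3f, %.3f) mm, theta = %.3f deg, scale = %.4f, rmsd = %.3g mm\n",
              x$tx, x$ty, x$theta * 180 / pi, x$scale, x$rmsd))
  invisible(x)
}

#' Apply / invert / compose rigid transforms
#' @param tf,a,b `rigid2d` objects.
#' @param pts n x 2 matrix of points (mm).
#' @export
apply_rigid <- function(tf, pts) {
  pts <- as.matrix(pts)
  R <- matrix(c(cos(tf$theta), sin(tf$theta), -sin(tf$theta), cos(tf$theta)), 2)
  sweep(tf$scale * pts %*% t(R), 2, c(tf$tx, tf$ty), "+")
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(tf) {
  R <- matrix(c(cos(-tf$theta), sin(-tf$theta), -sin(-tf$theta), cos(-tf$theta)), 2)
  tvec <- -as.vector(R %*% c(tf$tx, tf$ty)) / tf$scale
  structure(list(tx = tvec[1], ty = tvec[2], theta = -tf$theta,
                 scale = 1 / tf$scale, rmsd = NA_real_),
            class = "rigid2d")
}

#' @rdname apply_rigid
#' @export
compose_rigid <- function(a, b) {
  # returns the transform equivalent to applying `a` first, then `b`
  theta <- a$theta + b$theta
  s <- a$scale * b$scale
  Rb <- matrix(c(cos(b$theta), sin(b$theta), -sin(b$theta), cos(b$theta)), 2)
  tvec <- b$scale * as.vector(Rb %*% c(a$tx, a$ty)) + c(b$tx, b$ty)
  structure(list(tx = tvec[1], ty = tvec[2], theta = theta, scale = s,
                 rmsd = NA_real_), class = "rigid2d")
}

# --- thin-plate-spline landmark warp -----------------------------------------

tps_kernel <- function(r) ifelse(r < 1e-12, 0, r^2 * log(r))

#' Interpolating landmark warp between two outlines
#'
#' The multipoint deformation step: control points are sampled at matched
#' arc-length fractions along the (already rigidly aligned) schematic and
#' patient outlines, and a thin-plate-spline map interpolating every pair is
#' fitted. The warp maps each source control point exactly onto its target
#' (interpolating, not smoothing), is continuous over the plane, and reduces
#' to the identity when the outlines coincide.
#'
#' @param source_outline,target_outline closed polylines (n x 2, mm).
#' @param n_control number of control-point pairs.
#' @param align_start resolve the starting-point ambiguity by a circular shift
#'   of the target control points minimising total displacement.
#' @return An object of class `tps_warp` with `src`, `dst` (control points)
#'   and spline coefficients.
#' @export
fit_deformation <- function(source_outline, target_outline, n_control = 16,
                            align_start = TRUE) {
  if (polyline_self_intersects(source_outline))
    abort("invalid contour: source outline self-intersects")
  if (polyline_self_intersects(target_outline))
    abort("invalid contour: target outline self-intersects")
  src <- resample_closed(source_outline, n_control)
  dst <- resample_closed(target_outline, n_control)
  if (align_start) {
    costs <- vapply(0:(n_control - 1), function(sh) {
      idx <- ((seq_len(n_control) - 1 + sh) %% n_control) + 1
      sum((dst[idx, ] - src)^2)
    }, numeric(1))
    sh <- which.min(costs) - 1
    idx <- ((seq_len(n_control) - 1 + sh) %% n_control) + 1
    dst <- dst[idx, , drop = FALSE]
  }
  keep <- !duplicated(round(src, 9))
  src <- src[keep, , drop = FALSE]
  dst <- dst[keep, , drop = FALSE]
  n <- nrow(src)
  K <- tps_kernel(as.matrix(stats::dist(src)))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coef <- solve(L, rhs)
  structure(list(src = src, dst = dst, w = coef[seq_len(n), , drop = FALSE],
                 affine = coef[n + 1:3, , drop = FALSE]),
            class = "tps_warp")
}

#' Evaluate a thin-plate-spline warp at points
#' @param warp a `tps_warp`.
#' @param pts n x 2 matrix (mm).
#' @export
warp_points <- function(warp, pts) {
  pts <- as.matrix(pts)
  d2 <- outer(pts[, 1], warp$src[, 1], "-")^2 + outer(pts[, 2], warp$src[, 2], "-")^2
  U <- tps_kernel(sqrt(d2))
  cbind(1, pts) %*% warp$affine + U %*% warp$w
}

#' @export
print.tps_warp <- function(x, ...) {
  disp <- sqrt(rowSums((x$dst - x$src)^2))
  cat(sprintf("<tps_warp> %d control points, displacement %.2f-%.2f mm\n",
              nrow(x$src), min(disp), max(disp)))
  invisible(x)
}

# --- sector transfer ----------------------------------------------------------

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  poly <- open_ring(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

point_to_ring_dist <- function(px, py, poly) {
  poly <- open_ring(poly)
  n <- nrow(poly)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 < 1e-14) rep(0, length(px)) else
      pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    d <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    dmin <- pmin(dmin, d)
  }
  dmin
}

densify_polygon <- function(poly, per_edge = 4) {
  poly <- open_ring(poly)
  n <- nrow(poly)
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    t <- seq(0, 1, length.out = per_edge + 1)[-(per_edge + 1)]
    out[[i]] <- cbind(poly[i, 1] + t * (poly[j, 1] - poly[i, 1]),
                      poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
  }
  do.call(rbind, out)
}

#' Transfer schematic sectors onto a patient axial slice
#'
#' Forward-maps the region's twelve schematic polygons through the rigid
#' transform and the landmark warp, then assigns every prostate voxel on the
#' target slice to the (first) warped polygon containing its centre. A voxel
#' inside the prostate but outside all warped polygons is assigned to the
#' nearest polygon boundary and counted, never dropped.
#'
#' @param map a `sector_map`.
#' @param region `"apex"`, `"mid"` or `"base"`; the slice must belong to it.
#' @param anatomy the patient `prostate_anatomy`.
#' @param slice 1-based axial slice index.
#' @param rigid optional `rigid2d` (schematic -> patient plane); identity if
#'   `NULL`.
#' @param warp optional `tps_warp` applied after the rigid step.
#' @param per_edge polygon edge densification before warping.
#' @return List: `assignment` (2D integer matrix of sector ids over the slice,
#'   0 outside the prostate), `n_fallback` (voxels assigned by nearest
#'   polygon), `polygons` (the warped polygons, patient coordinates).
#' @export
transfer_sectors <- function(map, region, anatomy, slice, rigid = NULL,
                             warp = NULL, per_edge = 4) {
  region <- match.arg(region, region_names)
  ridx <- match(region, region_names)
  d <- dim(anatomy$mask)
  if (slice < 1 || slice > d[3]) abort("slice out of range")
  rslice <- anatomy$region[, , slice]
  pslice <- anatomy$mask[, , slice]
  if (!any(rslice == ridx & pslice))
    abort(sprintf("slice %d does not belong to the %s region", slice, region))

  polys <- map$polygons[[region]]$sectors
  warped <- lapply(polys, function(p) {
    q <- densify_polygon(p, per_edge)
    if (!is.null(rigid)) q <- apply_rigid(rigid, q)
    if (!is.null(warp)) q <- warp_points(warp, q)
    q
  })

  sel <- which(pslice, arr.ind = TRUE)
  px <- (sel[, 1] - 1) * anatomy$spacing[1]
  py <- (sel[, 2] - 1) * anatomy$spacing[2]
  seg <- rep(0L, nrow(sel))
  for (k in seq_along(warped)) {
    todo <- seg == 0L
    if (!any(todo)) break
    hit <- points_in_polygon(px[todo], py[todo], warped[[k]])
    seg[which(todo)[hit]] <- k
  }
  n_fallback <- sum(seg == 0L)
  if (n_fallback > 0) {
    miss <- which(seg == 0L)
    dmat <- vapply(warped, function(p) point_to_ring_dist(px[miss], py[miss], p),
                   numeric(length(miss)))
    dmat <- matrix(dmat, nrow = length(miss))
    seg[miss] <- max.col(-dmat, ties.method = "first")
  }
  assignment <- matrix(0L, d[1], d[2])
  assignment[sel] <- (ridx - 1L) * 12L + seg
  list(assignment = assignment, n_fallback = n_fallback, polygons = warped)
}
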