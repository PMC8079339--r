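test_that("synthetic rigid transforms are recovered exactly", {
  shape <- smooth_shape(1)

  tr <- fit_rigid(shape, sweep(shape, 2, c(5, -3), "+"))
  expect_equal(c(tr$tx, tr$ty), c(5, -3), tolerance = 1e-6)
  expect_lt(abs(tr$theta), 1e-6)

  th0 <- 30 * pi / 180
  R <- matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2)
  ctr <- colMeans(shape)
  rot <- sweep(sweep(shape, 2, ctr) %*% t(R), 2, ctr, "+")
  tr2 <- fit_rigid(shape, rot)
  expect_equal(tr2$theta, th0, tolerance = 1e-6)

  sc <- fit_rigid(shape, shape * 1.3, allow_scale = TRUE)
  expect_equal(sc$scale, 1.3, tolerance = 1e-6)

  line <- cbind(1:10, 2 * (1:10) + 1)
  expect_error(fit_rigid(line, line), "collinear")
})

test_that("noisy paired landmarks are recovered without material bias", {
  shape <- smooth_shape(2)
  th0 <- 30 * pi / 180
  R <- matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2)
  err <- vapply(1:50, function(s) {
    set.seed(s)
    tgt <- shape %*% t(R) +
      matrix(c(4, -2), nrow(shape), 2, byrow = TRUE) +
      matrix(rnorm(2 * nrow(shape), 0, 0.5), nrow(shape))
    f <- fit_rigid(shape, tgt, correspondence = "paired")
    c(f$tx - 4, f$ty + 2, (f$theta - th0) * 180 / pi)
  }, numeric(3))
  bias <- rowMeans(err)
  expect_lt(abs(bias[1]), 0.1)
  expect_lt(abs(bias[2]), 0.1)
  expect_lt(abs(bias[3]), 0.5)
})

test_that("rotating the target rotates the recovered angle, nothing else", {
  shape <- smooth_shape(3)
  base <- fit_rigid(shape, shape)
  for (extra in c(0.3, 1.1)) {
    R <- matrix(c(cos(extra), sin(extra), -sin(extra), cos(extra)), 2)
    tr <- fit_rigid(shape, shape %*% t(R))
    expect_equal(tr$theta, base$theta + extra, tolerance = 1e-9)
    expect_equal(tr$scale, 1)
  }
  # composing with the inverse yields the identity
  tf <- fit_rigid(shape, sweep(shape %*% t(matrix(c(cos(.4), sin(.4), -sin(.4), cos(.4)), 2)),
                               2, c(2, 1), "+"))
  comp <- compose_rigid(tf, invert_rigid(tf))
  expect_lt(abs(comp$theta), 1e-9)
  expect_lt(abs(comp$tx) + abs(comp$ty), 1e-9)
})

test_that("landmark warp interpolates exactly and is the identity for equal outlines", {
  shape <- smooth_shape(4)
  idw <- fit_deformation(shape, shape, n_control = 16)
  disp <- warp_points(idw, shape) - shape
  expect_lt(max(abs(disp)), 1e-9)

  for (s in 1:10) {
    src <- smooth_shape(100 + s)
    dst <- smooth_shape(200 + s)
    w <- fit_deformation(src, dst, n_control = 16)
    resid <- sqrt(rowSums((warp_points(w, w$src) - w$dst)^2))
    expect_lt(max(resid), 1e-9)
  }

  bow <- cbind(c(0, 4, 0, 4), c(0, 4, 4, 0))  # self-intersecting quadrilateral
  expect_error(fit_deformation(bow, shape), "self-intersects")
})

test_that("a circle is warped onto an analytic ellipse to sub-voxel accuracy", {
  ang <- seq(0, 2 * pi, length.out = 101)[1:100]
  circ <- cbind(20 * cos(ang), 20 * sin(ang))
  ell <- cbind(24 * cos(ang), 16 * sin(ang))
  w <- fit_deformation(circ, ell, n_control = 16)
  dense <- warp_points(w, iplconcord:::resample_closed(circ, 256))
  ref_ang <- seq(0, 2 * pi, length.out = 4000)
  ref <- cbind(24 * cos(ref_ang), 16 * sin(ref_ang))
  dmin <- iplconcord:::point_to_ring_dist(dense[, 1], dense[, 2], ref)
  expect_lt(mean(dmin), 0.2)
})

test_that("the deformation step never worsens the rigid-only outline residual", {
  for (s in 1:100) {
    src <- smooth_shape(1000 + s)
    dst <- sweep(smooth_shape(2000 + s), 2, c(3, -2), "+")
    rg <- fit_rigid(src, dst, allow_scale = TRUE)
    aligned <- apply_rigid(rg, src)
    pre <- mean(iplconcord:::point_to_ring_dist(aligned[, 1], aligned[, 2], dst))
    w <- fit_deformation(aligned, dst, n_control = 16)
    dense <- warp_points(w, iplconcord:::resample_closed(aligned, 128))
    post <- mean(iplconcord:::point_to_ring_dist(dense[, 1], dense[, 2], dst))
    expect_lte(post, pre + 1e-9)
  }
})

test_that("sector transfer assigns every gland voxel on the slice exactly once", {
  an <- fixture_symmetric_anatomy()
  map <- build_sector_map(an)
  zs <- which(apply(an$region == 2, 3, any))
  sl <- zs[ceiling(length(zs) / 2)]
  shift <- structure(list(tx = an$center_mm[1], ty = an$center_mm[2],
                          theta = 0, scale = 1, rmsd = 0), class = "rigid2d")

  tr <- transfer_sectors(map, "mid", an, sl, rigid = shift)
  gland <- an$mask[, , sl]
  expect_true(all((tr$assignment > 0) == gland))
  expect_lt(tr$n_fallback / sum(gland), 0.05)

  # translation-only transfer agrees with the analytic angle/zone rule away
  # from polygon chord edges
  sel <- which(gland, arr.ind = TRUE)
  px <- (sel[, 1] - 1) * an$spacing[1] - an$center_mm[1]
  py <- (sel[, 2] - 1) * an$spacing[2] - an$center_mm[2]
  side <- ifelse(px < 0, 0L, 1L)
  psi <- atan2(py, abs(px)) * 180 / pi
  wedge <- ifelse(psi < -30, 1L, ifelse(psi <= 30, 2L, 3L))
  rr <- sqrt(px^2 + py^2)
  zone <- ifelse(rr <= 0.62 * map$polygons$mid$radius_mm, 1L, 0L)
  analytic <- 12L + side * 6L + zone * 3L + wedge
  expect_gt(mean(tr$assignment[sel] == analytic), 0.95)

  # random smooth warps keep the assignment a partition of the slice
  for (s in 1:10) {
    sch <- sweep(map$polygons$mid$outline, 2, an$center_mm[1:2], "+")
    wob <- smooth_shape(300 + s, n = 48, R = map$polygons$mid$radius_mm)
    wob <- sweep(wob, 2, an$center_mm[1:2], "+")
    w <- fit_deformation(sch, wob, n_control = 12)
    trw <- transfer_sectors(map, "mid", an, sl, rigid = shift, warp = w)
    expect_true(all((trw$assignment > 0) == gland))
  }
})
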