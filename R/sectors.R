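sides_names <- c("left", "right")
wedge_names <- c("anterior", "lateral", "posterior")

ring_sector_poly <- function(th1_deg, th2_deg, r_in, r_out, step_deg = 7.5) {
  th <- seq(th1_deg, th2_deg, by = step_deg) * pi / 180
  outer <- cbind(r_out * cos(th), r_out * sin(th))
  if (r_in <= 0) {
    poly <- rbind(outer, c(0, 0))
  } else {
    inner <- cbind(r_in * cos(rev(th)), r_in * sin(rev(th)))
    poly <- rbind(outer, inner)
  }
  colnames(poly) <- c("x", "y")
  poly
}

# Angular spans (degrees, x = lateral right, y = posterior) for each
# side x wedge; boundaries are multiples of the 48-gon vertex step so the
# twelve polygons tile the schematic outline exactly.
wedge_spans <- function() {
  list(
    right = list(anterior = c(-90, -30), lateral = c(-30, 30), posterior = c(30, 90)),
    left  = list(anterior = c(210, 270), lateral = c(150, 210), posterior = c(90, 150))
  )
}

#' Build the 36-sector schematic map of a prostate
#'
#' Twelve segments at each of the apex, mid and base: per region the gland is
#' split into left/right halves, peripheral/transition zones, and three angular
#' wedges (anterior/lateral/posterior), giving 2 x 2 x 3 = 12 sectors. Every
#' prostate voxel is assigned to exactly one sector (the sector voxel sets
#' partition the mask), and each region carries a 2D schematic plane whose
#' twelve polygons tile a polygonal prostate outline without overlap.
#'
#' @param anatomy a `prostate_anatomy`.
#' @param wedge_breaks_deg two angles (degrees from the lateral axis) splitting
#'   each half into anterior/lateral/posterior wedges; the 12-segment geometry
#'   is not standardised, so the subdivision is configurable.
#' @param inner_fraction radial fraction of the schematic outline bounding the
#'   transition zone on the schematic planes.
#' @return An object of class `sector_map` with elements `sectors` (tibble of
#'   36 rows: region, segment 1-12, side, zone, wedge, voxel count, biopsy
#'   status and Gleason score), `assignment` (integer voxel array of sector
#'   ids, 0 outside the gland), `polygons` (per-region list of 12 polygons
#'   plus the outline), `spacing`, `center_mm`.
#' @export
build_sector_map <- function(anatomy, wedge_breaks_deg = c(-30, 30),
                             inner_fraction = 0.62) {
  stopifnot(inherits(anatomy, "prostate_anatomy"))
  dim <- dim(anatomy$mask)
  if (!any(anatomy$mask)) abort("invalid anatomy: empty prostate mask")
  for (r in 1:3)
    if (!any(anatomy$region == r))
      abort(sprintf("invalid anatomy: empty %s region", region_names[r]))

  co <- coord_arrays(dim, anatomy$spacing)
  cx <- anatomy$center_mm[1]
  cy <- anatomy$center_mm[2]
  inmask <- which(anatomy$mask)
  x <- co$x[inmask] - cx
  y <- co$y[inmask] - cy
  side <- ifelse(x < 0, 1L, 2L)                      # left, right
  psi <- atan2(y, abs(x)) * 180 / pi                 # mirror-symmetric angle
  wedge <- ifelse(psi < wedge_breaks_deg[1], 1L,
                  ifelse(psi <= wedge_breaks_deg[2], 2L, 3L))
  zone <- anatomy$zone[inmask]
  region <- anatomy$region[inmask]
  segment <- (side - 1L) * 6L + (zone - 1L) * 3L + wedge
  sector_id <- (region - 1L) * 12L + segment

  assignment <- array(0L, dim)
  assignment[inmask] <- sector_id

  catalog <- tidyr::expand_grid(
    region = factor(region_names, levels = region_names),
    side = factor(sides_names, levels = sides_names),
    zone = factor(zone_names, levels = zone_names),
    wedge = factor(wedge_names, levels = wedge_names)
  )
  catalog <- dplyr::mutate(
    catalog,
    segment = (as.integer(.data$side) - 1L) * 6L +
      (as.integer(.data$zone) - 1L) * 3L + as.integer(.data$wedge),
    sector_id = (as.integer(.data$region) - 1L) * 12L + .data$segment
  )
  counts <- tibble::tibble(sector_id = sector_id) |>
    dplyr::count(.data$sector_id, name = "n_voxels")
  catalog <- dplyr::left_join(catalog, counts, by = "sector_id") |>
    dplyr::mutate(
      n_voxels = dplyr::coalesce(.data$n_voxels, 0L),
      biopsy_status = factor("unsampled", levels = c("positive", "negative", "unsampled")),
      gleason = NA_character_
    ) |>
    dplyr::arrange(.data$sector_id) |>
    dplyr::relocate("sector_id", "region", "segment")

  spans <- wedge_spans()
  polygons <- list()
  for (r in 1:3) {
    rsel <- region == r
    R_r <- max(sqrt(x[rsel]^2 + y[rsel]^2))
    polys <- list()
    for (s in 1:2) for (zn in 1:2) for (w in 1:3) {
      sp <- spans[[sides_names[s]]][[wedge_names[w]]]
      seg <- (s - 1L) * 6L + (zn - 1L) * 3L + w
      rin <- if (zn == 2L) 0 else inner_fraction * R_r
      rout <- if (zn == 2L) inner_fraction * R_r else R_r
      polys[[seg]] <- ring_sector_poly(sp[1], sp[2], rin, rout)
    }
    th <- seq(0, 360, by = 7.5) * pi / 180
    outline <- cbind(x = R_r * cos(th[-length(th)]), y = R_r * sin(th[-length(th)]))
    polygons[[region_names[r]]] <- list(sectors = polys, outline = outline,
                                        radius_mm = R_r)
  }

  structure(
    list(sectors = catalog, assignment = assignment, polygons = polygons,
         spacing = anatomy$spacing, center_mm = anatomy$center_mm,
         cores = NULL, detected_lesions = integer(0)),
    class = "sector_map"
  )
}

#' @export
print.sector_map <- function(x, ...) {
  ns <- table(x$sectors$biopsy_status)
  cat(sprintf("<sector_map> 36 sectors (12 per region); %d positive, %d negative, %d unsampled\n",
              ns[["positive"]], ns[["negative"]], ns[["unsampled"]]))
  invisible(x)
}

#' Biopsy sampling scheme
#'
#' @param n_systematic number of systematic cores, at least 10 (10-12 per
#'   guidelines).
#' @param lambda_mm scale of the detection model: a core traversing a tumour
#'   path of length L detects it with probability `1 - exp(-L / lambda_mm)`,
#'   so short intra-core tumour paths (small foci) are easily missed.
#' @param targeted whether image-targeted cores are added to the systematic
#'   scheme.
#' @param n_targeted_per_lesion targeted cores aimed at each lesion centroid.
#' @param step_mm sampling step along each core.
#' @param detect optional override: function of the path length (mm) returning
#'   a detection probability.
#' @return An object of class `biopsy_scheme`.
#' @export
biopsy_scheme <- function(n_systematic = 12, lambda_mm = 3, targeted = TRUE,
                          n_targeted_per_lesion = 2, step_mm = 0.5,
                          detect = NULL) {
  if (n_systematic < 10)
    abort("guideline-conformant schemes use at least 10 systematic cores")
  structure(
    list(n_systematic = as.integer(n_systematic), lambda_mm = lambda_mm,
         targeted = isTRUE(targeted),
         n_targeted_per_lesion = as.integer(n_targeted_per_lesion),
         step_mm = step_mm, detect = detect),
    class = "biopsy_scheme"
  )
}

# Systematic core entry pattern: per region, lateral and medial pairs; the
# first n cores of this fixed ordering are used (base-medial pair dropped
# first when n < 12).
systematic_core_positions <- function(anatomy) {
  a <- anatomy$semi_axes_mm[1]
  cx <- anatomy$center_mm[1]
  co <- coord_arrays(dim(anatomy$mask), anatomy$spacing)
  zc <- vapply(1:3, function(r) mean(co$z[anatomy$region == r]), numeric(1))
  grid <- tibble::tibble(
    region = rep(region_names[c(1, 2, 3)], each = 4),
    z_mm = rep(zc, each = 4),
    x_off = rep(c(-0.7, 0.7, -0.35, 0.35), times = 3),
    lateral = rep(c(TRUE, TRUE, FALSE, FALSE), times = 3)
  )
  ord <- order(match(grid$region, c("apex", "mid", "base")), !grid$lateral)
  grid <- grid[ord, ]
  grid$x_mm <- cx + grid$x_off * a
  grid
}

trace_core <- function(x_mm, z_mm, anatomy, map, lesions, step_mm) {
  b <- anatomy$semi_axes_mm[2]
  cy <- anatomy$center_mm[2]
  ys <- seq(cy - 1.6 * b, cy + 1.6 * b, by = step_mm)
  d <- dim(anatomy$mask)
  sp <- anatomy$spacing
  i <- round(x_mm / sp[1]) + 1L
  k <- round(z_mm / sp[3]) + 1L
  j <- round(ys / sp[2]) + 1L
  ok <- j >= 1 & j <= d[2] & i >= 1 & i <= d[1] & k >= 1 & k <= d[3]
  j <- j[ok]
  if (length(j) == 0)
    return(list(sectors = integer(0), path = rep(0, length(lesions))))
  idx <- cbind(rep(i, length(j)), j, rep(k, length(j)))
  inside <- anatomy$mask[idx]
  sectors <- unique(map$assignment[idx[inside, , drop = FALSE]])
  path <- vapply(lesions, function(l) sum(l$mask[idx]) * step_mm, numeric(1))
  per_lesion_sectors <- lapply(lesions, function(l) {
    hit <- l$mask[idx]
    unique(map$assignment[idx[hit, , drop = FALSE]])
  })
  list(sectors = sectors, path = path, per_lesion_sectors = per_lesion_sectors)
}

#' Simulate systematic and targeted biopsy sampling
#'
#' Each core is a needle track through the gland (antero-posterior direction)
#' at a fixed lateral/axial position. A core crossing a lesion detects it with
#' probability `1 - exp(-path / lambda)` in the in-core tumour path length;
#' on detection, the sectors along the intersected path turn biopsy-positive
#' and inherit the lesion's Gleason score. Sectors traversed by cores without a
#' detection are negative; untraversed sectors stay unsampled. Targeted cores
#' aim at lesion centroids (or image-detected centroids when supplied) and are
#' drawn after the systematic cores, so enabling them never alters the
#' systematic draws for a given seed.
#'
#' @param map unlabelled `sector_map` from [build_sector_map()].
#' @param anatomy the case's `prostate_anatomy`.
#' @param lesions list of ground-truth lesions (each with a `mask`).
#' @param scheme a [biopsy_scheme()].
#' @param seed optional integer for an isolated RNG stream.
#' @param targeted_centers optional matrix/list of (x, z) mm aiming points; by
#'   default the true lesion centroids stand in for image-detected ones.
#' @return The labelled `sector_map`, with `cores` (tibble of core positions
#'   and outcomes) and `detected_lesions` filled in.
#' @export
simulate_biopsy <- function(map, anatomy, lesions, scheme = biopsy_scheme(),
                            seed = NULL, targeted_centers = NULL) {
  stopifnot(inherits(map, "sector_map"), inherits(scheme, "biopsy_scheme"))
  run <- function() {
    detect_p <- function(L) {
      if (!is.null(scheme$detect)) return(scheme$detect(L))
      1 - exp(-L / scheme$lambda_mm)
    }
    status <- as.character(map$sectors$biopsy_status)
    gl <- map$sectors$gleason
    detected <- integer(0)
    cores <- list()

    fire_core <- function(x_mm, z_mm, type) {
      tr <- trace_core(x_mm, z_mm, anatomy, map, lesions, scheme$step_mm)
      hit_any <- FALSE
      for (li in seq_along(lesions)) {
        L <- tr$path[li]
        if (L <= 0) next
        p <- detect_p(L)
        if (p > 0 && runif(1) < p) {
          hit_any <- TRUE
          detected <<- union(detected, li)
          pos <- tr$per_lesion_sectors[[li]]
          pos <- pos[pos > 0]
          status[pos] <<- "positive"
          for (sid in pos) {
            old <- gl[sid]
            new <- lesions[[li]]$gleason
            if (is.na(old) ||
                match(new, gleason_levels) > match(old, gleason_levels))
              gl[sid] <<- new
          }
        }
      }
      sampled <- tr$sectors[tr$sectors > 0]
      fresh <- sampled[status[sampled] == "unsampled"]
      status[fresh] <<- "negative"
      cores[[length(cores) + 1]] <<- tibble::tibble(
        type = type, x_mm = x_mm, z_mm = z_mm,
        n_sectors = length(sampled), hit = hit_any)
    }

    sys <- systematic_core_positions(anatomy)
    sys <- sys[seq_len(min(scheme$n_systematic, nrow(sys))), ]
    for (ci in seq_len(nrow(sys)))
      fire_core(sys$x_mm[ci], sys$z_mm[ci], "systematic")

    if (scheme$targeted) {
      centers <- targeted_centers
      if (is.null(centers) && length(lesions) > 0)
        centers <- t(vapply(lesions, function(l) l$center_mm[c(1, 3)], numeric(2)))
      if (!is.null(centers) && nrow(centers) > 0) {
        offs <- seq(0, by = 1.5, length.out = scheme$n_targeted_per_lesion) -
          0.75 * (scheme$n_targeted_per_lesion - 1)
        for (ti in seq_len(nrow(centers)))
          for (o in offs)
            fire_core(centers[ti, 1] + o, centers[ti, 2], "targeted")
      }
    }

    out <- map
    out$sectors$biopsy_status <- factor(status,
                                        levels = c("positive", "negative", "unsampled"))
    out$sectors$gleason <- gl
    out$cores <- dplyr::bind_rows(cores)
    out$detected_lesions <- sort(detected)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Sector label table I/O
#'
#' The labelled sector table round-trips losslessly through CSV; schematic
#' polygons are serialised as GeoJSON-style JSON.
#'
#' @param map a `sector_map`.
#' @param path output file.
#' @param case_id optional case identifier column.
#' @export
write_sector_csv <- function(map, path, case_id = NA_integer_) {
  tbl <- dplyr::mutate(
    map$sectors, case_id = case_id,
    dplyr::across(c("region", "side", "zone", "wedge", "biopsy_status"), as.character)
  ) |>
    dplyr::relocate("case_id")
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_sector_csv
#' @export
read_sector_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(gleason = readr::col_character()))
}

#' @rdname write_sector_csv
#' @export
write_sector_polygons_json <- function(map, path) {
  feat <- purrr::imap(map$polygons, function(pl, rg) {
    list(region = rg, radius_mm = pl$radius_mm,
         outline = unname(apply(pl$outline, 1, as.numeric, simplify = FALSE)),
         sectors = purrr::map(pl$sectors, function(p)
           unname(apply(p, 1, as.numeric, simplify = FALSE))))
  })
  jsonlite::write_json(feat, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
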