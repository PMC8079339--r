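new_stat_result <- function(test, statistic, p_value, groups = NA_character_,
                            n = NA_integer_, flag = NA_character_) {
  tibble::tibble(test = test, statistic = statistic, p_value = p_value,
                 groups = groups, n = n, flag = flag)
}

#' Normality screening per group
#'
#' One-sample Kolmogorov-Smirnov test of each group against a normal
#' distribution with the sample's own mean and SD (the screening step applied
#' before choosing non-parametric comparisons). Constant samples are flagged
#' and skipped rather than tested.
#'
#' @param data data frame with the metric and a grouping column, or a bare
#'   numeric vector.
#' @param value,group column names (tidy-selection by name, as strings).
#' @return Tibble with one row per group: statistic, p-value, n, flag.
#' @export
normality_screen <- function(data, value = "value", group = NULL) {
  if (is.numeric(data)) data <- tibble::tibble(value = data)
  groups <- if (is.null(group)) list(all = data) else
    split(data, data[[group]])
  purrr::imap_dfr(groups, function(g, nm) {
    x <- g[[value]]
    x <- x[!is.na(x)]
    if (length(x) < 5)
      return(new_stat_result("ks_normal", NA_real_, NA_real_, nm, length(x),
                             "too_few"))
    if (sd(x) == 0)
      return(new_stat_result("ks_normal", NA_real_, NA_real_, nm, length(x),
                             "degenerate_constant"))
    kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    new_stat_result("ks_normal", unname(kt$statistic), kt$p.value, nm, length(x))
  })
}

#' Kruskal-Wallis comparison of a metric across methods
#'
#' Non-parametric comparison of a correlation metric (DSC, YI, sensitivity or
#' specificity) between contouring methods. When every observation is tied
#' across all groups the comparison is vacuous: H = 0, p = 1.
#'
#' @param data data frame of per-lesion records.
#' @param value metric column name.
#' @param group method column name.
#' @return One-row tibble: H statistic, p-value, group count and sizes.
#' @export
compare_methods <- function(data, value = "dsc", group = "method") {
  x <- data[[value]]
  g <- factor(data[[group]])
  keep <- !is.na(x)
  x <- x[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 3)) abort("need n >= 3 per group")
  if (length(unique(x)) == 1)
    return(new_stat_result("kruskal_wallis", 0, 1,
                           paste(levels(g), collapse = "|"), length(x),
                           "all_tied"))
  kt <- kruskal.test(x, g)
  new_stat_result("kruskal_wallis", unname(kt$statistic), kt$p.value,
                  paste(levels(g), collapse = "|"), length(x))
}

#' Build the predictive-factor table from per-lesion records
#'
#' One row per lesion with the factor strata used in the predictive-factor
#' analysis: localisation (apex/mid/base), relative-volume threshold indicators
#' (lesion at least 5/10/15/20% of the gland — threshold semantics follow the
#' study's text, which found superior accuracy for lesions of at least 15%),
#' Gleason strata, PSA bins (<=10, 10-20, >20 ng/mL) and SUVmax bins
#' (2, 3, >=4).
#'
#' @param records tibble with columns `dsc`, `region`, `relvol`, `gleason`,
#'   `psa`, and `suvmax`.
#' @param volume_thresholds relative-volume thresholds (fractions).
#' @return The input plus indicator/stratum columns, class `factor_table`.
#' @export
factor_table <- function(records, volume_thresholds = c(0.05, 0.10, 0.15, 0.20)) {
  out <- records
  for (v in volume_thresholds)
    out[[sprintf("vol_ge_%d", round(100 * v))]] <- records$relvol >= v
  out$psa_bin <- cut(records$psa, c(-Inf, 10, 20, Inf),
                     labels = c("<=10", "10-20", ">20"))
  sv <- records$suvmax
  out$suvmax_bin <- cut(sv, c(-Inf, 2.5, 3.5, Inf), labels = c("2", "3", ">=4"))
  class(out) <- c("factor_table", class(out))
  out
}

point_biserial <- function(ind, y) {
  keep <- !is.na(ind) & !is.na(y)
  ind <- ind[keep]
  y <- y[keep]
  if (length(unique(ind)) < 2 || length(unique(y)) < 2 || length(y) < 3)
    return(list(r = NA_real_, p = NA_real_, n = length(y),
                flag = "single_class"))
  ct <- cor.test(as.numeric(ind), y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(y), flag = NA_character_)
}

#' Predictive-factor correlations with DSC
#'
#' Point-biserial Pearson correlation between stratum membership (or a
#' relative-volume threshold indicator) and the per-lesion DSC, one row per
#' factor/stratum, mirroring the layout of a factor-correlation table.
#' Single-class indicators are reported as missing rather than an error.
#'
#' @param table a [factor_table()].
#' @param value metric column (default `"dsc"`).
#' @return Tibble: `factor`, `stratum`, `r`, `p_value`, `n`, `flag`.
#' @export
factor_correlation <- function(table, value = "dsc") {
  y <- table[[value]]
  rows <- list()
  add <- function(factor, stratum, ind) {
    pb <- point_biserial(ind, y)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      factor = factor, stratum = stratum, r = pb$r, p_value = pb$p,
      n = pb$n, flag = pb$flag)
  }
  for (rg in c("apex", "mid", "base"))
    add("localisation", rg, table$region == rg)
  for (nm in grep("^vol_ge_", names(table), value = TRUE))
    add("relative_volume", paste0(">=", sub("vol_ge_", "", nm), "%"), table[[nm]])
  if ("gleason" %in% names(table))
    for (gs in intersect(gleason_levels, unique(table$gleason)))
      add("gleason", gs, table$gleason == gs)
  if ("psa_bin" %in% names(table))
    for (pb in levels(table$psa_bin))
      add("psa", pb, table$psa_bin == pb)
  if ("suvmax_bin" %in% names(table))
    for (sb in levels(table$suvmax_bin))
      add("suvmax", sb, table$suvmax_bin == sb)
  dplyr::bind_rows(rows)
}

#' Record-level cohort generator for statistical calibration
#'
#' Draws per-lesion records in which DSC degrades for small lesions: the DSC
#' response is a logistic function of the lesion's relative volume (low
#' plateau below the knee, high plateau above) plus Gaussian noise, clipped to
#' the unit interval. Used to calibrate and power-check the factor-correlation
#' layer without rendering images; the relative-volume range deliberately
#' extends below 5% so every volume-threshold indicator has both classes.
#'
#' @param n_lesions records per cohort.
#' @param knee relative volume at the response midpoint.
#' @param width logistic width.
#' @param low,high DSC plateaus.
#' @param noise_sd residual SD.
#' @param seed optional integer seed.
#' @return Tibble with `relvol`, `dsc`, `region`, `gleason`, `psa`, `suvmax`.
#' @export
simulate_metric_cohort <- function(n_lesions = 30, knee = 0.13, width = 0.03,
                                   low = 0.18, high = 0.72, noise_sd = 0.10,
                                   seed = NULL) {
  draw <- function() {
    relvol <- pmin(pmax(rlnorm(n_lesions, log(0.10), 0.9), 0.01), 0.75)
    mu <- low + (high - low) * stats::plogis((relvol - knee) / width)
    dsc <- pmin(pmax(mu + rnorm(n_lesions, 0, noise_sd), 0), 1)
    tibble::tibble(
      relvol = relvol, dsc = dsc,
      region = sample(region_names, n_lesions, replace = TRUE),
      gleason = sample(gleason_levels, n_lesions, replace = TRUE,
                       prob = c(0.23, 0.17, 0.14, 0.28, 0.18)),
      psa = rlnorm(n_lesions, log(15.4), 0.9),
      suvmax = pmin(pmax(rlnorm(n_lesions, log(8), 0.5), 1.9), 21.4)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}
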