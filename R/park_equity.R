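#' Park-equity analysis of one urban area
#'
#' The package's main entry point. Given a city (synthetic or read from
#' disk), it computes the Index of Concentration at the Extremes per tract
#' for the requested variants, ranks tracts into privilege quartiles,
#' sections parks by tract boundaries, computes the two park-size metrics
#' and the area-weighted park exposure means for every raster variable
#' (compositing NDVI from the scene stack when one is present), and
#' contrasts the least (Q1) and most (Q4) privileged quartiles with Welch
#' t-tests.
#'
#' @param city a `synthetic_city` from [generate_city()] or [read_city()]
#' @param variants ICE variants to compute: subset of "combined", "income",
#'   "race"
#' @param target_share income-cutpoint target population share (default
#'   0.20, the conventional 20th/80th percentile extremes)
#' @param cutpoint_scope "pooled" or "per_urban_area" income cutpoints
#' @param nonpark also compute non-park exposure means (sensitivity
#'   analysis contrasting park and non-park land)
#' @param max_cloud scene-discard threshold for NDVI compositing
#' @return object of class `park_equity` with components `ice`,
#'   `quartiles`, `cutpoints`, `sections`, `sizes`, `exposures`,
#'   `disparity` (one row per variant x variable), and `log`
#' @seealso [generate_city()], [run_pipeline()], [cross_city_summary()]
#' @examples
#' city <- generate_city(city_config(n_tracts_x = 6, n_tracts_y = 6,
#'                                   n_parks = 20, seed = 7))
#' fit <- park_equity(city, variants = "combined")
#' summary(fit)
#' coef(fit)
#' @export
park_equity <- function(city, variants = c("combined", "income", "race"),
                        target_share = 0.20,
                        cutpoint_scope = c("pooled", "per_urban_area"),
                        nonpark = FALSE, max_cloud = 0.20) {
  variants <- match.arg(variants, several.ok = TRUE)
  cutpoint_scope <- match.arg(cutpoint_scope)
  log <- list()

  rasters <- city$rasters
  if (!is.null(city$scenes)) {
    comp <- composite_ndvi(city$scenes, max_cloud = max_cloud)
    cov <- vapply(city$scenes$scenes, function(s) s$coverage, numeric(1))
    log$scenes_total <- length(cov)
    log$scenes_discarded <- sum(cov >= max_cloud)
    rasters$ndvi <- comp
  }
  work <- city
  work$rasters <- rasters

  cutpoints <- NULL
  if (any(variants != "race")) {
    cutpoints <- select_income_cutpoints(city$demographics, target_share,
                                         cutpoint_scope)
    if (is.null(cutpoints$by_area)) {
      log$achieved_low_share <- cutpoints$achieved_low_share
      log$achieved_high_share <- cutpoints$achieved_high_share
    }
  }
  ice <- do.call(rbind, lapply(variants, function(v) {
    compute_ice_table(city$demographics, cutpoints, v)
  }))
  quart <- do.call(rbind, lapply(variants, function(v) {
    assign_quartiles(ice[ice$variant == v, , drop = FALSE])
  }))
  rownames(quart) <- NULL
  excluded <- unique(ice$tract_id[is.na(ice$ice)])
  log$tracts_total <- nrow(city$tracts)
  log$tracts_excluded_undefined_ice <- excluded

  sections <- section_parks(city$parks, city$tracts)
  sizes <- size_metrics(city$parks, city$tracts, sections)
  expo <- exposure_summary(work, sections, nonpark = nonpark)

  disparity <- list(); k <- 0L
  ua <- if (!is.null(city$config$urban_area_id)) city$config$urban_area_id else "city"
  for (v in variants) {
    qv <- quart[quart$variant == v, c("tract_id", "quartile")]
    for (var in names(work$rasters)) {
      e <- expo[expo$variable == var, , drop = FALSE]
      m <- merge(e, qv, by = "tract_id")
      k <- k + 1L
      disparity[[k]] <- disparity_row(m$park_mean, m$quartile,
                                      m$urban_mean[1], ua, var, v)
    }
    ms <- merge(sizes, qv, by = "tract_id")
    for (var in c("percent_park", "largest_park_km2")) {
      k <- k + 1L
      disparity[[k]] <- disparity_row(ms[[var]], ms$quartile, NA_real_,
                                      ua, var, v)
    }
  }
  disparity <- do.call(rbind, disparity)
  rownames(disparity) <- NULL
  log$n_tests <- sum(!is.na(disparity$p_value))
  log$variants <- variants
  log$nonpark <- nonpark

  structure(list(ice = ice, quartiles = quart, cutpoints = cutpoints,
                 sections = sections, sizes = sizes, exposures = expo,
                 disparity = disparity, urban_area_id = ua,
                 tracts = city$tracts, log = log),
            class = "park_equity")
}

#' @export
print.park_equity <- function(x, ...) {
  cat(sprintf("Park-equity analysis: %s\n", x$urban_area_id))
  cat(sprintf("  %d tracts (%d excluded, undefined ICE), %d park sections\n",
              x$log$tracts_total, length(x$log$tracts_excluded_undefined_ice),
              nrow(x$sections)))
  if (!is.null(x$log$achieved_low_share)) {
    cat(sprintf("  income cutpoints: low %.1f%%, high %.1f%% of householders\n",
                100 * x$log$achieved_low_share, 100 * x$log$achieved_high_share))
  }
  d <- x$disparity[x$disparity$variant == x$disparity$variant[1], ]
  cat(sprintf("  Q1-Q4 contrasts (%s ICE):\n", d$variant[1]))
  for (i in seq_len(nrow(d))) {
    cat(sprintf("    %-16s Q1-Q4 = %8.3f  (p = %.3g %s)\n", d$variable[i],
                d$q1_minus_q4[i], d$p_value[i], d$significance[i]))
  }
  invisible(x)
}

#' @export
summary.park_equity <- function(object, ...) {
  structure(list(fit = object), class = "summary.park_equity")
}

#' @export
print.summary.park_equity <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nQuartile means (least -> most privileged):\n")
  d <- f$disparity
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  [%s] %-16s %9.3f %9.3f %9.3f %9.3f\n", d$variant[i],
                d$variable[i], d$q1_mean[i], d$q2_mean[i], d$q3_mean[i],
                d$q4_mean[i]))
  }
  invisible(x)
}

#' @export
#' @describeIn park_equity Q1 - Q4 differences for the combined ICE variant
#'   (or the first computed variant), as a named vector.
coef.park_equity <- function(object, variant = NULL, ...) {
  d <- object$disparity
  if (is.null(variant)) {
    variant <- if ("combined" %in% d$variant) "combined" else d$variant[1]
  }
  d <- d[d$variant == variant, ]
  stats::setNames(d$q1_minus_q4, d$variable)
}

#' Plot Q1-vs-Q4 percent differences
#'
#' A dot chart of the percent difference in park conditions between the
#' least and most privileged quartiles, one dot per variable; dots to the
#' right of the zero line indicate higher values in the least privileged
#' quartile. Significance is annotated with the usual star tiers.
#'
#' @param x a `park_equity` fit
#' @param variant ICE variant to plot
#' @param ... passed to [graphics::dotchart()]
#' @export
plot.park_equity <- function(x, variant = NULL, ...) {
  d <- x$disparity
  if (is.null(variant)) {
    variant <- if ("combined" %in% d$variant) "combined" else d$variant[1]
  }
  d <- d[d$variant == variant & !is.na(d$percent_diff_q1_q4), ]
  labs <- sprintf("%s %s", d$variable, d$significance)
  graphics::dotchart(d$percent_diff_q1_q4, labels = labs,
                     xlab = "Percent difference, Q1 vs Q4 (%)",
                     main = sprintf("Park conditions, least vs most privileged (%s ICE)",
                                    variant), ...)
  graphics::abline(v = 0, lty = 3, col = "red")
  invisible(x)
}
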