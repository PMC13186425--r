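# Synthetic urban areas with planted structure.
#
# A synthetic city is a rectangular lattice of square census tracts with a
# latent privilege score in [-1, 1] that rises along a configurable spatial
# gradient. Demographics (householder counts by income bracket, overall and
# for Black and white-alone non-Hispanic strata) are drawn so that computed
# ICE increases with the latent score; exposure rasters are affine functions
# of the containing tract's latent score plus iid cell noise; parks are
# rectangles whose placement and size can be biased toward privileged
# tracts. Every planted quantity is recorded in `$truth` so the downstream
# pipeline can be validated against ground truth.

#' Synthetic city configuration
#'
#' @param n_tracts_x,n_tracts_y lattice dimensions (tracts)
#' @param tract_size tract edge length (km)
#' @param privilege_gradient list(angle_deg, strength): latent privilege is
#'   the tract-centre position projected on the gradient direction, scaled
#'   to [-strength, strength]
#' @param n_parks number of parks
#' @param park_size_range park base-area range (km^2)
#' @param park_placement_bias logistic coefficient tying park placement
#'   probability and size multiplier to latent privilege (0 = unbiased)
#' @param exposure_params named list per variable of
#'   list(intercept, slope, noise_sd); slope is per unit latent privilege.
#'   Defaults emulate urban NO2 (ppb), PM2.5 (ug/m3), WBGT (degC) scales.
#' @param ndvi_params intercept/slope/noise_sd for the planted NDVI surface
#' @param raster_resolution exposure-raster cell size (km); must divide
#'   `tract_size` so cells nest within tracts
#' @param n_scenes number of two-band scenes in the NDVI stack
#' @param cloud_scene_fraction probability a scene is heavily clouded
#'   (pixel cloud rate 0.35, so it exceeds the 20% scene threshold)
#' @param cloud_pixel_fraction per-pixel cloud probability in ordinary
#'   scenes
#' @param water_fraction fraction of the city covered by the water blob
#' @param n_brackets income brackets in the demographic tables
#' @param households_per_tract householders per tract (fixed)
#' @param demographics "sampled" draws multinomial counts; "expected" uses
#'   rounded expected counts (noise-free demographics)
#' @param urban_area_id identifier stamped on all tables
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   cities
#' @return validated `city_config` list
#' @export
city_config <- function(n_tracts_x = 12, n_tracts_y = 12, tract_size = 1,
                        privilege_gradient = list(angle_deg = 35, strength = 1),
                        n_parks = 60,
                        park_size_range = c(0.02, 0.3),
                        park_placement_bias = 0,
                        exposure_params = list(
                          no2 = list(intercept = 12, slope = -5, noise_sd = 1),
                          pm25 = list(intercept = 8, slope = -1, noise_sd = 0.5),
                          wbgt = list(intercept = 24, slope = -0.8, noise_sd = 0.3)),
                        ndvi_params = list(intercept = 0.35, slope = 0.12,
                                           noise_sd = 0.04),
                        raster_resolution = 0.25,
                        n_scenes = 6, cloud_scene_fraction = 0.2,
                        cloud_pixel_fraction = 0.1,
                        water_fraction = 0.04,
                        n_brackets = 10, households_per_tract = 600,
                        demographics = c("sampled", "expected"),
                        urban_area_id = "synthcity", seed = 1L) {
  demographics <- match.arg(demographics)
  cfg <- list(n_tracts_x = as.integer(n_tracts_x),
              n_tracts_y = as.integer(n_tracts_y),
              tract_size = tract_size,
              privilege_gradient = privilege_gradient,
              n_parks = as.integer(n_parks),
              park_size_range = park_size_range,
              park_placement_bias = park_placement_bias,
              exposure_params = exposure_params,
              ndvi_params = ndvi_params,
              raster_resolution = raster_resolution,
              n_scenes = as.integer(n_scenes),
              cloud_scene_fraction = cloud_scene_fraction,
              cloud_pixel_fraction = cloud_pixel_fraction,
              water_fraction = water_fraction,
              n_brackets = as.integer(n_brackets),
              households_per_tract = as.integer(households_per_tract),
              demographics = demographics,
              urban_area_id = urban_area_id,
              seed = as.integer(seed))
  stopifnot(cfg$n_tracts_x >= 1, cfg$n_tracts_y >= 1, cfg$n_parks >= 0,
            cfg$n_scenes >= 1, cfg$n_brackets >= 3,
            cfg$households_per_tract >= 1)
  if (cfg$tract_size <= 0) stop("tract_size must be positive")
  if (cfg$raster_resolution <= 0) stop("raster_resolution must be positive")
  ratio <- cfg$tract_size / cfg$raster_resolution
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("raster_resolution must divide tract_size (cells nest within tracts)")
  }
  for (v in names(cfg$exposure_params)) {
    if (cfg$exposure_params[[v]]$noise_sd < 0) stop("noise_sd must be >= 0")
  }
  if (cfg$cloud_scene_fraction < 0 || cfg$cloud_scene_fraction > 1 ||
      cfg$cloud_pixel_fraction < 0 || cfg$cloud_pixel_fraction > 1) {
    stop("cloud fractions must lie in [0, 1]")
  }
  if (diff(range(cfg$park_size_range)) < 0 || min(cfg$park_size_range) <= 0) {
    stop("park_size_range must be positive and ordered")
  }
  class(cfg) <- "city_config"
  cfg
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Latent privilege per tract from the spatial gradient, in
# [-strength, strength].
latent_scores <- function(cfg, cx, cy) {
  th <- cfg$privilege_gradient$angle_deg * pi / 180
  proj <- cos(th) * cx + sin(th) * cy
  if (max(proj) - min(proj) < 1e-12) return(rep(0, length(proj)))
  cfg$privilege_gradient$strength *
    (2 * (proj - min(proj)) / (max(proj) - min(proj)) - 1)
}

# Bracket distribution shifting monotonically with latent privilege: a
# binomial pmf over bracket indices with success probability logistic in s.
bracket_probs <- function(s, k) {
  stats::dbinom(0:(k - 1L), k - 1L, stats::plogis(1.1 * s))
}

# Race/ethnicity shares (white-NH, Black, other), logistic in latent
# privilege and, for householders, in income bracket.
race_shares <- function(s, bracket_dev = 0) {
  lw <- 0.25 + 1.3 * s + 0.22 * bracket_dev
  lb <- -0.25 - 1.3 * s - 0.22 * bracket_dev
  ew <- exp(lw); eb <- exp(lb)
  tot <- ew + eb + 1
  c(white = ew / tot, black = eb / tot, other = 1 / tot)
}

generate_demographics <- function(cfg, tracts) {
  k <- cfg$n_brackets
  nhh <- cfg$households_per_tract
  sampled <- cfg$demographics == "sampled"
  n <- nrow(tracts)
  m_all <- matrix(0L, n, k)
  m_b <- matrix(0L, n, k)
  m_w <- matrix(0L, n, k)
  pop <- matrix(0L, n, 3L)
  pop_total <- round(2.5 * nhh)
  for (i in seq_len(n)) {
    s <- tracts$latent[i]
    pb <- bracket_probs(s, k)
    if (sampled) {
      all_i <- as.integer(stats::rmultinom(1L, nhh, pb))
    } else {
      all_i <- as.integer(round(nhh * pb))
    }
    for (j in seq_len(k)) {
      if (all_i[j] == 0L) next
      sh <- race_shares(s, j - (k + 1) / 2)
      if (sampled) {
        split3 <- as.integer(stats::rmultinom(1L, all_i[j], sh))
      } else {
        split3 <- as.integer(round(all_i[j] * sh[1:2]))
        split3[2] <- min(split3[2], all_i[j] - split3[1])
        split3 <- c(split3, all_i[j] - sum(split3))
      }
      m_w[i, j] <- split3[1]; m_b[i, j] <- split3[2]
    }
    m_all[i, ] <- all_i
    shp <- race_shares(s)
    if (sampled) {
      pop[i, ] <- as.integer(stats::rmultinom(1L, pop_total, shp))
    } else {
      pw <- as.integer(round(pop_total * shp[1]))
      pbk <- as.integer(min(round(pop_total * shp[2]), pop_total - pw))
      pop[i, ] <- c(pw, pbk, pop_total - pw - pbk)
    }
  }
  fmt <- function(m, stem) {
    colnames(m) <- sprintf("hh_%s_b%02d", stem, seq_len(k))
    m
  }
  out <- data.frame(tract_id = tracts$tract_id,
                    urban_area_id = cfg$urban_area_id,
                    stringsAsFactors = FALSE)
  out <- cbind(out, fmt(m_all, "all"), fmt(m_b, "black"), fmt(m_w, "white_nh"))
  out$pop_white_nh <- pop[, 1]
  out$pop_black <- pop[, 2]
  out$pop_total <- rowSums(pop)
  out
}

generate_parks <- function(cfg, tracts) {
  if (cfg$n_parks == 0L) return(list())
  wgt <- stats::plogis(cfg$park_placement_bias * tracts$latent)
  parks <- vector("list", cfg$n_parks)
  for (p in seq_len(cfg$n_parks)) {
    ti <- sample.int(nrow(tracts), 1L, prob = wgt)
    cx <- stats::runif(1, tracts$x0[ti], tracts$x1[ti])
    cy <- stats::runif(1, tracts$y0[ti], tracts$y1[ti])
    base <- stats::runif(1, cfg$park_size_range[1], cfg$park_size_range[2])
    mult <- 2 * stats::plogis(cfg$park_placement_bias * tracts$latent[ti])
    area <- base * mult
    aspect <- stats::runif(1, 0.6, 1.6)
    w <- sqrt(area * aspect); h <- area / w
    poly <- rect_poly(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    parks[[p]] <- list(park_id = sprintf("park_%03d", p),
                       name = sprintf("Synthetic Park %d", p),
                       poly = poly, area = area)
  }
  parks
}

generate_raster <- function(cfg, lat_grid, params, variable) {
  cpt <- as.integer(round(cfg$tract_size / cfg$raster_resolution))
  # per-cell latent: expand the tract lattice; lat_grid rows are north-first
  latc <- lat_grid[rep(seq_len(nrow(lat_grid)), each = cpt),
                   rep(seq_len(ncol(lat_grid)), each = cpt)]
  v <- params$intercept + params$slope * latc
  if (params$noise_sd > 0) {
    v <- v + matrix(stats::rnorm(length(latc), 0, params$noise_sd),
                    nrow(latc), ncol(latc))
  }
  H <- cfg$n_tracts_y * cfg$tract_size
  raster_field(v, c(0, H), cfg$raster_resolution, variable)
}

generate_water_mask <- function(cfg, nr, nc) {
  if (cfg$water_fraction <= 0) return(matrix(FALSE, nr, nc))
  W <- cfg$n_tracts_x * cfg$tract_size
  H <- cfg$n_tracts_y * cfg$tract_size
  cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
  rad <- sqrt(cfg$water_fraction * W * H / pi)
  res <- cfg$raster_resolution
  px <- res * (seq_len(nc) - 0.5)
  py <- H - res * (seq_len(nr) - 0.5)
  outer(py, px, function(y, x) (x - cx)^2 + (y - cy)^2 < rad^2)
}

#' Generate a synthetic city
#'
#' @param config a [city_config()]
#' @return a `synthetic_city`: list with `config`, `extent` (x0, y0, x1,
#'   y1), `tracts` (data.frame: tract_id, ix, iy, x0, y0, x1, y1, latent),
#'   `demographics`, `parks`, `rasters` (named `raster_field` list),
#'   `ndvi_truth`, `scenes` (a `scene_stack`), `water_mask`, and `truth`
#'   (planted latent scores and exposure parameters)
#' @export
generate_city <- function(config) {
  if (!inherits(config, "city_config")) config <- do.call(city_config, config)
  with_seed(config$seed, {
    nx <- config$n_tracts_x; ny <- config$n_tracts_y; ts <- config$tract_size
    grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
    tracts <- data.frame(
      tract_id = sprintf("t_%03d_%03d", grid$ix, grid$iy),
      ix = grid$ix, iy = grid$iy,
      x0 = (grid$ix - 1) * ts, y0 = (grid$iy - 1) * ts,
      x1 = grid$ix * ts, y1 = grid$iy * ts,
      stringsAsFactors = FALSE)
    tracts$latent <- latent_scores(config, (tracts$x0 + tracts$x1) / 2,
                                   (tracts$y0 + tracts$y1) / 2)
    demog <- generate_demographics(config, tracts)
    parks <- generate_parks(config, tracts)
    # latent on the tract lattice, row 1 = northern row (iy = ny)
    lat_grid <- matrix(NA_real_, ny, nx)
    lat_grid[cbind(ny - tracts$iy + 1L, tracts$ix)] <- tracts$latent
    rasters <- list()
    for (v in names(config$exposure_params)) {
      rasters[[v]] <- generate_raster(config, lat_grid,
                                      config$exposure_params[[v]], v)
    }
    ndvi_truth <- generate_raster(config, lat_grid, config$ndvi_params, "ndvi")
    ndvi_truth$values[] <- pmin(1, pmax(-1, ndvi_truth$values))
    wm <- generate_water_mask(config, nrow(ndvi_truth$values),
                              ncol(ndvi_truth$values))
    scenes <- generate_scene_stack(ndvi_truth, config, water_mask = wm)
    structure(list(
      config = config,
      extent = c(0, 0, nx * ts, ny * ts),
      tracts = tracts, demographics = demog, parks = parks,
      rasters = rasters, ndvi_truth = ndvi_truth, scenes = scenes,
      water_mask = wm,
      truth = list(latent = stats::setNames(tracts$latent, tracts$tract_id),
                   exposure_params = config$exposure_params,
                   ndvi_params = config$ndvi_params)),
      class = "synthetic_city")
  })
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> %s: %d x %d tracts (%g km), %d parks, %d exposure rasters, %d scenes\n",
              x$config$urban_area_id, x$config$n_tracts_x, x$config$n_tracts_y,
              x$config$tract_size, length(x$parks), length(x$rasters),
              length(x$scenes$scenes)))
  invisible(x)
}

#' Generate a two-band scene stack from a planted NDVI surface
#'
#' Each scene carries NIR and Red reflectance grids constructed so that
#' (NIR - Red)/(NIR + Red) equals the truth NDVI at every pixel, plus a
#' per-pixel cloud flag. A `cloud_scene_fraction` share of scenes is heavily
#' clouded (pixel cloud rate 0.35, exceeding the 20% scene-discard
#' threshold); the rest flag pixels at `cloud_pixel_fraction`.
#'
#' @param truth_ndvi a `raster_field` with values in [-1, 1]
#' @param config a [city_config()]
#' @param water_mask logical matrix passed through to the stack
#' @return a `scene_stack`: list(scenes, water_mask, origin, cellsize)
#' @export
generate_scene_stack <- function(truth_ndvi, config, water_mask = NULL) {
  v <- truth_ndvi$values
  if (any(v < -1 - 1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
    stop("truth NDVI values must lie in [-1, 1]")
  }
  nir <- (1 + v) / 2
  red <- (1 - v) / 2
  scenes <- vector("list", config$n_scenes)
  for (i in seq_len(config$n_scenes)) {
    heavy <- stats::runif(1) < config$cloud_scene_fraction
    p <- if (heavy) max(0.35, config$cloud_pixel_fraction) else config$cloud_pixel_fraction
    cl <- matrix(stats::runif(length(v)) < p, nrow(v), ncol(v))
    scenes[[i]] <- list(nir = nir, red = red, cloud = cl, coverage = mean(cl))
  }
  structure(list(scenes = scenes, water_mask = water_mask,
                 origin = truth_ndvi$origin, cellsize = truth_ndvi$cellsize),
            class = "scene_stack")
}

#' Write a synthetic city to disk
#'
#' Vectors as GeoJSON, demographics as CSV, rasters and masks as ESRI ASCII
#' grids, scenes as per-band grids, and the planted truth as JSON. The file
#' set round-trips losslessly through [read_city()].
#'
#' @param city a `synthetic_city`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_city <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  tr_feats <- lapply(seq_len(nrow(city$tracts)), function(i) {
    t <- city$tracts[i, ]
    list(geometry = rect_poly(t$x0, t$y0, t$x1, t$y1),
         properties = list(tract_id = t$tract_id,
                           urban_area_id = city$config$urban_area_id,
                           latent = t$latent))
  })
  write_geojson(tr_feats, file.path(dir, "tracts.geojson"))
  pk_feats <- lapply(city$parks, function(p) {
    list(geometry = p$poly,
         properties = list(park_id = p$park_id, name = p$name,
                           area_km2 = p$area))
  })
  write_geojson(pk_feats, file.path(dir, "parks.geojson"))
  utils::write.csv(city$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  for (v in names(city$rasters)) {
    write_asc(city$rasters[[v]], file.path(dir, sprintf("raster_%s.asc", v)))
  }
  write_asc(city$ndvi_truth, file.path(dir, "ndvi_truth.asc"))
  wm <- raster_field(city$water_mask + 0, city$ndvi_truth$origin,
                     city$ndvi_truth$cellsize, "water")
  write_asc(wm, file.path(dir, "water_mask.asc"))
  sdir <- file.path(dir, "scenes")
  dir.create(sdir, showWarnings = FALSE)
  for (i in seq_along(city$scenes$scenes)) {
    s <- city$scenes$scenes[[i]]
    for (band in c("nir", "red")) {
      write_asc(raster_field(s[[band]], city$scenes$origin,
                             city$scenes$cellsize, band),
                file.path(sdir, sprintf("scene_%02d_%s.asc", i, band)))
    }
    write_asc(raster_field(s$cloud + 0, city$scenes$origin,
                           city$scenes$cellsize, "cloud"),
              file.path(sdir, sprintf("scene_%02d_cloud.asc", i)))
  }
  truth <- list(urban_area_id = city$config$urban_area_id,
                extent = city$extent,
                latent = as.list(city$truth$latent),
                exposure_params = city$truth$exposure_params,
                ndvi_params = city$truth$ndvi_params,
                seed = city$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
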