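# Shared fixtures: small cities and rasters built in code.

# A compact city config for fast end-to-end runs.
small_config <- function(seed = 1, ...) {
  args <- list(n_tracts_x = 6, n_tracts_y = 6, n_parks = 25,
               raster_resolution = 0.5, n_scenes = 3,
               exposure_params = list(
                 no2 = list(intercept = 12, slope = -5, noise_sd = 1)),
               water_fraction = 0.03, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(city_config, args)
}

# A raster with explicit values on a unit grid: origin top-left (0, nrow),
# cellsize 1, values given row-major north-first.
unit_raster <- function(values, variable = "value") {
  raster_field(values, c(0, nrow(values)), 1, variable)
}

# Random convex polygon around (cx, cy).
random_convex_poly <- function(cx, cy, rmin = 0.4, rmax = 1.6) {
  n <- sample(3:8, 1)
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Fine-grid integration oracle for zonal means: deterministic lattice of
# points over the polygon bbox, point-in-polygon membership, cell lookup.
zonal_mean_gridded <- function(r, poly, n_grid = 800) {
  bb <- parkequity:::poly_bbox(poly)
  gx <- seq(bb[1], bb[3], length.out = n_grid)
  gy <- seq(bb[2], bb[4], length.out = n_grid)
  px <- rep(gx, times = n_grid)
  py <- rep(gy, each = n_grid)
  inside <- parkequity:::points_in_poly(px, py, poly)
  px <- px[inside]; py <- py[inside]
  ci <- 1L + floor((px - r$origin[1]) / r$cellsize)
  ri <- 1L + floor((r$origin[2] - py) / r$cellsize)
  ok <- ri >= 1 & ri <= nrow(r$values) & ci >= 1 & ci <= ncol(r$values)
  v <- r$values[cbind(ri[ok], ci[ok])]
  mean(v, na.rm = TRUE)
}

# Mean raster value per tract, using the nesting of cells within tracts.
tract_cell_means <- function(city, variable) {
  r <- city$rasters[[variable]]
  cpt <- as.integer(round(city$config$tract_size / city$config$raster_resolution))
  ny <- city$config$n_tracts_y
  sapply(seq_len(nrow(city$tracts)), function(i) {
    ix <- city$tracts$ix[i]; iy <- city$tracts$iy[i]
    rows <- ((ny - iy) * cpt + 1):((ny - iy + 1) * cpt)
    cols <- ((ix - 1) * cpt + 1):(ix * cpt)
    mean(r$values[rows, cols])
  })
}

# Exhaustive-search oracle for income cutpoints: enumerate every contiguous
# prefix (low) and suffix (high), pick the share closest to target, ties
# resolved toward the larger set.
cutpoints_oracle <- function(counts, target) {
  total <- sum(counts)
  k <- length(counts)
  best_set <- function(shares_by_size) {
    d <- abs(shares_by_size - target)
    sizes <- which(d <= min(d) + 1e-12)
    max(sizes)
  }
  lo_shares <- vapply(seq_len(k), function(j) sum(counts[1:j]) / total, 0)
  hi_shares <- vapply(seq_len(k), function(j) sum(counts[(k - j + 1):k]) / total, 0)
  nlo <- best_set(lo_shares)
  nhi <- best_set(hi_shares)
  list(low = seq_len(nlo), high = seq.int(k - nhi + 1L, k),
       low_share = lo_shares[nlo], high_share = hi_shares[nhi])
}
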