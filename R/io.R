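# Reading and writing the pipeline's file formats: GeoJSON vectors, ESRI
# ASCII grid rasters (see raster.R), CSV tables, YAML run configs, and the
# JSON run log.

#' Write features as GeoJSON
#'
#' @param features list of list(geometry = vertex matrix or list of
#'   matrices, properties = named list)
#' @param path output path
#' @export
write_geojson <- function(features, path) {
  close_ring <- function(m) {
    lapply(seq_len(nrow(m) + 1L), function(i) {
      v <- m[if (i > nrow(m)) 1L else i, ]
      c(v[[1]], v[[2]])
    })
  }
  feats <- lapply(features, function(f) {
    g <- f$geometry
    if (is.list(g) && !is.matrix(g)) {
      geom <- list(type = "MultiPolygon",
                   coordinates = lapply(g, function(p) list(close_ring(p))))
    } else {
      geom <- list(type = "Polygon", coordinates = list(close_ring(g)))
    }
    list(type = "Feature", geometry = geom, properties = f$properties)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON feature collection
#'
#' Supports Polygon and MultiPolygon features (outer rings only).
#'
#' @param path GeoJSON file
#' @return list of list(geometry, properties)
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  open_ring <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    colnames(m) <- c("x", "y")
    n <- nrow(m)
    if (n > 1L && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
    m
  }
  lapply(fc$features, function(f) {
    g <- f$geometry
    geom <- switch(g$type,
      Polygon = open_ring(g$coordinates[[1]]),
      MultiPolygon = {
        parts <- lapply(g$coordinates, function(pg) open_ring(pg[[1]]))
        if (length(parts) == 1L) parts[[1]] else parts
      },
      stop("unsupported geometry type: ", g$type))
    list(geometry = geom, properties = f$properties)
  })
}

#' Read a city file set written by [write_city()]
#'
#' @param dir directory containing tracts.geojson, parks.geojson,
#'   demographics.csv, raster_*.asc, and optionally ndvi_truth.asc,
#'   water_mask.asc, scenes/, truth.json
#' @return a `synthetic_city`-shaped list usable by [park_equity()]
#' @export
read_city <- function(dir) {
  need <- file.path(dir, c("tracts.geojson", "parks.geojson", "demographics.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("missing city input file(s): ",
                            paste(missing, collapse = ", "))
  tf <- read_geojson(need[1])
  tracts <- do.call(rbind, lapply(tf, function(f) {
    bb <- poly_bbox(f$geometry)
    data.frame(tract_id = f$properties$tract_id,
               x0 = bb[1], y0 = bb[2], x1 = bb[3], y1 = bb[4],
               latent = if (!is.null(f$properties$latent)) f$properties$latent else NA_real_,
               stringsAsFactors = FALSE)
  }))
  urban_area_id <- tf[[1]]$properties$urban_area_id
  if (is.null(urban_area_id)) urban_area_id <- "city"
  parks <- lapply(read_geojson(need[2]), function(f) {
    list(park_id = f$properties$park_id,
         name = f$properties$name,
         poly = f$geometry,
         area = if (!is.null(f$properties$area_km2)) f$properties$area_km2
                else poly_area(f$geometry))
  })
  demog <- utils::read.csv(file.path(dir, "demographics.csv"),
                           stringsAsFactors = FALSE)
  rfiles <- list.files(dir, pattern = "^raster_.*\\.asc$", full.names = TRUE)
  rasters <- list()
  for (f in rfiles) {
    v <- sub("^raster_(.*)\\.asc$", "\\1", basename(f))
    rasters[[v]] <- read_asc(f, v)
  }
  out <- list(extent = c(min(tracts$x0), min(tracts$y0),
                         max(tracts$x1), max(tracts$y1)),
              tracts = tracts, demographics = demog, parks = parks,
              rasters = rasters,
              config = list(urban_area_id = urban_area_id))
  tp <- file.path(dir, "ndvi_truth.asc")
  if (file.exists(tp)) out$ndvi_truth <- read_asc(tp, "ndvi")
  wp <- file.path(dir, "water_mask.asc")
  if (file.exists(wp)) out$water_mask <- read_asc(wp, "water")$values > 0.5
  sdir <- file.path(dir, "scenes")
  if (dir.exists(sdir)) {
    nf <- sort(list.files(sdir, pattern = "_nir\\.asc$", full.names = TRUE))
    scenes <- lapply(nf, function(f) {
      stem <- sub("_nir\\.asc$", "", f)
      cl <- read_asc(paste0(stem, "_cloud.asc"))$values > 0.5
      list(nir = read_asc(f)$values,
           red = read_asc(paste0(stem, "_red.asc"))$values,
           cloud = cl, coverage = mean(cl))
    })
    if (length(scenes)) {
      ref <- read_asc(nf[1])
      out$scenes <- structure(list(scenes = scenes, water_mask = out$water_mask,
                                   origin = ref$origin, cellsize = ref$cellsize),
                              class = "scene_stack")
    }
  }
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  class(out) <- "synthetic_city"
  out
}

#' Run the full park-equity pipeline from a config
#'
#' Stages: synthesis (optional) -> ICE and quartiles -> park sectioning and
#' size metrics -> exposure means -> quartile disparity. All result tables
#' are written as CSV alongside a machine-readable JSON run log recording
#' excluded tracts, discarded scenes, achieved cutpoint shares, and the
#' number of tests performed.
#'
#' @param config a YAML file path or a list with either a `synth` block
#'   (arguments to [city_config()]) or an `inputs` block
#'   (`list(city_dir = ...)`), plus optional `variants`, `target_share`,
#'   `cutpoint_scope`, `nonpark`, `seed`
#' @param out_dir output directory (created); NULL to skip writing
#' @return the [park_equity()] fit, invisibly
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_synth <- !is.null(config$synth)
  has_inputs <- !is.null(config$inputs)
  if (has_synth == has_inputs) {
    stop("config must have exactly one of 'synth' or 'inputs'")
  }
  if (has_synth) {
    args <- config$synth
    if (!is.null(config$seed)) args$seed <- config$seed
    city <- generate_city(do.call(city_config, args))
  } else {
    city <- read_city(config$inputs$city_dir)
  }
  fit <- park_equity(
    city,
    variants = if (!is.null(config$variants)) unlist(config$variants)
               else c("combined", "income", "race"),
    target_share = if (!is.null(config$target_share)) config$target_share else 0.20,
    cutpoint_scope = if (!is.null(config$cutpoint_scope)) config$cutpoint_scope else "pooled",
    nonpark = isTRUE(config$nonpark))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit$ice, file.path(out_dir, "ice.csv"), row.names = FALSE)
    utils::write.csv(fit$sizes, file.path(out_dir, "size_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$exposures, file.path(out_dir, "exposure.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$disparity, file.path(out_dir, "disparity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(fit$log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}
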