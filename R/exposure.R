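# Exposure assessment: NDVI compositing from scene stacks and area-weighted
# zonal means of raster surfaces over park sections, tracts, and urban
# extents.

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red), in [-1, 1]. Vectorised; cells where
#' both bands are zero are nodata (`NA`).
#'
#' @param nir near-infrared reflectance (>= 0)
#' @param red red-band reflectance (>= 0)
#' @return unitless NDVI
#' @export
ndvi <- function(nir, red) {
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE)) {
    stop("reflectances must be non-negative")
  }
  s <- nir + red
  out <- (nir - red) / s
  out[s == 0] <- NA_real_
  out
}

#' Composite NDVI from a scene stack
#'
#' Scenes whose cloud coverage is at or above `max_cloud` are discarded
#' outright; in the retained scenes, per-pixel NDVI is computed with cloudy
#' pixels masked, then averaged per pixel over the clear observations.
#' Water-masked pixels and pixels with no clear observation are nodata.
#'
#' @param stack a `scene_stack` (see [generate_scene_stack()]): list with
#'   `scenes` (each with `nir`, `red` matrices and logical `cloud` mask),
#'   `water_mask` logical matrix, `origin`, `cellsize`
#' @param max_cloud scene-level cloud-coverage exclusion threshold
#'   (proportion, default 0.20; scenes must be strictly below it)
#' @return a `raster_field` with variable "ndvi"
#' @export
composite_ndvi <- function(stack, max_cloud = 0.20) {
  cov <- vapply(stack$scenes, function(s) {
    if (!is.null(s$coverage)) s$coverage else mean(s$cloud)
  }, numeric(1))
  keep <- which(cov < max_cloud)
  if (length(keep) == 0L) stop("no usable scenes: all at or above ",
                               100 * max_cloud, "% cloud coverage")
  d <- dim(stack$scenes[[1]]$nir)
  acc <- matrix(0, d[1], d[2])
  nobs <- matrix(0L, d[1], d[2])
  for (i in keep) {
    s <- stack$scenes[[i]]
    v <- ndvi(s$nir, s$red)
    v[s$cloud] <- NA_real_
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    nobs <- nobs + ok
  }
  out <- acc / nobs
  out[nobs == 0L] <- NA_real_
  if (!is.null(stack$water_mask)) out[stack$water_mask] <- NA_real_
  raster_field(out, stack$origin, stack$cellsize, "ndvi")
}

# Fractional cell-overlap weights of a geometry on a raster grid.
# Returns list(ri, ci, w): parallel vectors of row/col indices and the
# cell-intersection areas (km^2). Only positive weights are returned.
cell_weights <- function(r, poly) {
  if (is.list(poly) && !is.matrix(poly)) {
    parts <- lapply(poly, cell_weights, r = r)
    return(list(ri = unlist(lapply(parts, `[[`, "ri")),
                ci = unlist(lapply(parts, `[[`, "ci")),
                w = unlist(lapply(parts, `[[`, "w"))))
  }
  ed <- raster_edges(r)
  nr <- nrow(r$values); nc <- ncol(r$values)
  bb <- poly_bbox(poly)
  # candidate columns/rows overlapping the bbox
  c0 <- max(1L, 1L + floor((bb[1] - r$origin[1]) / r$cellsize))
  c1 <- min(nc, 1L + floor((bb[3] - r$origin[1]) / r$cellsize + 1e-12))
  r0 <- max(1L, 1L + floor((r$origin[2] - bb[4]) / r$cellsize))
  r1 <- min(nr, 1L + floor((r$origin[2] - bb[2]) / r$cellsize + 1e-12))
  if (c0 > c1 || r0 > r1) return(list(ri = integer(), ci = integer(), w = numeric()))
  cols <- c0:c1; rows <- r0:r1
  if (is_axis_rect(poly)) {
    wx <- pmax(0, pmin(bb[3], ed$xs[cols + 1L]) - pmax(bb[1], ed$xs[cols]))
    wy <- pmax(0, pmin(bb[4], ed$ys[rows]) - pmax(bb[2], ed$ys[rows + 1L]))
    W <- outer(wy, wx)
    pos <- which(W > 0, arr.ind = TRUE)
    return(list(ri = rows[pos[, 1]], ci = cols[pos[, 2]], w = W[pos]))
  }
  ri <- integer(); ci <- integer(); w <- numeric()
  for (rr in rows) {
    y1 <- ed$ys[rr]; y0 <- ed$ys[rr + 1L]
    for (cc in cols) {
      x0 <- ed$xs[cc]; x1 <- ed$xs[cc + 1L]
      cl <- clip_poly(poly, rect_poly(x0, y0, x1, y1))
      if (is.null(cl)) next
      a <- poly_area(cl)
      if (a > 0) { ri <- c(ri, rr); ci <- c(ci, cc); w <- c(w, a) }
    }
  }
  list(ri = ri, ci = ci, w = w)
}

zonal_stats <- function(r, poly) {
  cw <- cell_weights(r, poly)
  if (length(cw$w) == 0L) {
    return(list(num = 0, den = 0, w_total = 0))
  }
  v <- r$values[cbind(cw$ri, cw$ci)]
  ok <- !is.na(v)
  list(num = sum(cw$w[ok] * v[ok]), den = sum(cw$w[ok]), w_total = sum(cw$w))
}

#' Area-weighted zonal mean of a raster over a polygon
#'
#' Cell values are weighted by the exact area of cell-polygon intersection
#' (not cell-centre membership), so polygons smaller than a cell are handled
#' correctly. Nodata cells are excluded from numerator and denominator.
#'
#' @param r a `raster_field`
#' @param poly polygon matrix, or list of matrices for multi-part geometry
#' @return weighted mean in raster units, with attributes `weight_km2`
#'   (valid weight used) and `valid_fraction` (valid weight / total
#'   overlapped weight); `NA` when the polygon overlaps no valid cell
#' @export
zonal_mean <- function(r, poly) {
  zs <- zonal_stats(r, poly)
  if (zs$den == 0) {
    out <- NA_real_
  } else {
    out <- zs$num / zs$den
  }
  attr(out, "weight_km2") <- zs$den
  attr(out, "valid_fraction") <- if (zs$w_total > 0) zs$den / zs$w_total else 0
  out
}

#' Area-weighted park exposure for one tract
#'
#' The mean of section zonal means weighted by section area: the average
#' area-weighted value over all park sections within the tract. Sections
#' whose zonal mean is undefined (no valid cells) are excluded together
#' with their weight.
#'
#' @param sections section rows for one tract (list-column `poly`,
#'   `area_km2`)
#' @param r a `raster_field`
#' @return list: `park_mean` (NA when no sections or no valid weight),
#'   `weight_km2`, `valid_fraction`
#' @export
tract_park_exposure <- function(sections, r) {
  if (is.null(sections) || nrow(sections) == 0L) {
    return(list(park_mean = NA_real_, weight_km2 = 0, valid_fraction = NA_real_))
  }
  num <- 0; den <- 0; wtot <- 0
  for (i in seq_len(nrow(sections))) {
    zs <- zonal_stats(r, sections$poly[[i]])
    a <- sections$area_km2[i]
    wtot <- wtot + a
    if (zs$den > 0) {
      num <- num + a * (zs$num / zs$den)
      den <- den + a
    }
  }
  list(park_mean = if (den > 0) num / den else NA_real_,
       weight_km2 = den,
       valid_fraction = if (wtot > 0) den / wtot else NA_real_)
}

#' Mean exposure over the non-park part of a tract
#'
#' Zonal mean over the tract after removing the union of its park sections:
#' per cell, the weight is area(cell ∩ tract) minus area(cell ∩ park
#' union). Undefined when parks cover the whole tract.
#'
#' @param tract_rect numeric (x0, y0, x1, y1) tract bounds
#' @param sections section rows for the tract
#' @param r a `raster_field`
#' @return mean in raster units, `NA` when no non-park weight remains
#' @export
nonpark_exposure <- function(tract_rect, sections, r) {
  tp <- rect_poly(tract_rect[1], tract_rect[2], tract_rect[3], tract_rect[4])
  cw <- cell_weights(r, tp)
  if (length(cw$w) == 0L) return(NA_real_)
  wpark <- numeric(length(cw$w))
  if (!is.null(sections) && nrow(sections) > 0L) {
    ed <- raster_edges(r)
    for (k in seq_along(cw$w)) {
      x0 <- ed$xs[cw$ci[k]]; x1 <- ed$xs[cw$ci[k] + 1L]
      y1 <- ed$ys[cw$ri[k]]; y0 <- ed$ys[cw$ri[k] + 1L]
      clips <- lapply(sections$poly, function(p) clip_to_rect(p, x0, y0, x1, y1))
      clips <- clips[!vapply(clips, is.null, logical(1))]
      # flatten any multi-part clips for the union
      flat <- list()
      for (cl in clips) {
        if (is.list(cl) && !is.matrix(cl)) flat <- c(flat, cl) else flat <- c(flat, list(cl))
      }
      if (length(flat) > 0L) wpark[k] <- union_area(flat)
    }
  }
  wnp <- pmax(0, cw$w - wpark)
  v <- r$values[cbind(cw$ri, cw$ci)]
  ok <- !is.na(v) & wnp > 1e-12
  if (!any(ok)) return(NA_real_)
  sum(wnp[ok] * v[ok]) / sum(wnp[ok])
}

#' Area-weighted mean over the urban extent
#'
#' Computed over the raster footprint intersected with the urban rectangle,
#' land (valid) cells only — water and nodata cells are excluded.
#'
#' @param r a `raster_field`
#' @param extent numeric (x0, y0, x1, y1) urban rectangle
#' @return mean in raster units
#' @export
urban_mean <- function(r, extent) {
  as.numeric(zonal_mean(r, rect_poly(extent[1], extent[2], extent[3], extent[4])))
}

#' Park, non-park, and urban exposure means for every tract and variable
#'
#' @param city a `synthetic_city` (or any list with `tracts`, `parks`,
#'   `rasters`, `extent`)
#' @param sections precomputed [section_parks()] output (computed when NULL)
#' @param nonpark also compute non-park means (sensitivity analysis)
#' @return data.frame: tract_id, variable, park_mean, nonpark_mean,
#'   urban_mean, weight_km2, valid_fraction
#' @export
exposure_summary <- function(city, sections = NULL, nonpark = FALSE) {
  if (is.null(sections)) sections <- section_parks(city$parks, city$tracts)
  sp <- split(seq_len(nrow(sections)), sections$tract_id)
  out <- list(); k <- 0L
  for (var in names(city$rasters)) {
    r <- city$rasters[[var]]
    um <- urban_mean(r, city$extent)
    for (i in seq_len(nrow(city$tracts))) {
      tid <- as.character(city$tracts$tract_id[i])
      idx <- sp[[tid]]
      sec <- if (is.null(idx)) NULL else sections[idx, , drop = FALSE]
      pe <- tract_park_exposure(sec, r)
      np <- if (nonpark) {
        nonpark_exposure(c(city$tracts$x0[i], city$tracts$y0[i],
                           city$tracts$x1[i], city$tracts$y1[i]), sec, r)
      } else NA_real_
      k <- k + 1L
      out[[k]] <- data.frame(tract_id = tid, variable = var,
                             park_mean = pe$park_mean, nonpark_mean = np,
                             urban_mean = um, weight_km2 = pe$weight_km2,
                             valid_fraction = pe$valid_fraction,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
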