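# Single-variable north-up raster grids.

#' Construct a raster field
#'
#' A north-up single-variable grid: row 1 of `values` is the northernmost
#' row, columns run west to east. `NA` cells are nodata.
#'
#' @param values numeric matrix (rows = north to south)
#' @param origin numeric length-2, (x, y) of the top-left corner (km)
#' @param cellsize cell edge length (km), square cells
#' @param variable variable name, e.g. "no2" (ppb), "pm25" (ug/m3),
#'   "wbgt" (degC), "ndvi" (unitless)
#' @return object of class `raster_field`
#' @export
raster_field <- function(values, origin, cellsize, variable = "value") {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0,
            length(origin) == 2)
  structure(list(values = values, origin = as.numeric(origin),
                 cellsize = as.numeric(cellsize), variable = variable),
            class = "raster_field")
}

#' @export
print.raster_field <- function(x, ...) {
  rg <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<raster_field> %s: %d x %d cells @ %g km, range [%.4g, %.4g], %d nodata\n",
              x$variable, nrow(x$values), ncol(x$values), x$cellsize,
              rg[1], rg[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_field <- function(x) dim(x$values)

# Extent as (x0, y0, x1, y1); y0 is the southern edge.
raster_extent <- function(r) {
  c(r$origin[1], r$origin[2] - nrow(r$values) * r$cellsize,
    r$origin[1] + ncol(r$values) * r$cellsize, r$origin[2])
}

# Cell edge coordinates: xs has ncol+1 entries west->east, ys has nrow+1
# entries north->south (decreasing).
raster_edges <- function(r) {
  list(xs = r$origin[1] + r$cellsize * (0:ncol(r$values)),
       ys = r$origin[2] - r$cellsize * (0:nrow(r$values)))
}

# Cell centre coordinates, matching the values matrix layout.
raster_centres <- function(r) {
  list(x = r$origin[1] + r$cellsize * (seq_len(ncol(r$values)) - 0.5),
       y = r$origin[2] - r$cellsize * (seq_len(nrow(r$values)) - 0.5))
}

#' Write a raster field as an ESRI ASCII grid
#'
#' Plain-text `.asc` with the standard six-line header; nodata written as
#' -9999. Cell values are written at full double precision.
#'
#' @param r a `raster_field`
#' @param path output file path
#' @export
write_asc <- function(r, path) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- r$origin[2] - nr * r$cellsize
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.17g", r$origin[1]),
           sprintf("yllcorner %.17g", yll),
           sprintf("cellsize %.17g", r$cellsize),
           "NODATA_value -9999")
  v[is.na(v)] <- -9999
  lines <- apply(v, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a raster field
#'
#' @param path `.asc` file path
#' @param variable variable name to attach
#' @return a `raster_field`
#' @export
read_asc <- function(path, variable = "value") {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    vals[i, ] <- as.numeric(strsplit(trimws(lines[6 + i]), "\\s+")[[1]])
  }
  nod <- hdr$nodata_value
  if (!is.null(nod)) vals[vals == nod] <- NA_real_
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  raster_field(vals, origin, hdr$cellsize, variable)
}
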