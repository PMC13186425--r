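# Park sectioning and park-size metrics.
#
# Parks are lists with fields park_id, name, poly (vertex matrix or list of
# matrices), area (km^2); tracts carry tract_id and poly. A park section is
# the positive-area intersection of one park with one tract, the unit of
# area weighting for park exposures.

park_area <- function(park) {
  if (!is.null(park$area)) park$area else poly_area(park$poly)
}

#' Section parks by tract boundaries
#'
#' Spatial join between park and tract geometries: every (park, tract) pair
#' with a positive-area intersection yields one section, so parks crossing
#' tract boundaries appear once per tract. Edge-only touches produce no
#' section. Invalid geometries get one repair attempt (duplicate-vertex
#' removal); unrepairable features are dropped with a warning.
#'
#' @param parks list of park records (`park_id`, `name`, `poly`)
#' @param tracts data.frame with `tract_id` and bounding columns `x0, y0,
#'   x1, y1` for rectangular tracts, or a list-column `poly` of convex
#'   polygons
#' @return data.frame: park_id, tract_id, area_km2, with the section
#'   geometries in the list-column `poly`
#' @export
section_parks <- function(parks, tracts) {
  rows <- list(); polys <- list(); k <- 0L
  rect_tracts <- all(c("x0", "y0", "x1", "y1") %in% names(tracts))
  for (p in parks) {
    g <- repair_poly(p$poly)
    if (is.null(g)) {
      warning("dropping park with unrepairable geometry: ", p$park_id)
      next
    }
    bb <- poly_bbox(g)
    for (i in seq_len(nrow(tracts))) {
      if (rect_tracts) {
        tx0 <- tracts$x0[i]; ty0 <- tracts$y0[i]
        tx1 <- tracts$x1[i]; ty1 <- tracts$y1[i]
        if (bb[1] >= tx1 || bb[3] <= tx0 || bb[2] >= ty1 || bb[4] <= ty0) next
        sec <- clip_to_rect(g, tx0, ty0, tx1, ty1)
      } else {
        sec <- if (is.list(g) && !is.matrix(g)) {
          parts <- lapply(g, clip_poly, clip = tracts$poly[[i]])
          parts <- parts[!vapply(parts, is.null, logical(1))]
          if (length(parts) == 0L) NULL else if (length(parts) == 1L) parts[[1L]] else parts
        } else clip_poly(g, tracts$poly[[i]])
      }
      if (is.null(sec)) next
      a <- poly_area(sec)
      if (a <= 0) next
      k <- k + 1L
      rows[[k]] <- data.frame(park_id = p$park_id, tract_id = tracts$tract_id[i],
                              area_km2 = a, stringsAsFactors = FALSE)
      polys[[k]] <- sec
    }
  }
  if (k == 0L) {
    out <- data.frame(park_id = character(), tract_id = character(),
                      area_km2 = numeric(), stringsAsFactors = FALSE)
    out$poly <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$poly <- polys
  out
}

#' Percentage of a tract covered by parks
#'
#' Overlapping park footprints are unioned before dividing by tract area, so
#' the result cannot exceed 100.
#'
#' @param sections section rows for one tract (from [section_parks()])
#' @param tract_area_km2 tract area
#' @return percent of tract area that is park, in [0, 100]
#' @export
percent_park <- function(sections, tract_area_km2) {
  if (tract_area_km2 <= 0) stop("tract area must be positive")
  if (is.null(sections) || nrow(sections) == 0L) return(0)
  a <- union_area(sections$poly)
  min(100, 100 * a / tract_area_km2)
}

#' Area of the largest park intersecting a tract
#'
#' Uses intersects semantics including boundary touches, and returns the
#' park's full (unclipped) area — a tract touching the corner of a large
#' park counts the whole park as accessible.
#'
#' @param parks list of park records
#' @param tract_poly tract polygon (convex) or rectangle
#' @return km^2 of the largest intersecting park; 0 when none intersect
#' @export
largest_intersecting_park <- function(parks, tract_poly) {
  best <- 0
  bbt <- poly_bbox(tract_poly)
  for (p in parks) {
    g <- repair_poly(p$poly)
    if (is.null(g)) next
    bb <- poly_bbox(g)
    # bbox reject with closed comparison: boundary touches count
    if (bb[1] > bbt[3] || bb[3] < bbt[1] || bb[2] > bbt[4] || bb[4] < bbt[2]) next
    if (polys_intersect(g, tract_poly)) best <- max(best, park_area(p))
  }
  best
}

# Closed intersection predicate (shared boundary counts) between a geometry
# and a convex polygon.
polys_intersect <- function(g, clip) {
  if (is.list(g) && !is.matrix(g)) {
    return(any(vapply(g, polys_intersect, logical(1), clip = clip)))
  }
  # positive-area overlap?
  if (!is.null(clip_poly(g, clip))) return(TRUE)
  # boundary touch: any vertex of one on/inside the other, or crossing edges
  if (any(points_on_or_in(g[, 1], g[, 2], clip))) return(TRUE)
  if (any(points_on_or_in(clip[, 1], clip[, 2], g))) return(TRUE)
  edges_touch(g, clip)
}

points_on_or_in <- function(px, py, poly) {
  inside <- points_in_poly(px, py, poly)
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1L)
  for (e in seq_len(n)) {
    ax <- poly[e, 1]; ay <- poly[e, 2]; bx <- poly[nxt[e], 1]; by <- poly[nxt[e], 2]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    on <- abs(cross) < 1e-12 &
      px >= pmin(ax, bx) - 1e-12 & px <= pmax(ax, bx) + 1e-12 &
      py >= pmin(ay, by) - 1e-12 & py <= pmax(ay, by) + 1e-12
    inside <- inside | on
  }
  inside
}

edges_touch <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  nxa <- c(seq_len(na)[-1], 1L); nxb <- c(seq_len(nb)[-1], 1L)
  for (i in seq_len(na)) {
    s1 <- c(x1 = a[i, 1], y1 = a[i, 2], x2 = a[nxa[i], 1], y2 = a[nxa[i], 2])
    for (j in seq_len(nb)) {
      s2 <- c(x1 = b[j, 1], y1 = b[j, 2], x2 = b[nxb[j], 1], y2 = b[nxb[j], 2])
      if (!is.na(seg_cross_x(s1, s2))) return(TRUE)
    }
  }
  FALSE
}

#' Park size metrics for every tract
#'
#' @param parks list of park records
#' @param tracts tract table (rectangular schema: tract_id, x0, y0, x1, y1)
#' @param sections optional precomputed [section_parks()] output
#' @return data.frame: tract_id, percent_park, largest_park_km2, n_sections
#' @export
size_metrics <- function(parks, tracts, sections = NULL) {
  if (is.null(sections)) sections <- section_parks(parks, tracts)
  sp <- split(seq_len(nrow(sections)), sections$tract_id)
  out <- data.frame(tract_id = tracts$tract_id,
                    percent_park = 0, largest_park_km2 = 0, n_sections = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tracts))) {
    tid <- as.character(tracts$tract_id[i])
    tp <- rect_poly(tracts$x0[i], tracts$y0[i], tracts$x1[i], tracts$y1[i])
    ta <- poly_area(tp)
    idx <- sp[[tid]]
    if (!is.null(idx)) {
      out$percent_park[i] <- percent_park(sections[idx, , drop = FALSE], ta)
      out$n_sections[i] <- length(idx)
    }
    out$largest_park_km2[i] <- largest_intersecting_park(parks, tp)
  }
  out
}
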