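# Planar polygon primitives.
#
# All geometry lives in a planar, equal-area frame with km units, so polygon
# area is Euclidean area (shoelace). Polygons are n x 2 numeric matrices of
# vertices (columns x, y), not closed (the last vertex differs from the
# first); multi-part geometries are lists of such matrices.

#' Construct an axis-aligned rectangle polygon
#'
#' @param x0,y0 lower-left corner (km)
#' @param x1,y1 upper-right corner (km)
#' @return a 4 x 2 vertex matrix in counter-clockwise order
#' @export
rect_poly <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0)
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Polygon area by the shoelace formula
#'
#' @param poly vertex matrix (open ring) or a list of them (multi-part,
#'   assumed disjoint)
#' @return area in squared frame units (km^2); always non-negative
#' @export
poly_area <- function(poly) {
  if (is.list(poly)) return(sum(vapply(poly, poly_area, numeric(1))))
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

poly_bbox <- function(poly) {
  if (is.list(poly)) {
    bb <- vapply(poly, poly_bbox, numeric(4))
    return(c(min(bb[1, ]), min(bb[2, ]), max(bb[3, ]), max(bb[4, ])))
  }
  c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
}

# TRUE when poly is an axis-aligned rectangle (any vertex order/rotation).
is_axis_rect <- function(poly) {
  if (is.list(poly)) return(FALSE)
  if (nrow(poly) != 4L) return(FALSE)
  xs <- unique(poly[, 1]); ys <- unique(poly[, 2])
  if (length(xs) != 2L || length(ys) != 2L) return(FALSE)
  # all four corner combinations present exactly once
  nrow(unique(poly)) == 4L &&
    isTRUE(all.equal(poly_area(poly),
                     abs(diff(xs)) * abs(diff(ys)), tolerance = 1e-12))
}

#' Clip a polygon against a convex polygon (Sutherland--Hodgman)
#'
#' The subject polygon may be any simple polygon; the clip polygon must be
#' convex and given in counter-clockwise order.
#'
#' @param subject vertex matrix of the polygon to clip
#' @param clip vertex matrix of a convex clip polygon (CCW)
#' @return clipped vertex matrix, or NULL when the intersection is empty or
#'   degenerate (zero area)
#' @export
clip_poly <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # signed distance: > 0 means inside (left of the CCW edge)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1], 1L)
    keep_x <- numeric(2L * n); keep_y <- numeric(2L * n); k <- 0L
    for (v in seq_len(n)) {
      w <- nxt[v]
      cin <- side[v] >= 0; nin <- side[w] >= 0
      if (cin) {
        k <- k + 1L; keep_x[k] <- out[v, 1]; keep_y[k] <- out[v, 2]
      }
      if (xor(cin, nin)) {
        t <- side[v] / (side[v] - side[w])
        k <- k + 1L
        keep_x[k] <- out[v, 1] + t * (out[w, 1] - out[v, 1])
        keep_y[k] <- out[v, 2] + t * (out[w, 2] - out[v, 2])
      }
    }
    out <- if (k >= 3L) cbind(x = keep_x[seq_len(k)], y = keep_y[seq_len(k)]) else NULL
  }
  if (is.null(out) || poly_area(out) <= 0) return(NULL)
  out
}

#' Clip a geometry to an axis-aligned rectangle
#'
#' Fast path for rectangle-against-rectangle; multi-part geometries are
#' clipped part by part.
#'
#' @param poly polygon matrix or list of matrices
#' @param x0,y0,x1,y1 rectangle bounds
#' @return clipped geometry (matrix, list, or NULL when empty)
#' @export
clip_to_rect <- function(poly, x0, y0, x1, y1) {
  if (is.list(poly)) {
    parts <- lapply(poly, clip_to_rect, x0 = x0, y0 = y0, x1 = x1, y1 = y1)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    return(parts)
  }
  if (is_axis_rect(poly)) {
    bb <- poly_bbox(poly)
    a0 <- max(bb[1], x0); b0 <- max(bb[2], y0)
    a1 <- min(bb[3], x1); b1 <- min(bb[4], y1)
    if (a1 - a0 <= 0 || b1 - b0 <= 0) return(NULL)
    return(rect_poly(a0, b0, a1, b1))
  }
  clip_poly(poly, rect_poly(x0, y0, x1, y1))
}

# Even-odd point-in-polygon test, vectorised over points.
points_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Area of the union of polygons
#'
#' Overlapping footprints are counted once. Axis-aligned rectangles take an
#' exact coordinate-compression path; the general case uses a vertical slab
#' decomposition split at all vertex abscissae and pairwise edge crossings,
#' within which the union boundary is linear.
#'
#' @param polys list of polygon matrices (each a simple polygon)
#' @return union area
#' @export
union_area <- function(polys) {
  polys <- polys[!vapply(polys, is.null, logical(1))]
  if (length(polys) == 0L) return(0)
  if (length(polys) == 1L) return(poly_area(polys[[1L]]))
  if (all(vapply(polys, is_axis_rect, logical(1)))) {
    return(rect_union_area(polys))
  }
  slab_union_area(polys)
}

rect_union_area <- function(rects) {
  bb <- vapply(rects, poly_bbox, numeric(4))
  xs <- sort(unique(c(bb[1, ], bb[3, ])))
  ys <- sort(unique(c(bb[2, ], bb[4, ])))
  if (length(xs) < 2L || length(ys) < 2L) return(0)
  nx <- length(xs) - 1L; ny <- length(ys) - 1L
  covered <- matrix(FALSE, ny, nx)
  xm <- (xs[-1] + xs[-length(xs)]) / 2
  ym <- (ys[-1] + ys[-length(ys)]) / 2
  for (k in seq_along(rects)) {
    ci <- which(xm > bb[1, k] & xm < bb[3, k])
    ri <- which(ym > bb[2, k] & ym < bb[4, k])
    covered[ri, ci] <- TRUE
  }
  w <- diff(xs); h <- diff(ys)
  sum(outer(h, w) * covered)
}

# General union area by vertical slab decomposition. Exact up to float
# round-off; O((total edges)^2) which is fine at the sizes sections reach.
slab_union_area <- function(polys) {
  segs <- do.call(rbind, lapply(seq_along(polys), function(k) {
    p <- polys[[k]]
    n <- nrow(p)
    nxt <- c(seq_len(n)[-1], 1L)
    cbind(poly = k, x1 = p[, 1], y1 = p[, 2], x2 = p[nxt, 1], y2 = p[nxt, 2])
  }))
  xs <- c(segs[, "x1"], segs[, "x2"])
  # add pairwise crossing abscissae so edge ordering is constant per slab
  m <- nrow(segs)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      x <- seg_cross_x(segs[i, ], segs[j, ])
      if (!is.na(x)) xs <- c(xs, x)
    }
  }
  xs <- sort(unique(xs))
  total <- 0
  for (s in seq_len(length(xs) - 1L)) {
    xl <- xs[s]; xr <- xs[s + 1L]
    w <- xr - xl
    if (w <= 0) next
    xm <- (xl + xr) / 2
    # edges crossing the slab
    lo <- pmin(segs[, "x1"], segs[, "x2"])
    hi <- pmax(segs[, "x1"], segs[, "x2"])
    act <- which(lo < xm & hi > xm)
    if (length(act) == 0L) next
    y_at <- function(x) {
      s1 <- segs[act, , drop = FALSE]
      s1[, "y1"] + (s1[, "y2"] - s1[, "y1"]) *
        (x - s1[, "x1"]) / (s1[, "x2"] - s1[, "x1"])
    }
    ym <- y_at(xm); yl <- y_at(xl); yr <- y_at(xr)
    ints <- NULL  # rows: bottom/top y at (mid, left, right)
    for (k in unique(segs[act, "poly"])) {
      idx <- which(segs[act, "poly"] == k)
      ord <- idx[order(ym[idx])]
      if (length(ord) %% 2L != 0L) next  # grazing a vertex; measure-zero slab
      for (q in seq(1L, length(ord), by = 2L)) {
        a <- ord[q]; b <- ord[q + 1L]
        ints <- rbind(ints, c(ym[a], ym[b], yl[a], yl[b], yr[a], yr[b]))
      }
    }
    if (is.null(ints)) next
    ord <- order(ints[, 1])
    ints <- ints[ord, , drop = FALSE]
    # merge intervals (ordering constant within the slab)
    cur_top_m <- -Inf; cur <- NULL
    for (r in seq_len(nrow(ints))) {
      if (is.null(cur) || ints[r, 1] > cur_top_m + 1e-12) {
        if (!is.null(cur)) {
          total <- total + w * ((cur[["tl"]] - cur[["bl"]]) +
                                  (cur[["tr"]] - cur[["br"]])) / 2
        }
        cur <- c(bl = ints[r, 3], tl = ints[r, 4], tr = ints[r, 6], br = ints[r, 5])
        cur_top_m <- ints[r, 2]
      } else if (ints[r, 2] > cur_top_m) {
        cur["tl"] <- ints[r, 4]; cur["tr"] <- ints[r, 6]
        cur_top_m <- ints[r, 2]
      }
    }
    if (!is.null(cur)) {
      total <- total + w * ((cur[["tl"]] - cur[["bl"]]) +
                              (cur[["tr"]] - cur[["br"]])) / 2
    }
  }
  total
}

# x-coordinate where two segments cross in their interiors, NA otherwise.
seg_cross_x <- function(s1, s2) {
  x1 <- s1[["x1"]]; y1 <- s1[["y1"]]; x2 <- s1[["x2"]]; y2 <- s1[["y2"]]
  x3 <- s2[["x1"]]; y3 <- s2[["y1"]]; x4 <- s2[["x2"]]; y4 <- s2[["y2"]]
  d <- (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3)
  if (abs(d) < 1e-14) return(NA_real_)
  t <- ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / d
  u <- ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / d
  if (t <= 0 || t >= 1 || u <= 0 || u >= 1) return(NA_real_)
  x1 + t * (x2 - x1)
}

# One-shot validity repair: drop consecutive duplicate vertices and require
# at least 3 distinct vertices with positive area.
repair_poly <- function(poly) {
  if (is.list(poly)) {
    parts <- lapply(poly, repair_poly)
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    return(parts)
  }
  if (is.null(poly) || nrow(poly) < 3L) return(NULL)
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1L)
  dup <- abs(poly[, 1] - poly[nxt, 1]) < 1e-12 &
    abs(poly[, 2] - poly[nxt, 2]) < 1e-12
  poly <- poly[!dup, , drop = FALSE]
  if (nrow(poly) < 3L || poly_area(poly) <= 0) return(NULL)
  poly
}
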