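#' @name range_geometry
#' @title Planar range-geometry metrics
#' @description All geometry here is planar, on equal-area-projected
#' coordinates supplied in kilometres; the package performs no map
#' projection itself. A range is a list of rings; each ring is a two-column
#' matrix of (x, y) vertices. Rings with attribute `hole = TRUE` subtract
#' from the area; every ring's length counts toward the perimeter.
NULL

ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

ring_perimeter <- function(ring) {
  d <- diff(rbind(ring, ring[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

ring_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  seg <- function(i) list(ring[i, ], ring[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next # adjacent segments share a point
      a <- seg(i); b <- seg(j)
      if (segments_intersect(a[[1]], a[[2]], b[[1]], b[[2]])) return(FALSE)
    }
  }
  TRUE
}

point_in_ring <- function(pt, ring) {
  # ray casting
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1))
  crosses <- ((y > pt[2]) != (y[j] > pt[2])) &
    (pt[1] < (x[j] - x) * (pt[2] - y) / (y[j] - y) + x)
  sum(crosses) %% 2 == 1
}

check_rings <- function(polygons, species = "range") {
  if (!is.list(polygons) || !length(polygons))
    stop("empty polygon set for ", species)
  for (i in seq_along(polygons)) {
    ring <- polygons[[i]]
    if (!is.matrix(ring) || ncol(ring) != 2 || !all(is.finite(ring)))
      stop("ring ", i, " of ", species, " is not a finite two-column matrix")
    if (!ring_is_simple(ring))
      stop("self-intersecting ring ", i, " in ", species)
    if (abs(ring_area_signed(ring)) == 0)
      stop("zero-area ring ", i, " in ", species)
  }
  invisible(polygons)
}

is_hole <- function(ring) isTRUE(attr(ring, "hole"))

#' Area, perimeter and shape index of a (multi-part) range
#'
#' Area by the shoelace formula summed over parts, holes subtracting;
#' perimeter summed over all rings. The shape index is area divided by
#' perimeter, so disjunct ranges (same area split over more parts, hence
#' more perimeter) score lower — small values mean elongated or disjunct
#' ranges.
#'
#' @param polygons List of rings (two-column matrices, km); rings with
#'   attribute `hole = TRUE` are holes.
#' @param species Label used in error messages.
#' @return List with `area` (km^2), `perimeter` (km), `shape_index` (km).
#' @examples
#' sq <- list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' polygon_metrics(sq)
#' @export
polygon_metrics <- function(polygons, species = "range") {
  check_rings(polygons, species)
  area <- 0
  perim <- 0
  for (ring in polygons) {
    a <- abs(ring_area_signed(ring))
    area <- area + if (is_hole(ring)) -a else a
    perim <- perim + ring_perimeter(ring)
  }
  if (area <= 0) stop("non-positive total area for ", species)
  list(area = area, perimeter = perim, shape_index = area / perim)
}

#' Bounding-box extent and midpoints of a range
#'
#' Axis-aligned bounding box over all vertices. `length` is the north-south
#' (y) extent and `width` the east-west (x) extent, in km. Midpoints are the
#' box centres in the supplied planar units; the area-weighted centroid is
#' also reported (midpoints, not centroids, are what feed the regressions).
#'
#' @inheritParams polygon_metrics
#' @return List with `length`, `width`, `lon_midpoint` (x), `lat_midpoint`
#'   (y), `centroid` (x, y).
#' @export
extent_metrics <- function(polygons, species = "range") {
  check_rings(polygons, species)
  all_xy <- do.call(rbind, lapply(polygons, function(r) r[, 1:2]))
  bx <- range(all_xy[, 1]); by <- range(all_xy[, 2])
  # area-weighted centroid over non-hole rings minus holes
  cx <- 0; cy <- 0; atot <- 0
  for (ring in polygons) {
    a <- abs(ring_area_signed(ring))
    sgn <- if (is_hole(ring)) -1 else 1
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring)
    j <- c(n, seq_len(n - 1))
    cross <- x[j] * y - x * y[j]
    s <- ring_area_signed(ring)
    cxr <- sum((x[j] + x) * cross) / (6 * s)
    cyr <- sum((y[j] + y) * cross) / (6 * s)
    cx <- cx + sgn * a * cxr
    cy <- cy + sgn * a * cyr
    atot <- atot + sgn * a
  }
  list(length = diff(by), width = diff(bx),
       lon_midpoint = mean(bx), lat_midpoint = mean(by),
       centroid = c(x = cx / atot, y = cy / atot))
}

#' Classify a range as continental or island
#'
#' `"continental"` iff any range ring overlaps the continental mask (any
#' vertex of one inside the other, or any pair of edges crossing) — overlap,
#' not containment, suffices.
#'
#' @param polygons Range rings (holes ignored for the overlap test).
#' @param continental_mask List of mask rings.
#' @param species Label for error messages.
#' @return `"continental"` or `"island"`.
#' @export
classify_geographic_setting <- function(polygons, continental_mask,
                                        species = "range") {
  if (missing(continental_mask) || is.null(continental_mask))
    stop("a continental mask polygon set is required")
  check_rings(polygons, species)
  check_rings(continental_mask, "continental mask")
  polys <- Filter(function(r) !is_hole(r), polygons)
  masks <- Filter(function(r) !is_hole(r), continental_mask)
  overlap <- function(a, b) {
    if (any(apply(a, 1, point_in_ring, ring = b))) return(TRUE)
    if (any(apply(b, 1, point_in_ring, ring = a))) return(TRUE)
    na <- nrow(a); nb <- nrow(b)
    for (i in seq_len(na)) {
      i2 <- if (i == na) 1 else i + 1
      for (j in seq_len(nb)) {
        j2 <- if (j == nb) 1 else j + 1
        if (segments_intersect(a[i, ], a[i2, ], b[j, ], b[j2, ]))
          return(TRUE)
      }
    }
    FALSE
  }
  for (p in polys) for (m in masks) if (overlap(p, m)) return("continental")
  "island"
}

#' Hand-wing index
#'
#' `100 * kipps / wing_length`. When per-individual measurements are
#' supplied, they are averaged per species *before* the ratio is taken.
#'
#' @param kipps Kipp's distance (mm), scalar or vector of individuals.
#' @param wing_length Wing length (mm), same length as `kipps`.
#' @return Unitless HWI scalar.
#' @examples
#' hand_wing_index(25, 100)
#' @export
hand_wing_index <- function(kipps, wing_length) {
  stopifnot(length(kipps) == length(wing_length))
  k <- mean(kipps)
  w <- mean(wing_length)
  if (w <= 0) stop("wing length must be positive")
  if (k < 0 || k > w)
    stop("Kipp's distance must lie in [0, wing length]")
  100 * k / w
}
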