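#' Read species range polygons from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features, one per
#' species, with the species label in a `name` property. Coordinates are
#' taken as planar (equal-area projected, km); no projection is applied.
#' The first ring of each polygon is the outer boundary, further rings are
#' holes (marked with attribute `hole = TRUE`).
#'
#' @param path GeoJSON file path.
#' @return Named list: per species, a list of rings (two-column matrices).
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  out <- list()
  for (ft in gj$features) {
    nm <- ft$properties$name
    if (is.null(nm)) stop("feature without a 'name' property")
    geom <- ft$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    rings <- list()
    for (poly in polys) {
      for (i in seq_along(poly)) {
        ring <- do.call(rbind, lapply(poly[[i]], function(pt)
          c(pt[[1]], pt[[2]])))
        # GeoJSON rings repeat the first vertex at the end; drop it
        if (nrow(ring) > 1 &&
            all(ring[1, ] == ring[nrow(ring), ]))
          ring <- ring[-nrow(ring), , drop = FALSE]
        if (i > 1) attr(ring, "hole") <- TRUE
        rings[[length(rings) + 1]] <- ring
      }
    }
    out[[nm]] <- rings
  }
  out
}

#' Parse a WKT POLYGON or MULTIPOLYGON string into a ring list
#'
#' @param wkt WKT string (planar coordinates).
#' @return List of rings (two-column matrices; rings after the first of
#'   each polygon are marked as holes).
#' @export
parse_wkt_polygon <- function(wkt) {
  wkt <- trimws(wkt)
  type <- toupper(sub("\\s*\\(.*$", "", wkt))
  body <- sub("^[A-Za-z ]+\\s*\\(", "", wkt)
  body <- sub("\\)$", "", body)
  parse_ring <- function(txt) {
    pts <- strsplit(trimws(strsplit(txt, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  split_top <- function(txt) {
    # split on commas at parenthesis depth 0
    chars <- strsplit(txt, "")[[1]]
    depth <- 0L
    cuts <- integer(0)
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") depth <- depth - 1L
      if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
    }
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts - 1L, length(chars))
    vapply(seq_along(starts), function(j)
      paste(chars[starts[j]:ends[j]], collapse = ""), character(1))
  }
  strip <- function(s) gsub("^\\s*\\(|\\)\\s*$", "", s)
  if (type == "POLYGON") {
    ring_txt <- split_top(body)
    rings <- lapply(ring_txt, function(s) parse_ring(strip(s)))
  } else if (type == "MULTIPOLYGON") {
    rings <- list()
    for (ptxt in split_top(body)) {
      ring_txt <- split_top(strip(ptxt))
      sub <- lapply(ring_txt, function(s) parse_ring(strip(s)))
      for (i in seq_along(sub)) {
        if (i > 1) attr(sub[[i]], "hole") <- TRUE
        rings[[length(rings) + 1]] <- sub[[i]]
      }
    }
    return(rings)
  } else stop("unsupported WKT type: ", type)
  for (i in seq_along(rings)) if (i > 1) attr(rings[[i]], "hole") <- TRUE
  rings
}
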