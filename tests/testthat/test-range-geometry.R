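square <- function(x0 = 0, y0 = 0, s = 1) {
  cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
}

test_that("polygon metrics match hand geometry", {
  m <- polygon_metrics(list(square()))
  expect_equal(m$area, 1)
  expect_equal(m$perimeter, 4)
  expect_equal(m$shape_index, 0.25)
  rect <- list(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))
  m2 <- polygon_metrics(rect)
  expect_equal(m2$area, 2)
  expect_equal(m2$perimeter, 6)
  expect_equal(m2$shape_index, 1 / 3)
  # disjunct range: same area, more perimeter, smaller shape index
  two_sq <- list(square(), square(x0 = 5))
  m3 <- polygon_metrics(two_sq)
  expect_equal(m3$area, 2)
  expect_equal(m3$perimeter, 8)
  expect_lt(m3$shape_index, m2$shape_index)
  # a hole subtracts area but adds perimeter
  hole <- square(0.25, 0.25, 0.5)
  attr(hole, "hole") <- TRUE
  m4 <- polygon_metrics(list(square(), hole))
  expect_equal(m4$area, 0.75)
  expect_equal(m4$perimeter, 6)
})

test_that("degenerate polygons are rejected with the species label", {
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(polygon_metrics(list(bowtie), species = "sp_x"),
               "self-intersecting.*sp_x")
  flat <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(polygon_metrics(list(flat), species = "sp_y"), "zero-area")
  expect_error(polygon_metrics(list(), species = "sp_z"), "empty polygon")
})

test_that("area and perimeter agree with a segment-sum oracle on random convex polygons", {
  set.seed(51)
  for (i in 1:50) {
    th <- sort(stats::runif(sample(4:12, 1), 0, 2 * pi))
    r <- stats::runif(1, 0.5, 20)
    ring <- cbind(r * cos(th), r * sin(th))
    m <- polygon_metrics(list(ring))
    # oracle: triangle fan from the centroid for area; explicit edge sum
    cx <- mean(ring[, 1]); cy <- mean(ring[, 2])
    n <- nrow(ring)
    a_or <- 0; p_or <- 0
    for (j in seq_len(n)) {
      k <- if (j == n) 1 else j + 1
      a_or <- a_or + abs((ring[j, 1] - cx) * (ring[k, 2] - cy) -
                         (ring[k, 1] - cx) * (ring[j, 2] - cy)) / 2
      p_or <- p_or + sqrt(sum((ring[k, ] - ring[j, ])^2))
    }
    expect_lt(abs(m$area - a_or) / a_or, 1e-9)
    expect_lt(abs(m$perimeter - p_or) / p_or, 1e-9)
  }
})

test_that("shape index is invariant under translation and rotation", {
  set.seed(52)
  th <- sort(stats::runif(8, 0, 2 * pi))
  ring <- cbind(3 * cos(th), 3 * sin(th))
  base <- polygon_metrics(list(ring))$shape_index
  shift <- polygon_metrics(list(ring + 100))$shape_index
  ang <- 0.77
  R <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  rot <- polygon_metrics(list(ring %*% t(R)))$shape_index
  expect_equal(shift, base, tolerance = 1e-12)
  expect_equal(rot, base, tolerance = 1e-12)
})

test_that("extent metrics give box extents, midpoints and centroid", {
  m <- extent_metrics(list(square()))
  expect_equal(m$length, 1)
  expect_equal(m$width, 1)
  expect_equal(m$lon_midpoint, 0.5)
  expect_equal(m$lat_midpoint, 0.5)
  expect_equal(unname(m$centroid), c(0.5, 0.5))
  # L-shape: bbox midpoint differs from the area-weighted centroid
  L <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 3, 3))
  mL <- extent_metrics(list(L))
  expect_equal(c(mL$lon_midpoint, mL$lat_midpoint), c(1, 1.5))
  expect_false(isTRUE(all.equal(unname(mL$centroid),
                                c(mL$lon_midpoint, mL$lat_midpoint))))
  expect_error(extent_metrics(list()), "empty polygon")
})

test_that("geographic setting classification uses any-overlap", {
  mask <- list(square(0, 0, 10))
  inside <- list(square(2, 2, 1))
  outside <- list(square(20, 20, 1))
  straddle <- list(square(9.5, 4, 2))
  expect_equal(classify_geographic_setting(inside, mask), "continental")
  expect_equal(classify_geographic_setting(outside, mask), "island")
  expect_equal(classify_geographic_setting(straddle, mask), "continental")
  expect_error(classify_geographic_setting(inside, NULL), "mask")
  # insensitive to vertex order
  rev_str <- list(straddle[[1]][rev(seq_len(4)), ])
  expect_equal(classify_geographic_setting(rev_str, mask), "continental")
})

test_that("hand-wing index averages individuals before the ratio", {
  expect_equal(hand_wing_index(25, 100), 25)
  expect_equal(hand_wing_index(0, 100), 0)
  # mean(k)/mean(w), not mean(k/w)
  k <- c(20, 40)
  w <- c(100, 80)
  expect_equal(hand_wing_index(k, w), 100 * mean(k) / mean(w))
  expect_false(isTRUE(all.equal(hand_wing_index(k, w),
                                mean(100 * k / w))))
  expect_error(hand_wing_index(120, 100), "Kipp")
  expect_error(hand_wing_index(10, 0), "positive")
})

test_that("WKT and GeoJSON readers produce usable ring lists", {
  wkt <- "POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))"
  rings <- parse_wkt_polygon(wkt)
  expect_equal(polygon_metrics(rings)$area, 1)
  mp <- parse_wkt_polygon(
    "MULTIPOLYGON (((0 0, 1 0, 1 1, 0 1, 0 0)), ((5 0, 6 0, 6 1, 5 1, 5 0)))")
  expect_equal(polygon_metrics(mp)$area, 2)
  gj <- tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(name = "sp1"),
      geometry = list(type = "Polygon",
                      coordinates = list(list(
                        list(0, 0), list(2, 0), list(2, 1), list(0, 1),
                        list(0, 0))))))), auto_unbox = TRUE), gj)
  ranges <- read_ranges_geojson(gj)
  expect_named(ranges, "sp1")
  expect_equal(polygon_metrics(ranges$sp1)$area, 2)
})
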