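test_that("spherical cell areas recover the sphere and the closed form", {
  g <- grid_spec(resolution = 5)
  expect_equal(sum(cell_areas(g)), 4 * pi * 6371^2, tolerance = 1e-6)
  ca <- cell_areas(g)
  expect_true(all(apply(ca, 1, function(r) max(r) - min(r) == 0)))

  band <- 6371^2 * (pi / 180) * (sin(1 * pi / 180) - sin(0))
  g_eq <- grid_spec(0, 1, 0, 1, 1)
  expect_equal(cell_areas(g_eq)[1, 1], band)
  expected <- 6371^2 * (pi / 180) * (sin(0.5 * pi / 180) - sin(-0.5 * pi / 180))
  g_sym <- grid_spec(0, 1, -0.5, 0.5, 1)
  expect_equal(cell_areas(g_sym)[1, 1], expected)
})

test_that("grid construction rejects invalid bounds", {
  expect_error(grid_spec(lat_min = -100), "latitude")
  expect_error(grid_spec(resolution = -1), "resolution")
  expect_error(grid_spec(0, 10, 0, 10, 3), "multiples")
})

test_that("center-rule rasterization covers exactly the enclosed cells", {
  g <- grid_spec(0, 10, 0, 10, 1)
  r <- rasterize_range(rect_ring(0, 2, 0, 2), g)
  expect_equal(sum(r$presence), 4)
  expect_true(all(r$presence[1:2, 1:2]))
  expect_error(rasterize_range(rect_ring(50, 60, 50, 60), g), "no grid cell")
  expect_error(rasterize_range(list(), g), "empty polygon")
})

test_that("polygons crossing the antimeridian rasterize on both sides", {
  g <- grid_spec(-180, 180, -10, 20, 1)
  ring <- cbind(c(170, 190, 190, 170, 170), c(0, 0, 10, 10, 0))
  r <- rasterize_range(ring, g, "dateline")
  lon_idx <- function(lon) floor(lon - (-180)) + 1L
  lat_idx <- function(lat) floor(lat - (-10)) + 1L
  expect_true(r$presence[lat_idx(5), lon_idx(175)])
  expect_true(r$presence[lat_idx(5), lon_idx(-175)])
  expect_false(r$presence[lat_idx(5), lon_idx(0)])
  expect_equal(sum(r$presence), 20 * 10)
})

test_that("probability grids threshold correctly", {
  g <- grid_spec(0, 2, 0, 2, 1)
  pm <- matrix(c(0.4, 0.5, 0.6, 0.9), 2, 2)
  expect_equal(sum(threshold_probability(pm, g, cutoff = 0.5)$presence), 3)
  expect_equal(sum(threshold_probability(pm, g, cutoff = 0)$presence), 4)
  expect_equal(sum(threshold_probability(matrix(c(1, 0.99, 1, 0), 2, 2), g,
                                         cutoff = 1)$presence), 2)
  expect_error(threshold_probability(matrix(c(1.2, 0, 0, 0), 2, 2), g), "\\[0, 1\\]")
})

test_that("range areas are additive and empty ranges error", {
  g <- grid_spec(0, 10, -5, 5, 1)
  expect_error(range_area(range_raster("none", g, matrix(FALSE, 10, 10))), "empty")
  r1 <- make_raster(g, c(1, 2, 3))
  r2 <- make_raster(g, c(50, 60))
  ru <- range_raster("u", g, r1$presence | r2$presence)
  expect_equal(range_area(ru), range_area(r1) + range_area(r2))
})

test_that("overlap and symmetry endpoints match their definitions", {
  g <- grid_spec(0, 10, -5, 5, 1)
  a <- make_raster(g, 1:20, "a")
  b <- make_raster(g, 21:40, "b")
  expect_equal(overlap_index(a, b), 0)

  nest_out <- make_raster(g, 1:40, "big")
  nest_in <- make_raster(g, 5:20, "small")
  expect_equal(overlap_index(nest_out, nest_in), 1)
  expect_equal(overlap_index(nest_in, nest_out), 1)

  # equal-area cells: same latitude row
  row <- 5
  idx <- function(cols) row + (cols - 1) * g$n_lat
  a2 <- make_raster(g, idx(1:4), "a2")
  b2 <- make_raster(g, idx(4:5), "b2")
  expect_equal(overlap_index(a2, b2), 0.5)
  expect_equal(symmetry_index(a2, make_raster(g, idx(5:8), "c2")), 0.5)
  expect_equal(symmetry_index(a2, b2), 2 / 6)

  g2 <- grid_spec(20, 30, -5, 5, 1)
  expect_error(overlap_index(a, make_raster(g2, 1:3)), "different grids")
})

test_that("indices are order-invariant and bounded on random rasters", {
  set.seed(11)
  g <- grid_spec(0, 10, 30, 40, 1)
  for (i in 1:50) {
    a <- random_raster(g, "a"); b <- random_raster(g, "b")
    expect_identical(overlap_index(a, b), overlap_index(b, a))
    expect_equal(symmetry_index(a, b), symmetry_index(b, a))
    expect_equal(overlap_index(a, a), 1)
    s <- symmetry_index(a, b)
    expect_gt(s, 0); expect_lte(s, 0.5)
    ca <- cell_areas(g)
    inter <- sum(ca[a$presence & b$presence])
    expect_lte(inter, min(range_area(a), range_area(b)))
    expect_lte(min(range_area(a), range_area(b)), max(range_area(a), range_area(b)))
    expect_lte(max(range_area(a), range_area(b)), range_area(a) + range_area(b))
  }
})

test_that("classification uses the >= threshold rule", {
  expect_equal(classify_overlap(0.02), "allopatric")
  expect_equal(classify_overlap(0.16), "sympatric")
  expect_equal(classify_overlap(0.05), "sympatric")
  expect_equal(classify_overlap(c(0, 1)), c("allopatric", "sympatric"))
  expect_equal(classify_overlap(0.3, threshold = 0.5), "allopatric")
  expect_error(classify_overlap(1.2), "\\[0, 1\\]")
})

test_that("richness stacks presence counts per cell", {
  g <- grid_spec(0, 5, 0, 5, 1)
  r1 <- make_raster(g, 1:5, "a")
  rich1 <- range_richness(list(r1))
  expect_equal(unclass(rich1)[cbind(1:5, 1)], rep(1L, 5))
  rich3 <- range_richness(list(r1, r1, r1))
  expect_equal(max(rich3), 3)
  r2 <- make_raster(g, 5:8, "b")
  rich <- range_richness(list(r1, r2))
  expect_equal(sum(rich == 2), 1)
  expect_true(all(rich <= 2))
})

test_that("grid CSV dialect round-trips presence and grid metadata", {
  g <- grid_spec(-10, 10, 0, 10, 0.5)
  r <- random_raster(g, "x", 0.2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(r$presence, g, f)
  back <- read_grid_csv(f, logical_values = TRUE)
  expect_equal(back$matrix, r$presence)
  expect_equal(back$grid$resolution, 0.5)
  expect_equal(back$grid$n_lat, g$n_lat)
})

test_that("GeoJSON feature collections load by species property", {
  f <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature", properties = list(species = "sp1"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(0, 0), list(4, 0),
                                                   list(4, 4), list(0, 4), list(0, 0))))),
      list(type = "Feature", properties = list(species = "sp2"),
           geometry = list(type = "MultiPolygon",
                           coordinates = list(list(list(list(5, 5), list(7, 5),
                                                        list(7, 7), list(5, 7), list(5, 5))))))
    )
  )
  jsonlite::write_json(gj, f, auto_unbox = TRUE)
  geoms <- read_ranges_geojson(f)
  expect_named(geoms, c("sp1", "sp2"))
  g <- grid_spec(0, 10, 0, 10, 1)
  r1 <- rasterize_range(geoms$sp1, g, "sp1")
  expect_equal(sum(r1$presence), 16)
})
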