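test_that("cell indexing is row-major 0-based and centres follow the grid origin", {
  grid <- seascape_grid(4, 6, 250, origin = c(1000, 2000))
  ids <- c(0L, 5L, 6L, 23L)
  rc <- cell_to_rc(grid, ids)
  expect_equal(rc[, "row"], c(1L, 1L, 2L, 4L), ignore_attr = TRUE)
  expect_equal(rc[, "col"], c(1L, 6L, 1L, 6L), ignore_attr = TRUE)
  expect_equal(rc_to_cell(grid, rc[, "row"], rc[, "col"]), ids)
  xy <- cell_xy(grid, 0L)
  expect_equal(xy[1, "x"], 1000 + 125, ignore_attr = TRUE)
  expect_equal(xy[1, "y"], 2000 - 125, ignore_attr = TRUE)
  expect_error(cell_to_rc(grid, 24L), "out of range")
})

test_that("layer constructors enforce their invariants", {
  grid <- seascape_grid(2, 2, 100, water = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  expect_error(habitat_layer(grid, matrix(c(0, 0.7, 0, 0), 2, 2)), "illegal")
  expect_error(habitat_layer(grid, matrix(c(0, 0, 0, 1), 2, 2)), "land")
  expect_silent(habitat_layer(grid, matrix(c(1, 0.5, 0, 0), 2, 2)))
  expect_error(disturbance_layer(grid, matrix(c(0, 6, 0, 0), 2, 2)), "illegal")
  expect_error(feature_layer(grid, matrix(-1, 2, 2), "sp", "habitat"),
               "nonnegative")
  expect_error(species_profile("x", habitat_layer(grid, matrix(0, 2, 2)),
                               d_max = -5), "positive")
})

test_that("ASCII raster round-trip preserves values and geometry exactly", {
  set.seed(11)
  for (rep in 1:5) {
    nr <- sample(3:12, 1); nc <- sample(3:12, 1)
    water <- matrix(stats::runif(nr * nc) > 0.3, nr, nc)
    if (!any(water)) water[1] <- TRUE
    grid <- seascape_grid(nr, nc, 250, origin = c(612500.5, 6571250.25),
                          water = water)
    q <- matrix(sample(c(0, 0.5, 1), nr * nc, replace = TRUE), nr, nc)
    q[!water] <- 0
    hab <- habitat_layer(grid, q)
    p <- withr::local_tempfile(fileext = ".asc")
    write_raster_layer(hab, p)
    hab2 <- read_raster_layer(p, "habitat", grid = grid)
    expect_identical(hab2$values, hab$values)

    pm <- withr::local_tempfile(fileext = ".asc")
    write_raster_layer(grid, pm)
    grid2 <- read_raster_layer(pm, "mask")
    expect_identical(grid2$water, grid$water)
    expect_identical(grid2$resolution, grid$resolution)
    expect_identical(grid2$origin, grid$origin)
  }
})

test_that("typed raster reading enforces class values and geometry", {
  grid <- seascape_grid(2, 2, 100)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(matrix(c(0, 1, 0.5, 0.5), 2, 2), grid, p)
  hab <- read_raster_layer(p, "habitat", grid = grid)
  expect_equal(sort(unique(as.vector(hab$values))), c(0, 0.5, 1))

  write_ascii_grid(matrix(c(0, 0.7, 0, 0), 2, 2), grid, p)
  expect_error(read_raster_layer(p, "habitat", grid = grid), "0.7")
  expect_silent(read_raster_layer(p, "habitat", grid = grid, strict = FALSE))

  other <- seascape_grid(2, 2, 200)
  expect_error(read_raster_layer(p, "habitat", grid = other),
               "geometry mismatch")
})

test_that("MPA rasterization is by cell centre, strictest designation wins, order-free", {
  grid <- seascape_grid(4, 4, 100, origin = c(0, 400))
  # strict Ia over left half, nonstrict V overlapping the middle
  polys <- mpa_polygons(
    list(list(square_ring(0, 100, 200, 400)),
         list(square_ring(100, 0, 300, 400))),
    c("Ia", "V"))
  st <- rasterize_mpas(polys, grid)
  expect_equal(st$values[1, 1], MPA_STRICT)   # strict only
  expect_equal(st$values[1, 2], MPA_STRICT)   # overlap -> strictest
  expect_equal(st$values[1, 3], MPA_NONSTRICT)
  expect_equal(st$values[1, 4], MPA_UNPROTECTED)

  # polygon order must not matter
  polys_rev <- mpa_polygons(rev(polys$rings), rev(polys$category))
  expect_identical(rasterize_mpas(polys_rev, grid)$values, st$values)

  # missing or non-listed categories are non-strict
  for (cat in list("V", "IV", NA_character_, "other")) {
    p1 <- mpa_polygons(list(list(square_ring(0, 0, 400, 400))), cat)
    expect_true(all(rasterize_mpas(p1, grid)$values == MPA_NONSTRICT))
  }
  for (cat in c("Ia", "Ib", "II")) {
    p1 <- mpa_polygons(list(list(square_ring(0, 0, 400, 400))), cat)
    expect_true(all(rasterize_mpas(p1, grid)$values == MPA_STRICT))
  }

  # empty polygon set: all unprotected, not an error
  empty <- rasterize_mpas(mpa_polygons(list(), character(0)), grid)
  expect_true(all(empty$values == MPA_UNPROTECTED))

  # invalid geometry rejected
  expect_error(mpa_polygons(list(list(cbind(c(0, 1), c(0, 1)))), "Ia"),
               "invalid polygon")
})

test_that("GeoJSON MPA round-trip preserves rings and categories", {
  polys <- mpa_polygons(
    list(list(square_ring(0, 0, 300, 300)),
         list(square_ring(150, 150, 500, 500))),
    c("Ib", NA))
  p <- withr::local_tempfile(fileext = ".geojson")
  write_mpa_polygons(polys, p)
  back <- read_mpa_polygons(p)
  expect_equal(length(back), 2L)
  expect_identical(back$category, polys$category)
  # rings come back closed; compare the open part
  r1 <- back$rings[[1]][[1]]
  expect_equal(r1[-nrow(r1), ], polys$rings[[1]][[1]], ignore_attr = TRUE)
  grid <- seascape_grid(5, 5, 100, origin = c(0, 500))
  expect_identical(rasterize_mpas(back, grid)$values,
                   rasterize_mpas(polys, grid)$values)
})
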