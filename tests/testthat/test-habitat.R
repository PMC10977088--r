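# Habitat delineation: same-value matching, bathymetry constraint, stacking.

sight_at <- function(grid, row, col, date = "2018-07-02") {
  cen <- cell_centroid(grid, row, col)
  ll <- unproject(cen, grid$crs)
  data.frame(date = as.Date(date), matched = TRUE,
             lat = ll[, 2], lon = ll[, 1], stringsAsFactors = FALSE)
}

test_that("daily_layer masks exactly the pixels sharing the sighting value", {
  g <- geo_grid(5, 5)
  v <- matrix(10, 5, 5); v[2, 3] <- 42
  r <- raster_layer(g, v)
  ly <- daily_layer(sight_at(g, 2, 3), r)
  expect_equal(sum(ly$mask), 1)        # unique value -> single pixel
  expect_true(ly$mask[2, 3])

  # k pixels share the value: brute-force full scan agrees at tolerance 0
  set.seed(5)
  v2 <- matrix(sample(1:6, 25, replace = TRUE), 5, 5)
  r2 <- raster_layer(g, v2)
  ly2 <- daily_layer(sight_at(g, 4, 4), r2)
  expect_identical(ly2$mask, v2 == v2[4, 4])

  # two sightings with distinct values: union semantics
  v3 <- matrix(c(rep(1, 12), rep(2, 13)), 5, 5)
  r3 <- raster_layer(g, v3)
  s2 <- rbind(sight_at(g, 1, 1), sight_at(g, 5, 5))
  ly3 <- daily_layer(s2, r3)
  expect_identical(ly3$mask, v3 == 1 | v3 == 2)
  expect_equal(ly3$source_values, c(1, 2))
})

test_that("daily_layer handles nodata sightings and enforces one date", {
  g <- geo_grid(3, 3)
  v <- matrix(7, 3, 3); v[2, 2] <- -9999
  r <- raster_layer(g, v)
  expect_warning(ly <- daily_layer(rbind(sight_at(g, 2, 2), sight_at(g, 1, 1)), r),
                 "nodata")
  expect_false(ly$mask[2, 2])  # nodata pixels never masked
  expect_error(suppressWarnings(daily_layer(sight_at(g, 2, 2), r)),
               "every sighting fell on nodata")
  two_dates <- rbind(sight_at(g, 1, 1, "2018-07-02"),
                     sight_at(g, 1, 2, "2018-07-03"))
  expect_error(daily_layer(two_dates, r), "several dates")
})

test_that("masks grow monotonically with the matching tolerance and include their sightings", {
  g <- geo_grid(6, 6)
  set.seed(8)
  for (i in 1:10) {
    v <- matrix(sample(100:110, 36, replace = TRUE), 6, 6)
    r <- raster_layer(g, v)
    s <- sight_at(g, sample(6, 1), sample(6, 1))
    rc <- cell_of(g, project(cbind(s$lon, s$lat), g$crs)[, 1],
                  project(cbind(s$lon, s$lat), g$crs)[, 2])
    prev <- NULL
    for (tol in c(0, 1, 3, 10)) {
      ly <- daily_layer(s, r, tolerance = tol)
      expect_true(ly$mask[rc$row, rc$col])  # self-inclusion
      if (!is.null(prev)) expect_true(all(ly$mask >= prev))
      prev <- ly$mask
    }
  }
})

test_that("apply_bathymetry trims to the depth limit and never adds cells", {
  g <- geo_grid(4, 10)
  v <- matrix(5, 4, 10)
  ly <- daily_layer(sight_at(g, 2, 2), raster_layer(g, v))
  expect_true(all(ly$mask))
  shallow <- raster_layer(g, matrix(10, 4, 10))
  expect_identical(apply_bathymetry(ly, shallow, 50)$mask, ly$mask)  # no-op
  deep <- raster_layer(g, matrix(80, 4, 10))
  expect_equal(sum(apply_bathymetry(ly, deep, 50)$mask), 0)          # all removed

  # linear gradient crossing the limit: analytic half-plane within one column
  depth <- matrix(rep(seq(5, 95, length.out = 10), each = 4), 4, 10)
  grad <- raster_layer(g, depth)
  kept <- apply_bathymetry(ly, grad, 50)$mask
  analytic_cols <- sum(seq(5, 95, length.out = 10) <= 50)
  expect_equal(sum(kept) / 4, analytic_cols, tolerance = 1 / analytic_cols)
  expect_true(all(kept <= ly$mask))

  holey <- raster_layer(g, matrix(c(-9999, rep(10, 39)), 4, 10))
  expect_error(apply_bathymetry(ly, holey, 50), "nodata")
})

test_that("stacking counts each layer at most once per cell", {
  g <- geo_grid(4, 4)
  one <- matrix(FALSE, 4, 4); one[2, 3] <- TRUE
  mk <- function(mask) structure(list(date = Sys.Date(), mask = mask,
                                      source_values = 1, grid = g),
                                 class = "daily_habitat_layer")
  pd1 <- stack_layers(list(mk(one)), g)
  expect_equal(pd1$index[2, 3], 1)
  expect_equal(sum(pd1$index), 1)

  # D identical layers -> index = D on covered cells
  pd4 <- stack_layers(rep(list(mk(one)), 4), g)
  expect_equal(pd4$index[2, 3], 4)
  expect_equal(max(pd4$index), pd4$n_layers)

  # a layer whose pixels are finer than the analysis cell still adds 1
  fine <- grid_spec(GX0, GY0, 500, 8, 8, g$crs)
  fm <- matrix(FALSE, 8, 8); fm[3:4, 5:6] <- TRUE  # 4 pixels in one 1-km cell
  lyf <- structure(list(date = Sys.Date(), mask = fm, source_values = 1,
                        grid = fine), class = "daily_habitat_layer")
  pdf <- stack_layers(list(lyf), g)
  expect_equal(max(pdf$index), 1)
  expect_equal(sum(pdf$index), 1)
  expect_error(stack_layers(list(), g), "empty")
})

test_that("stacked counts equal the exhaustive (cell x layer) membership loop", {
  g <- geo_grid(5, 5)
  set.seed(21)
  layers <- lapply(1:3, function(i) {
    m <- matrix(runif(25) < 0.4, 5, 5)
    structure(list(date = Sys.Date() + i, mask = m, source_values = 1,
                   grid = g), class = "daily_habitat_layer")
  })
  pd <- stack_layers(layers, g)
  brute <- matrix(0L, 5, 5)
  for (r in 1:5) for (cc in 1:5) for (ly in layers)
    if (ly$mask[r, cc]) brute[r, cc] <- brute[r, cc] + 1L
  expect_identical(pd$index, brute)
  # conservation: total index equals summed per-layer coverage
  expect_equal(sum(pd$index), sum(vapply(layers, function(l) sum(l$mask), 0)))
})

test_that("habitat_area is the union of layers, not their sum", {
  g <- geo_grid(4, 4)
  bathy <- raster_layer(g, matrix(10, 4, 4))
  mk <- function(cells) {
    m <- matrix(FALSE, 4, 4); m[cells] <- TRUE
    structure(list(date = Sys.Date(), mask = m, source_values = 1, grid = g),
              class = "daily_habitat_layer")
  }
  # two disjoint single-cell layers -> 2 km2
  ha <- habitat_area(list(mk(cbind(1, 1)), mk(cbind(3, 3))), bathy)
  expect_equal(ha$total_km2, 2)
  # two identical layers -> one layer's area (idempotence)
  ha2 <- habitat_area(list(mk(cbind(2, 2)), mk(cbind(2, 2))), bathy)
  expect_equal(ha2$total_km2, 1)
  expect_gte(ha$total_km2, 1)  # union >= any single layer

  # random layers: union equals the cell-by-cell rasterized union
  set.seed(31)
  rnd <- lapply(1:4, function(i) mk(which(matrix(runif(16) < 0.3, 4, 4),
                                          arr.ind = TRUE)))
  ha3 <- habitat_area(rnd, bathy)
  u <- Reduce(`|`, lapply(rnd, `[[`, "mask"))
  expect_equal(ha3$total_km2, sum(u) * cell_area_km2(g))
  expect_identical(ha3$mask, u)
})

test_that("depth strata areas are reported at the configured isobaths", {
  g <- geo_grid(2, 10)
  depth <- matrix(rep(seq(5, 95, length.out = 10), each = 2), 2, 10)
  bathy <- raster_layer(g, depth)
  full <- structure(list(date = Sys.Date(), mask = matrix(TRUE, 2, 10),
                         source_values = 1, grid = g),
                    class = "daily_habitat_layer")
  ha <- habitat_area(list(full), bathy, depth_limit = 50, strata = c(20, 50))
  expect_named(ha$depth_strata_km2, c("within_20m", "within_50m"))
  expect_equal(unname(ha$depth_strata_km2["within_20m"]),
               2 * sum(seq(5, 95, length.out = 10) <= 20))
  expect_equal(ha$total_km2, unname(ha$depth_strata_km2["within_50m"]))
})
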