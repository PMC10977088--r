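# Risk scores and IDW extrapolation.

pd_of <- function(g, index, n_layers = max(index)) {
  structure(list(grid = g, index = index, n_layers = n_layers),
            class = "potential_distribution")
}
fi_of <- function(g, counts) {
  structure(list(grid = g, trips_per_cell = counts, max_trips = max(counts),
                 n_trips = max(counts)), class = "fishing_intensity")
}

test_that("risk_score is the product of log10(x + 1) factors on the shared grid", {
  g <- tiny_grid(2, 2)
  idx <- matrix(c(0L, 9L, 9L, 2L), 2, 2)
  cnt <- matrix(c(40L, 9L, 0L, 2L), 2, 2)
  sc <- risk_score(pd_of(g, idx), fi_of(g, cnt))
  grab <- function(r, c) sc$score[sc$row == r & sc$col == c]
  expect_equal(grab(1, 1), 0)                       # pd = 0 annihilates
  expect_equal(grab(2, 1), 1.0)                     # log10(10) * log10(10)
  expect_equal(grab(1, 2), 0)                       # fi = 0 annihilates
  expect_true(all(sc$score >= 0))
  # commutativity of the two factors
  sc_swapped <- risk_score(pd_of(g, cnt, 40), fi_of(g, idx))
  expect_equal(sc_swapped$score, sc$score)
})

test_that("risk_score refuses misaligned grids instead of silently resampling", {
  g1 <- tiny_grid(2, 2)
  g2 <- grid_spec(1000, 0, 1000, 2, 2, g1$crs)
  expect_error(risk_score(pd_of(g1, matrix(0L, 2, 2)),
                          fi_of(g2, matrix(0L, 2, 2))),
               "alignment")
})

test_that("IDW is exact at samples, constant under equal values, and averages midpoints", {
  s <- data.frame(x = c(0, 1000), y = c(0, 0), value = c(0, 1))
  expect_equal(idw_extrapolate(s, data.frame(x = 0, y = 0)), 0)
  expect_equal(idw_extrapolate(s, data.frame(x = 1000, y = 0)), 1)
  for (p in c(0.5, 1, 2, 4))
    expect_equal(idw_extrapolate(s, data.frame(x = 500, y = 0), power = p), 0.5)

  sc <- data.frame(x = runif(5, 0, 100), y = runif(5, 0, 100), value = 7)
  expect_equal(idw_extrapolate(sc, data.frame(x = runif(10), y = runif(10))),
               rep(7, 10))
  # single sample -> constant surface
  one <- data.frame(x = 3, y = 4, value = 2.5)
  expect_equal(idw_extrapolate(one, data.frame(x = c(0, 50), y = c(0, 9))),
               c(2.5, 2.5))
  expect_error(idw_extrapolate(one[0, ], data.frame(x = 1, y = 1)),
               "zero samples")
  dup <- data.frame(x = c(1, 1), y = c(2, 2), value = c(0, 5))
  expect_error(idw_extrapolate(dup, data.frame(x = 0, y = 0)), "conflicting")
})

test_that("IDW values stay within the sample range and respect monotonicity", {
  set.seed(71)
  s <- data.frame(x = runif(20, 0, 10000), y = runif(20, 0, 10000),
                  value = runif(20, 0, 5))
  t <- data.frame(x = runif(1000, 0, 10000), y = runif(1000, 0, 10000))
  v <- idw_extrapolate(s, t)
  expect_true(all(v >= min(s$value) - 1e-12))
  expect_true(all(v <= max(s$value) + 1e-12))
  # raising one sample value never lowers the surface
  s2 <- s; s2$value[4] <- s2$value[4] + 3
  v2 <- idw_extrapolate(s2, t)
  expect_true(all(v2 >= v - 1e-12))
  # k-nearest variant also stays within bounds
  vk <- idw_extrapolate(s, t, neighbors = 5)
  expect_true(all(vk >= min(s$value) - 1e-12 & vk <= max(s$value) + 1e-12))
})

test_that("risk_surface is confined to the habitat area and exact at sampled cells", {
  g <- tiny_grid(4, 4)
  idx <- matrix(0L, 4, 4); idx[2:3, 2:3] <- 3L
  cnt <- matrix(0L, 4, 4); cnt[2, 2] <- 5L; cnt[4, 4] <- 2L
  hab <- structure(list(grid = g, mask = idx > 0, total_km2 = 4,
                        depth_strata_km2 = c(within_50m = 4),
                        depth_limit = 50), class = "habitat_area")
  rs <- risk_surface(pd_of(g, idx), fi_of(g, cnt), hab)
  v <- rs$raster$values
  expect_true(all(v[!hab$mask] == rs$raster$nodata))   # nodata outside habitat
  expect_equal(v[2, 2], log10(3 + 1) * log10(5 + 1))   # sampled cell exact
  inhab <- v[hab$mask]
  expect_true(all(inhab >= min(rs$samples$value) &
                    inhab <= max(rs$samples$value)))
})

test_that("the risk maximum falls inside the planted habitat-traffic overlap", {
  fix <- scenario_fixture()
  res <- run_scenario_memory(fix$scenario)
  v <- res$risk$raster$values
  am <- which(v == max(v[v != res$risk$raster$nodata]), arr.ind = TRUE)
  pm <- planted_mask(fix$scenario)
  expect_true(all(pm[am]))
  expect_true(all(res$fi$trips_per_cell[am] > 0))
})

test_that("equal-interval classification covers the score range", {
  g <- tiny_grid(3, 3)
  r <- raster_layer(g, matrix(c(0, 1, 2, 3, 4, 5, 6, 7, -9999), 3, 3))
  cls <- classify_equal_interval(r, n_classes = 4)
  ok <- cls$values != -9999
  expect_true(all(cls$values[ok] %in% 1:4))
  expect_equal(min(cls$values[ok]), 1)
  expect_equal(max(cls$values[ok]), 4)
})
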