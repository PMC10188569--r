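test_that("projection reproduces training-cell predictions and propagates nodata", {
  w <- small_world(seed = 61)
  fit <- maxent(w$stack, w$occ, classes = "LQ", n_background = 400, seed = 1)
  map <- project_map(fit, w$stack)
  land <- stack_samples(w$stack)
  direct <- predict(fit, land)
  expect_equal(map$values[attr(land, "cell_index")], direct, tolerance = 1e-12)
  # all-nodata stack projects to all-nodata
  na_stack <- raster_stack(lapply(w$stack$layers, function(g)
    raster_grid(matrix(NA_real_, g$nrows, g$ncols), g$xll, g$yll, g$cellsize)))
  expect_true(all(is.na(project_map(fit, na_stack)$values)))
  # uniform model projects to the constant 1 - exp(-1)
  unif <- maxent(w$stack, w$occ, classes = "LQ", n_background = 400,
                 seed = 1, rm = 1e9)
  umap <- project_map(unif, w$stack)
  expect_equal(unique(as.vector(umap$values)), 1 - exp(-1), tolerance = 1e-9)
  # a stack missing a model variable errors by name
  partial <- raster_stack(w$stack$layers[-1])
  expect_error(project_map(fit, partial), "bio1")
})

test_that("ensemble means average cellwise with nodata dominance", {
  g <- function(v) raster_grid(matrix(v, 2, 2))
  expect_equal(ensemble_mean(list(g(0.3)))$values, g(0.3)$values)
  expect_equal(ensemble_mean(list(g(0.2), g(0.4)))$values, matrix(0.3, 2, 2))
  expect_equal(ensemble_mean(list(g(0.7), g(0.7), g(0.7)))$values, matrix(0.7, 2, 2))
  a <- g(0.2); a$values[1, 1] <- NA
  em <- ensemble_mean(list(a, g(0.4)))
  expect_true(is.na(em$values[1, 1]))
  expect_equal(em$values[2, 2], 0.3)
  # bounded by input envelope
  set.seed(1)
  maps <- lapply(1:4, function(i) g(runif(4)))
  em2 <- ensemble_mean(maps)
  lo <- Reduce(pmin, lapply(maps, `[[`, "values"))
  hi <- Reduce(pmax, lapply(maps, `[[`, "values"))
  expect_true(all(em2$values >= lo & em2$values <= hi))
  expect_error(ensemble_mean(list()), "at least one")
})

test_that("threshold multiples reproduce the five printed class bounds", {
  t <- 0.1945
  m <- raster_grid(matrix(c(0, 0.2, 0.5, 0.95), 2, 2))
  cl <- classify_suitability(m, t)
  expect_equal(round_half_up(cl$breaks, 3), c(0.195, 0.389, 0.584, 0.778))
  expect_equal(cl$grid$values[1, 1], 0)  # v = 0 -> unsuitable
  expect_equal(cl$grid$values[2, 2], 4)  # v = 0.95 -> high
  expect_equal(cl$grid$values[2, 1], 1)  # 0.195 <= 0.2 < 0.389 -> low
  expect_equal(cl$grid$values[1, 2], 2)  # 0.389 <= 0.5 < 0.584 -> moderate
  expect_error(classify_suitability(m, 0.3), "0.25")
})

test_that("classification is monotone in the threshold and handles nodata", {
  set.seed(3)
  v <- matrix(runif(100), 10, 10); v[1, ] <- NA
  m <- raster_grid(v)
  c1 <- classify_suitability(m, 0.15)$grid$values
  c2 <- classify_suitability(m, 0.20)$grid$values
  expect_true(all(c2 <= c1, na.rm = TRUE))  # raising t never raises a class
  expect_true(all(is.na(c1[1, ])))
})

test_that("cell areas follow spherical geometry and close over the sphere", {
  # one 1-degree cell spanning the equator band 0-1 degrees
  g <- raster_grid(matrix(1, 1, 1), xll = 0, yll = 0, cellsize = 1)
  a <- class_areas(classify_suitability(raster_grid(matrix(0.5, 1, 1),
                                                    xll = 0, yll = 0, cellsize = 1),
                                        t = 0.1))
  expect_equal(attr(a, "total_km2"), 12364, tolerance = 1e-4)
  # whole sphere at 1-degree resolution sums to 4 pi R^2
  world <- raster_grid(matrix(0.5, 180, 360), xll = -180, yll = -90, cellsize = 1)
  aw <- class_areas(classify_suitability(world, t = 0.1))
  expect_equal(attr(aw, "total_km2"), 4 * pi * 6371.0088^2, tolerance = 1e-3)
  # classes partition the land: per-class areas sum to the total
  set.seed(5)
  v <- matrix(runif(400), 20, 20); v[sample(400, 30)] <- NA
  cl <- classify_suitability(raster_grid(v, xll = 70, yll = 8, cellsize = 0.25), 0.1945)
  tab <- class_areas(cl)
  expect_equal(sum(tab$area_km2), attr(tab, "total_km2"), tolerance = 1e-9)
  # identical land masks give identical totals across scenarios
  v2 <- v * 0.5
  tab2 <- class_areas(classify_suitability(raster_grid(v2, xll = 70, yll = 8,
                                                       cellsize = 0.25), 0.1945))
  expect_equal(attr(tab2, "total_km2"), attr(tab, "total_km2"))
})

test_that("change tables implement both denominator conventions with infinity markers", {
  mk <- function(areas) data.frame(class = 0:4,
                                   label = c("unsuitable", "low", "moderate",
                                             "optimum", "high"),
                                   area_km2 = areas)
  pres <- mk(c(500, 100, 100, 100, 100))
  fut <- mk(c(520, 80, 100, 100, 100))
  cp <- change_table(pres, fut, "present")
  expect_equal(cp$change_pct[cp$class == 1], -20)
  cf <- change_table(pres, fut, "future")
  expect_equal(cf$change_pct[cf$class == 1], -25)
  expect_equal(cp$change_pct[cp$class == 3], 0)
  expect_equal(cf$change_pct[cf$class == 3], 0)
  # empty-to-nonempty class reports an infinity marker, not a number
  pres0 <- mk(c(500, 0, 100, 100, 100))
  c0 <- change_table(pres0, fut, "present")
  expect_identical(c0$change_pct[c0$class == 1], Inf)
})
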