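test_that("ESRI ASCII read parses header and values, and round-trips", {
  g <- grid_from_rows(list(c(1, 2), c(3, 4)), xll = 10, yll = 20, cellsize = 0.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  g2 <- read_esri_ascii(path)
  expect_identical(g2$nrows, 2L)
  expect_identical(g2$ncols, 2L)
  expect_equal(g2$values, matrix(c(1, 2, 3, 4), 2, byrow = TRUE))
  expect_equal(g2$xll, 10)
  expect_equal(g2$yll, 20)
  expect_equal(g2$cellsize, 0.5)
})

test_that("xllcenter dialect converts to corner by subtracting half a cell", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcenter 100", "yllcenter 50",
               "cellsize 2", "NODATA_value -9999", "1 2"), path)
  g <- read_esri_ascii(path)
  expect_equal(g$xll, 100 - 1)
  expect_equal(g$yll, 50 - 1)
})

test_that("malformed headers and ragged rows give informative errors", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "yllcorner 0", "cellsize 1",
               "NODATA_value -9999", "1 2"), path)
  expect_error(read_esri_ascii(path), "xllcorner")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3"), path)
  expect_error(read_esri_ascii(path), "row 2")
})

test_that("all-nodata grid reads with zero valid cells and extraction fails cleanly", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 1", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "-9999"), path)
  g <- read_esri_ascii(path)
  expect_true(all(is.na(g$values)))
  stk <- raster_stack(list(a = g))
  pts <- occurrences(0.5, 0.5)
  expect_error(suppressMessages(extract_samples(stk, pts)), "no valid samples")
})

test_that("round-trip identity holds on randomized grids including nodata", {
  set.seed(42)
  for (i in 1:5) {
    nr <- sample(1:30, 1); nc <- sample(1:30, 1)
    v <- matrix(rnorm(nr * nc) * 1000, nr, nc)
    v[sample(length(v), length(v) %/% 5)] <- NA
    g <- raster_grid(v, xll = runif(1, -180, 90), yll = runif(1, -90, 60),
                     cellsize = runif(1, 0.01, 2))
    path <- withr::local_tempfile(fileext = ".asc")
    write_esri_ascii(g, path)
    g2 <- read_esri_ascii(path)
    expect_equal(g2$values, g$values, tolerance = 1e-10)
    expect_identical(is.na(g2$values), is.na(g$values))
    expect_equal(g2$nodata, g$nodata)
  }
})

test_that("round-trip holds at 1000x1000 scale", {
  set.seed(7)
  v <- matrix(runif(1e6, -1e4, 1e4), 1000, 1000)
  g <- raster_grid(v, cellsize = 0.05)
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  expect_equal(read_esri_ascii(path)$values, g$values, tolerance = 1e-10)
})

test_that("occurrence CSV reading filters bounds and deduplicates per cell", {
  grid <- raster_grid(matrix(0, 4, 4), xll = 0, yll = 0, cellsize = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(species = "sp",
                       longitude = c(0.2, 0.4, 2.5),
                       latitude = c(0.3, 0.4, 1.5)),
            path, row.names = FALSE)
  occ <- read_occurrences_csv(path, grid = grid, dedupe_per_cell = TRUE)
  expect_identical(nrow(occ), 2L)  # first two rows share a cell
  occ2 <- read_occurrences_csv(path, grid = grid, dedupe_per_cell = FALSE)
  expect_identical(nrow(occ2), 3L)

  write.csv(data.frame(species = "sp", longitude = 99, latitude = 99),
            path, row.names = FALSE)
  expect_message(
    occ3 <- read_occurrences_csv(path, grid = grid),
    "outside the grid bounds")
  expect_identical(nrow(occ3), 0L)

  write.csv(data.frame(species = "sp", longitude = 1, latitude = "abc"),
            path, row.names = FALSE)
  expect_error(read_occurrences_csv(path, grid = grid), "row 1")
  write.csv(data.frame(species = "sp", x = 1, latitude = 2), path, row.names = FALSE)
  expect_error(read_occurrences_csv(path, grid = grid), "longitude")
})

test_that("125 in-bounds rows without dedup survive unchanged", {
  grid <- raster_grid(matrix(0, 50, 50), xll = 70, yll = 8, cellsize = 0.5)
  set.seed(1)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(species = "Thrips tabaci",
                       longitude = runif(125, 70, 95),
                       latitude = runif(125, 8, 33)),
            path, row.names = FALSE)
  occ <- read_occurrences_csv(path, grid = grid, dedupe_per_cell = FALSE)
  expect_identical(nrow(occ), 125L)
})

test_that("per-cell dedup is idempotent", {
  grid <- raster_grid(matrix(0, 4, 4), xll = 0, yll = 0, cellsize = 1)
  occ <- occurrences(c(0.1, 0.2, 1.5, 1.6, 3.2), c(0.1, 0.9, 2.5, 2.5, 3.3))
  once <- suppressMessages(filter_occurrences(occ, grid))
  twice <- suppressMessages(filter_occurrences(once, grid))
  expect_equal(as.data.frame(once), as.data.frame(twice))
})

test_that("extraction uses half-open cell membership and drops nodata points", {
  a <- grid_from_rows(list(c(1, 2), c(3, 4)))  # 2x2, xll 0, yll 0, cellsize 1
  b <- grid_from_rows(list(c(10, 20), c(30, NA)))
  stk <- raster_stack(list(a = a, b = b))
  # exact centre of top-left cell (row 1, col 1) -> lon 0.5, lat 1.5
  s <- extract_samples(stk, occurrences(0.5, 1.5))
  expect_equal(s$a, 1); expect_equal(s$b, 10)
  # point on the shared vertical edge lon = 1 belongs to the right cell
  s <- extract_samples(stk, occurrences(1, 1.5))
  expect_equal(s$a, 2)
  # point on the shared horizontal edge lat = 1 belongs to the upper cell
  s <- extract_samples(stk, occurrences(0.5, 1))
  expect_equal(s$a, 1)
  # point over the cell that is nodata in layer b is dropped
  expect_error(suppressMessages(extract_samples(stk, occurrences(1.5, 0.5))),
               "no valid samples")
})

test_that("extraction is invariant to layer ordering", {
  w <- small_world(seed = 5)
  pts <- w$occ
  s1 <- extract_samples(w$stack, pts)
  stk_rev <- raster_stack(rev(w$stack$layers))
  s2 <- extract_samples(stk_rev, pts)
  expect_equal(unname(as.matrix(s1)), unname(as.matrix(s2[names(s1)])))
})
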