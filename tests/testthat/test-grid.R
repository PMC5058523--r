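test_that("ASCII grid files are transcribed and round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 2", "3 4"), f)
  g <- read_ascii_grid(f)
  expect_equal(g$values, matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(g$xmin, 0)
  expect_equal(g$ymax, 2)

  # nodata sentinel becomes NA
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "5 -9999"), f)
  g2 <- read_ascii_grid(f)
  expect_true(is.na(g2$values[1, 2]))

  # byte-exact round trip on a generated 10x10 fixture
  set.seed(1)
  vals <- matrix(round(rnorm(100), 6), 10, 10)
  vals[3, 7] <- NA
  g3 <- egrid(vals, xmin = 75.25, ymax = 12.5, cell_size = 0.05)
  f3 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g3, f3)
  g4 <- read_ascii_grid(f3)
  f4 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g4, f4)
  expect_identical(readLines(f3), readLines(f4))
  expect_identical(g3$values, g4$values)
})

test_that("malformed ASCII grids produce named format errors", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "wrongkey 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3 4"), f)
  expect_error(read_ascii_grid(f), "nrows")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3"), f)
  expect_error(read_ascii_grid(f), "row 2")
})

test_that("rescale01 maps linearly, preserves rank, handles degenerate grids", {
  g <- make_grid(c(0, 5, 10))
  expect_equal(as.numeric(rescale01(g)$values), c(0, 0.5, 1))

  expect_warning(r <- rescale01(make_grid(c(7, 7, 7))), "constant")
  expect_equal(as.numeric(r$values), c(0, 0, 0))

  expect_error(rescale01(make_grid(c(NA_real_, NA_real_))), "nodata")

  set.seed(3)
  g2 <- egrid(matrix(rnorm(400), 20, 20))
  r2 <- rescale01(g2)
  expect_equal(min(r2$values), 0)
  expect_equal(max(r2$values), 1)
  expect_equal(cor(as.numeric(g2$values), as.numeric(r2$values),
                   method = "spearman"), 1)
  # idempotent once on the unit scale
  expect_equal(rescale01(r2)$values, r2$values)
})

test_that("proximity scores invert rescaled nearest-occurrence distance", {
  # single occurrence at a masked cell's center scores 1 there
  mask <- egrid(matrix(1, 3, 3), xmin = 0, ymax = 3, cell_size = 1)
  occ <- data.frame(lon = 0.5, lat = 2.5)  # center of cell (1,1)
  p <- proximity_component(mask, occ)
  expect_equal(p$values[1, 1], 1)

  # two masked cells: nearest = 1, furthest = 0
  mask2 <- egrid(matrix(c(1, NA, NA, 1), 2, 2), xmin = 0, ymax = 2,
                 cell_size = 1)
  p2 <- proximity_component(mask2, data.frame(lon = 0.5, lat = 1.5))
  expect_equal(p2$values[1, 1], 1)
  expect_equal(p2$values[2, 2], 0)

  # brute-force all-pairs oracle on a 5x5 mask with 3 points
  set.seed(11)
  mask3 <- egrid(matrix(rbinom(25, 1, 0.6), 5, 5), xmin = 0, ymax = 5,
                 cell_size = 1)
  pts <- data.frame(lon = runif(3, 0, 5), lat = runif(3, 0, 5))
  p3 <- proximity_component(mask3, pts)
  idx <- which(mask3$values == 1, arr.ind = TRUE)
  d <- apply(idx, 1L, function(rc) {
    cx <- rc[2] - 0.5; cy <- 5 - rc[1] + 0.5
    min(sqrt((cx - pts$lon)^2 + (cy - pts$lat)^2))
  })
  expected <- 1 - (d - min(d)) / (max(d) - min(d))
  expect_equal(p3$values[idx], expected)
  expect_true(all(is.na(p3$values[mask3$values == 0])))
})

test_that("latitude band counts partition non-nodata cells by cell center", {
  g <- egrid(matrix(1, 4, 4), xmin = 0, ymax = 10.4, cell_size = 0.1)
  tab <- latitude_band_counts(g, band_width = 1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$count, 16L)

  # 2-row grid straddling a band boundary: one row per band
  g2 <- egrid(matrix(1, 2, 3), xmin = 0, ymax = 11, cell_size = 1)
  tab2 <- latitude_band_counts(g2, band_width = 1)
  expect_equal(tab2$band, c(9, 10))
  expect_equal(tab2$count, c(3L, 3L))

  # random binary grid against a per-cell tally oracle
  set.seed(5)
  v <- matrix(rbinom(100, 1, 0.5), 10, 10)
  v[2, 2] <- NA
  g3 <- egrid(v, xmin = 70, ymax = 14, cell_size = 0.5)
  tab3 <- latitude_band_counts(g3, band_width = 1)
  lat <- grid_lat(g3)
  for (i in seq_len(nrow(tab3))) {
    n <- 0L
    for (r in 1:10) for (c in 1:10)
      if (!is.na(v[r, c]) && floor(lat[r]) == tab3$band[i] &&
            v[r, c] == tab3$value[i]) n <- n + 1L
    expect_equal(tab3$count[i], n)
  }
  expect_equal(sum(tab3$count), sum(!is.na(v)))
  expect_error(latitude_band_counts(g3, band_width = 0), "band_width")
})

test_that("point-in-cell lookups use half-open cell intervals", {
  g <- egrid(matrix(1:9, 3, 3), xmin = 0, ymax = 3, cell_size = 1)
  # a point on a shared edge belongs to exactly one cell (south-west rule)
  rc <- invasim:::point_to_cell(g, c(1, 0.5, 3), c(1, 2.5, 3))
  expect_equal(rc$col, c(2L, 1L, NA_integer_))
  expect_equal(rc$row, c(2L, 1L, NA_integer_))
})

test_that("occurrence thinning keeps one point per cell and drops misses", {
  g <- egrid(matrix(1, 3, 3), xmin = 0, ymax = 3, cell_size = 1)
  occ <- data.frame(species = "s",
                    lon = c(0.2, 0.4, 1.5, 9),
                    lat = c(0.3, 0.1, 1.5, 9))
  expect_warning(th <- thin_occurrences(occ, g), "dropped")
  expect_equal(nrow(th), 2L)
  expect_equal(th$lon, c(0.5, 1.5))  # snapped to cell centers
})

test_that("grid stacks enforce shared geometry and nodata masks", {
  a <- egrid(matrix(1:4, 2, 2))
  b <- egrid(matrix(5:8, 2, 2))
  expect_s3_class(egridstack(list(x = a, y = b)), "egridstack")
  c_off <- egrid(matrix(1:4, 2, 2), xmin = 1)
  expect_error(egridstack(list(x = a, y = c_off)), "aligned")
  d <- egrid(matrix(c(1, NA, 3, 4), 2, 2))
  expect_error(egridstack(list(x = a, y = d)), "nodata mask")
})
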