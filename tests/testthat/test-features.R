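test_that("seasonal percentiles follow the documented convention", {
  # constant band -> P50 = P75 = the constant
  b <- array(0.3, c(4, 4, 4, 12))
  s <- monthly_series(b)
  met <- seasonal_metrics(s)
  expect_equal(met$s1_green_p50, matrix(0.3, 4, 4))

  # {0.1, 0.2, 0.3, 0.4} -> P50 = 0.25, P75 = 0.325 (type-7 interpolation)
  b2 <- array(0, c(2, 2, 4, 4))
  vals <- c(0.1, 0.2, 0.3, 0.4)
  b2[1, 1, 3, ] <- vals          # nir
  b2[1, 1, 2, ] <- 0.05          # red, so NDVI is defined
  s2 <- monthly_series(b2, months = 1:4)
  met2 <- seasonal_metrics(s2, windows = list(w1 = 1:4))
  expect_equal(met2$s1_nir_p50[1, 1], 0.25)
  expect_equal(met2$s1_nir_p50[1, 1],
               unname(stats::quantile(vals, 0.5, type = 7)))

  # one masked month -> percentile over the remaining three
  v <- array(TRUE, c(2, 2, 4)); v[1, 1, 4] <- FALSE
  s3 <- monthly_series(b2, valid = v, months = 1:4)
  met3 <- seasonal_metrics(s3, windows = list(w1 = 1:4))
  expect_equal(met3$s1_nir_p50[1, 1], 0.2)
  # no valid observation -> NA
  v2 <- array(FALSE, c(2, 2, 4))
  s4 <- monthly_series(b2, valid = v2, months = 1:4)
  met4 <- seasonal_metrics(s4, windows = list(w1 = 1:4))
  expect_true(all(is.na(met4$s1_nir_p50)))
  # P75 >= P50 wherever both are defined
  met5 <- seasonal_metrics(feature_scene()$series)
  ok <- is.finite(met5$s1_ndvi_p50)
  expect_true(all(met5$s1_ndvi_p75[ok] >= met5$s1_ndvi_p50[ok]))
})

test_that("texture index is a bounded focal median", {
  const <- matrix(0.4, 20, 20)
  expect_equal(texture_index(const, 25, pixel_size = 4.77), const)

  # single bright pixel vanishes under a kernel that out-votes it
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  ti <- texture_index(m, 25, pixel_size = 4.77) # radius ~5 px, ~80 px kernel
  expect_equal(ti[11, 11], 0)

  # radius below the pixel size: identity
  expect_identical(texture_index(m, 2, pixel_size = 4.77), m)

  # median stays within the local range
  set.seed(31)
  r <- matrix(stats::runif(400), 20, 20)
  tir <- texture_index(r, 15, pixel_size = 4.77)
  expect_true(all(tir >= min(r) & tir <= max(r)))

  # NA-aware: missing neighbours are skipped, not propagated
  m2 <- matrix(1, 9, 9); m2[5, 5] <- NA
  ti2 <- texture_index(m2, 10, pixel_size = 4.77)
  expect_equal(ti2[5, 5], 1)
})

test_that("contrast index follows its normalised-difference contract", {
  expect_equal(contrast_index(matrix(0.4, 2, 2), matrix(0.4, 2, 2)),
               matrix(0, 2, 2))
  expect_equal(contrast_index(matrix(0.6, 1, 1), matrix(0.2, 1, 1))[1, 1],
               0.5)
  expect_equal(contrast_index(matrix(0, 1, 1), matrix(0, 1, 1))[1, 1], 0)
  # bounded in [-1, 1] for non-negative inputs, sign matches P50 - TI
  set.seed(32)
  a <- matrix(stats::runif(100), 10, 10)
  b <- matrix(stats::runif(100), 10, 10)
  ci <- contrast_index(a, b)
  expect_true(all(ci >= -1 & ci <= 1))
  expect_true(all(sign(ci) == sign(a - b)))
})

test_that("terrain and coordinate layers follow their conventions", {
  flat <- field_grid(matrix(500, 10, 10), pixel_size = 1)
  expect_equal(terrain_features(flat)$slope, matrix(0, 10, 10))

  # plane rising 1 m per 1 m pixel eastward -> 45 degrees
  incl <- field_grid(matrix(rep(1:10, each = 10), 10, 10), pixel_size = 1)
  slope <- terrain_features(incl)$slope
  expect_equal(slope[5, 5], 45, tolerance = 1e-9)

  cf <- coordinate_features(4, 4, pixel_size = 2, origin = c(100, 200))
  expect_equal(cf$longitude[1, 1], 101) # origin + half pixel
  expect_equal(cf$latitude[4, 1], 201)  # bottom row is half a pixel up
  expect_equal(cf$latitude[1, 1], 207)
})

test_that("the assembled stack has 31 uniquely named, manifest-listed layers", {
  fs <- feature_scene()
  expect_length(fs$stack$layers, 31)
  expect_false(anyDuplicated(names(fs$stack$layers)) > 0)
  expect_identical(fs$stack$manifest$layer, names(fs$stack$layers))
  expect_setequal(unique(fs$stack$manifest$group),
                  c("seasonal", "texture", "contrast", "terrain", "coordinate"))

  # point extraction equals the raster value of the containing pixel
  pts <- tibble::tibble(row = c(1, 17, 60), col = c(1, 80, 33))
  ext <- extract_features(pts, fs$stack)
  for (nm in c("s1_ndvi_p50", "ti_s3_r100", "elevation")) {
    expect_equal(ext[[nm]], fs$stack$layers[[nm]][cbind(pts$row, pts$col)])
  }

  dir <- withr::local_tempdir()
  write_stack(fs$stack, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_ascii_grid(file.path(dir, "s1_ndvi_p50.asc"))
  expect_equal(back$values, fs$stack$layers$s1_ndvi_p50, tolerance = 1e-6)
})
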