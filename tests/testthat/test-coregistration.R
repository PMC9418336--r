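test_that("seasonal reference is the median of valid NIR observations", {
  # 4 identical cloud-free months -> composite equals any month
  b <- array(0.4, c(8, 8, 4, 4))
  s <- monthly_series(b, months = 1:4)
  ref <- build_seasonal_reference(s, windows = list(only = 1:4))
  expect_equal(ref$only$composite$values, matrix(0.4, 8, 8))

  # {0.2, 0.4, 0.6, masked} -> 0.4; all masked -> undefined
  b2 <- array(0, c(2, 2, 4, 4))
  b2[1, 1, 3, ] <- c(0.2, 0.4, 0.6, 0.9)
  v <- array(TRUE, c(2, 2, 4))
  v[1, 1, 4] <- FALSE
  v[2, 2, ] <- FALSE
  s2 <- monthly_series(b2, valid = v, months = 1:4)
  ref2 <- build_seasonal_reference(s2, windows = list(only = 1:4))
  expect_equal(ref2$only$composite$values[1, 1], 0.4)
  expect_true(is.na(ref2$only$composite$values[2, 2]))
  expect_equal(ref2$only$count[2, 2], 0)

  # windows must partition the months
  expect_error(build_seasonal_reference(s2, windows = list(w = 1:3)),
               "partition")
})

test_that("known constant shifts are recovered below 0.5 px MAE", {
  sc <- clean_scene(seed = 3)
  ref <- sc$series$bands[, , "nir", 1]
  cfg <- coreg_config(block_px = 32, search_px = 6)
  for (sh in list(c(3, -2), c(-8, 12), c(15, -15))) {
    fld <- displacement_field(matrix(sh[1], 96, 96), matrix(sh[2], 96, 96))
    tgt <- smallfield:::warp_matrix(ref, fld$dx, fld$dy, "bilinear")
    tgt[is.na(tgt)] <- mean(ref)
    est <- estimate_displacement(tgt, ref, cfg)
    # correcting field is the negative of the applied shift
    mae <- mean(abs(est$dx + sh[1]) + abs(est$dy + sh[2])) / 2
    expect_lt(mae, 0.5)
  }
})

test_that("identity target yields a (near) zero field", {
  sc <- clean_scene(seed = 4)
  ref <- sc$series$bands[, , "nir", 1]
  est <- estimate_displacement(ref, ref, coreg_config(block_px = 32))
  expect_true(all(abs(est$dx) < 0.1))
  expect_true(all(abs(est$dy) < 0.1))
})

test_that("offsets are clamped to the configured maximum", {
  sc <- clean_scene(seed = 5)
  ref <- sc$series$bands[, , "nir", 1]
  big <- 150 / 4.77 # a 150 m shift against a 100 m cap
  fld <- displacement_field(matrix(big, 96, 96), matrix(0, 96, 96))
  tgt <- smallfield:::warp_matrix(ref, fld$dx, fld$dy, "bilinear")
  tgt[is.na(tgt)] <- mean(ref)
  est <- estimate_displacement(tgt, ref, coreg_config(block_px = 32))
  expect_lte(max(sqrt(est$dx^2 + est$dy^2)) * 4.77, 100 + 1e-6)
})

test_that("textureless targets give a zero field with a warning", {
  flat <- matrix(0.3, 96, 96)
  ref <- flat + 1e-13
  expect_warning(est <- estimate_displacement(flat, ref,
                                              coreg_config(block_px = 32)),
                 "low confidence")
  expect_true(all(est$dx == 0 & est$dy == 0))
})

test_that("insufficient overlap is rejected", {
  a <- matrix(NA_real_, 64, 64)
  a[1:10, 1:10] <- 1
  b <- matrix(stats::runif(64 * 64), 64, 64)
  expect_error(estimate_displacement(a, b, coreg_config(block_px = 32)),
               "overlap")
})

test_that("warping honours the zero-field and integer-shift oracles", {
  sc <- clean_scene(seed = 6)
  g <- field_grid(sc$series$bands[, , "nir", 1])
  zero <- displacement_field(matrix(0, 96, 96), matrix(0, 96, 96))
  expect_identical(apply_displacement(g, zero)$values, g$values)

  # constant integer shift equals an array roll on interior pixels
  sh <- displacement_field(matrix(2, 96, 96), matrix(-3, 96, 96))
  w <- apply_displacement(g, sh)
  inner_r <- 5:90; inner_c <- 5:90
  expect_equal(w$values[inner_r, inner_c],
               g$values[inner_r - 3, inner_c + 2], tolerance = 1e-12)

  # round trip through +d then -d is close to the identity on the interior
  fld <- simulate_displacement(96, 96, max_px = 2, seed = 7)
  back <- apply_displacement(apply_displacement(g, fld),
                             displacement_field(-fld$dx, -fld$dy))
  mad <- mean(abs(back$values - g$values)[10:86, 10:86], na.rm = TRUE)
  expect_lt(mad, 0.01)
})

test_that("series warping carries all bands and the validity mask", {
  truth <- simulate_scene(64, 64, cloud_fraction = 0.1, seed = 8)
  series <- render_monthly_series(truth, noise_sd = 0, spatial_noise_sd = 0,
                                  seed = 9)
  sh <- displacement_field(matrix(5, 64, 64), matrix(0, 64, 64))
  w <- apply_displacement(series, sh)
  expect_equal(w$bands[10:50, 10:50, "red", 2],
               series$bands[10:50, 15:55, "red", 2], tolerance = 1e-12)
  expect_equal(w$valid[10:50, 10:50, 2], series$valid[10:50, 15:55, 2])
  # pixels warped from outside the grid become invalid
  expect_true(all(!w$valid[, 60:64, 1]))
})

test_that("tiled and untiled estimation agree away from tile seams", {
  sc <- clean_scene(seed = 10)
  ref <- sc$series$bands[, , "nir", 1]
  fld <- displacement_field(matrix(3, 96, 96), matrix(-2, 96, 96))
  tgt <- smallfield:::warp_matrix(ref, fld$dx, fld$dy, "bilinear")
  tgt[is.na(tgt)] <- mean(ref)
  cfg1 <- coreg_config(block_px = 32, search_px = 6)
  cfg2 <- coreg_config(block_px = 32, search_px = 6, tile_px = 48,
                       buffer_px = 26)
  whole <- estimate_displacement(tgt, ref, cfg1)
  tiled <- smallfield:::estimate_displacement_tiled(tgt, ref, cfg2)
  expect_lt(mean(abs(whole$dx - tiled$dx)), 0.3)
  expect_lt(mean(abs(whole$dy - tiled$dy)), 0.3)
  # and the tiled correction still lands within 0.5 px of the truth
  expect_lt(mean(abs(tiled$dx + 3)), 0.5)
  expect_lt(mean(abs(tiled$dy - 2)), 0.5)
})

test_that("coregistration reduces time-series noise on jittered scenes", {
  sc <- jittered_scene(seed = 61)
  cr <- coregister_series(sc$series, coreg_config(block_px = 32),
                          reference = sc$reference)
  before <- noise_map(sc$series)$values
  after <- noise_map(cr$series)$values
  expect_lt(mean(after, na.rm = TRUE), mean(before, na.rm = TRUE))
  edge <- boundary_pixels(sc$truth$class_map)
  expect_gte(mean((after <= before)[edge], na.rm = TRUE), 0.9)
})
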