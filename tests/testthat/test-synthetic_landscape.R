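test_that("class map matches requested proportions and is deterministic", {
  m1 <- generate_class_map(128, 128, seed = 42)
  m2 <- generate_class_map(128, 128, seed = 42)
  expect_identical(m1$values, m2$values)

  req <- default_class_mix()
  got <- attr(m1, "proportions")
  expect_true(all(abs(got - req) <= 0.05))
  # active cropland / fallow shares of the published assessment
  expect_lt(abs(got[["active_cropland"]] - 0.162), 0.05)
  expect_lt(abs(got[["short_fallow"]] - 0.066), 0.05)

  m3 <- generate_class_map(128, 128, seed = 43)
  expect_false(identical(m1$values, m3$values))
})

test_that("single-class mix gives a uniform map; degenerate inputs reject", {
  m <- generate_class_map(64, 64, class_mix = c(water = 1))
  expect_true(all(m$values == 7L))
  expect_error(generate_class_map(32, 32), "extent too small")
  expect_error(generate_class_map(64, 64, class_mix = c(water = 0.5)),
               "sum to 1")
  expect_error(generate_class_map(64, 64, class_mix = c(moon_base = 1)),
               "unknown class")
})

test_that("noiseless rendering reproduces the phenology exactly", {
  sc <- clean_scene()
  nd <- ndvi_series(sc$series)
  phen <- default_phenology()
  for (cl in c(1, 4, 7)) {
    pix <- which(sc$truth$class_map$values == cl)[1]
    r <- ((pix - 1) %% 96) + 1
    co <- ((pix - 1) %/% 96) + 1
    expect_equal(nd[r, co, ], unname(phen$ndvi[cl, ]), tolerance = 1e-12)
  }
})

test_that("rendering is deterministic and errors on missing phenology", {
  truth <- simulate_scene(64, 64, seed = 9)
  s1 <- render_monthly_series(truth, seed = 10)
  s2 <- render_monthly_series(truth, seed = 10)
  expect_identical(s1$bands, s2$bands)

  phen <- default_phenology()
  phen$ndvi <- phen$ndvi[-1, , drop = FALSE] # drop active cropland
  expect_error(render_monthly_series(truth, phen = phen), "active_cropland")
})

test_that("a constant shift shows up as a cross-correlation lag peak", {
  sc <- clean_scene(seed = 8)
  truth <- sc$truth
  # month 2 shifted by +3 columns relative to month 1
  truth$displacement[[2]]$dx[] <- 3
  series <- render_monthly_series(truth, noise_sd = 0, spatial_noise_sd = 0,
                                  seed = 11)
  a <- series$bands[, , "nir", 1]
  b <- series$bands[, , "nir", 2]
  # brute-force correlation over integer column lags
  lags <- -6:6
  cors <- vapply(lags, function(l) {
    ca <- a[, 10:80]
    cb <- b[, 10:80 - l]
    stats::cor(as.vector(ca), as.vector(cb))
  }, numeric(1))
  # month 2 samples the scene 3 columns east (b[, c] = a[, c + 3]), so
  # shifting it back by +3 columns realigns it with month 1
  expect_equal(lags[which.max(cors)], 3)
})

test_that("cloud masks hit the requested fraction", {
  for (seed in 1:3) {
    mask <- simulate_clouds(128, 128, fraction = 0.2, seed = seed)
    expect_lt(abs(mean(mask) - 0.2), 0.05)
  }
  expect_equal(mean(simulate_clouds(64, 64, fraction = 0)), 0)
})

test_that("reference points respect distance, labels and determinism", {
  truth <- simulate_scene(128, 128, seed = 13)
  min_d <- 222 / 2 # metres; the scene is only ~610 m wide
  s1 <- suppressWarnings(
    sample_reference_points(truth, 5, min_dist_m = min_d, seed = 14))
  s2 <- suppressWarnings(
    sample_reference_points(truth, 5, min_dist_m = min_d, seed = 14))
  expect_identical(s1, s2)
  dmat <- as.matrix(stats::dist(cbind(s1$x, s1$y)))
  diag(dmat) <- Inf
  expect_true(all(dmat >= min_d))
  # labels agree with the map at the sampled pixel, always
  expect_identical(s1$code,
                   truth$class_map$values[cbind(s1$row, s1$col)])

  one <- sample_reference_points(truth, 1, min_dist_m = 0, seed = 15)
  expect_equal(nrow(one), 7)
  expect_setequal(one$code, 1:7)

  expect_warning(
    sample_reference_points(truth, 500, min_dist_m = 100, seed = 16),
    "short")
})

test_that("scene truths honour displacement and cloud caps", {
  truth <- simulate_scene(64, 64, displacement_max_px = 2,
                          cloud_fraction = 0.15, seed = 21)
  for (d in truth$displacement) {
    expect_true(all(sqrt(d$dx^2 + d$dy^2) <= 2 + 1e-9))
  }
  for (m in 1:12) expect_lt(mean(truth$clouds[, , m]), 0.15 + 0.05)
})

test_that("scene and series round-trip through plain-text rasters", {
  truth <- simulate_scene(64, 64, seed = 31)
  dir <- withr::local_tempdir()
  write_scene(truth, dir = dir)
  back <- read_ascii_grid(file.path(dir, "class_map.asc"))
  expect_equal(back$values, truth$class_map$values + 0)
  expect_equal(back$pixel_size, truth$pixel_size)
})
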