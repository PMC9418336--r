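# Shared small synthetic fixtures, built once per test run.

# clean scene: no displacement, no clouds, no noise of any kind
clean_scene <- function(seed = 3L, n = 96L) {
  truth <- simulate_scene(n, n, displacement_max_px = 0, cloud_fraction = 0,
                          seed = seed)
  series <- render_monthly_series(truth, noise_sd = 0, spatial_noise_sd = 0,
                                  seed = seed + 1L)
  list(truth = truth, series = series)
}

# scene with translation-dominant monthly jitter (the mosaic misregistration
# mode): per-month constant shift in [-3, 3] px plus a 0.5 px smooth field
jittered_scene <- function(seed, n = 80L, noise_sd = 0.01,
                           cloud_fraction = 0.05) {
  truth <- simulate_scene(n, n, displacement_max_px = 0.5,
                          cloud_fraction = cloud_fraction, seed = seed)
  set.seed(seed * 7L)
  for (m in seq_along(truth$displacement)) {
    sh <- stats::runif(2, -3, 3)
    truth$displacement[[m]]$dx <- truth$displacement[[m]]$dx + sh[1]
    truth$displacement[[m]]$dy <- truth$displacement[[m]]$dy + sh[2]
  }
  series <- render_monthly_series(truth, noise_sd = noise_sd,
                                  spatial_noise_sd = 0, seed = seed + 1L)
  # external well-registered reference (the role Sentinel-2 plays)
  truth0 <- truth
  truth0$displacement <- lapply(truth0$displacement, function(d) {
    d$dx[] <- 0; d$dy[] <- 0; d
  })
  ref <- build_seasonal_reference(
    render_monthly_series(truth0, noise_sd = noise_sd / 2,
                          spatial_noise_sd = 0, seed = seed + 2L))
  list(truth = truth, series = series, reference = ref)
}

# boundary pixels of a class map (4-neighbour definition)
boundary_pixels <- function(map) {
  v <- map$values
  v != rbind(v[-1, ], v[nrow(v), ]) | v != cbind(v[, -1], v[, ncol(v)]) |
    v != rbind(v[1, ], v[-nrow(v), ]) | v != cbind(v[, 1], v[, -ncol(v)])
}

.cached_feature_scene <- NULL
# mid-noise scene + feature stack used by classifier tests
feature_scene <- function() {
  if (is.null(.cached_feature_scene)) {
    truth <- simulate_scene(96, 96, cloud_fraction = 0.1, seed = 5L)
    series <- render_monthly_series(truth, noise_sd = 0.05,
                                    spatial_noise_sd = 0.08, seed = 6L)
    stack <- assemble_stack(series, truth$dem)
    .cached_feature_scene <<- list(truth = truth, series = series,
                                   stack = stack)
  }
  .cached_feature_scene
}
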