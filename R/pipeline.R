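#' Default end-to-end run configuration
#'
#' One nested list drives the whole pipeline; every random operation draws
#' from a seed derived from the single master `seed`, so a run is
#' reproducible end to end. Values not supplied fall back to these
#' defaults, which state the conditions the package targets: a 4.77 m
#' pixel, three 4-month seasons, 100 m maximum coregistration offset with
#' stiffness 5, a 250-tree forest, 25th-percentile margin augmentation with
#' 50 locations per class, and a validation design with a 200-per-class
#' floor.
#'
#' @param seed master seed.
#' @param ... named overrides of the defaults (nested lists are merged
#'   shallowly per section).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    scene = list(nrow = 128, ncol = 128, class_mix = default_class_mix(),
                 n_months = 12, displacement_max_px = 2, cloud_fraction = 0.1,
                 pixel_size = 4.77, noise_sd = 0.02),
    coreg = list(enabled = TRUE, max_offset_m = 100, stiffness = 5,
                 levels = 3, block_px = 32, search_px = 6),
    features = list(kernel_radii_m = c(25, 100, 200), texture_seasons = c(1, 3)),
    learner = list(n_trees = 100, initial_per_class = 30, min_dist_m = 0,
                   margin_q = 0.25, augment_per_class = 50, extra_random = 0),
    validation = list(se_target = 0.01, ua_assumed = 0.75,
                      per_class_floor = 25, labelable_rate = 1),
    aggregation = list(cell_px = 16)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full pipeline on a synthetic scene
#'
#' Orchestrates `simulate -> coregister -> tsnoise -> features -> learn ->
#' classify -> validate -> aggregate` from one seeded configuration and
#' returns all artifacts. Designed as the demonstration and test harness of
#' the package; on real data the stages are called individually on imported
#' rasters.
#'
#' @param cfg a [run_config()].
#' @param log_path optional path for a JSON-lines run log.
#' @return list of artifacts: `truth`, `series`, `coreg` (fields + series),
#'   `noise` (before/after `field_grid`s), `stack`, `learning` (model,
#'   training, log), `map`, `validation` (`error_matrix_estimate`),
#'   `grid_summary`, `curve`, `fallow_shares`, `config`, `config_hash`.
#' @export
run_end_to_end <- function(cfg = run_config(), log_path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- rlang::hash(cfg)
  t0 <- Sys.time()
  logs <- list()
  say <- function(stage, ...) {
    entry <- list(stage = stage, elapsed_s = round(
      as.numeric(difftime(Sys.time(), t0, units = "secs")), 2), ...)
    logs[[length(logs) + 1]] <<- entry
    if (!is.null(log_path)) {
      cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
          file = log_path, append = TRUE, sep = "")
    }
  }
  seed <- cfg$seed
  sc <- cfg$scene
  truth <- simulate_scene(sc$nrow, sc$ncol, sc$class_mix, sc$n_months,
                          sc$displacement_max_px, sc$cloud_fraction,
                          sc$pixel_size, seed = seed)
  series <- render_monthly_series(truth, noise_sd = sc$noise_sd,
                                  seed = seed + 1L)
  say("simulate", pixels = sc$nrow * sc$ncol)

  noise_before <- noise_map(series)
  coreg <- NULL
  if (isTRUE(cfg$coreg$enabled) && sc$displacement_max_px > 0) {
    ccfg <- coreg_config(max_offset_m = cfg$coreg$max_offset_m,
                         stiffness = cfg$coreg$stiffness,
                         levels = cfg$coreg$levels,
                         block_px = cfg$coreg$block_px,
                         search_px = cfg$coreg$search_px,
                         pixel_size = sc$pixel_size)
    coreg <- coregister_series(series, ccfg)
    series_use <- coreg$series
  } else {
    series_use <- series
  }
  noise_after <- noise_map(series_use)
  say("tsnoise",
      mean_before = mean(noise_before$values, na.rm = TRUE),
      mean_after = mean(noise_after$values, na.rm = TRUE))

  stack <- assemble_stack(series_use, truth$dem,
                          kernel_radii_m = cfg$features$kernel_radii_m,
                          texture_seasons = cfg$features$texture_seasons)
  say("features", layers = length(stack$layers))

  init <- sample_reference_points(truth, cfg$learner$initial_per_class,
                                  min_dist_m = cfg$learner$min_dist_m,
                                  seed = seed + 2L)
  al <- run_active_learning(stack, init, truth_labeler(truth),
                            n_trees = cfg$learner$n_trees,
                            margin_q = cfg$learner$margin_q,
                            augment_per_class = cfg$learner$augment_per_class,
                            min_dist_m = cfg$learner$min_dist_m,
                            extra_random = cfg$learner$extra_random,
                            seed = seed + 3L)
  prob <- predict_probabilities(al$model, stack)
  map <- classify(prob)
  say("classify", n_train = al$model$n_train)

  W <- class_shares(map)$share
  n <- sample_size(W[W > 0], cfg$validation$ua_assumed,
                   cfg$validation$se_target)
  k <- sum(W > 0)
  floor_pc <- min(cfg$validation$per_class_floor, floor(n / k))
  alloc7 <- integer(7)
  alloc7[W > 0] <- allocate(min(n, sum(W > 0) * 200), W[W > 0] / sum(W[W > 0]),
                            per_class_floor = floor_pc)
  vs <- draw_validation_sample(map, alloc7,
                               labelable_rate = cfg$validation$labelable_rate,
                               seed = seed + 4L)
  vs$ref_code <- truth$class_map$values[cbind(vs$row, vs$col)]
  vs$ref_code[!vs$labelable] <- NA_integer_
  est <- error_matrix_from_sample(vs, map)
  say("validate", oa = est$oa)

  gs <- gridcell_fractions(map, cfg$aggregation$cell_px)
  curve <- fallow_share_curve(gs)
  shares <- fallow_share_comparison(map, est)
  say("aggregate", cells = nrow(gs))

  list(truth = truth, series = series, coreg = coreg,
       noise = list(before = noise_before, after = noise_after),
       stack = stack, learning = al, map = map,
       validation = est, validation_sample = vs,
       grid_summary = gs, curve = curve, fallow_shares = shares,
       config = cfg, config_hash = hash, log = logs)
}
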