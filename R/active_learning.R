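#' Train the random-forest classifier
#'
#' Fits a bootstrap ensemble of CART trees (Gini splits, per-split feature
#' subsampling) returning calibrated-by-averaging class probabilities — the
#' classical random forest, 250 trees by default. Rows with missing feature
#' values are dropped with a logged count; per-feature training medians are
#' stored so prediction can impute incomplete pixels. Training is fully
#' deterministic given `seed` (the ensemble uses its own RNG stream and does
#' not touch R's RNG state).
#'
#' @param train tibble with a `code` column (class codes 1-7) and numeric
#'   feature columns.
#' @param features character vector naming the feature columns; default all
#'   numeric columns except bookkeeping ones (`code`, `row`, `col`, `x`,
#'   `y`).
#' @param n_trees number of trees (default 250).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param min_split minimum node size to attempt a split.
#' @param max_depth maximum tree depth.
#' @param sample_frac bootstrap fraction (with replacement).
#' @param seed integer seed.
#' @return a `fallow_forest` model object.
#' @export
train_classifier <- function(train, features = NULL, n_trees = 250,
                             mtry = NULL, min_split = 2, max_depth = 30,
                             sample_frac = 1, seed = 1L) {
  stopifnot("code" %in% names(train))
  if (is.null(features)) {
    drop <- c("code", "class", "row", "col", "x", "y", "provenance", "split",
              "iteration", "pred_code", "map_code", "ref_code", "labelable")
    features <- setdiff(names(train)[vapply(train, is.numeric, logical(1))],
                        drop)
  }
  stopifnot(length(features) >= 1)
  X <- as.matrix(train[, features])
  y <- as.integer(train$code)
  ok <- stats::complete.cases(X) & !is.na(y)
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(sprintf("dropped %d row(s) with missing feature values", dropped))
    X <- X[ok, , drop = FALSE]; y <- y[ok]
  }
  if (length(unique(y)) < 2) stop("training data contains a single class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- sf_grow_forest(X, y - 1L, n_class = 7L, n_trees = as.integer(n_trees),
                        mtry = as.integer(mtry), min_split = as.integer(min_split),
                        max_depth = as.integer(max_depth),
                        sample_frac = sample_frac, seed = as.double(seed))
  structure(
    list(trees = fit$trees,
         importance = stats::setNames(fit$importance, features),
         features = features,
         feature_medians = apply(X, 2, stats::median),
         n_trees = n_trees, mtry = mtry, seed = seed,
         n_train = length(y), dropped = dropped,
         class_counts = tabulate(y, 7)),
    class = "fallow_forest"
  )
}

#' @export
print.fallow_forest <- function(x, ...) {
  cat(sprintf("<fallow_forest> %d trees, %d features, %d training samples\n",
              x$n_trees, length(x$features), x$n_train))
  invisible(x)
}

#' @export
predict.fallow_forest <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_stack")) {
    stack_matrix(newdata)[, object$features, drop = FALSE]
  } else if (is.matrix(newdata)) {
    newdata[, object$features, drop = FALSE]
  } else {
    as.matrix(newdata[, object$features])
  }
  for (j in seq_len(ncol(X))) { # impute incomplete pixels with train medians
    na <- !is.finite(X[, j])
    if (any(na)) X[na, j] <- object$feature_medians[j]
  }
  p <- sf_predict_forest(object$trees, X, 7L)
  colnames(p) <- class_catalog()$class
  p
}

#' Broom-style accessors for the classifier
#'
#' `tidy()` returns per-feature Gini importance; `glance()` a one-row model
#' summary.
#'
#' @param x a `fallow_forest`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.fallow_forest <- function(x, ...) {
  tibble::tibble(feature = x$features,
                 importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.fallow_forest
#' @export
glance.fallow_forest <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_features = length(x$features),
                 n_trees = x$n_trees, mtry = x$mtry,
                 n_classes = sum(x$class_counts > 0),
                 dropped_rows = x$dropped)
}

#' Predict per-pixel class probabilities over a feature stack
#'
#' @param model a `fallow_forest`.
#' @param stack a `feature_stack`.
#' @return a `probability_stack`: array `[row, col, class]` whose slices sum
#'   to 1 at every pixel, plus grid metadata.
#' @export
predict_probabilities <- function(model, stack) {
  stopifnot(inherits(stack, "feature_stack"))
  d <- dim(stack$layers[[1]])
  p <- predict(model, stack)
  probs <- array(p, c(d[1], d[2], 7))
  dimnames(probs)[[3]] <- class_catalog()$class
  structure(list(probs = probs, pixel_size = stack$pixel_size,
                 origin = stack$origin),
            class = "probability_stack")
}

#' Hard classification of a probability stack
#'
#' Argmax per pixel; ties broken toward the lowest class code so maps are
#' deterministic.
#'
#' @param prob a `probability_stack`.
#' @return a `class_map`.
#' @export
classify <- function(prob) {
  stopifnot(inherits(prob, "probability_stack"))
  d <- dim(prob$probs)
  m <- matrix(prob$probs, d[1] * d[2], d[3])
  cls <- max.col(m, ties.method = "first")
  structure(
    list(values = matrix(as.integer(cls), d[1], d[2]),
         pixel_size = prob$pixel_size, origin = prob$origin,
         catalog = class_catalog()),
    class = "class_map",
    proportions = stats::setNames(tabulate(cls, 7) / length(cls),
                                  class_catalog()$class)
  )
}

#' Probability margin map
#'
#' Per-pixel margin `M_prob` = probability of the most likely class minus
#' that of the second most likely: the classifier's pixel-level confidence,
#' in `[0, 1]`.
#'
#' @param prob a `probability_stack`.
#' @return a `field_grid` named `"margin"`.
#' @export
prob_margin <- function(prob) {
  stopifnot(inherits(prob, "probability_stack"))
  d <- dim(prob$probs)
  m <- matrix(prob$probs, d[1] * d[2], d[3])
  top2 <- apply(m, 1, function(p) {
    s <- sort(p, decreasing = TRUE)[1:2]
    s[1] - s[2]
  })
  field_grid(matrix(top2, d[1], d[2]), prob$pixel_size, prob$origin,
             name = "margin")
}

#' Class-wise margin thresholds
#'
#' For each predicted class, the `q`-quantile (default 25th percentile) of
#' the margin over that class's pixels: pixels below it count as classified
#' with relatively low confidence. On very large rasters the quantile is
#' taken over a seeded subsample of at most `max_pixels` pixels.
#'
#' @param margin a `field_grid` from [prob_margin()].
#' @param pred the `class_map` from [classify()].
#' @param q quantile level in (0, 1).
#' @param max_pixels subsample cap for the quantile.
#' @param seed seed for the subsample.
#' @return tibble `code`, `class`, `threshold`, `n_pixels`; classes absent
#'   from the prediction get an `NA` threshold and a warning.
#' @export
classwise_margin_threshold <- function(margin, pred, q = 0.25,
                                       max_pixels = 1e6, seed = 1L) {
  stopifnot(inherits(margin, "field_grid"), inherits(pred, "class_map"))
  mv <- as.vector(margin$values)
  cv <- as.vector(pred$values)
  if (length(mv) > max_pixels) {
    set.seed(seed)
    keep <- sample.int(length(mv), max_pixels)
    mv <- mv[keep]; cv <- cv[keep]
  }
  out <- class_catalog()[, c("code", "class")]
  out$threshold <- NA_real_
  out$n_pixels <- 0L
  for (i in seq_len(7)) {
    sel <- cv == i & is.finite(mv)
    out$n_pixels[i] <- sum(sel)
    if (out$n_pixels[i] > 0) {
      out$threshold[i] <- unname(stats::quantile(mv[sel], q, type = 7))
    }
  }
  if (any(out$n_pixels == 0)) {
    warning("class(es) absent from prediction, threshold undefined: ",
            paste(out$class[out$n_pixels == 0], collapse = ", "))
  }
  out
}

#' Sample low-confidence locations for augmentation
#'
#' Draws up to `n_per_class` seeded random locations per (predicted) class
#' among pixels whose margin falls below the class threshold, optionally
#' enforcing a minimum pairwise distance. The locations are unlabeled; a
#' labeler (human or synthetic truth) assigns classes afterwards.
#'
#' @param margin a `field_grid` from [prob_margin()].
#' @param pred the `class_map` from [classify()].
#' @param thresholds tibble from [classwise_margin_threshold()].
#' @param n_per_class locations per class (default 50).
#' @param min_dist_m minimum pairwise distance in metres (0 disables).
#' @param classes class codes to sample (default all 7); restricting to one
#'   class gives the targeted single-class augmentation pass.
#' @param seed integer seed.
#' @return tibble `x`, `y`, `row`, `col`, `pred_code`, `provenance`
#'   (`"margin"`). A shortfall (too few low-margin pixels) is messaged.
#' @export
sample_low_confidence <- function(margin, pred, thresholds, n_per_class = 50,
                                  min_dist_m = 0, classes = 1:7, seed = 1L) {
  set.seed(seed)
  nr <- nrow(pred$values); nc <- ncol(pred$values)
  cc <- pixel_centers(nr, nc, pred$pixel_size, pred$origin)
  mv <- margin$values; cv <- pred$values
  acc_x <- numeric(0); acc_y <- numeric(0)
  rows <- integer(0); cols <- integer(0); pcode <- integer(0)
  shortfall <- 0L
  for (cl in classes) {
    thr <- thresholds$threshold[thresholds$code == cl]
    if (length(thr) != 1 || !is.finite(thr)) next
    cand <- which(cv == cl & mv < thr)
    if (!length(cand)) { shortfall <- shortfall + n_per_class; next }
    cand <- cand[sample.int(length(cand))]
    got <- 0L
    for (p in cand) {
      if (got >= n_per_class) break
      r <- ((p - 1L) %% nr) + 1L
      co <- ((p - 1L) %/% nr) + 1L
      x <- cc$x[r, co]; y <- cc$y[r, co]
      if (min_dist_m > 0 && length(acc_x) &&
          any((acc_x - x)^2 + (acc_y - y)^2 < min_dist_m^2)) next
      acc_x <- c(acc_x, x); acc_y <- c(acc_y, y)
      rows <- c(rows, r); cols <- c(cols, co); pcode <- c(pcode, cl)
      got <- got + 1L
    }
    shortfall <- shortfall + (n_per_class - got)
  }
  if (shortfall > 0) {
    message(sprintf("low-confidence sampling fell short by %d location(s)",
                    shortfall))
  }
  tibble::tibble(x = acc_x, y = acc_y, row = rows, col = cols,
                 pred_code = pcode, provenance = "margin")
}

#' A labeler that reads labels from a scene truth
#'
#' Returns a callback suitable for [run_active_learning()]: given a tibble
#' of locations (`row`, `col`) it returns the true class codes from the
#' scene's class map. Production use replaces this with a human-in-the-loop
#' file exchange.
#'
#' @param truth a `scene_truth` or `class_map`.
#' @return function(samples) -> integer codes.
#' @export
truth_labeler <- function(truth) {
  map <- if (inherits(truth, "scene_truth")) truth$class_map else truth
  stopifnot(inherits(map, "class_map"))
  function(samples) map$values[cbind(samples$row, samples$col)]
}

#' Margin-driven active learning
#'
#' Two-stage procedure: an initial model trained on the starting samples;
#' then the training set is augmented with (a) optional extra random
#' locations, (b) an optional targeted pass on hard classes (e.g.
#' under-represented fallows), and (c) `augment_per_class` locations per
#' class drawn where the probability margin falls below the class-wise
#' `margin_q` quantile; the labeler assigns classes and the model is
#' retrained. Each iteration's hold-out accuracy is logged when a hold-out
#' set is supplied.
#'
#' @param stack a `feature_stack`.
#' @param initial tibble of labelled samples with `row`, `col`, `code` (as
#'   from [sample_reference_points()]); features are extracted internally.
#' @param labeler callback assigning codes to new locations (see
#'   [truth_labeler()]).
#' @param n_trees,margin_q,augment_per_class,min_dist_m learner and
#'   augmentation settings (defaults 250 trees, 0.25, 50/class, 0 m).
#' @param extra_random additional random labelled locations added before
#'   margin sampling (0 disables).
#' @param target_classes class codes for a targeted low-confidence pass
#'   before the all-class pass (NULL disables).
#' @param holdout optional labelled tibble (`row`, `col`, `code`) for the
#'   accuracy log.
#' @param seed integer master seed.
#' @return list with `model` (final `fallow_forest`), `initial_model`,
#'   `training` (tibble with per-sample `provenance` and `iteration`), and
#'   `log` (per-iteration tibble `iteration`, `n_train`, `accuracy`).
#' @export
run_active_learning <- function(stack, initial, labeler, n_trees = 250,
                                margin_q = 0.25, augment_per_class = 50,
                                min_dist_m = 0, extra_random = 0,
                                target_classes = NULL, holdout = NULL,
                                seed = 1L) {
  stopifnot(inherits(stack, "feature_stack"), is.function(labeler))
  cat7 <- class_catalog()
  train0 <- extract_features(
    dplyr::mutate(initial[, c("x", "y", "row", "col", "code")],
                  provenance = "random", iteration = 0L),
    stack)
  model0 <- train_classifier(train0, n_trees = n_trees, seed = seed)
  acc <- function(model) {
    if (is.null(holdout)) return(NA_real_)
    hp <- predict(model, extract_features(holdout, stack))
    mean(max.col(hp, ties.method = "first") == holdout$code)
  }
  log <- tibble::tibble(iteration = 0L, n_train = model0$n_train,
                        accuracy = acc(model0))

  prob <- predict_probabilities(model0, stack)
  pred <- classify(prob)
  marg <- prob_margin(prob)
  thr <- classwise_margin_threshold(marg, pred, q = margin_q,
                                    seed = seed + 11L)
  train <- train0
  if (extra_random > 0) {
    d <- dim(stack$layers[[1]])
    set.seed(seed + 23L)
    pix <- sample.int(d[1] * d[2], extra_random)
    r <- ((pix - 1L) %% d[1]) + 1L
    co <- ((pix - 1L) %/% d[1]) + 1L
    cc <- pixel_centers(d[1], d[2], stack$pixel_size, stack$origin)
    extra <- tibble::tibble(x = cc$x[cbind(r, co)], y = cc$y[cbind(r, co)],
                            row = r, col = co)
    extra$code <- as.integer(labeler(extra))
    extra$provenance <- "random_extra"; extra$iteration <- 1L
    train <- dplyr::bind_rows(train, extract_features(extra, stack))
  }
  if (!is.null(target_classes)) {
    targeted <- sample_low_confidence(marg, pred, thr,
                                      n_per_class = augment_per_class,
                                      min_dist_m = min_dist_m,
                                      classes = target_classes,
                                      seed = seed + 31L)
    if (nrow(targeted)) {
      targeted$code <- as.integer(labeler(targeted))
      targeted$provenance <- "targeted"; targeted$iteration <- 1L
      train <- dplyr::bind_rows(
        train, extract_features(
          targeted[, c("x", "y", "row", "col", "code", "provenance",
                       "iteration")], stack))
    }
  }
  aug <- sample_low_confidence(marg, pred, thr,
                               n_per_class = augment_per_class,
                               min_dist_m = min_dist_m, seed = seed + 47L)
  if (nrow(aug)) {
    aug$code <- as.integer(labeler(aug))
    aug$provenance <- "margin"; aug$iteration <- 1L
    train <- dplyr::bind_rows(
      train, extract_features(
        aug[, c("x", "y", "row", "col", "code", "provenance", "iteration")],
        stack))
  }
  model1 <- train_classifier(train, n_trees = n_trees, seed = seed + 1L)
  log <- dplyr::bind_rows(
    log, tibble::tibble(iteration = 1L, n_train = model1$n_train,
                        accuracy = acc(model1)))
  train$class <- cat7$class[train$code]
  list(model = model1, initial_model = model0, training = train, log = log)
}
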