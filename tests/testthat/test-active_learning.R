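make_sep_data <- function(n = 60, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    code = rep(c(1L, 4L), each = n / 2),
    f1 = c(stats::rnorm(n / 2, 0), stats::rnorm(n / 2, 10)),
    f2 = stats::rnorm(n)
  )
}

test_that("the forest fits separable data and is seed-deterministic", {
  d <- make_sep_data()
  m <- train_classifier(d, n_trees = 25, seed = 5)
  p <- predict(m, d)
  expect_equal(max.col(p, ties.method = "first"), d$code)

  m2 <- train_classifier(d, n_trees = 25, seed = 5)
  expect_equal(predict(m2, d), p)
  m3 <- train_classifier(d, n_trees = 25, seed = 6)
  expect_false(identical(predict(m3, d), p))

  expect_error(train_classifier(dplyr::mutate(d, code = 1L)),
               "single class")

  # rows with missing features are dropped with a message
  d2 <- d; d2$f1[1] <- NA
  expect_message(m4 <- train_classifier(d2, n_trees = 10, seed = 1),
                 "dropped 1")
  expect_equal(m4$n_train, nrow(d) - 1)

  expect_s3_class(tidy(m), "tbl_df")
  expect_named(glance(m), c("n_train", "n_features", "n_trees", "mtry",
                            "n_classes", "dropped_rows"))
})

test_that("label permutation drives hold-out accuracy to chance", {
  set.seed(9)
  n <- 400
  d <- tibble::tibble(code = rep(1:4, n / 4),
                      f1 = stats::rnorm(n), f2 = stats::rnorm(n),
                      f3 = stats::rnorm(n))
  train <- d[1:300, ]; test <- d[301:400, ]
  m <- train_classifier(train, n_trees = 50, seed = 2)
  p <- max.col(predict(m, test), ties.method = "first")
  expect_lt(abs(mean(p == test$code) - 0.25), 0.1)
})

test_that("probabilities normalise and margins follow their contract", {
  fs <- feature_scene()
  init <- sample_reference_points(fs$truth, 20, min_dist_m = 0, seed = 41)
  m <- train_classifier(extract_features(init, fs$stack), n_trees = 50,
                        seed = 42)
  prob <- predict_probabilities(m, fs$stack)
  sums <- apply(prob$probs, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(prob$probs >= 0))

  mg <- prob_margin(prob)
  expect_true(all(mg$values >= 0 & mg$values <= 1))

  # hand-built probability stacks give the textbook margins
  mk <- function(p) {
    a <- array(rep(p, each = 1), c(1, 1, length(p)))
    structure(list(probs = a, pixel_size = 1, origin = c(0, 0)),
              class = "probability_stack")
  }
  expect_equal(prob_margin(mk(c(0.6, 0.3, 0.1)))$values[1, 1], 0.3)
  expect_equal(prob_margin(mk(rep(1 / 7, 7)))$values[1, 1], 0)
  expect_equal(prob_margin(mk(c(1, 0, 0)))$values[1, 1], 1)

  pred <- classify(prob)
  expect_true(all(pred$values %in% 1:7))
  # argmax ties break toward the lowest class code
  tie <- mk(c(0.4, 0.4, 0.2))
  expect_equal(classify(tie)$values[1, 1], 1L)
})

test_that("class-wise margin thresholds sit at the requested quantile", {
  set.seed(55)
  n <- 100 # 10^4 pixels
  mg <- field_grid(matrix(stats::runif(n * n), n, n))
  pred <- structure(list(values = matrix(1L, n, n), pixel_size = 4.77,
                         origin = c(0, 0), catalog = class_catalog()),
                    class = "class_map")
  thr <- suppressWarnings(classwise_margin_threshold(mg, pred, q = 0.25))
  expect_lt(abs(thr$threshold[1] - 0.25), 0.02)
  # ~25% of the class pixels fall below the threshold
  expect_lt(abs(mean(mg$values < thr$threshold[1]) - 0.25), 0.01)
  # constant margins -> threshold equals the constant
  mg2 <- field_grid(matrix(0.4, 20, 20))
  pred2 <- pred; pred2$values <- matrix(2L, 20, 20)
  thr2 <- suppressWarnings(classwise_margin_threshold(mg2, pred2))
  expect_equal(thr2$threshold[2], 0.4)
  # absent classes are skipped with a warning and an NA threshold
  expect_warning(classwise_margin_threshold(mg2, pred2), "absent")
  expect_true(is.na(thr2$threshold[5]))
})

test_that("low-confidence sampling respects thresholds and distances", {
  fs <- feature_scene()
  init <- sample_reference_points(fs$truth, 25, min_dist_m = 0, seed = 43)
  m <- train_classifier(extract_features(init, fs$stack), n_trees = 50,
                        seed = 44)
  prob <- predict_probabilities(m, fs$stack)
  pred <- classify(prob)
  mg <- prob_margin(prob)
  thr <- suppressWarnings(classwise_margin_threshold(mg, pred))
  aug <- suppressMessages(
    sample_low_confidence(mg, pred, thr, n_per_class = 10,
                          min_dist_m = 20, seed = 45))
  expect_true(all(mg$values[cbind(aug$row, aug$col)] <
                    thr$threshold[aug$pred_code]))
  expect_true(all(pred$values[cbind(aug$row, aug$col)] == aug$pred_code))
  d <- as.matrix(stats::dist(cbind(aug$x, aug$y))); diag(d) <- Inf
  expect_true(all(d >= 20))
  aug2 <- suppressMessages(
    sample_low_confidence(mg, pred, thr, n_per_class = 10,
                          min_dist_m = 20, seed = 45))
  expect_identical(aug, aug2)
})

test_that("active learning logs iterations and improves the initial model", {
  fs <- feature_scene()
  init <- sample_reference_points(fs$truth, 30, min_dist_m = 0, seed = 46)
  hold <- sample_reference_points(fs$truth, 40, min_dist_m = 0, seed = 47)
  al <- suppressMessages(
    run_active_learning(fs$stack, init, truth_labeler(fs$truth),
                        n_trees = 100, augment_per_class = 10,
                        holdout = hold, seed = 48))
  expect_equal(al$log$iteration, c(0L, 1L))
  expect_gt(al$log$n_train[2], al$log$n_train[1])
  expect_true(all(al$training$provenance %in% c("random", "margin")))
  expect_true(all(is.finite(al$log$accuracy)))
  # the augmented model should not be materially worse than the initial one
  expect_gt(al$log$accuracy[2], al$log$accuracy[1] - 0.05)

  # targeted single-class augmentation machinery (hard-class pass)
  al2 <- suppressMessages(
    run_active_learning(fs$stack, init, truth_labeler(fs$truth),
                        n_trees = 50, augment_per_class = 10,
                        target_classes = 2L, extra_random = 20, seed = 49))
  expect_true("targeted" %in% al2$training$provenance)
  expect_true("random_extra" %in% al2$training$provenance)
})

test_that("training bookkeeping reproduces the published sample arithmetic", {
  tc <- training_catalog()
  expect_equal(sum(tc$final), 2878L)
  expect_equal(sum(tc$initial), 2295L)
  expect_equal(nrow(tc), 7L)
  expect_equal(sum(tc$final - tc$initial), 583L)
  expect_true(all(tc$final >= tc$initial))
})
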