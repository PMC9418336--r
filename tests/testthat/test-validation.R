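test_that("sample size formula and allocation reproduce the design", {
  expect_equal(sample_size(rep(1 / 7, 7), 0.75, 0.01), 1875L)
  # independent of the weights when accuracies are equal
  expect_equal(sample_size(c(0.5, 0.2, 0.3), 0.75, 0.01), 1875L)
  expect_equal(sample_size(rep(0.25, 4), 0.5, 0.01), 2500L)
  # doubling the target SE quarters the sample
  expect_equal(sample_size(rep(0.25, 4), 0.5, 0.02), 625L)

  W <- c(0.4, 0.3, 0.2, 0.1)
  a <- allocate(1000, W, per_class_floor = 100)
  expect_equal(sum(a), 1000L)
  expect_true(all(a >= 100L))
  expect_equal(a, c(340L, 280L, 220L, 160L))
  # largest-remainder rounding still sums exactly
  W2 <- c(1, 1, 1) / 3
  a2 <- allocate(101, W2, per_class_floor = 30)
  expect_equal(sum(a2), 101L)
  expect_error(allocate(100, W, per_class_floor = 100), "cannot cover")
})

test_that("stratified validation draws respect the allocation", {
  map <- generate_class_map(96, 96, seed = 81)
  alloc <- c(20L, 15L, 15L, 20L, 20L, 10L, 5L)
  vs <- draw_validation_sample(map, alloc, seed = 82)
  got <- table(factor(vs$map_code, levels = 1:7))
  avail <- tabulate(map$values, 7)
  expect_equal(as.integer(got), pmin(alloc, avail))
  expect_identical(map$values[cbind(vs$row, vs$col)], vs$map_code)
  expect_false(anyDuplicated(vs[, c("row", "col")]) > 0)
  vs2 <- draw_validation_sample(map, alloc, seed = 82)
  expect_identical(vs, vs2)
  vs3 <- draw_validation_sample(map, alloc, labelable_rate = 0.9, seed = 83)
  expect_lt(abs(mean(vs3$labelable) - 0.9), 0.1)
})

test_that("counts and proportions ingestion agree algebraically", {
  set.seed(84)
  counts <- matrix(stats::rpois(16, 8) + 1, 4, 4) + diag(4) * 40
  W <- c(0.4, 0.3, 0.2, 0.1)
  from_counts <- error_matrix_from_counts(counts, W)
  from_props <- error_matrix_from_proportions(from_counts$p)
  expect_equal(from_props$oa, from_counts$oa, tolerance = 1e-12)
  expect_equal(from_props$ua, from_counts$ua, tolerance = 1e-12)
  expect_equal(from_props$pa, from_counts$pa, tolerance = 1e-12)
  expect_equal(from_props$area, from_counts$area, tolerance = 1e-12)
  # proportions mode carries no uncertainty
  expect_true(all(is.na(from_props$ua_se)))
  expect_false(anyNA(from_counts$ua_se))
})

test_that("degenerate matrices behave: identity, all-to-one, tiny strata", {
  p_id <- diag(5) / 5
  est <- error_matrix_from_proportions(p_id)
  expect_equal(est$oa, 1)
  expect_equal(est$ua, rep(1, 5))
  expect_equal(est$pa, rep(1, 5))

  est1 <- merge_classes(est, rep(1, 5))
  expect_equal(est1$oa, 1)

  counts <- matrix(c(5, 1, 0, 1, 2, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  em <- error_matrix_from_counts(counts, c(0.5, 0.3, 0.2))
  expect_equal(em$small_strata, 3L)
  expect_true(is.na(em$oa_se)) # a 1-sample stratum poisons the overall CI

  expect_error(error_matrix_from_proportions(diag(3) * 0.5), "tolerance")
})

test_that("merging never decreases overall accuracy and ignores order", {
  set.seed(85)
  for (rep in 1:20) {
    p <- matrix(stats::runif(49), 7, 7)
    p <- p / sum(p)
    est <- error_matrix_from_proportions(p)
    mapping <- sample(1:3, 7, replace = TRUE)
    mapping[1:3] <- 1:3 # keep all three groups populated
    merged <- merge_classes(est, mapping)
    expect_gte(merged$oa + 1e-12, est$oa)

    # estimators are invariant to class reordering
    perm <- sample(7)
    est_p <- error_matrix_from_proportions(p[perm, perm])
    expect_equal(sort(est_p$ua), sort(est$ua))
    expect_equal(est_p$oa, est$oa)
  }
})

test_that("counts-mode merging keeps design-based CIs coherent", {
  set.seed(86)
  counts <- matrix(stats::rpois(49, 3), 7, 7) + diag(7) * 30
  W <- default_class_mix()
  est <- error_matrix_from_counts(counts, W)
  merged <- merge_classes(est, c(1, 2, 3, 3, 3, 3, 3),
                          labels = c("active", "fallow", "noncrop"))
  expect_equal(merged$mode, "counts")
  expect_length(merged$ua, 3)
  expect_true(all(is.finite(merged$ua_se)))
  # identity grouping reproduces the original estimate
  same <- merge_classes(est, 1:7)
  expect_equal(same$oa, est$oa)
  expect_equal(same$ua_se, est$ua_se)
  # point estimates equal the cell-wise aggregation of the unmerged matrix
  expect_equal(merged$p[1, 1], est$p[1, 1])
  expect_equal(merged$p[3, 3], sum(est$p[3:7, 3:7]))
})

test_that("area CIs achieve close-to-nominal coverage", {
  # reduced-size coverage simulation: 4 strata, stratified counts drawn
  # from known per-stratum reference distributions, checking whether the
  # 95% interval for the area of class 1 covers the truth
  set.seed(87)
  W <- c(0.45, 0.3, 0.15, 0.1)
  Q <- rbind(c(0.85, 0.08, 0.05, 0.02),
             c(0.10, 0.80, 0.06, 0.04),
             c(0.05, 0.10, 0.85, 0.00),
             c(0.05, 0.05, 0.05, 0.85))
  true_area <- colSums(W * Q)
  n_i <- c(60, 55, 50, 45)
  hits <- logical(1000)
  for (r in seq_len(1000)) {
    counts <- t(vapply(1:4, function(i) {
      as.integer(stats::rmultinom(1, n_i[i], Q[i, ]))
    }, integer(4)))
    est <- error_matrix_from_counts(counts, W)
    lo <- est$area[1] - 1.96 * est$area_se[1]
    hi <- est$area[1] + 1.96 * est$area_se[1]
    hits[r] <- lo <= true_area[1] && true_area[1] <= hi
  }
  expect_lt(abs(mean(hits) - 0.95), 0.05)
})

test_that("a labelled sample from a map yields an unbiased area estimate", {
  map <- generate_class_map(128, 128, seed = 88)
  alloc <- allocate(700, class_shares(map)$share, per_class_floor = 60)
  vs <- draw_validation_sample(map, alloc, seed = 89)
  # reference equals the map itself -> perfect accuracy, exact areas
  vs$ref_code <- vs$map_code
  est <- error_matrix_from_sample(vs, map)
  expect_equal(est$oa, 1)
  expect_equal(est$area, class_shares(map)$share, tolerance = 1e-12)
})
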