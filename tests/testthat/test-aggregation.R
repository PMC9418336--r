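uniform_map <- function(code, nr = 64, nc = 64) {
  structure(list(values = matrix(as.integer(code), nr, nc),
                 pixel_size = 4.77, origin = c(0, 0),
                 catalog = class_catalog()),
            class = "class_map")
}

test_that("grid-cell fractions count pixels exactly", {
  gs <- gridcell_fractions(uniform_map(1), cell_px = 16)
  expect_true(all(gs$active == 1))
  expect_true(all(gs$cropland == 1))
  expect_true(all(gs$fallow == 0))
  expect_equal(nrow(gs), 16)

  # constructed cells with exactly 25% active cropland each
  v <- matrix(4L, 64, 64)
  v[1:32, ] <- rep(rep(c(1L, 4L, 4L, 4L), each = 8), 8) # 8-px stripes
  m <- uniform_map(4); m$values <- v
  gs2 <- gridcell_fractions(m, cell_px = 32)
  top <- gs2[gs2$cell_row == 1, ]
  expect_equal(top$active, rep(0.25, 2))

  # empty classes are zero everywhere; totals are conserved
  expect_true(all(gs2$short_fallow == 0))
  glob <- colSums(gs2[class_catalog()$class] * gs2$n_pixels) / sum(gs2$n_pixels)
  expect_equal(unname(glob), class_shares(m)$share)

  # partial edge cells use their actual pixel counts
  m3 <- uniform_map(2, 40, 50)
  gs3 <- gridcell_fractions(m3, cell_px = 32)
  expect_setequal(gs3$n_pixels, c(32 * 32, 32 * 18, 8 * 32, 8 * 18))
  expect_true(all(gs3$fallow == 1))
})

test_that("fallow share curve recovers a constructed monotone law", {
  set.seed(91)
  crop <- stats::runif(400, 0.05, 0.95)
  f_of_c <- 0.05 + 0.4 * crop^2 # monotone truth
  gs <- tibble::tibble(cropland = crop,
                       fallow_frac = pmin(1, f_of_c +
                                            stats::rnorm(400, 0, 0.01)))
  curve <- fallow_share_curve(gs, bins = 8)
  expect_true(all(diff(curve$median) > 0))
  expect_true(all(curve$q75 >= curve$q25))

  # order invariance and the single-bin degenerate case
  curve2 <- fallow_share_curve(gs[sample.int(400), ], bins = 8)
  expect_equal(curve, curve2)
  one <- fallow_share_curve(gs, bins = c(0, 1))
  expect_equal(nrow(one), 1)

  # cells with zero cropland are excluded
  gs_zero <- dplyr::bind_rows(gs, tibble::tibble(cropland = 0,
                                                 fallow_frac = NA_real_))
  expect_equal(fallow_share_curve(gs_zero, bins = 8), curve)
})

test_that("map-based fallow share underestimates under omission bias", {
  # map that systematically misses fallow (calls half of it woodland)
  truth_map <- generate_class_map(96, 96, seed = 92)
  biased <- truth_map
  fallow_pix <- which(truth_map$values == 2L)
  miss <- fallow_pix[seq_len(length(fallow_pix) %/% 2)]
  biased$values[miss] <- 4L
  # validation sample labelled against the truth reveals the bias
  alloc <- allocate(700, class_shares(biased)$share, per_class_floor = 40)
  vs <- draw_validation_sample(biased, alloc, seed = 93)
  vs$ref_code <- truth_map$values[cbind(vs$row, vs$col)]
  est <- error_matrix_from_sample(vs, biased)
  cmp <- fallow_share_comparison(biased, est)
  expect_lt(cmp$map_share, cmp$design_share)
})
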