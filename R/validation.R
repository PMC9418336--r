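#' Stratified sample size for a target overall-accuracy standard error
#'
#' `n = (sum_i W_i S_i / SE_target)^2` with `S_i = sqrt(UA_i (1 - UA_i))`,
#' rounded to the nearest integer. With equal assumed user's accuracies the
#' result is independent of the stratum weights; the conventional planning
#' values UA = 0.75 and SE = 1% give n = 1,875.
#'
#' @param W stratum (mapped-proportion) weights, summing to 1.
#' @param ua_assumed assumed user's accuracy per stratum (recycled).
#' @param se_target target standard error of overall accuracy.
#' @return integer sample size.
#' @export
#' @examples
#' sample_size(rep(1 / 7, 7)) # 1875
sample_size <- function(W, ua_assumed = 0.75, se_target = 0.01) {
  stopifnot(abs(sum(W) - 1) < 1e-3, se_target > 0)
  W <- W / sum(W)
  ua <- rep_len(ua_assumed, length(W))
  stopifnot(all(ua > 0 & ua < 1))
  s <- sqrt(ua * (1 - ua))
  as.integer(round((sum(W * s) / se_target)^2))
}

#' Allocate validation samples to strata
#'
#' Every stratum receives a fixed floor (default 200); the remainder is
#' distributed proportionally to the stratum weights with largest-remainder
#' rounding, so the allocation sums exactly to `n`.
#'
#' @param n total sample size.
#' @param W stratum weights, summing to 1.
#' @param per_class_floor minimum allocation per stratum.
#' @return integer vector of per-stratum allocations (named like `W`).
#' @export
allocate <- function(n, W, per_class_floor = 200) {
  k <- length(W)
  stopifnot(abs(sum(W) - 1) < 1e-3)
  W <- W / sum(W)
  if (n < k * per_class_floor) {
    stop(sprintf("n = %d cannot cover the per-class floor (%d x %d)",
                 n, k, per_class_floor))
  }
  remainder <- n - k * per_class_floor
  raw <- remainder * W / sum(W)
  extra <- floor(raw)
  left <- remainder - sum(extra)
  if (left > 0) {
    ord <- order(raw - extra, decreasing = TRUE)
    extra[ord[seq_len(left)]] <- extra[ord[seq_len(left)]] + 1
  }
  out <- as.integer(per_class_floor + extra)
  names(out) <- names(W)
  out
}

#' Draw a stratified random validation sample from a map
#'
#' Simple random sampling without replacement within each map stratum.
#' An optional labelable rate marks a seeded fraction of units as
#' unlabelable (response code `NA`); these are excluded from the error
#' matrix with the design weights unchanged.
#'
#' @param map a `class_map`.
#' @param allocation per-stratum sample sizes (length 7, by class code).
#' @param labelable_rate fraction of units that can be labelled (default 1).
#' @param seed integer seed.
#' @return tibble `x`, `y`, `row`, `col`, `map_code`, `labelable`.
#' @export
draw_validation_sample <- function(map, allocation, labelable_rate = 1,
                                   seed = 1L) {
  stopifnot(inherits(map, "class_map"), length(allocation) == 7)
  set.seed(seed)
  nr <- nrow(map$values); nc <- ncol(map$values)
  cc <- pixel_centers(nr, nc, map$pixel_size, map$origin)
  out <- list()
  for (cl in 1:7) {
    pix <- which(map$values == cl)
    ni <- min(allocation[cl], length(pix))
    if (ni == 0) next
    pick <- pix[sample.int(length(pix), ni)]
    r <- ((pick - 1L) %% nr) + 1L
    co <- ((pick - 1L) %/% nr) + 1L
    out[[cl]] <- tibble::tibble(
      x = cc$x[cbind(r, co)], y = cc$y[cbind(r, co)],
      row = r, col = co, map_code = cl)
  }
  res <- dplyr::bind_rows(out)
  res$labelable <- stats::runif(nrow(res)) <= labelable_rate
  res
}

# core design-based computation on counts with optional class grouping.
# counts: S x S integer matrix (map strata x reference classes),
# W: stratum weights; row_group/col_group: integer group id per class.
em_from_counts <- function(counts, W, row_group = NULL, col_group = NULL,
                           labels = NULL) {
  S <- nrow(counts)
  stopifnot(ncol(counts) == S, length(W) == S, abs(sum(W) - 1) < 1e-6)
  if (is.null(row_group)) row_group <- seq_len(S)
  if (is.null(col_group)) col_group <- row_group
  K <- max(row_group)
  stopifnot(max(col_group) == K)
  n_i <- rowSums(counts)
  frac <- counts / ifelse(n_i > 0, n_i, 1) # n_ij / n_i.
  p_full <- W * frac                        # S x S unbiased cell proportions

  # grouped proportion matrix (K x K)
  p <- matrix(0, K, K)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    p[row_group[i], col_group[j]] <- p[row_group[i], col_group[j]] + p_full[i, j]
  }

  W_g <- as.vector(tapply(W, row_group, sum))
  # per-stratum fraction of reference labels falling in group g (S x K)
  q <- matrix(0, S, K)
  for (j in seq_len(S)) q[, col_group[j]] <- q[, col_group[j]] + frac[, j]
  # fraction agreeing with own map group, per stratum
  a <- q[cbind(seq_len(S), row_group)]
  vfac <- ifelse(n_i > 1, 1 / (n_i - 1), NA_real_)

  oa <- sum(diag(p))
  v_oa <- sum(W^2 * a * (1 - a) * vfac)

  ua <- diag(p) / rowSums(p)
  v_ua <- vapply(seq_len(K), function(g) {
    i_in <- which(row_group == g)
    sum((W[i_in] / W_g[g])^2 * a[i_in] * (1 - a[i_in]) * vfac[i_in])
  }, numeric(1))

  area <- colSums(p)
  v_area <- vapply(seq_len(K), function(g) {
    sum(W^2 * q[, g] * (1 - q[, g]) * vfac)
  }, numeric(1))

  pa <- diag(p) / area
  # Taylor-linearised ratio variance; reduces to the standard
  # producer's-accuracy variance when each class is one stratum
  v_pa <- vapply(seq_len(K), function(g) {
    r <- pa[g]
    coef <- ifelse(row_group == g, (1 - r)^2, r^2)
    sum(W^2 * coef * q[, g] * (1 - q[, g]) * vfac) / area[g]^2
  }, numeric(1))

  if (is.null(labels)) labels <- as.character(seq_len(K))
  structure(
    list(mode = "counts", classes = labels, p = p,
         counts = counts, n_i = n_i, W = W,
         row_group = row_group, col_group = col_group,
         oa = oa, oa_se = sqrt(v_oa),
         ua = ua, ua_se = sqrt(v_ua),
         pa = pa, pa_se = sqrt(v_pa),
         area = area, area_se = sqrt(v_area),
         small_strata = which(n_i <= 1)),
    class = "error_matrix_estimate"
  )
}

#' Error matrix and accuracy/area estimators from stratified counts
#'
#' Builds the area-weighted error matrix `p_ij = W_i n_ij / n_i.` from raw
#' per-stratum counts and derives the design-based estimators: overall
#' accuracy (sum of the diagonal), user's accuracy (row-wise), producer's
#' accuracy (column-wise), error-adjusted area shares (column sums) and
#' their standard errors, with 95% confidence intervals as 1.96 SE. A
#' stratum with one or zero samples leaves the affected CIs undefined and
#' is flagged.
#'
#' @param counts square integer matrix: rows = map strata, columns =
#'   reference classes, `counts[i, j]` = validation units mapped as `i` and
#'   labelled `j`. An optional extra column named `"unlabelable"` is dropped
#'   (units without a reference label are excluded, design weights
#'   unchanged).
#' @param W mapped-proportion weights of the strata (sums to 1).
#' @param labels optional class labels.
#' @return an `error_matrix_estimate`.
#' @export
error_matrix_from_counts <- function(counts, W, labels = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(colnames(counts)) && "unlabelable" %in% colnames(counts)) {
    counts <- counts[, colnames(counts) != "unlabelable", drop = FALSE]
  }
  if (is.null(labels)) {
    labels <- rownames(counts)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(counts)))
  }
  em_from_counts(counts, W, labels = labels)
}

#' Error matrix estimators from printed area-weighted proportions
#'
#' Ingests a published probability-populated confusion matrix directly and
#' returns point estimates only (no CIs without counts). The cell sum may
#' deviate from 1 by up to `1e-3` (publication rounding); renormalisation is
#' off by default so printed figures reproduce as printed.
#'
#' @param p square matrix of area-weighted proportions (rows = map,
#'   columns = reference).
#' @param renormalise divide by the cell sum first (default FALSE).
#' @param labels optional class labels.
#' @return an `error_matrix_estimate` (mode `"proportions"`).
#' @export
error_matrix_from_proportions <- function(p, renormalise = FALSE,
                                          labels = NULL) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == ncol(p), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-3) {
    stop(sprintf("cell proportions sum to %.5f, outside the 1e-3 tolerance",
                 sum(p)))
  }
  if (renormalise) p <- p / sum(p)
  if (is.null(labels)) {
    labels <- rownames(p)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(p)))
  }
  K <- nrow(p)
  area <- colSums(p)
  structure(
    list(mode = "proportions", classes = labels, p = p,
         counts = NULL, n_i = NULL, W = rowSums(p),
         row_group = seq_len(K), col_group = seq_len(K),
         oa = sum(diag(p)), oa_se = NA_real_,
         ua = diag(p) / rowSums(p), ua_se = rep(NA_real_, K),
         pa = diag(p) / area, pa_se = rep(NA_real_, K),
         area = area, area_se = rep(NA_real_, K),
         small_strata = integer(0)),
    class = "error_matrix_estimate"
  )
}

#' Merge classes of an error-matrix estimate
#'
#' Cell-wise aggregation of the matrix under a class mapping (e.g. collapse
#' to active cropland / fallow / non-cropland). For counts mode all
#' estimators and their variances are recomputed on the grouped cells while
#' keeping the original strata, so CIs remain design-based.
#'
#' @param est an `error_matrix_estimate`.
#' @param mapping integer group index per original class (length = number
#'   of classes), or a list of class-index vectors.
#' @param labels optional labels for the merged classes.
#' @return an `error_matrix_estimate` over the merged classes.
#' @export
merge_classes <- function(est, mapping, labels = NULL) {
  stopifnot(inherits(est, "error_matrix_estimate"))
  K0 <- length(est$classes)
  if (is.list(mapping)) {
    g <- integer(K0)
    for (k in seq_along(mapping)) g[mapping[[k]]] <- k
    stopifnot(all(g > 0))
    mapping <- g
  }
  stopifnot(length(mapping) == K0)
  mapping <- as.integer(factor(mapping, levels = unique(mapping)))
  K <- max(mapping)
  if (is.null(labels)) {
    labels <- vapply(seq_len(K), function(k) {
      paste(est$classes[mapping == k], collapse = "+")
    }, character(1))
  }
  if (est$mode == "counts") {
    return(em_from_counts(est$counts, est$W, row_group = mapping,
                          col_group = mapping, labels = labels))
  }
  p <- matrix(0, K, K)
  for (i in seq_len(K0)) for (j in seq_len(K0)) {
    p[mapping[i], mapping[j]] <- p[mapping[i], mapping[j]] + est$p[i, j]
  }
  out <- error_matrix_from_proportions(p, labels = labels)
  out
}

#' @export
print.error_matrix_estimate <- function(x, ...) {
  cat(sprintf("<error_matrix_estimate> %d classes (%s mode)\n",
              length(x$classes), x$mode))
  cat(sprintf("  overall accuracy: %.1f%%", 100 * x$oa))
  if (is.finite(x$oa_se)) cat(sprintf(" (+/- %.1f%%)", 196 * x$oa_se))
  cat("\n")
  print(tidy(x), n = length(x$classes))
  invisible(x)
}

#' Tidy an error-matrix estimate
#'
#' One row per class with user's and producer's accuracy, error-adjusted
#' area share and 95% confidence half-widths (NA in proportions mode).
#'
#' @param x an `error_matrix_estimate`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.error_matrix_estimate <- function(x, ...) {
  tibble::tibble(
    class = x$classes,
    ua = x$ua, ua_ci = 1.96 * x$ua_se,
    pa = x$pa, pa_ci = 1.96 * x$pa_se,
    area = x$area, area_ci = 1.96 * x$area_se
  )
}

#' @rdname tidy.error_matrix_estimate
#' @export
glance.error_matrix_estimate <- function(x, ...) {
  tibble::tibble(
    oa = x$oa, oa_ci = 1.96 * x$oa_se,
    n = if (is.null(x$n_i)) NA_integer_ else sum(x$n_i),
    n_classes = length(x$classes), mode = x$mode
  )
}

#' Error-adjusted area report
#'
#' @param est an `error_matrix_estimate`.
#' @return tibble `class`, `area` (share of the study area), `ci95`
#'   (half-width; NA without counts). Shares sum to 1 up to the tolerance of
#'   the ingested matrix.
#' @export
area_report <- function(est) {
  stopifnot(inherits(est, "error_matrix_estimate"))
  tibble::tibble(class = est$classes, area = est$area,
                 ci95 = 1.96 * est$area_se)
}

#' Build an error matrix from a labelled validation sample
#'
#' Cross-tabulates map codes against reference codes and weights strata by
#' the map's class shares. Unlabelable units (`NA` reference code) are
#' excluded.
#'
#' @param samples tibble with `map_code` and `ref_code` columns.
#' @param map the classified `class_map` the sample was drawn from (its
#'   pixel shares provide the stratum weights), or a weight vector `W`.
#' @return an `error_matrix_estimate`.
#' @export
error_matrix_from_sample <- function(samples, map) {
  stopifnot(all(c("map_code", "ref_code") %in% names(samples)))
  W <- if (inherits(map, "class_map")) class_shares(map)$share else map
  keep <- W > 0
  samples <- samples[!is.na(samples$ref_code), ]
  counts <- table(factor(samples$map_code, levels = which(keep)),
                  factor(samples$ref_code, levels = which(keep)))
  em_from_counts(unclass(counts), W[keep] / sum(W[keep]),
                 labels = class_catalog()$class[keep])
}

#' Published error matrix of the reference cropland assessment
#'
#' The probability-populated 7-class confusion matrix of a published
#' 4.77 m cropland/fallow map of Northern Mozambique (2020/2021 cropping
#' season), shipped as plain text. Ingesting it with
#' [error_matrix_from_proportions()] reproduces the published accuracy and
#' area figures (overall accuracy 88.6%, active cropland area share 16.2%,
#' short-term fallow 6.6%, ...).
#'
#' @return 7 x 7 matrix of area-weighted proportions (rows = map,
#'   columns = reference) with class names.
#' @export
published_error_matrix <- function() {
  path <- system.file("extdata", "published_error_matrix_7class.csv",
                      package = "smallfield")
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
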