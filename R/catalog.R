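#' Land-cover class catalog
#'
#' The seven-class scheme used throughout the package: active cropland
#' (recently managed fields), short-term fallow (cropland last cultivated
#' within ~5 years), herbaceous vegetation, open woodland (10-75% woody
#' cover), closed woodland (>75%), unvegetated surfaces, and perennial
#' water. Class codes are stable integers 1-7; every map, sample and error
#' matrix in the package uses them.
#'
#' @return tibble with columns `code`, `class`, `label`.
#' @export
#' @examples
#' class_catalog()
class_catalog <- function() {
  tibble::tibble(
    code = 1:7,
    class = c("active_cropland", "short_fallow", "herbaceous",
              "open_woodland", "closed_woodland", "unvegetated", "water"),
    label = c("Active cropland", "Short-term fallow", "Herbaceous vegetation",
              "Open woodland", "Closed woodland", "Unvegetated", "Water")
  )
}

#' Training-sample bookkeeping of the published reference map
#'
#' Per-class training sample counts of the published regional cropland
#' assessment this package re-implements: the initial random sample, the
#' final sample after fallow-targeted and margin-targeted augmentation, and
#' the validation samples. Used as the reference for the active-learning
#' bookkeeping arithmetic (final counts must sum to 2,878 and initial counts
#' to 2,295).
#'
#' @return tibble with columns `code`, `class`, `initial`, `final`,
#'   `validation`.
#' @export
training_catalog <- function() {
  dplyr::mutate(
    class_catalog()[, c("code", "class")],
    initial = c(582L, 209L, 239L, 532L, 514L, 168L, 51L),
    final = c(677L, 301L, 370L, 650L, 601L, 226L, 53L),
    validation = c(325L, 232L, 245L, 383L, 336L, 213L, 206L)
  )
}
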