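#' Grid-cell cropland fractions
#'
#' Summarises a classified map as exact pixel-count fractions per grid
#' cell: share of active cropland, short-term fallow, total cropland
#' (active + fallow), and fallow fraction of total cropland (NA where a
#' cell has no cropland). Partial edge cells use their actual pixel counts,
#' so aggregation conserves the map totals.
#'
#' @param map a `class_map`.
#' @param cell_px cell size in pixels (the metre/degree cell size divided
#'   by the pixel size; e.g. a 0.1-degree cell is about 2332 px at 4.77 m).
#' @return a `grid_summary` tibble: `cell_row`, `cell_col`, `n_pixels`,
#'   `active`, `fallow`, `cropland`, `fallow_frac`, plus one share column
#'   per remaining class.
#' @export
gridcell_fractions <- function(map, cell_px = 32) {
  stopifnot(inherits(map, "class_map"), cell_px >= 1)
  v <- map$values
  nr <- nrow(v); nc <- ncol(v)
  cr <- ceiling(nr / cell_px); ccn <- ceiling(nc / cell_px)
  cell_row <- ((seq_len(nr) - 1L) %/% cell_px) + 1L
  cell_col <- ((seq_len(nc) - 1L) %/% cell_px) + 1L
  df <- tibble::tibble(
    cell_row = rep(cell_row, times = nc),
    cell_col = rep(cell_col, each = nr),
    code = as.vector(v)
  )
  out <- df |>
    dplyr::count(.data$cell_row, .data$cell_col, .data$code) |>
    tidyr::pivot_wider(names_from = "code", values_from = "n",
                       values_fill = 0L, names_prefix = "c")
  for (k in 1:7) {
    nm <- paste0("c", k)
    if (!nm %in% names(out)) out[[nm]] <- 0L
  }
  n_pixels <- rowSums(out[paste0("c", 1:7)])
  shares <- out[paste0("c", 1:7)] / n_pixels
  names(shares) <- class_catalog()$class
  res <- dplyr::bind_cols(out[c("cell_row", "cell_col")],
                          tibble::tibble(n_pixels = as.integer(n_pixels)),
                          shares)
  res$active <- res$active_cropland
  res$fallow <- res$short_fallow
  res$cropland <- res$active + res$fallow
  res$fallow_frac <- ifelse(res$cropland > 0, res$fallow / res$cropland,
                            NA_real_)
  class(res) <- c("grid_summary", class(res))
  attr(res, "cell_px") <- cell_px
  res
}

#' Fallow share versus cropland share curve
#'
#' Bins grid cells by their total-cropland share and summarises the fallow
#' fraction of cropland per bin (count, median, interquartile range).
#' Cells without cropland are excluded. The published pattern this
#' summarises: fallow fractions increase non-linearly with cropland
#' fraction, i.e. consolidated production regions carry relatively more
#' short-term fallow.
#'
#' @param summary a `grid_summary` from [gridcell_fractions()] (or any
#'   tibble with `cropland` and `fallow_frac` columns).
#' @param bins number of equal-width cropland-share bins, or a vector of
#'   break points on `[0, 1]`.
#' @return tibble `bin_mid`, `n`, `median`, `q25`, `q75` (one row per
#'   non-empty bin, ordered by bin).
#' @export
fallow_share_curve <- function(summary, bins = 10) {
  stopifnot(all(c("cropland", "fallow_frac") %in% names(summary)))
  df <- dplyr::filter(summary, .data$cropland > 0, !is.na(.data$fallow_frac))
  breaks <- if (length(bins) == 1) seq(0, 1, length.out = bins + 1) else bins
  df$bin <- cut(df$cropland, breaks, include.lowest = TRUE)
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$fallow_frac),
      q25 = unname(stats::quantile(.data$fallow_frac, 0.25)),
      q75 = unname(stats::quantile(.data$fallow_frac, 0.75)),
      .groups = "drop") |>
    dplyr::mutate(bin_mid = mids[as.integer(.data$bin)], .before = 1) |>
    dplyr::select(!"bin") |>
    dplyr::arrange(.data$bin_mid)
}

#' Map-based versus design-based fallow share
#'
#' Reports the fallow share of total cropland counted from map pixels next
#' to the error-adjusted (design-based) estimate. On maps whose fallow
#' class suffers omission error the map-based share underestimates the
#' design-based one.
#'
#' @param map a classified `class_map`.
#' @param est an `error_matrix_estimate` on the 7 classes.
#' @return one-row tibble `map_share`, `design_share`.
#' @export
fallow_share_comparison <- function(map, est) {
  sh <- class_shares(map)
  map_share <- sh$share[2] / (sh$share[1] + sh$share[2])
  design_share <- est$area[2] / (est$area[1] + est$area[2])
  tibble::tibble(map_share = map_share, design_share = design_share)
}
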