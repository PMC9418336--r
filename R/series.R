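#' Monthly multiband image series
#'
#' Container for a stack of monthly 4-band mosaics on one grid: a 4-D
#' reflectance array `[row, col, band, month]` with bands
#' `green`, `red`, `nir`, `extra`, a logical validity array
#' `[row, col, month]` (FALSE = cloud/invalid), and the acquisition month
#' index of each slice. Month indices run over the season year, 1 = first
#' month of the stack (September by convention) through 12 = August.
#'
#' @param bands numeric 4-D array `[row, col, 4, month]`.
#' @param valid logical 3-D array `[row, col, month]`; defaults to all valid.
#' @param months integer acquisition month index per slice (strictly
#'   increasing), default `1:dim(bands)[4]`.
#' @param pixel_size pixel size in metres.
#' @param origin (x, y) of the lower-left corner in metres.
#' @return a `monthly_series` object.
#' @export
monthly_series <- function(bands, valid = NULL, months = NULL,
                           pixel_size = 4.77, origin = c(0, 0)) {
  stopifnot(is.array(bands), length(dim(bands)) == 4, dim(bands)[3] == 4)
  d <- dim(bands)
  if (is.null(valid)) valid <- array(TRUE, d[c(1, 2, 4)])
  if (is.null(months)) months <- seq_len(d[4])
  stopifnot(all(dim(valid) == d[c(1, 2, 4)]), length(months) == d[4],
            !is.unsorted(months, strictly = TRUE))
  dimnames(bands)[[3]] <- c("green", "red", "nir", "extra")
  structure(
    list(bands = bands, valid = valid, months = as.integer(months),
         pixel_size = pixel_size, origin = as.numeric(origin)),
    class = "monthly_series"
  )
}

#' @export
print.monthly_series <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<monthly_series> %d x %d px, %d months @ %.2f m\n",
              d[1], d[2], d[4], x$pixel_size))
  cat(sprintf("  valid fraction: %.3f\n", mean(x$valid)))
  invisible(x)
}

#' @export
dim.monthly_series <- function(x) dim(x$bands)

#' Per-month NDVI from a monthly series
#'
#' NDVI = (NIR - red) / (NIR + red) per pixel and month; `NA` where the
#' validity mask is FALSE or the denominator is zero.
#'
#' @param series a `monthly_series`.
#' @return numeric 3-D array `[row, col, month]` in `[-1, 1]`.
#' @export
ndvi_series <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  nir <- series$bands[, , "nir", , drop = FALSE]
  red <- series$bands[, , "red", , drop = FALSE]
  d <- dim(series$bands)[c(1, 2, 4)]
  nir <- array(nir, d); red <- array(red, d)
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA_real_
  out[!series$valid] <- NA_real_
  out
}

# internal: pull one band of one month as a field_grid
series_band <- function(series, band, month_idx) {
  v <- series$bands[, , band, month_idx]
  v[!series$valid[, , month_idx]] <- NA_real_
  field_grid(v, series$pixel_size, series$origin,
             name = sprintf("%s_m%02d", band, series$months[month_idx]))
}

#' Season windows of the cropping year
#'
#' The three four-month windows the pipeline composites over, counted from
#' the first month of the stack (September): months 1-4 (Sep-Dec), 5-8
#' (Jan-Apr) and 9-12 (May-Aug).
#'
#' @return named list of integer month-index vectors.
#' @export
season_windows <- function() {
  list(sep_dec = 1:4, jan_apr = 5:8, may_aug = 9:12)
}
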