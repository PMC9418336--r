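#' Time-series noise of an NDVI sequence
#'
#' Quantifies multi-temporal consistency as the mean squared deviation of
#' each interior observation from the linear interpolation between its two
#' temporal neighbours:
#' \deqn{TSNoise = \frac{1}{N-2} \sum_{i=1}^{N-2}
#'   \left(y_{i+1} - \left[y_i + (y_{i+2} - y_i)
#'   \frac{month_{i+1} - month_i}{month_{i+2} - month_i}\right]\right)^2}
#' Unequal month spacing (missing observations) enters through the month
#' terms; masked months simply shrink the triplet set. The statistic is zero
#' iff every interior point lies exactly on the chord of its triplet, is
#' invariant to adding a constant, and scales as \eqn{a^2} when the series
#' is scaled by \eqn{a}. High values flag residual misregistration or cloud
#' contamination (or genuinely dynamic surfaces).
#'
#' @param y numeric NDVI observations (valid only).
#' @param months integer acquisition months, strictly increasing, same
#'   length as `y`.
#' @param root if TRUE return the square root (NDVI units instead of
#'   NDVI^2); reporting option, default FALSE.
#' @return non-negative scalar; `NA` when fewer than 3 observations.
#' @export
#' @examples
#' ts_noise(c(0.1, 0.2, 0.3), 1:3) # exactly linear -> 0
#' ts_noise(c(0, 1, 0), 1:3)       # -> 1
ts_noise <- function(y, months = seq_along(y), root = FALSE) {
  keep <- is.finite(y)
  y <- y[keep]; months <- months[keep]
  n <- length(y)
  if (n < 3) return(NA_real_)
  stopifnot(length(months) == n, !is.unsorted(months, strictly = TRUE))
  i <- seq_len(n - 2)
  interp <- y[i] + (y[i + 2] - y[i]) *
    (months[i + 1] - months[i]) / (months[i + 2] - months[i])
  val <- sum((y[i + 1] - interp)^2) / (n - 2)
  if (root) sqrt(val) else val
}

#' Per-pixel time-series noise map
#'
#' Applies [ts_noise()] to the NDVI series of every pixel, using valid
#' months only. Pixels with fewer than 3 valid observations are undefined
#' (`NA`).
#'
#' @param series a `monthly_series`.
#' @param root report the square-root variant (NDVI units).
#' @return a `field_grid` named `"tsnoise"`.
#' @export
noise_map <- function(series, root = FALSE) {
  stopifnot(inherits(series, "monthly_series"))
  nd <- ndvi_series(series)
  d <- dim(nd)
  months <- series$months
  npix <- d[1] * d[2]
  ymat <- matrix(nd, npix, d[3])
  out <- vapply(seq_len(npix), function(p) {
    yy <- ymat[p, ]
    ok <- is.finite(yy)
    if (sum(ok) < 3) return(NA_real_)
    ts_noise(yy[ok], months[ok], root = root)
  }, numeric(1))
  field_grid(matrix(out, d[1], d[2]), series$pixel_size, series$origin,
             name = if (root) "tsnoise_root" else "tsnoise")
}

#' Summarise a noise map as a density table
#'
#' @param nm a `field_grid` from [noise_map()].
#' @param breaks histogram breaks (passed to [hist()]); default 50 bins.
#' @return tibble with `mid`, `count`, `density` per bin.
#' @export
noise_density <- function(nm, breaks = 50) {
  v <- nm$values[is.finite(nm$values)]
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  tibble::tibble(mid = h$mids, count = h$counts, density = h$density)
}
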