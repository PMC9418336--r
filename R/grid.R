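#' Lightweight raster grid
#'
#' A `field_grid` is a numeric matrix with a nominal pixel size (metres) and
#' an origin offset, the minimal raster container the pipeline needs. Rows run
#' north to south (row 1 is the northern edge), columns west to east, so
#' `values[r, c]` is the pixel in row `r` from the top. All geometry is in
#' pixel units; the pixel size and origin are carried as metadata only.
#'
#' @param values numeric matrix of cell values.
#' @param pixel_size pixel edge length in metres (default 4.77 m, the nominal
#'   resolution of the monthly mosaics the pipeline targets).
#' @param origin numeric length-2, (x, y) map coordinate of the grid's
#'   lower-left corner in metres.
#' @param name optional layer name.
#' @return a `field_grid` object.
#' @export
field_grid <- function(values, pixel_size = 4.77, origin = c(0, 0), name = NULL) {
  stopifnot(is.matrix(values), is.numeric(pixel_size), pixel_size > 0,
            length(origin) == 2)
  structure(
    list(values = values, pixel_size = pixel_size,
         origin = as.numeric(origin), name = name),
    class = "field_grid"
  )
}

#' @export
dim.field_grid <- function(x) dim(x$values)

#' @export
print.field_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<field_grid%s> %d x %d pixels @ %.2f m\n",
              if (is.null(x$name)) "" else paste0(": ", x$name),
              d[1], d[2], x$pixel_size))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values in [%.4g, %.4g], %d NA\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Pixel-centre coordinates of a grid
#'
#' Returns matrices of x (easting) and y (northing) pixel-centre coordinates
#' following the pixel-centre convention: pixel (1, 1) is the north-west
#' corner cell and its centre sits half a pixel in from the grid edge.
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param pixel_size pixel size in metres.
#' @param origin (x, y) of the lower-left grid corner.
#' @return list with matrices `x` and `y` (metres).
#' @export
pixel_centers <- function(nrow, ncol, pixel_size = 4.77, origin = c(0, 0)) {
  x <- origin[1] + (seq_len(ncol) - 0.5) * pixel_size
  y <- origin[2] + (nrow - seq_len(nrow) + 0.5) * pixel_size
  list(x = matrix(x, nrow, ncol, byrow = TRUE),
       y = matrix(y, nrow, ncol, byrow = FALSE))
}

#' Convert a grid to a tibble of pixels
#'
#' @param x a `field_grid`.
#' @param ... unused.
#' @return tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
as_tibble.field_grid <- function(x, ...) {
  d <- dim(x$values)
  cc <- pixel_centers(d[1], d[2], x$pixel_size, x$origin)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    x = as.vector(cc$x), y = as.vector(cc$y),
    value = as.vector(x$values)
  )
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format used for all on-disk rasters (one band
#' per file). `NA` is written as the `NODATA_value`.
#'
#' @param grid a `field_grid`.
#' @param path file path (conventionally `.asc`).
#' @param nodata value standing in for `NA` on disk.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a `field_grid`.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "field_grid"))
  v <- grid$values
  v[is.na(v)] <- nodata
  d <- dim(v)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2]),
    sprintf("cellsize %.6f", grid$pixel_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  ncols <- val(1); nrows <- val(2)
  xll <- val(3); yll <- val(4); cs <- val(5); nodata <- val(6)
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  v <- matrix(as.numeric(unlist(body)), nrow = nrows, ncol = ncols, byrow = TRUE)
  v[v == nodata] <- NA_real_
  field_grid(v, pixel_size = cs, origin = c(xll, yll))
}

# internal: bilinear sample of matrix `m` at fractional (row, col) positions.
# Positions outside the grid return NA. Vectorised over positions.
bilinear_sample <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # exact grid lines at the far edge still valid
  edge <- (r0 == nr & fr == 0 & c0 >= 1 & c0 + 1 <= nc) |
    (c0 == nc & fc == 0 & r0 >= 1 & r0 + 1 <= nr) |
    (r0 == nr & fr == 0 & c0 == nc & fc == 0)
  out <- rep(NA_real_, length(row))
  idx <- which(ok)
  if (length(idx)) {
    i0 <- cbind(r0[idx], c0[idx])
    v00 <- m[i0]
    v01 <- m[cbind(r0[idx], c0[idx] + 1)]
    v10 <- m[cbind(r0[idx] + 1, c0[idx])]
    v11 <- m[cbind(r0[idx] + 1, c0[idx] + 1)]
    out[idx] <- v00 * (1 - fr[idx]) * (1 - fc[idx]) +
      v01 * (1 - fr[idx]) * fc[idx] +
      v10 * fr[idx] * (1 - fc[idx]) +
      v11 * fr[idx] * fc[idx]
  }
  idx2 <- which(!ok & edge)
  if (length(idx2)) {
    rr <- pmin(r0[idx2], nr); cc <- pmin(c0[idx2], nc)
    out[idx2] <- m[cbind(rr, cc)]
  }
  out
}

# internal: nearest-neighbour sample, NA outside
nearest_sample <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  r <- round(row); c <- round(col)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  out <- rep(m[1][NA], length(row))
  out[ok] <- m[cbind(r[ok], c[ok])]
  out
}
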