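#' Seasonal percentile metrics
#'
#' Per 4-month season window, per-pixel median (P50) of the green, red and
#' NIR bands and P50 plus 75th percentile (P75) of NDVI, computed over valid
#' observations only (15 layers in total). Percentiles use linear
#' interpolation between order statistics (R quantile type 7). Pixels with
#' no valid observation in a window are `NA`.
#'
#' @param series a `monthly_series`.
#' @param windows named list of three 4-month windows
#'   (default [season_windows()]).
#' @return named list of matrices, names `s<season>_<band>_p<q>`.
#' @export
seasonal_metrics <- function(series, windows = season_windows()) {
  stopifnot(inherits(series, "monthly_series"))
  d <- dim(series$bands)
  npix <- d[1] * d[2]
  nd <- ndvi_series(series)
  out <- list()
  for (k in seq_along(windows)) {
    sl <- which(series$months %in% windows[[k]])
    stopifnot(length(sl) >= 1)
    vmask <- matrix(series$valid[, , sl], npix, length(sl))
    for (band in c("green", "red", "nir")) {
      m <- matrix(series$bands[, , band, sl], npix, length(sl))
      m[!vmask] <- NA_real_
      out[[sprintf("s%d_%s_p50", k, band)]] <-
        matrix(row_quantile(m, 0.5), d[1], d[2])
    }
    m <- matrix(nd[, , sl], npix, length(sl))
    out[[sprintf("s%d_ndvi_p50", k)]] <- matrix(row_quantile(m, 0.5), d[1], d[2])
    out[[sprintf("s%d_ndvi_p75", k)]] <- matrix(row_quantile(m, 0.75), d[1], d[2])
  }
  out
}

# row-wise type-7 quantile with NA removal; rows with no finite value -> NA
row_quantile <- function(m, p) {
  nv <- rowSums(is.finite(m))
  srt <- t(apply(m, 1, sort, na.last = TRUE)) # finite values first, ascending
  out <- rep(NA_real_, nrow(m))
  for (n in unique(nv[nv > 0])) {
    rows <- which(nv == n)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    out[rows] <- srt[rows, lo] + (h - lo) * (srt[rows, hi] - srt[rows, lo])
  }
  out
}

#' Texture index: focal median in a radial kernel
#'
#' Median of a seasonal NDVI composite within a circular kernel of the
#' given metre radius (pixel centres within the radius; truncated at scene
#' edges). Kernel radii of 25, 100 and 200 m bracket the field-size
#' distribution of fragmented smallholder landscapes.
#'
#' @param p50_ndvi a `field_grid` (or matrix) of seasonal NDVI P50.
#' @param radius_m kernel radius in metres (must be >= the pixel size to
#'   have any effect; below it the input is returned unchanged).
#' @param pixel_size pixel size in metres (taken from the grid if present).
#' @return object of the same type as the input.
#' @export
texture_index <- function(p50_ndvi, radius_m, pixel_size = NULL) {
  g <- inherits(p50_ndvi, "field_grid")
  m <- if (g) p50_ndvi$values else p50_ndvi
  if (is.null(pixel_size)) {
    pixel_size <- if (g) p50_ndvi$pixel_size else 4.77
  }
  radius_px <- radius_m / pixel_size
  out_m <- if (radius_px < 1) m else sf_focal_median(m, radius_px)
  if (g) {
    out <- p50_ndvi
    out$values <- out_m
    out$name <- sprintf("ti_r%.0fm", radius_m)
    out
  } else {
    out_m
  }
}

#' Contrast index
#'
#' Normalised difference between a pixel's seasonal NDVI P50 and its kernel
#' median (texture index): `CI = (P50 - TI) / (P50 + TI)`. Bounded in
#' `[-1, 1]` for non-negative inputs; zero wherever the pixel equals its
#' neighbourhood median; pixels with a zero denominator are set to 0 by
#' convention. CI highlights fields against their surroundings.
#'
#' @param p50_ndvi,ti `field_grid`s or matrices on the same grid.
#' @return same type as `p50_ndvi`.
#' @export
contrast_index <- function(p50_ndvi, ti) {
  g <- inherits(p50_ndvi, "field_grid")
  a <- if (g) p50_ndvi$values else p50_ndvi
  b <- if (inherits(ti, "field_grid")) ti$values else ti
  stopifnot(all(dim(a) == dim(b)))
  den <- a + b
  out_m <- (a - b) / den
  out_m[abs(den) < 1e-12] <- 0
  if (g) {
    out <- p50_ndvi; out$values <- out_m; out$name <- "ci"
    out
  } else {
    out_m
  }
}

#' Terrain features: elevation and slope
#'
#' Slope in degrees from central differences on the DEM (one-sided at
#' edges): `atan(sqrt((dz/dx)^2 + (dz/dy)^2))`.
#'
#' @param dem a `field_grid` of elevations (metres).
#' @return list with matrices `elevation` and `slope` (degrees).
#' @export
terrain_features <- function(dem) {
  stopifnot(inherits(dem, "field_grid"))
  z <- dem$values
  px <- dem$pixel_size
  nr <- nrow(z); nc <- ncol(z)
  dzdx <- matrix(0, nr, nc)
  dzdx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * px)
  dzdx[, 1] <- (z[, 2] - z[, 1]) / px
  dzdx[, nc] <- (z[, nc] - z[, nc - 1]) / px
  dzdy <- matrix(0, nr, nc)
  dzdy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / (2 * px)
  dzdy[1, ] <- (z[2, ] - z[1, ]) / px
  dzdy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / px
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  list(elevation = z, slope = slope)
}

#' Coordinate features
#'
#' Per-pixel centre coordinates as feature layers (longitude = easting x,
#' latitude = northing y; metre offsets in the synthetic world, geographic
#' coordinates pass through unchanged on real grids).
#'
#' @param nrow,ncol grid dimensions.
#' @param pixel_size pixel size in metres.
#' @param origin (x, y) of the lower-left corner.
#' @return list with matrices `latitude` and `longitude`.
#' @export
coordinate_features <- function(nrow, ncol, pixel_size = 4.77, origin = c(0, 0)) {
  cc <- pixel_centers(nrow, ncol, pixel_size, origin)
  list(latitude = cc$y, longitude = cc$x)
}

#' Assemble the classification feature stack
#'
#' Builds the full default stack of 31 named layers: 15 seasonal percentile
#' metrics, texture indices (focal NDVI-P50 medians at 25/100/200 m) for
#' the first and third season, the matching 6 contrast indices, elevation,
#' slope, latitude and longitude. Layer order is fixed and recorded in the
#' manifest; no silent reordering.
#'
#' @param series a `monthly_series` (coregistered in the full pipeline).
#' @param dem a `field_grid` DEM on the same grid.
#' @param windows season windows.
#' @param kernel_radii_m texture kernel radii in metres.
#' @param texture_seasons season indices the texture/contrast layers use
#'   (default first and third).
#' @return a `feature_stack`: named list `layers` of matrices plus a
#'   `manifest` tibble (`layer`, `group`, `season`, `radius_m`).
#' @export
assemble_stack <- function(series, dem, windows = season_windows(),
                           kernel_radii_m = c(25, 100, 200),
                           texture_seasons = c(1, 3)) {
  stopifnot(inherits(series, "monthly_series"))
  layers <- seasonal_metrics(series, windows)
  manifest <- tibble::tibble(
    layer = names(layers), group = "seasonal",
    season = as.integer(substr(names(layers), 2, 2)), radius_m = NA_real_
  )
  px <- series$pixel_size
  ti_layers <- list(); ci_layers <- list()
  for (s in texture_seasons) {
    p50 <- layers[[sprintf("s%d_ndvi_p50", s)]]
    for (r in kernel_radii_m) {
      ti <- texture_index(p50, r, pixel_size = px)
      ti_layers[[sprintf("ti_s%d_r%03.0f", s, r)]] <- ti
      ci_layers[[sprintf("ci_s%d_r%03.0f", s, r)]] <- contrast_index(p50, ti)
    }
  }
  manifest <- dplyr::bind_rows(
    manifest,
    tibble::tibble(layer = names(ti_layers), group = "texture",
                   season = rep(as.integer(texture_seasons),
                                each = length(kernel_radii_m)),
                   radius_m = rep(kernel_radii_m, length(texture_seasons))),
    tibble::tibble(layer = names(ci_layers), group = "contrast",
                   season = rep(as.integer(texture_seasons),
                                each = length(kernel_radii_m)),
                   radius_m = rep(kernel_radii_m, length(texture_seasons)))
  )
  terr <- terrain_features(dem)
  coords <- coordinate_features(nrow(dem$values), ncol(dem$values),
                                px, series$origin)
  layers <- c(layers, ti_layers, ci_layers,
              list(elevation = terr$elevation, slope = terr$slope,
                   latitude = coords$latitude, longitude = coords$longitude))
  manifest <- dplyr::bind_rows(
    manifest,
    tibble::tibble(layer = c("elevation", "slope", "latitude", "longitude"),
                   group = c("terrain", "terrain", "coordinate", "coordinate"),
                   season = NA_integer_, radius_m = NA_real_)
  )
  stopifnot(!anyDuplicated(names(layers)))
  structure(list(layers = layers, pixel_size = px, origin = series$origin,
                 manifest = manifest),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<feature_stack> %d layers, %d x %d px @ %.2f m\n",
              length(x$layers), d[1], d[2], x$pixel_size))
  print(x$manifest, n = 5)
  invisible(x)
}

#' Flatten a feature stack to a pixel-by-layer matrix
#'
#' Column-major pixel order (pixel index = (col-1) * nrow + row), one column
#' per layer in manifest order.
#'
#' @param stack a `feature_stack`.
#' @return numeric matrix, `npixels x nlayers`, with layer column names.
#' @export
stack_matrix <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"))
  do.call(cbind, lapply(stack$layers, as.vector))
}

#' Extract feature values at sample points
#'
#' Reads the raster value of the containing pixel (no interpolation) for
#' each sample and appends one column per layer.
#'
#' @param samples tibble with `row`, `col` columns (e.g. from
#'   [sample_reference_points()]).
#' @param stack a `feature_stack`.
#' @return `samples` with the feature columns appended.
#' @export
extract_features <- function(samples, stack) {
  stopifnot(inherits(stack, "feature_stack"),
            all(c("row", "col") %in% names(samples)))
  idx <- cbind(samples$row, samples$col)
  feat <- lapply(stack$layers, function(l) l[idx])
  dplyr::bind_cols(samples, tibble::as_tibble(feat))
}

#' Write a feature stack to disk
#'
#' One ASCII grid per layer plus a JSON manifest.
#'
#' @param stack a `feature_stack`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_ascii_grid(field_grid(stack$layers[[nm]], stack$pixel_size,
                                stack$origin, name = nm),
                     file.path(dir, paste0(nm, ".asc")))
  }
  jsonlite::write_json(stack$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
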