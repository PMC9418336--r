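#' Per-pixel displacement field
#'
#' A pair of offset matrices in pixel units. `dx` is the offset toward
#' increasing column index (east), `dy` toward increasing row index (south).
#' Applying a field samples the source image at `(row + dy, col + dx)`, so a
#' field estimated against a reference maps the target back onto the
#' reference geometry.
#'
#' @param dx,dy numeric matrices of offsets (pixels), equal dimensions.
#' @param pixel_size pixel size in metres.
#' @param max_offset_m optional maximum offset (metres) the field was
#'   clamped to; offsets are checked against it when given.
#' @return a `displacement_field`.
#' @export
displacement_field <- function(dx, dy, pixel_size = 4.77, max_offset_m = NULL) {
  stopifnot(is.matrix(dx), is.matrix(dy), all(dim(dx) == dim(dy)),
            all(is.finite(dx)), all(is.finite(dy)))
  if (!is.null(max_offset_m)) {
    mag_m <- sqrt(dx^2 + dy^2) * pixel_size
    stopifnot(all(mag_m <= max_offset_m + 1e-9))
  }
  structure(list(dx = dx, dy = dy, pixel_size = pixel_size,
                 max_offset_m = max_offset_m),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<displacement_field> %d x %d px; |d| mean %.3f px, max %.3f px\n",
              nrow(x$dx), ncol(x$dx), mean(mag), max(mag)))
  invisible(x)
}

#' Coregistration configuration
#'
#' @param max_offset_m maximum allowed offset in metres (offsets are clamped
#'   to this magnitude).
#' @param stiffness smoothing strength of the block displacement field;
#'   mapped to the sigma of a Gaussian smoother, `sigma = stiffness / 2`
#'   block units, so higher stiffness means a smoother (stiffer) field.
#' @param levels pyramid levels; the global-shift search runs at a
#'   `2^(levels - 1)`-fold downsampling and is refined level by level.
#' @param block_px block size (pixels) of the fine-scale matching stage.
#' @param search_px local search radius (pixels) of each block around the
#'   propagated global shift.
#' @param min_corr blocks whose correlation peak falls below this are
#'   treated as uninformative and inherit the smoothed neighbourhood field.
#' @param tile_px,buffer_px optional tile size and buffer (pixels) for tiled
#'   processing of large scenes; the buffer must cover the maximum offset so
#'   clamped offsets never read outside the buffered tile.
#' @param pixel_size pixel size in metres.
#' @return a `coreg_config` list.
#' @export
coreg_config <- function(max_offset_m = 100, stiffness = 5, levels = 3,
                         block_px = 64, search_px = 6, min_corr = 0.3,
                         tile_px = NULL, buffer_px = NULL, pixel_size = 4.77) {
  stopifnot(max_offset_m > 0, levels >= 1, block_px >= 8, search_px >= 1)
  max_off_px <- max_offset_m / pixel_size
  if (!is.null(tile_px)) {
    if (is.null(buffer_px)) buffer_px <- ceiling(max_off_px) + search_px
    stopifnot(buffer_px >= ceiling(max_off_px))
  }
  structure(list(max_offset_m = max_offset_m, stiffness = stiffness,
                 levels = levels, block_px = block_px, search_px = search_px,
                 min_corr = min_corr, tile_px = tile_px,
                 buffer_px = buffer_px, pixel_size = pixel_size),
            class = "coreg_config")
}

#' Seasonal reference composites
#'
#' Per-pixel median of the valid NIR observations inside each 4-month
#' season window. Compositing over a season damps both phenology and the
#' month-to-month geometric jitter, which is what makes the composite usable
#' as a matching reference. Pixels with zero valid observations are flagged
#' undefined (`NA`) rather than raising an error.
#'
#' @param series a `monthly_series`.
#' @param windows named list of month-index vectors partitioning the stack
#'   into three 4-month blocks (default [season_windows()]).
#' @return a `seasonal_reference`: per season a list with `composite`
#'   (`field_grid`, NA where undefined) and `count` (valid observations per
#'   pixel).
#' @export
build_seasonal_reference <- function(series, windows = season_windows()) {
  stopifnot(inherits(series, "monthly_series"))
  months <- series$months
  idx <- lapply(windows, function(w) which(months %in% w))
  if (length(windows) && sum(lengths(idx)) != length(months)) {
    stop("season windows must partition the months of the series")
  }
  out <- lapply(seq_along(windows), function(k) {
    sl <- idx[[k]]
    nir <- series$bands[, , "nir", sl, drop = FALSE]
    d <- dim(series$bands)[1:2]
    nir <- array(nir, c(d, length(sl)))
    v <- series$valid[, , sl, drop = FALSE]
    nir[!v] <- NA_real_
    comp <- apply(nir, c(1, 2), stats::median, na.rm = TRUE)
    comp[is.nan(comp)] <- NA_real_
    count <- apply(v, c(1, 2), sum)
    list(composite = field_grid(comp, series$pixel_size, series$origin,
                                name = names(windows)[k]),
         count = count, months = windows[[k]])
  })
  names(out) <- names(windows)
  structure(out, class = "seasonal_reference")
}

# correlation of block `a` against window `b` over all integer lags
# (-s..s)^2; b has the same dims as a padded by s on every side. NA pairs
# are dropped pairwise; returns (2s+1) x (2s+1) matrix of correlations
# (rows = dy, cols = dx).
lag_correlation <- function(a, b, s) {
  na <- nrow(a); ca <- ncol(a)
  out <- matrix(NA_real_, 2 * s + 1, 2 * s + 1)
  av <- as.vector(a)
  for (dy in -s:s) {
    for (dx in -s:s) {
      sub <- b[(1 + s + dy):(s + dy + na), (1 + s + dx):(s + dx + ca)]
      bv <- as.vector(sub)
      ok <- is.finite(av) & is.finite(bv)
      if (sum(ok) >= 30 && stats::sd(av[ok]) > 0 && stats::sd(bv[ok]) > 0) {
        out[dy + s + 1, dx + s + 1] <- stats::cor(av[ok], bv[ok])
      }
    }
  }
  out
}

# quadratic sub-pixel refinement along one axis of a correlation surface
subpixel_offset <- function(cm1, c0, cp1) {
  den <- cm1 - 2 * c0 + cp1
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (cm1 - cp1) / den
  max(-0.5, min(0.5, off))
}

# block-mean downsampling by integer factor f (NA-aware)
downsample_mean <- function(m, f) {
  if (f <= 1) return(m)
  nr <- floor(nrow(m) / f) * f
  nc <- floor(ncol(m) / f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(m, c(f, nr / f, f, nc / f))
  apply(a, c(2, 4), function(x) {
    x <- x[is.finite(x)]
    if (length(x)) mean(x) else NA_real_
  })
}

# Gaussian smoothing with NA-aware normalised convolution, optional weights
gaussian_smooth <- function(m, sigma, w = NULL) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k1 <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(k1, k1)
  if (is.null(w)) w <- matrix(1, nrow(m), ncol(m))
  w2 <- w; w2[!is.finite(m)] <- 0
  m2 <- m; m2[!is.finite(m)] <- 0
  nr <- nrow(m); nc <- ncol(m)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (i in -r:r) {
    if (max(1, 1 - i) > min(nr, nr - i)) next
    rs <- max(1, 1 - i):min(nr, nr - i)
    rt <- rs + i
    for (j in -r:r) {
      if (max(1, 1 - j) > min(nc, nc - j)) next
      cs <- max(1, 1 - j):min(nc, nc - j)
      ct <- cs + j
      kk <- k[i + r + 1, j + r + 1]
      num[rs, cs] <- num[rs, cs] + kk * (m2[rt, ct] * w2[rt, ct])
      den[rs, cs] <- den[rs, cs] + kk * w2[rt, ct]
    }
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Estimate a displacement field by block cross-correlation
#'
#' Multi-scale "rubber-sheeting": a global integer shift is found by
#' normalised cross-correlation at the coarsest pyramid level and refined
#' level by level; at full resolution each block searches a small radius
#' around the propagated shift, with quadratic sub-pixel refinement of the
#' correlation peak. Blocks whose peak correlation falls below
#' `cfg$min_corr` get zero weight and inherit the Gaussian-smoothed
#' neighbourhood estimate (smoothing sigma = stiffness/2 block units).
#' Offsets are clamped to `cfg$max_offset_m`.
#'
#' @param target single-band `field_grid` (or matrix) to be matched.
#' @param reference `field_grid`/matrix on the same grid (a seasonal
#'   composite in the pipeline); undefined pixels may be `NA`.
#' @param cfg a [coreg_config()].
#' @return a `displacement_field` such that applying it to `target`
#'   reproduces the reference geometry; attribute `"confidence"` holds the
#'   mean block peak correlation.
#' @export
estimate_displacement <- function(target, reference, cfg = coreg_config()) {
  t_m <- if (inherits(target, "field_grid")) target$values else target
  r_m <- if (inherits(reference, "field_grid")) reference$values else reference
  stopifnot(all(dim(t_m) == dim(r_m)))
  nr <- nrow(t_m); nc <- ncol(t_m)
  px <- cfg$pixel_size
  max_off_px <- cfg$max_offset_m / px
  overlap <- mean(is.finite(t_m) & is.finite(r_m))
  if (overlap < 0.25) stop("defined-pixel overlap below 25%")
  zero_field <- function(conf = 0) {
    f <- displacement_field(matrix(0, nr, nc), matrix(0, nr, nc),
                            pixel_size = px, max_offset_m = cfg$max_offset_m)
    attr(f, "confidence") <- conf
    f
  }
  if (stats::sd(t_m[is.finite(t_m)]) < 1e-10 ||
      stats::sd(r_m[is.finite(r_m)]) < 1e-10) {
    warning("near-constant image: returning zero displacement (low confidence)")
    return(zero_field())
  }

  # coarse-to-fine global shift
  gdx <- 0; gdy <- 0
  for (lev in seq(cfg$levels, 1)) {
    f <- 2^(lev - 1)
    td <- downsample_mean(t_m, f); rd <- downsample_mean(r_m, f)
    s <- if (lev == cfg$levels) {
      min(ceiling(max_off_px / f), floor(min(dim(td)) / 3))
    } else 2L
    s <- max(s, 1L)
    pad <- matrix(NA_real_, nrow(td) + 2 * s, ncol(td) + 2 * s)
    # window centred on current estimate
    cdy <- round(gdy / f); cdx <- round(gdx / f)
    src_r <- seq_len(nrow(td)) + cdy; src_c <- seq_len(ncol(td)) + cdx
    ok_r <- src_r >= 1 & src_r <= nrow(td); ok_c <- src_c >= 1 & src_c <= ncol(td)
    pad[s + which(ok_r), s + which(ok_c)] <- td[src_r[ok_r], src_c[ok_c]]
    cm <- lag_correlation(rd, pad, s)
    if (all(!is.finite(cm))) next
    pk <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    gdy <- (cdy + (pk[1] - s - 1)) * f
    gdx <- (cdx + (pk[2] - s - 1)) * f
  }

  # block stage at full resolution
  bs <- min(cfg$block_px, nr, nc)
  s <- cfg$search_px
  br <- seq(1, nr - bs + 1, by = bs)
  bc <- seq(1, nc - bs + 1, by = bs)
  nbr <- length(br); nbc <- length(bc)
  BDX <- matrix(NA_real_, nbr, nbc); BDY <- matrix(NA_real_, nbr, nbc)
  WGT <- matrix(0, nbr, nbc)
  pad_t <- matrix(NA_real_, nr + 2 * s, nc + 2 * s)
  src_r <- seq_len(nr) + round(gdy); src_c <- seq_len(nc) + round(gdx)
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  pad_t[s + which(ok_r), s + which(ok_c)] <- t_m[src_r[ok_r], src_c[ok_c]]
  for (i in seq_len(nbr)) {
    for (j in seq_len(nbc)) {
      rb <- br[i]:(br[i] + bs - 1); cb <- bc[j]:(bc[j] + bs - 1)
      B <- r_m[rb, cb]
      W <- pad_t[rb[1]:(rb[bs] + 2 * s), cb[1]:(cb[bs] + 2 * s)]
      cm <- lag_correlation(B, W, s)
      if (all(!is.finite(cm))) next
      pk <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
      peak <- cm[pk[1], pk[2]]
      dy0 <- pk[1] - s - 1; dx0 <- pk[2] - s - 1
      sub_y <- sub_x <- 0
      if (pk[1] > 1 && pk[1] < 2 * s + 1 &&
          all(is.finite(cm[(pk[1] - 1):(pk[1] + 1), pk[2]]))) {
        sub_y <- subpixel_offset(cm[pk[1] - 1, pk[2]], peak, cm[pk[1] + 1, pk[2]])
      }
      if (pk[2] > 1 && pk[2] < 2 * s + 1 &&
          all(is.finite(cm[pk[1], (pk[2] - 1):(pk[2] + 1)]))) {
        sub_x <- subpixel_offset(cm[pk[1], pk[2] - 1], peak, cm[pk[1], pk[2] + 1])
      }
      BDY[i, j] <- round(gdy) + dy0 + sub_y
      BDX[i, j] <- round(gdx) + dx0 + sub_x
      WGT[i, j] <- max(0, peak)
    }
  }
  conf <- mean(WGT)
  WGT[WGT < cfg$min_corr] <- 0
  if (all(WGT == 0)) {
    warning("no informative blocks: returning zero displacement (low confidence)")
    return(zero_field(conf))
  }
  sigma <- cfg$stiffness / 2
  SDX <- gaussian_smooth(BDX, sigma, WGT)
  SDY <- gaussian_smooth(BDY, sigma, WGT)
  # blocks still undefined (all-zero weight neighbourhood): fall back to the
  # weighted mean of informative blocks
  fill_na <- function(m) {
    if (anyNA(m)) m[is.na(m)] <- sum(m * WGT, na.rm = TRUE) / sum(WGT[!is.na(m)])
    m
  }
  mdx <- sum(BDX[WGT > 0] * WGT[WGT > 0]) / sum(WGT[WGT > 0])
  mdy <- sum(BDY[WGT > 0] * WGT[WGT > 0]) / sum(WGT[WGT > 0])
  SDX[is.na(SDX)] <- mdx; SDY[is.na(SDY)] <- mdy

  # bilinear upsampling of block centres to pixels
  centres_r <- br + (bs - 1) / 2
  centres_c <- bc + (bs - 1) / 2
  dx <- upsample_block_field(SDX, centres_r, centres_c, nr, nc)
  dy <- upsample_block_field(SDY, centres_r, centres_c, nr, nc)

  mag <- sqrt(dx^2 + dy^2)
  over <- mag > max_off_px & mag > 0
  if (any(over)) {
    sc <- max_off_px / mag[over]
    dx[over] <- dx[over] * sc
    dy[over] <- dy[over] * sc
  }
  f <- displacement_field(dx, dy, pixel_size = px,
                          max_offset_m = cfg$max_offset_m)
  attr(f, "confidence") <- conf
  f
}

# bilinear interpolation of a block-centre field to the full pixel grid,
# constant extrapolation beyond the outer block centres
upsample_block_field <- function(bm, centres_r, centres_c, nr, nc) {
  if (length(centres_r) == 1 && length(centres_c) == 1) {
    return(matrix(bm[1, 1], nr, nc))
  }
  rows_interp <- if (length(centres_r) == 1) {
    matrix(bm, 1, ncol(bm))[rep(1, nr), , drop = FALSE]
  } else {
    apply(bm, 2, function(col) {
      stats::approx(centres_r, col, xout = seq_len(nr), rule = 2)$y
    })
  }
  if (length(centres_c) == 1) {
    matrix(rows_interp, nr, nc)
  } else {
    t(apply(rows_interp, 1, function(row) {
      stats::approx(centres_c, row, xout = seq_len(nc), rule = 2)$y
    }))
  }
}

# warp one matrix through (dx, dy): out[r, c] = m[r + dy, c + dx]
warp_matrix <- function(m, dx, dy, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  nr <- nrow(m); nc <- ncol(m)
  rows <- matrix(seq_len(nr), nr, nc) + dy
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc) + dx
  v <- if (method == "bilinear") {
    bilinear_sample(m, as.vector(rows), as.vector(cols))
  } else {
    nearest_sample(m, as.vector(rows), as.vector(cols))
  }
  matrix(v, nr, nc)
}

#' Apply a displacement field to a series or grid
#'
#' Resamples every band through the same field (bilinear), and the validity
#' mask with nearest-neighbour; the output grid is unchanged. Pixels whose
#' source location falls outside the grid become `NA` (invalid).
#'
#' @param x a `monthly_series` or `field_grid`.
#' @param field a `displacement_field` on the same grid.
#' @param month for a series: month slice indices to warp (default all).
#' @return object of the same class as `x`.
#' @export
apply_displacement <- function(x, field, month = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  if (inherits(x, "field_grid")) {
    stopifnot(all(dim(x$values) == dim(field$dx)))
    out <- x
    out$values <- warp_matrix(x$values, field$dx, field$dy, "bilinear")
    return(out)
  }
  stopifnot(inherits(x, "monthly_series"))
  d <- dim(x$bands)
  stopifnot(all(d[1:2] == dim(field$dx)))
  if (is.null(month)) month <- seq_len(d[4])
  out <- x
  for (m in month) {
    for (k in 1:4) {
      out$bands[, , k, m] <- warp_matrix(x$bands[, , k, m],
                                         field$dx, field$dy, "bilinear")
    }
    v <- warp_matrix(x$valid[, , m] + 0, field$dx, field$dy, "nearest")
    v[is.na(v)] <- 0
    na_band <- is.na(out$bands[, , 3, m])
    out$valid[, , m] <- (v > 0) & !na_band
  }
  out
}

#' Coregister a monthly series against seasonal references
#'
#' Matches each month's NIR band to the composite of its season (all other
#' bands inherit the estimated field) and warps the whole series. When
#' `cfg$tile_px` is set the scene is processed in buffered tiles and
#' re-assembled, which is seam-free because the buffer covers the maximum
#' offset.
#'
#' @param series a `monthly_series`.
#' @param cfg a [coreg_config()].
#' @param reference optional `seasonal_reference` built from an external
#'   (better-registered) source; default builds one from the series itself.
#' @param windows season windows (default [season_windows()]).
#' @return list with `series` (coregistered `monthly_series`) and `fields`
#'   (per-month `displacement_field`s).
#' @export
coregister_series <- function(series, cfg = coreg_config(), reference = NULL,
                              windows = season_windows()) {
  stopifnot(inherits(series, "monthly_series"))
  if (is.null(reference)) reference <- build_seasonal_reference(series, windows)
  season_of <- integer(max(series$months))
  for (k in seq_along(windows)) season_of[windows[[k]]] <- k
  out <- series
  fields <- vector("list", dim(series)[4])
  for (mi in seq_len(dim(series)[4])) {
    mo <- series$months[mi]
    ref <- reference[[season_of[mo]]]$composite
    tgt <- series_band(series, "nir", mi)
    fld <- if (is.null(cfg$tile_px)) {
      estimate_displacement(tgt, ref, cfg)
    } else {
      estimate_displacement_tiled(tgt, ref, cfg)
    }
    fields[[mi]] <- fld
    warped <- apply_displacement(series, fld, month = mi)
    out$bands[, , , mi] <- warped$bands[, , , mi]
    out$valid[, , mi] <- warped$valid[, , mi]
  }
  list(series = out, fields = fields)
}

# tiled displacement estimation: buffered tiles, cropped and mosaicked
estimate_displacement_tiled <- function(target, reference, cfg) {
  t_m <- if (inherits(target, "field_grid")) target$values else target
  r_m <- if (inherits(reference, "field_grid")) reference$values else reference
  nr <- nrow(t_m); nc <- ncol(t_m)
  ts <- cfg$tile_px; bf <- cfg$buffer_px
  dx <- matrix(0, nr, nc); dy <- matrix(0, nr, nc)
  conf <- c()
  for (r0 in seq(1, nr, by = ts)) {
    for (c0 in seq(1, nc, by = ts)) {
      r1 <- min(nr, r0 + ts - 1); c1 <- min(nc, c0 + ts - 1)
      rb0 <- max(1, r0 - bf); rb1 <- min(nr, r1 + bf)
      cb0 <- max(1, c0 - bf); cb1 <- min(nc, c1 + bf)
      sub_cfg <- cfg; sub_cfg$tile_px <- NULL
      fld <- estimate_displacement(t_m[rb0:rb1, cb0:cb1],
                                   r_m[rb0:rb1, cb0:cb1], sub_cfg)
      conf <- c(conf, attr(fld, "confidence"))
      rr <- (r0:r1) - rb0 + 1; cc <- (c0:c1) - cb0 + 1
      dx[r0:r1, c0:c1] <- fld$dx[rr, cc]
      dy[r0:r1, c0:c1] <- fld$dy[rr, cc]
    }
  }
  f <- displacement_field(dx, dy, pixel_size = cfg$pixel_size,
                          max_offset_m = cfg$max_offset_m)
  attr(f, "confidence") <- mean(conf)
  f
}
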