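#' Default class mixture for synthetic scenes
#'
#' Class proportions of a synthetic scene default to the error-adjusted area
#' shares of the published regional assessment (active cropland 16.2%,
#' short-term fallow 6.6%, herbaceous 11.2%, open woodland 39.1%, closed
#' woodland 24.0%, unvegetated 2.1%, water 0.7%), renormalised to sum to 1.
#'
#' @return named numeric vector over the seven class codes, summing to 1.
#' @export
default_class_mix <- function() {
  p <- c(active_cropland = 16.2, short_fallow = 6.6, herbaceous = 11.2,
         open_woodland = 39.1, closed_woodland = 24.0, unvegetated = 2.1,
         water = 0.7)
  p / sum(p)
}

#' Default per-class NDVI phenology library
#'
#' Twelve-month mean NDVI trajectories per class (month 1 = September through
#' month 12 = August, i.e. one southern-hemisphere cropping year), a
#' band-brightness term, and a reflectance noise standard deviation. The
#' trajectories encode the seasonality the classifier exploits: cropland has
#' a pronounced green-up after planting (Nov-Dec) peaking in the late wet
#' season and collapsing at harvest; short-term fallow shows a damped
#' herbaceous version of the same cycle; woodlands stay greener year-round
#' with muted amplitude; unvegetated and water are flat. Reflectance is
#' derived so that (nir - red)/(nir + red) returns the trajectory exactly:
#' nir = b (1 + NDVI)/2, red = b (1 - NDVI)/2 with brightness b = nir + red.
#'
#' @param noise_sd default per-band reflectance noise (standard deviation).
#' @return a `phenology_library`: list with matrix `ndvi` (7 classes x 12
#'   months), vector `brightness`, scalar `noise_sd`.
#' @export
default_phenology <- function(noise_sd = 0.02) {
  ndvi <- rbind(
    active_cropland = c(0.22, 0.25, 0.35, 0.55, 0.75, 0.82, 0.80, 0.65,
                        0.45, 0.32, 0.26, 0.23),
    short_fallow    = c(0.30, 0.32, 0.38, 0.46, 0.55, 0.60, 0.58, 0.52,
                        0.44, 0.38, 0.34, 0.31),
    herbaceous      = c(0.35, 0.36, 0.42, 0.52, 0.62, 0.66, 0.65, 0.60,
                        0.52, 0.45, 0.40, 0.37),
    open_woodland   = c(0.45, 0.46, 0.50, 0.58, 0.66, 0.70, 0.70, 0.67,
                        0.62, 0.56, 0.50, 0.47),
    closed_woodland = c(0.72, 0.72, 0.74, 0.78, 0.82, 0.84, 0.84, 0.83,
                        0.80, 0.77, 0.74, 0.72),
    unvegetated     = c(0.12, 0.12, 0.13, 0.14, 0.15, 0.15, 0.15, 0.14,
                        0.13, 0.12, 0.12, 0.12),
    water           = c(-0.10, -0.10, -0.10, -0.12, -0.12, -0.12, -0.12,
                        -0.11, -0.10, -0.10, -0.10, -0.10)
  )
  stopifnot(all(ndvi >= -1), all(ndvi <= 1))
  structure(
    list(
      ndvi = ndvi,
      brightness = c(active_cropland = 0.50, short_fallow = 0.46,
                     herbaceous = 0.44, open_woodland = 0.40,
                     closed_woodland = 0.36, unvegetated = 0.60,
                     water = 0.20),
      noise_sd = noise_sd
    ),
    class = "phenology_library"
  )
}

#' Generate a patchy synthetic class map
#'
#' Builds a fragmented land-cover mosaic by capacity-constrained random
#' region growing (Eden growth) from seeds on a jittered grid. Each class
#' receives a pixel budget equal to its requested proportion; growth of a
#' class stops when its budget is exhausted, so realised proportions match
#' the request to within rounding. Field classes (active cropland, fallow)
#' use small patches — the landscapes targeted here have most fields below
#' 0.64 ha, about 280 pixels at 4.77 m — while woodland patches are larger.
#'
#' @param nrow,ncol extent in pixels (>= 64 each).
#' @param class_mix named proportions over class codes/names, summing to 1.
#' @param mean_patch_px mean patch size (pixels) per class, recycled to 7.
#' @param pixel_size pixel size in metres.
#' @param seed integer seed; the map is byte-identical across runs for a
#'   fixed seed.
#' @return a `class_map`: integer matrix of codes 1-7 plus metadata; the
#'   realised proportions are stored in `attr(, "proportions")`.
#' @export
generate_class_map <- function(nrow = 128, ncol = 128,
                               class_mix = default_class_mix(),
                               mean_patch_px = NULL,
                               pixel_size = 4.77, seed = 1L) {
  if (nrow < 64 || ncol < 64) {
    stop("extent too small: need at least 64 x 64 pixels, got ",
         nrow, " x ", ncol)
  }
  cat7 <- class_catalog()
  mix <- normalise_mix(class_mix)
  if (is.null(mean_patch_px)) {
    mean_patch_px <- c(280, 280, 1500, 4000, 4000, 800, 1200)
  }
  mean_patch_px <- rep_len(mean_patch_px, 7)

  n <- nrow * ncol
  # largest-remainder integer budgets per class
  raw <- mix * n
  budget <- floor(raw)
  rem <- n - sum(budget)
  if (rem > 0) {
    ord <- order(raw - budget, decreasing = TRUE)
    budget[ord[seq_len(rem)]] <- budget[ord[seq_len(rem)]] + 1L
  }

  set.seed(seed)
  cls <- integer(n) # 0 = unassigned; column-major pixel index
  left <- budget

  n_seeds <- pmax(1L, round(budget / mean_patch_px))
  n_seeds[budget == 0] <- 0L
  seed_class <- rep.int(1:7, n_seeds)
  total_seeds <- length(seed_class)

  # jittered-grid seed placement
  g <- max(1, floor(sqrt(n / max(total_seeds, 1))))
  gr <- pmax(1, floor(nrow / g)); gc <- pmax(1, floor(ncol / g))
  cells <- expand.grid(i = seq_len(gr), j = seq_len(gc))
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
  seed_class <- sample(seed_class)
  k <- min(total_seeds, nrow(cells))
  srow <- pmin(nrow, (cells$i[seq_len(k)] - 1) * g + sample.int(g, k, replace = TRUE))
  scol <- pmin(ncol, (cells$j[seq_len(k)] - 1) * g + sample.int(g, k, replace = TRUE))
  if (total_seeds > k) { # more seeds than grid cells: place the rest anywhere
    extra <- total_seeds - k
    srow <- c(srow, sample.int(nrow, extra, replace = TRUE))
    scol <- c(scol, sample.int(ncol, extra, replace = TRUE))
  }
  spix <- (scol - 1L) * nrow + srow

  grow <- function(front_pix, front_cls) {
    # Eden growth: pop a random frontier element, claim it, push neighbours
    fp <- front_pix; fc <- front_cls; m <- length(fp)
    while (m > 0) {
      j <- sample.int(m, 1L)
      p <- fp[j]; cl <- fc[j]
      fp[j] <- fp[m]; fc[j] <- fc[m]; m <- m - 1L
      if (cls[p] == 0L && left[cl] > 0L) {
        cls[p] <<- cl
        left[cl] <<- left[cl] - 1L
        r <- ((p - 1L) %% nrow) + 1L
        cc <- ((p - 1L) %/% nrow) + 1L
        nb <- c(if (r > 1L) p - 1L, if (r < nrow) p + 1L,
                if (cc > 1L) p - nrow, if (cc < ncol) p + nrow)
        nb <- nb[cls[nb] == 0L]
        ln <- length(nb)
        if (ln) {
          if (m + ln > length(fp)) {
            fp <- c(fp, integer(max(ln, length(fp))))
            fc <- c(fc, integer(max(ln, length(fc))))
          }
          fp[(m + 1L):(m + ln)] <- nb
          fc[(m + 1L):(m + ln)] <- cl
          m <- m + ln
        }
      }
    }
  }

  keep <- left[seed_class] > 0L
  grow(spix[keep], seed_class[keep])

  # mop up pixels stranded by exhausted budgets: reseed remaining budget
  while (any(cls == 0L)) {
    open <- which(cls == 0L)
    avail <- which(left > 0L)
    if (!length(avail)) { # numeric safety; cannot happen as budgets sum to n
      cls[open] <- which.max(budget)
      break
    }
    ns <- pmax(1L, pmin(left[avail], ceiling(left[avail] / 500)))
    sc <- rep.int(avail, ns)
    sp <- open[sample.int(length(open), min(length(sc), length(open)))]
    grow(sp, sc[seq_along(sp)])
  }

  values <- matrix(cls, nrow, ncol)
  realised <- tabulate(cls, 7) / n
  structure(
    list(values = values, pixel_size = pixel_size, origin = c(0, 0),
         catalog = cat7),
    class = "class_map",
    proportions = stats::setNames(realised, cat7$class),
    seed = seed
  )
}

# accept named (by class name or code) or positional proportions
normalise_mix <- function(class_mix) {
  cat7 <- class_catalog()
  mix <- numeric(7)
  if (!is.null(names(class_mix)) && any(names(class_mix) != "")) {
    idx <- match(names(class_mix), cat7$class)
    if (anyNA(idx)) {
      idx <- match(suppressWarnings(as.integer(names(class_mix))), cat7$code)
    }
    if (anyNA(idx)) stop("unknown class name(s) in class_mix: ",
                         paste(names(class_mix)[is.na(idx)], collapse = ", "))
    mix[idx] <- class_mix
  } else {
    stopifnot(length(class_mix) == 7)
    mix <- as.numeric(class_mix)
  }
  if (any(mix < 0) || sum(mix) <= 0) stop("class_mix must be non-negative and non-empty")
  if (abs(sum(mix) - 1) > 1e-6) stop("class proportions must sum to 1")
  mix
}

#' @export
print.class_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<class_map> %d x %d px @ %.2f m\n", d[1], d[2], x$pixel_size))
  p <- attr(x, "proportions")
  if (!is.null(p)) {
    for (i in seq_along(p)) cat(sprintf("  %-16s %.3f\n", names(p)[i], p[i]))
  }
  invisible(x)
}

#' @export
dim.class_map <- function(x) dim(x$values)

#' Realised class proportions of a class map
#'
#' @param map a `class_map`.
#' @return tibble with `code`, `class`, `share` (pixel-count fractions).
#' @export
class_shares <- function(map) {
  stopifnot(inherits(map, "class_map"))
  n <- length(map$values)
  dplyr::mutate(class_catalog()[, c("code", "class")],
                share = tabulate(map$values, 7) / n)
}

#' Simulate a smooth displacement field
#'
#' Low-frequency smooth offsets (a sum of random long-wavelength cosine
#' harmonics) plus an optional constant shift, emulating the spatially
#' coherent multi-temporal misregistration of monthly mosaics. Magnitudes
#' are rescaled so the maximum offset equals `max_px` pixels.
#'
#' @param nrow,ncol extent in pixels.
#' @param max_px maximum offset magnitude in pixels (0 = zero field).
#' @param constant constant (dx, dy) shift in pixels added on top.
#' @param n_harmonics number of random cosine harmonics per component.
#' @param pixel_size pixel size in metres.
#' @param seed integer seed.
#' @return a `displacement_field`.
#' @export
simulate_displacement <- function(nrow, ncol, max_px = 2, constant = c(0, 0),
                                  n_harmonics = 3, pixel_size = 4.77,
                                  seed = 1L) {
  set.seed(seed)
  smooth_field <- function() {
    f <- matrix(0, nrow, ncol)
    rr <- matrix(seq_len(nrow) / nrow, nrow, ncol)
    cc <- matrix(rep(seq_len(ncol) / ncol, each = nrow), nrow, ncol)
    for (k in seq_len(n_harmonics)) {
      fx <- stats::runif(1, 0.3, 1.5); fy <- stats::runif(1, 0.3, 1.5)
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.3, 1)
      f <- f + amp * cos(2 * pi * (fx * cc + fy * rr) + ph)
    }
    f
  }
  dx <- smooth_field(); dy <- smooth_field()
  mag <- sqrt(dx^2 + dy^2)
  mx <- max(mag)
  if (max_px == 0 || mx == 0) {
    dx[] <- 0; dy[] <- 0
  } else {
    dx <- dx / mx * max_px
    dy <- dy / mx * max_px
  }
  dx <- dx + constant[1]
  dy <- dy + constant[2]
  displacement_field(dx, dy, pixel_size = pixel_size)
}

#' Simulate an elliptical-blob cloud mask
#'
#' Clouds are random rotated ellipses accumulated until the requested masked
#' fraction is reached; they are recorded in the validity mask only (no
#' reflectance perturbation), matching how downstream compositing consumes
#' cloud information.
#'
#' @param nrow,ncol extent in pixels.
#' @param fraction target cloudy fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return logical matrix, TRUE = cloudy.
#' @export
simulate_clouds <- function(nrow, ncol, fraction = 0.1, seed = 1L) {
  set.seed(seed)
  mask <- matrix(FALSE, nrow, ncol)
  if (fraction <= 0) return(mask)
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol)
  guard <- 0L
  while (mean(mask) < fraction && guard < 500L) {
    guard <- guard + 1L
    r0 <- stats::runif(1, 1, nrow); c0 <- stats::runif(1, 1, ncol)
    a <- stats::runif(1, 0.04, 0.12) * max(nrow, ncol)
    b <- a * stats::runif(1, 0.4, 1)
    th <- stats::runif(1, 0, pi)
    u <- (cc - c0) * cos(th) + (rr - r0) * sin(th)
    v <- -(cc - c0) * sin(th) + (rr - r0) * cos(th)
    mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
  }
  mask
}

#' Simulate a smooth synthetic DEM
#'
#' @param nrow,ncol extent in pixels.
#' @param base,relief base elevation and relief amplitude in metres.
#' @param seed integer seed.
#' @return a `field_grid` of elevations (metres). The DEM is a synthetic
#'   stand-in for a real elevation model.
#' @export
simulate_dem <- function(nrow, ncol, base = 400, relief = 300, seed = 1L) {
  set.seed(seed)
  rr <- matrix(seq_len(nrow) / nrow, nrow, ncol)
  cc <- matrix(rep(seq_len(ncol) / ncol, each = nrow), nrow, ncol)
  z <- matrix(0, nrow, ncol)
  for (k in 1:4) {
    fx <- stats::runif(1, 0.2, 1.2); fy <- stats::runif(1, 0.2, 1.2)
    ph <- stats::runif(1, 0, 2 * pi)
    z <- z + stats::runif(1, 0.2, 1) * cos(2 * pi * (fx * cc + fy * rr) + ph)
  }
  z <- base + relief * (z - min(z)) / diff(range(z))
  field_grid(z, name = "elevation")
}

#' Simulate a full scene truth
#'
#' Bundles everything downstream stages are tested against: a class map,
#' one true displacement field per month, per-month cloud masks, and a DEM.
#'
#' @param nrow,ncol extent in pixels.
#' @param class_mix class proportions (see [generate_class_map()]).
#' @param n_months number of monthly slices (12 = one cropping year).
#' @param displacement_max_px maximum true offset magnitude (pixels); 0
#'   disables misregistration.
#' @param cloud_fraction per-month cloudy fraction cap.
#' @param pixel_size pixel size in metres.
#' @param seed integer master seed; per-month seeds are derived from it.
#' @return a `scene_truth` list: `class_map`, `displacement` (list of
#'   per-month `displacement_field`s), `clouds` (`[row, col, month]`
#'   logical), `dem`, `pixel_size`.
#' @export
simulate_scene <- function(nrow = 128, ncol = 128,
                           class_mix = default_class_mix(),
                           n_months = 12, displacement_max_px = 0,
                           cloud_fraction = 0, pixel_size = 4.77, seed = 1L) {
  map <- generate_class_map(nrow, ncol, class_mix,
                            pixel_size = pixel_size, seed = seed)
  disp <- lapply(seq_len(n_months), function(m) {
    simulate_displacement(nrow, ncol, max_px = displacement_max_px,
                          pixel_size = pixel_size, seed = seed * 131L + m)
  })
  clouds <- array(FALSE, c(nrow, ncol, n_months))
  if (cloud_fraction > 0) {
    for (m in seq_len(n_months)) {
      clouds[, , m] <- simulate_clouds(nrow, ncol, cloud_fraction,
                                       seed = seed * 977L + m)
    }
  }
  dem <- simulate_dem(nrow, ncol, seed = seed + 7L)
  structure(
    list(class_map = map, displacement = disp, clouds = clouds, dem = dem,
         pixel_size = pixel_size, seed = seed),
    class = "scene_truth"
  )
}

#' Render a monthly image series from a scene truth
#'
#' Each month is rendered from the class phenology (bands derived so NDVI
#' reproduces the class trajectory exactly), warped by that month's true
#' displacement field, contaminated with Gaussian band noise, and masked by
#' the month's cloud layer in the validity band. With zero displacement and
#' zero noise the per-class NDVI time series equal the phenology
#' trajectories exactly.
#'
#' Besides independent per-band pixel noise, a static low-frequency NDVI
#' perturbation field (amplitude `spatial_noise_sd`) shifts whole regions
#' greener or drier across the year, emulating the spatially coherent
#' moisture and condition gradients that make patches of different classes
#' genuinely confusable.
#'
#' @param truth a `scene_truth`.
#' @param phen a `phenology_library` (default [default_phenology()]).
#' @param noise_sd per-band reflectance noise sd; `NULL` uses the library's.
#' @param spatial_noise_sd amplitude (NDVI units) of the static smooth
#'   perturbation field; 0 disables it.
#' @param seed integer seed for the noise draws.
#' @return a `monthly_series`.
#' @export
render_monthly_series <- function(truth, phen = default_phenology(),
                                  noise_sd = NULL, spatial_noise_sd = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(truth, "scene_truth"))
  if (is.null(noise_sd)) noise_sd <- phen$noise_sd
  map <- truth$class_map$values
  present <- sort(unique(as.vector(map)))
  missing <- setdiff(present, match(rownames(phen$ndvi), class_catalog()$class))
  if (length(missing)) {
    stop("phenology library missing class(es): ",
         paste(class_catalog()$class[missing], collapse = ", "))
  }
  nr <- nrow(map); nc <- ncol(map)
  n_months <- length(truth$displacement)
  bands <- array(NA_real_, c(nr, nc, 4, n_months))
  set.seed(seed)
  b <- phen$brightness[map] # per-pixel brightness, recycled by class code
  dim(b) <- c(nr, nc)
  spert <- matrix(0, nr, nc)
  if (spatial_noise_sd > 0) {
    rr <- matrix(seq_len(nr) / nr, nr, nc)
    cc <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
    for (k in 1:4) {
      fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
      ph <- stats::runif(1, 0, 2 * pi)
      spert <- spert + stats::runif(1, 0.3, 1) *
        cos(2 * pi * (fx * cc + fy * rr) + ph)
    }
    spert <- spert / stats::sd(spert) * spatial_noise_sd
  }
  for (m in seq_len(n_months)) {
    month_of_year <- ((m - 1) %% 12) + 1
    ndvi <- phen$ndvi[cbind(as.vector(map), month_of_year)]
    dim(ndvi) <- c(nr, nc)
    ndvi <- pmax(-1, pmin(1, ndvi + spert))
    nir <- b * (1 + ndvi) / 2
    red <- b * (1 - ndvi) / 2
    green <- red * 0.9 + 0.02
    extra <- red * 0.8 + 0.01
    ideal <- list(green = green, red = red, nir = nir, extra = extra)
    d <- truth$displacement[[m]]
    shifted <- if (all(d$dx == 0) && all(d$dy == 0)) {
      ideal
    } else {
      lapply(ideal, warp_matrix, dx = d$dx, dy = d$dy, method = "bilinear")
    }
    for (k in 1:4) {
      v <- shifted[[k]]
      # fill warp edges with the un-warped value so the scene stays complete
      na <- is.na(v)
      if (any(na)) v[na] <- ideal[[k]][na]
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      bands[, , k, m] <- v
    }
  }
  valid <- !truth$clouds[, , seq_len(n_months), drop = FALSE]
  monthly_series(bands, valid = valid, months = seq_len(n_months),
                 pixel_size = truth$pixel_size)
}

#' Sample labelled reference points from a scene truth
#'
#' Simple random per-class sampling with a global minimum-distance
#' constraint (greedy thinning), mirroring field practice of spreading
#' photo-interpretation points at least ~222 m apart. Labels are read from
#' the true class map, so label agreement with the map is exact.
#'
#' @param truth a `scene_truth` (or a bare `class_map`).
#' @param n_per_class points requested per class.
#' @param min_dist_m minimum pairwise distance in metres (applies across the
#'   whole sample).
#' @param seed integer seed.
#' @return tibble of samples: `x`, `y` (metres), `row`, `col`, `code`,
#'   `class`, `provenance` (`"random"`), `split` (`NA`). If a class is too
#'   rare to satisfy the constraint the sample is partial and a warning
#'   reports the shortfall.
#' @export
sample_reference_points <- function(truth, n_per_class = 50,
                                    min_dist_m = 222, seed = 1L) {
  map <- if (inherits(truth, "scene_truth")) truth$class_map else truth
  stopifnot(inherits(map, "class_map"), n_per_class >= 1)
  set.seed(seed)
  nr <- nrow(map$values); nc <- ncol(map$values)
  px <- map$pixel_size
  cc <- pixel_centers(nr, nc, px, map$origin)
  acc_x <- numeric(0); acc_y <- numeric(0)
  rows <- integer(0); cols <- integer(0); codes <- integer(0)
  shortfall <- integer(0)
  for (cl in class_catalog()$code) {
    cand <- which(map$values == cl)
    if (!length(cand)) { shortfall[as.character(cl)] <- n_per_class; next }
    cand <- cand[sample.int(length(cand))]
    got <- 0L
    for (p in cand) {
      if (got >= n_per_class) break
      r <- ((p - 1L) %% nr) + 1L
      co <- ((p - 1L) %/% nr) + 1L
      x <- cc$x[r, co]; y <- cc$y[r, co]
      if (length(acc_x) == 0 ||
          all((acc_x - x)^2 + (acc_y - y)^2 >= min_dist_m^2)) {
        acc_x <- c(acc_x, x); acc_y <- c(acc_y, y)
        rows <- c(rows, r); cols <- c(cols, co); codes <- c(codes, cl)
        got <- got + 1L
      }
    }
    if (got < n_per_class) shortfall[as.character(cl)] <- n_per_class - got
  }
  if (length(shortfall)) {
    warning(sprintf(
      "min-distance constraint left %d sample(s) short (classes: %s)",
      sum(shortfall), paste(names(shortfall), collapse = ", ")))
  }
  cat7 <- class_catalog()
  tibble::tibble(
    x = acc_x, y = acc_y, row = rows, col = cols, code = codes,
    class = cat7$class[codes], provenance = "random", split = NA_character_
  )
}

#' Write a scene truth to plain-text rasters
#'
#' Writes the class map, DEM and per-month true displacement components as
#' ASCII grids, and per-month band/validity grids for a rendered series.
#'
#' @param truth a `scene_truth`.
#' @param series optional `monthly_series` rendered from it.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(truth, series = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- truth$pixel_size
  write_ascii_grid(field_grid(truth$class_map$values + 0, px),
                   file.path(dir, "class_map.asc"))
  write_ascii_grid(truth$dem, file.path(dir, "dem.asc"))
  for (m in seq_along(truth$displacement)) {
    d <- truth$displacement[[m]]
    write_ascii_grid(field_grid(d$dx, px),
                     file.path(dir, sprintf("disp_dx_m%02d.asc", m)))
    write_ascii_grid(field_grid(d$dy, px),
                     file.path(dir, sprintf("disp_dy_m%02d.asc", m)))
  }
  if (!is.null(series)) {
    for (m in seq_len(dim(series)[4])) {
      for (band in c("green", "red", "nir", "extra")) {
        write_ascii_grid(
          field_grid(series$bands[, , band, m], px),
          file.path(dir, sprintf("%s_m%02d.asc", band, m)))
      }
      write_ascii_grid(field_grid(series$valid[, , m] + 0, px),
                       file.path(dir, sprintf("valid_m%02d.asc", m)))
    }
  }
  invisible(dir)
}
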