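#' Default window sides for the local connected fractal dimension
#'
#' Odd window sides from 3 up to `max_side` (default 33) in steps of 2.
#'
#' @param max_side Largest window side, odd.
#' @return Integer vector of odd window sides.
#' @export
lcfd_scales <- function(max_side = 33) {
  if (max_side < 7) stop("need at least 3 odd scales", call. = FALSE)
  seq.int(3L, as.integer(max_side), 2L)
}

check_lcfd_scales <- function(scales) {
  scales <- as.integer(scales)
  if (length(scales) < 3L) stop("need at least 3 scales", call. = FALSE)
  if (any(scales %% 2L == 0L) || any(scales < 3L)) {
    stop("scales must be odd integers >= 3", call. = FALSE)
  }
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be strictly increasing", call. = FALSE)
  }
  scales
}

check_seed_pixel <- function(m, seed) {
  seed <- as.integer(seed)
  if (length(seed) != 2L || any(seed < 1L) || seed[1] > nrow(m) ||
      seed[2] > ncol(m)) {
    stop("seed must be a valid c(row, col) pixel", call. = FALSE)
  }
  if (m[seed[1], seed[2]] == 0L) {
    stop("seed pixel must be foreground", call. = FALSE)
  }
  seed
}

#' Locally connected mass around a seed pixel
#'
#' Size of the 8-connected component containing the seed, evaluated inside
#' the `epsilon` x `epsilon` window centred on the seed (the window is
#' clipped at the image borders, and connectivity is evaluated only among
#' pixels inside the window).  The seed always counts itself, so the mass is
#' at least 1.
#'
#' @param mask A [binary_raster()] or \{0,1\} matrix.
#' @param seed `c(row, col)` of a foreground pixel (1-based).
#' @param epsilon Odd window side, at least 3.
#' @return Integer mass `M(epsilon)`.
#' @export
connected_mass <- function(mask, seed, epsilon) {
  m <- mask_of(mask)
  seed <- check_seed_pixel(m, seed)
  epsilon <- as.integer(epsilon)
  if (epsilon < 3L || epsilon %% 2L == 0L) {
    stop("epsilon must be an odd integer >= 3", call. = FALSE)
  }
  cpp_connected_mass(m, seed[1] - 1L, seed[2] - 1L, epsilon)
}

#' Local connected fractal dimension at one pixel
#'
#' The scaling exponent of the locally connected mass: the OLS slope of
#' `log M(eps)` against `log eps` across the window sides, i.e. the
#' regression form of `M(eps) ~ F * eps^LCFD` with `log F` as intercept.
#' The slope is exactly 1 at an interior pixel of a one-pixel-wide straight
#' line and exactly 2 inside a completely filled region.
#'
#' @inheritParams connected_mass
#' @param scales Strictly increasing odd window sides, at least 3 of them.
#' @return The slope (a real number; 0 for an isolated pixel).
#' @export
lcfd_at_pixel <- function(mask, seed, scales = lcfd_scales()) {
  m <- mask_of(mask)
  seed <- check_seed_pixel(m, seed)
  scales <- check_lcfd_scales(scales)
  masses <- cpp_masses(m, seed[1] - 1L, seed[2] - 1L, scales)
  ols_fit(log(scales), log(masses))$slope
}

#' Per-pixel map of the local connected fractal dimension
#'
#' Evaluates [lcfd_at_pixel()] at every foreground pixel.  Windows are
#' always clipped at the image borders when computing the map; the
#' `border_policy` controls which pixels enter the mean and histogram:
#' under `"exclude"` (recommended for scalar reporting) pixels whose
#' largest window would be clipped are omitted, which makes the analytic
#' line/filled anchors exact.
#'
#' @inheritParams lcfd_at_pixel
#' @param border_policy `"clip"` or `"exclude"`.
#' @param breaks Histogram bin edges for the summarized distribution.
#' @return An object of class `lcfd_result`: `map` (real matrix, 0 at
#'   background), `mean`, `histogram` (list of `breaks`, `counts`),
#'   `n_pixels` (number of counted foreground pixels), `scales`,
#'   `border_policy`.
#' @export
lcfd_map <- function(mask, scales = lcfd_scales(),
                     border_policy = c("clip", "exclude"),
                     breaks = seq(-0.25, 2.25, by = 0.125)) {
  border_policy <- match.arg(border_policy)
  m <- mask_of(mask)
  if (sum(m) == 0L) stop("lcfd_map: empty mask", call. = FALSE)
  scales <- check_lcfd_scales(scales)
  map <- cpp_lcfd_map(m, scales)
  counted <- m == 1L
  if (border_policy == "exclude") {
    h <- max(scales) %/% 2L
    inside <- matrix(FALSE, nrow(m), ncol(m))
    if (nrow(m) >= 2L * h + 1L && ncol(m) >= 2L * h + 1L) {
      inside[(h + 1L):(nrow(m) - h), (h + 1L):(ncol(m) - h)] <- TRUE
    }
    counted <- counted & inside
  }
  vals <- map[counted]
  hist <- if (length(vals) > 0L) {
    edges <- breaks
    if (min(vals) < min(edges) || max(vals) > max(edges)) {
      edges <- seq(floor(min(vals)), ceiling(max(vals)) + 0.125, by = 0.125)
    }
    list(breaks = edges,
         counts = as.integer(table(cut(vals, edges, include.lowest = TRUE))))
  } else {
    list(breaks = breaks, counts = integer(length(breaks) - 1L))
  }
  structure(
    list(map = map, mean = if (length(vals)) mean(vals) else NA_real_,
         histogram = hist, n_pixels = length(vals), scales = scales,
         border_policy = border_policy),
    class = "lcfd_result"
  )
}

#' @export
print.lcfd_result <- function(x, ...) {
  cat(sprintf(
    "<lcfd> mean %.4f over %d pixels (scales %d..%d, border '%s')\n",
    x$mean, x$n_pixels, min(x$scales), max(x$scales), x$border_policy))
  invisible(x)
}
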