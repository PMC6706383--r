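#' Box occupancies on a fixed grid
#'
#' Occupancy counts `p(r, i)` of every cell of a fixed non-overlapping grid
#' of side `r` anchored at the top-left corner, partial boxes at the right
#' and bottom edges included.  Zero counts are kept: the grid has
#' `ceiling(H/r) * ceiling(W/r)` cells.
#'
#' @param mask A [binary_raster()] or \{0,1\} matrix.
#' @param r Box side, `1 <= r <= min(dim)`.
#' @return Integer vector of occupancies, one per grid cell.
#' @export
box_occupancy <- function(mask, r) {
  m <- mask_of(mask)
  r <- as.integer(r)
  if (r < 1L || r > min(dim(m))) {
    stop("r must lie in [1, min(dim)]", call. = FALSE)
  }
  grid_occupancy(m, r)
}

#' Exact fixed-grid lacunarity
#'
#' The normalized second moment of the box occupancies,
#' `Lambda(r) = N(r) * sum(p^2) / (sum(p))^2`, where `N(r)` is the total
#' number of grid boxes (empty ones included), `sum(p^2)` approximates the
#' second moment `Z^2` and `(sum(p))^2` the squared total mass `L^2`.
#' `Lambda(r) >= 1` for any non-empty mask (Cauchy-Schwarz), with equality
#' when every box holds the same count; mass confined to a single box of an
#' `N`-box grid attains the maximum `Lambda = N`.
#'
#' @inheritParams box_occupancy
#' @return The lacunarity, a real `>= 1`.
#' @export
exact_lacunarity <- function(mask, r) {
  p <- box_occupancy(mask, r)
  total <- sum(p)
  if (total == 0L) stop("exact_lacunarity: empty mask", call. = FALSE)
  length(p) * sum(as.numeric(p)^2) / as.numeric(total)^2
}

#' Tug-of-War sketch of the second moment
#'
#' Randomized estimator of `Z^2 = sum(p_i^2)`: each of `s1 * s2` replicates
#' draws independent Rademacher signs `sigma_i` in \{-1, +1\} and computes
#' `(sum_i sigma_i p_i)^2`, which has expectation `Z^2`; the estimate is the
#' median over `s2` groups of the mean over `s1` replicates (median of
#' means).  Deterministic given `seed`.
#'
#' @param occupancies Numeric vector of box occupancies.
#' @param s1 Replicates per group (controls variance).
#' @param s2 Number of groups (odd recommended, for an unambiguous median).
#' @param seed Integer seed for the sign draws.
#' @return Estimate of the second moment.
#' @export
tow_second_moment <- function(occupancies, s1, s2, seed) {
  stopifnot(s1 >= 1, s2 >= 1)
  p <- as.numeric(occupancies)
  n <- length(p)
  withr::with_seed(as.integer(seed), {
    signs <- matrix(sample(c(-1, 1), n * s1 * s2, replace = TRUE), nrow = n)
    proj <- as.numeric(crossprod(p, signs))
    median(colMeans(matrix(proj^2, nrow = s1, ncol = s2)))
  })
}

#' Default lacunarity scale set
#'
#' Dyadic box sides from 2 up to a quarter of the shorter image side — the
#' scale set behind the single per-layer lacunarity scalar.
#'
#' @param mask Mask or matrix setting the range.
#' @return Integer vector of box sides.
#' @export
default_lacunarity_scales <- function(mask) {
  hi <- min(dim(mask)) / 4
  if (hi < 2) stop("image too small for a lacunarity profile", call. = FALSE)
  2^(seq.int(1, floor(log2(hi))))
}

#' Lacunarity profile over a set of box sides
#'
#' `Lambda(r)` per scale, by the exact second moment (default) or by the
#' randomized Tug-of-War sketch, plus the arithmetic-mean aggregate used as
#' the per-layer heterogeneity scalar.
#'
#' @inheritParams box_occupancy
#' @param scales Box sides; default [default_lacunarity_scales()].
#' @param method `"exact"` or `"tug_of_war"`.
#' @param s1,s2,seed Sketch parameters, used by `"tug_of_war"` only.
#' @return An object of class `lacunarity_profile`: `scales`, `lambdas`,
#'   `aggregate` (mean over scales), `method`, `sketch_params`.
#' @export
lacunarity_profile <- function(mask, scales = NULL,
                               method = c("exact", "tug_of_war"),
                               s1 = 100, s2 = 5, seed = 1) {
  method <- match.arg(method)
  m <- mask_of(mask)
  if (is.null(scales)) scales <- default_lacunarity_scales(m)
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 1L) || any(scales > min(dim(m)))) {
    stop("scales must lie in [1, min(dim)]", call. = FALSE)
  }
  lambdas <- vapply(seq_along(scales), function(i) {
    r <- scales[i]
    if (method == "exact") {
      exact_lacunarity(m, r)
    } else {
      p <- box_occupancy(m, r)
      total <- sum(p)
      if (total == 0L) stop("lacunarity_profile: empty mask", call. = FALSE)
      z2 <- tow_second_moment(p, s1, s2, seed + i - 1L)
      length(p) * z2 / as.numeric(total)^2
    }
  }, numeric(1))
  structure(
    list(scales = scales, lambdas = lambdas, aggregate = mean(lambdas),
         method = method,
         sketch_params = if (method == "tug_of_war")
           list(s1 = s1, s2 = s2, seed = seed) else NULL),
    class = "lacunarity_profile"
  )
}

#' @export
print.lacunarity_profile <- function(x, ...) {
  cat(sprintf("<lacunarity> aggregate %.4f over r = {%s} (%s)\n",
              x$aggregate, paste(x$scales, collapse = ", "), x$method))
  invisible(x)
}
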