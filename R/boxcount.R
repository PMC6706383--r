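#' Inner-boundary perimeter of a binary mask
#'
#' A pixel belongs to the perimeter set iff it is foreground and at least one
#' of its 4-neighbours is background or lies outside the image.  With this
#' definition a single pixel (or any 1-pixel-wide figure) is its own
#' perimeter, which makes the single-pixel fragmentation identity
#' `FFI = 0` exact.
#'
#' @param mask A [binary_raster()] or \{0,1\} matrix.
#' @return A [binary_raster()] of the perimeter set.
#' @export
extract_perimeter <- function(mask) {
  m <- mask_of(mask)
  H <- nrow(m); W <- ncol(m)
  up    <- rbind(m[-1, , drop = FALSE], matrix(0L, 1, W))
  down  <- rbind(matrix(0L, 1, W), m[-H, , drop = FALSE])
  left  <- cbind(m[, -1, drop = FALSE], matrix(0L, H, 1))
  right <- cbind(matrix(0L, H, 1), m[, -W, drop = FALSE])
  # treat out-of-image as background: the shifted matrices pad with 0
  per <- m == 1L & (up == 0L | down == 0L | left == 0L | right == 0L)
  binary_raster(per + 0L, pixel_size_of(mask))
}

#' Default dyadic box-counting scales
#'
#' Powers of two from 2 up to an eighth of the shorter image side (extended
#' towards half the side only when fewer than three dyadic scales would
#' fit).  The 1-pixel scale is excluded because N(1) equals the raw pixel
#' count and dominates the log-log fit; boxes larger than about a tenth of
#' the image hold too few counts to inform the small-scale slope that the
#' dimension is defined by, and bias it upward.
#'
#' @param mask A mask or matrix whose dimensions set the range.
#' @param from Smallest scale (default 2).
#' @return Integer vector of box sides.
#' @export
default_box_scales <- function(mask, from = 2) {
  d <- dim(mask)
  lo <- floor(log2(from))
  hi <- max(floor(log2(min(d) / 8)), lo + 2)   # at least 3 dyadic scales
  if (2^hi > min(d) / 2) hi <- floor(log2(min(d) / 2))
  if (hi < lo + 2) stop("image too small for box counting", call. = FALSE)
  2^(seq.int(lo, hi))
}

# OLS of y on x with degenerate-fit handling (constant y => slope 0, R^2 1).
ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate fit: constant predictor", call. = FALSE)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot == 0) 1 else {
    ss_res <- sum((y - (intercept + slope * x))^2)
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Occupancy of each cell of a fixed grid of side r anchored at the top-left
# corner; partial boxes at the right/bottom edges are included.  Returns an
# integer vector over all grid cells (row-major over box rows).
grid_occupancy <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  nbr <- ceiling(H / r); nbc <- ceiling(W / r)
  bi <- (seq_len(H) - 1L) %/% r          # box row of each pixel row
  bj <- (seq_len(W) - 1L) %/% r
  id <- outer(bi * nbc, bj, "+") + 1L    # box id per pixel, 1-based
  tabulate(id[m == 1L], nbins = nbr * nbc)
}

#' Box counting of a binary mask
#'
#' Covers the image with a fixed non-overlapping grid of boxes of side
#' `eps` anchored at the top-left corner (partial boxes at the right and
#' bottom edges included) and counts boxes containing at least one
#' foreground pixel.  The box-counting dimension is the OLS slope of
#' `log N(eps)` against `log(1/eps)`.
#'
#' @param mask A [binary_raster()] or \{0,1\} matrix with at least one
#'   foreground pixel.
#' @param scales Box sides, all in `[1, min(dim))]`; at least 3.  Default
#'   [default_box_scales()].
#' @return An object of class `box_count_result`: `scales`, `counts`,
#'   `slope` (the dimension estimate), `intercept`, `r_squared`.
#' @examples
#' full <- matrix(1L, 64, 64)
#' box_count(full)$slope  # exactly 2
#' @export
box_count <- function(mask, scales = NULL) {
  m <- mask_of(mask)
  if (sum(m) == 0L) stop("box_count: no foreground pixels", call. = FALSE)
  if (is.null(scales)) scales <- default_box_scales(m)
  scales <- as.integer(scales)
  if (length(scales) < 3L) stop("need at least 3 scales", call. = FALSE)
  if (any(scales < 1L) || any(scales > min(dim(m)))) {
    stop("scales must lie in [1, min(dim)]", call. = FALSE)
  }
  scales <- sort(unique(scales))
  counts <- vapply(scales, function(r) sum(grid_occupancy(m, r) > 0L),
                   integer(1))
  fit <- ols_fit(log(1 / scales), log(counts))
  structure(
    list(scales = scales, counts = counts, slope = fit$slope,
         intercept = fit$intercept, r_squared = fit$r_squared),
    class = "box_count_result"
  )
}

#' @export
print.box_count_result <- function(x, ...) {
  cat(sprintf("<box_count> D = %.4f (R2 = %.4f) over %d scales [%d..%d]\n",
              x$slope, x$r_squared, length(x$scales), min(x$scales),
              max(x$scales)))
  invisible(x)
}

#' Fractal Fragmentation Index
#'
#' `FFI = D_A - D_P`: the box-counting dimension of the area set minus that
#' of its inner-boundary perimeter set, both counted on the same fixed grid
#' and scale set.  Values near 1 indicate compact objects (a filled region
#' has `D_A = 2` and a roughly one-dimensional boundary); values near 0
#' indicate small, fragmented objects whose perimeter set approaches the
#' area set; a single-pixel object gives exactly 0.
#'
#' @inheritParams box_count
#' @return An object of class `ffi_result`: `d_area`, `d_perimeter`, `ffi`,
#'   plus the two underlying `box_count_result` fits (`area_fit`,
#'   `perimeter_fit`).
#' @export
compute_ffi <- function(mask, scales = NULL) {
  m <- mask_of(mask)
  if (is.null(scales)) scales <- default_box_scales(m)
  a <- box_count(m, scales)
  p <- box_count(extract_perimeter(m)$mask, scales)
  structure(
    list(d_area = a$slope, d_perimeter = p$slope, ffi = a$slope - p$slope,
         area_fit = a, perimeter_fit = p),
    class = "ffi_result"
  )
}

#' @export
print.ffi_result <- function(x, ...) {
  cat(sprintf("<ffi> FFI = %.4f (D_A = %.4f, D_P = %.4f)\n",
              x$ffi, x$d_area, x$d_perimeter))
  invisible(x)
}
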