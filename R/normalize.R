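#' Min-max standardization of a metric series
#'
#' Maps a series onto `[0, 1]` by `(V - Vmin) / (Vmax - Vmin)`, so that the
#' minimum maps to 0 and the maximum to 1 — used to plot particle and
#' fractal metrics with different units on a common axis.  A constant
#' series, for which the mapping is undefined, returns all zeros with a
#' warning rather than an error so batch reporting over degenerate runs
#' never aborts.  `NA` entries are preserved and ignored when locating the
#' extremes.
#'
#' @param values Numeric vector with at least 2 non-missing values.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @examples
#' standardize(c(2, 4, 6))  # 0, 0.5, 1
#' @export
standardize <- function(values) {
  v <- as.numeric(values)
  obs <- v[!is.na(v)]
  if (length(obs) < 2L) {
    stop("standardize: need at least 2 observed values", call. = FALSE)
  }
  lo <- min(obs); hi <- max(obs)
  if (hi == lo) {
    warning("standardize: constant series, returning zeros", call. = FALSE)
    out <- v
    out[!is.na(v)] <- 0
    return(out)
  }
  (v - lo) / (hi - lo)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties receive mean ranks), as
#' used for the metric-metric association table.  Constant input has no
#' defined rank correlation and returns `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` for degenerate
#'   input.
#' @examples
#' spearman_rho(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not supported",
                                 call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("spearman_rho: constant input, correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
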