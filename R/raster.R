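#' Grayscale raster
#'
#' A minimal in-memory single-band raster: an integer matrix plus the side of
#' a square pixel in metres.  Row 1 is the top of the image and indexing is
#' `values[row, col]`; every function in the package shares this convention.
#'
#' @param values Integer matrix (rectangular, non-empty).
#' @param pixel_size_m Positive side length of a square pixel in metres.
#'   Defaults to 30, the resolution of Landsat-derived global forest-change
#'   layers.
#' @param nodata Optional integer code marking missing pixels.
#' @return An object of class `grayscale_raster` with fields `values`,
#'   `pixel_size_m` and `nodata`.
#' @seealso [binary_raster()], [binarize()], [read_raster()]
#' @export
grayscale_raster <- function(values, pixel_size_m = 30, nodata = NULL) {
  values <- as_value_matrix(values)
  check_pixel_size(pixel_size_m)
  if (!is.null(nodata)) {
    nodata <- as.integer(nodata)
    stopifnot(length(nodata) == 1L, !is.na(nodata))
  }
  structure(
    list(values = values, pixel_size_m = as.numeric(pixel_size_m),
         nodata = nodata),
    class = "grayscale_raster"
  )
}

#' Binary raster
#'
#' The universal input of the fragmentation metrics: a \{0,1\} mask with a
#' pixel size in metres.
#'
#' @param mask Matrix with values strictly in \{0, 1\}.
#' @inheritParams grayscale_raster
#' @return An object of class `binary_raster` with fields `mask` and
#'   `pixel_size_m`.
#' @export
binary_raster <- function(mask, pixel_size_m = 30) {
  mask <- as_value_matrix(mask)
  if (!all(mask == 0L | mask == 1L)) {
    stop("binary_raster: values must be strictly in {0, 1}", call. = FALSE)
  }
  check_pixel_size(pixel_size_m)
  structure(
    list(mask = mask, pixel_size_m = as.numeric(pixel_size_m)),
    class = "binary_raster"
  )
}

as_value_matrix <- function(x) {
  if (!is.matrix(x)) stop("raster values must be a matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("raster must be non-empty", call. = FALSE)
  }
  if (anyNA(x)) stop("raster values must not contain NA", call. = FALSE)
  storage.mode(x) <- "integer"
  x
}

check_pixel_size <- function(pixel_size_m) {
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1L ||
      is.na(pixel_size_m) || pixel_size_m <= 0) {
    stop("pixel_size_m must be a positive number", call. = FALSE)
  }
  invisible(pixel_size_m)
}

# Extract the value matrix from a binary_raster (or validate a bare matrix).
mask_of <- function(x) {
  if (inherits(x, "binary_raster")) return(x$mask)
  if (inherits(x, "grayscale_raster")) {
    stop("expected a binary raster; call binarize() first", call. = FALSE)
  }
  m <- as_value_matrix(x)
  if (!all(m == 0L | m == 1L)) {
    stop("mask values must be in {0, 1}", call. = FALSE)
  }
  m
}

pixel_size_of <- function(x, default = 30) {
  if (inherits(x, c("binary_raster", "grayscale_raster"))) {
    return(x$pixel_size_m)
  }
  default
}

#' @export
print.grayscale_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grayscale_raster> %d x %d, pixel %g m, values %d..%d\n",
              nrow(v), ncol(v), x$pixel_size_m, min(v), max(v)))
  invisible(x)
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("<binary_raster> %d x %d, pixel %g m, %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_m, sum(x$mask)))
  invisible(x)
}

#' @export
dim.grayscale_raster <- function(x) dim(x$values)

#' @export
dim.binary_raster <- function(x) dim(x$mask)

#' Threshold a grayscale raster to a binary mask
#'
#' Mode `">0"` (the default) marks every strictly positive pixel as
#' foreground; mode `">=t"` marks pixels at or above `threshold`, the
#' conventional way of thresholding canopy-percent layers.  Nodata pixels
#' always map to background.
#'
#' @param raster A [grayscale_raster()] (a [binary_raster()] passes through
#'   mode `">0"` unchanged).
#' @param threshold Integer cut-off, required for mode `">=t"`.
#' @param mode `">0"` or `">=t"`.
#' @return A [binary_raster()] with the same shape and pixel size.
#' @examples
#' g <- grayscale_raster(matrix(c(0L, 5L, 0L, 100L), 2, 2))
#' binarize(g)$mask
#' binarize(g, threshold = 25, mode = ">=t")$mask
#' @export
binarize <- function(raster, threshold = NULL, mode = c(">0", ">=t")) {
  mode <- match.arg(mode)
  if (inherits(raster, "binary_raster")) {
    raster <- grayscale_raster(raster$mask, raster$pixel_size_m)
  }
  if (!inherits(raster, "grayscale_raster")) {
    raster <- grayscale_raster(raster)
  }
  v <- raster$values
  if (mode == ">0") {
    m <- (v > 0L)
  } else {
    if (is.null(threshold)) stop("mode \">=t\" requires a threshold",
                                 call. = FALSE)
    if (threshold < min(v) || threshold > max(v)) {
      stop(sprintf("threshold %s outside value range [%d, %d]",
                   format(threshold), min(v), max(v)), call. = FALSE)
    }
    m <- (v >= threshold)
  }
  if (!is.null(raster$nodata)) m[v == raster$nodata] <- FALSE
  binary_raster(m + 0L, raster$pixel_size_m)
}

#' Read a single-band TIFF raster
#'
#' Reads a plain or GeoTIFF single-band image into a [grayscale_raster()].
#' The container carries no coordinate system: inputs are assumed to be in a
#' metric projection already, and the pixel size is taken from the
#' `pixel_size_m` argument (default 30 m).  Multi-band images are rejected.
#'
#' @param path Path to a single-band TIFF file.
#' @param pixel_size_m Pixel side in metres; default 30.
#' @param nodata Optional nodata code to record.
#' @return A [grayscale_raster()].
#' @export
read_raster <- function(path, pixel_size_m = 30, nodata = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read raster: no such file '%s'", path),
         call. = FALSE)
  }
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) {
                    stop(sprintf("cannot read raster '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (length(dim(img)) == 3L) {
    stop(sprintf("expected a single-band image, got %d bands in '%s'",
                 dim(img)[3], path), call. = FALSE)
  }
  grayscale_raster(img, pixel_size_m = pixel_size_m, nodata = nodata)
}

#' Write a raster as a single-band TIFF
#'
#' Values are stored losslessly as 8- or 16-bit integer samples, so
#' `read_raster(write_raster(x))` reproduces the grid bit-exactly for \{0,1\}
#' masks and small-integer grids such as loss-year codes.
#'
#' @param raster A [binary_raster()] or [grayscale_raster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  v <- if (inherits(raster, "binary_raster")) raster$mask else
    as_value_matrix(if (inherits(raster, "grayscale_raster"))
      raster$values else raster)
  if (min(v) < 0L) stop("write_raster: negative values unsupported",
                        call. = FALSE)
  bits <- if (max(v) < 256L) 8L else 16L
  if (max(v) >= 65536L) {
    stop("write_raster: values exceed 16-bit range", call. = FALSE)
  }
  ok <- tryCatch(
    tiff::writeTIFF(v / (2^bits - 1), path, bits.per.sample = bits,
                    compression = "none"),
    error = function(e) {
      stop(sprintf("cannot write raster '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  invisible(path)
}

#' Three-layer forest-change raster stack
#'
#' Bundles the layers of a global forest-change style dataset: a baseline
#' tree-cover mask, a loss-year layer whose codes give the year index of
#' loss (0 = never lost, t = lost in year `years[t]`), and a cumulative
#' regeneration (gain) mask for the whole period.
#'
#' @param cover_baseline [binary_raster()] of baseline tree cover.
#' @param loss_year [grayscale_raster()] of loss-year codes in `0..T`.
#' @param gain_cumulative [binary_raster()] of cumulative gain.
#' @param years Ordered vector of year labels, length `T`.
#' @return An object of class `forest_layer_set`.
#' @export
forest_layer_set <- function(cover_baseline, loss_year, gain_cumulative,
                             years) {
  stopifnot(inherits(cover_baseline, "binary_raster"),
            inherits(loss_year, "grayscale_raster"),
            inherits(gain_cumulative, "binary_raster"))
  if (length(years) < 1L) stop("need at least one year", call. = FALSE)
  dims <- list(dim(cover_baseline), dim(loss_year), dim(gain_cumulative))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("layers must share the same shape", call. = FALSE)
  }
  px <- c(cover_baseline$pixel_size_m, loss_year$pixel_size_m,
          gain_cumulative$pixel_size_m)
  if (diff(range(px)) > 1e-9) {
    stop("layers must share pixel_size_m", call. = FALSE)
  }
  if (max(loss_year$values) > length(years)) {
    stop(sprintf("loss-year code %d exceeds the number of years (%d)",
                 max(loss_year$values), length(years)), call. = FALSE)
  }
  if (min(loss_year$values) < 0L) {
    stop("loss-year codes must be non-negative", call. = FALSE)
  }
  structure(
    list(cover_baseline = cover_baseline, loss_year = loss_year,
         gain_cumulative = gain_cumulative, years = years),
    class = "forest_layer_set"
  )
}

#' @export
print.forest_layer_set <- function(x, ...) {
  cat(sprintf("<forest_layer_set> %d x %d, %d years (%s..%s), pixel %g m\n",
              nrow(x$cover_baseline$mask), ncol(x$cover_baseline$mask),
              length(x$years), x$years[1], x$years[length(x$years)],
              x$cover_baseline$pixel_size_m))
  invisible(x)
}
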