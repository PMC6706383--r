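#' Label connected forest patches
#'
#' Connected-component labelling of a binary mask.  A "particle" is a forest
#' patch: a maximal set of foreground pixels mutually connected under the
#' chosen adjacency.  The default is 8-connectivity (diagonal neighbours
#' count), matching the connectivity used by the local connected fractal
#' dimension.
#'
#' @param mask A [binary_raster()] or \{0,1\} matrix.
#' @param connectivity 4 or 8.
#' @return An object of class `labeled_raster` with fields `labels` (integer
#'   matrix, 0 = background, patch ids contiguous `1..K`), `connectivity`
#'   and `pixel_size_m`.
#' @examples
#' m <- matrix(0L, 3, 3); m[1, 1] <- 1L; m[2, 2] <- 1L
#' max(label_components(m, 8)$labels)  # 1 patch
#' max(label_components(m, 4)$labels)  # 2 patches
#' @export
label_components <- function(mask, connectivity = 8) {
  connectivity <- check_connectivity(connectivity)
  m <- mask_of(mask)
  structure(
    list(labels = cpp_label(m, connectivity), connectivity = connectivity,
         pixel_size_m = pixel_size_of(mask)),
    class = "labeled_raster"
  )
}

check_connectivity <- function(connectivity) {
  if (!connectivity %in% c(4, 8)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  as.integer(connectivity)
}

#' Patch count, area and average patch size
#'
#' Per-patch areas in hectares (pixel count times the pixel area
#' `pixel_size_m^2 / 10000`), together with patch count, total area and
#' average patch size — the particle statistics reported per layer and year.
#'
#' @param labeled A `labeled_raster` from [label_components()].
#' @param pixel_size_m Pixel side in metres; defaults to the value recorded
#'   in `labeled`.
#' @return An object of class `particle_summary`: `count`, `total_area_ha`,
#'   `average_size_ha` (0 when there are no patches) and `sizes_ha`.
#' @export
summarize_particles <- function(labeled, pixel_size_m = NULL) {
  stopifnot(inherits(labeled, "labeled_raster"))
  if (is.null(pixel_size_m)) pixel_size_m <- labeled$pixel_size_m
  check_pixel_size(pixel_size_m)
  lab <- labeled$labels
  k <- max(lab)
  px_ha <- pixel_size_m^2 / 1e4
  sizes <- if (k > 0L) tabulate(lab[lab > 0L], nbins = k) * px_ha else
    numeric(0)
  structure(
    list(count = k, total_area_ha = sum(sizes),
         average_size_ha = if (k > 0L) sum(sizes) / k else 0,
         sizes_ha = sizes),
    class = "particle_summary"
  )
}

#' @export
print.particle_summary <- function(x, ...) {
  cat(sprintf("<particle_summary> %d patches, %.4f ha total, %.4f ha mean\n",
              x$count, x$total_area_ha, x$average_size_ha))
  invisible(x)
}

# Binary dilation by one pixel under the 8-neighbourhood (Chebyshev ball).
dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  shift <- function(dr, dc) {
    s <- matrix(0L, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    s[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    s
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, shift(dr, dc))
  }
  out
}

#' Count loss patches appearing in fresh locations
#'
#' Number of connected components of `new_loss` that do not touch (under
#' 8-adjacency) any pixel of the previously accumulated loss — loss patches
#' opening up in fresh locations rather than extending an existing loss
#' cluster.
#'
#' @param prev_cum_loss [binary_raster()] or mask of loss accumulated up to
#'   the previous year.
#' @param new_loss [binary_raster()] or mask of the current year's loss.
#' @param connectivity Adjacency used to identify patches of `new_loss`.
#' @return Integer count of fresh-location patches.
#' @export
count_new_patches <- function(prev_cum_loss, new_loss, connectivity = 8) {
  prev <- mask_of(prev_cum_loss)
  new <- mask_of(new_loss)
  if (!identical(dim(prev), dim(new))) {
    stop("prev_cum_loss and new_loss must share shape", call. = FALSE)
  }
  lab <- label_components(new, connectivity)$labels
  k <- max(lab)
  if (k == 0L) return(0L)
  halo <- dilate8(prev) > 0L
  touched <- unique(lab[halo & lab > 0L])
  k - length(touched)
}
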