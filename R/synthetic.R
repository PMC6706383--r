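#' Deterministic analytic test figures
#'
#' Small binary geometries with known fractal behaviour, used as analytic
#' anchors: a single pixel (dimension 0), a one-pixel-wide line (dimension
#' 1), a filled rectangle (dimension 2), a hollow frame, a checkerboard and
#' a set of well-separated small squares (a maximally fragmented
#' configuration of fixed total area).
#'
#' @param kind One of `"single_pixel"`, `"h_line"`, `"filled_rect"`,
#'   `"frame"`, `"checkerboard"`, `"scattered_squares"`.
#' @param shape `c(rows, cols)`.
#' @param row Row of the horizontal line (default: middle row).
#' @param height,width Size of the filled rectangle or frame (default: the
#'   full image).
#' @param k,side,gap For `"scattered_squares"`: number of squares, square
#'   side, and minimum empty gap between squares (and to the image edge).
#' @param pixel_size_m Pixel size of the returned raster.
#' @return A [binary_raster()].
#' @export
make_primitive <- function(kind = c("single_pixel", "h_line", "filled_rect",
                                    "frame", "checkerboard",
                                    "scattered_squares"),
                           shape = c(64, 64), row = NULL, height = NULL,
                           width = NULL, k = 9, side = 4, gap = 8,
                           pixel_size_m = 30) {
  kind <- match.arg(kind)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (H < 1L || W < 1L) stop("shape must be positive", call. = FALSE)
  m <- matrix(0L, H, W)
  if (kind == "single_pixel") {
    m[(H + 1L) %/% 2L, (W + 1L) %/% 2L] <- 1L
  } else if (kind == "h_line") {
    r <- if (is.null(row)) (H + 1L) %/% 2L else as.integer(row)
    if (r < 1L || r > H) stop("line row outside image", call. = FALSE)
    m[r, ] <- 1L
  } else if (kind %in% c("filled_rect", "frame")) {
    h <- if (is.null(height)) H else as.integer(height)
    w <- if (is.null(width)) W else as.integer(width)
    if (h > H || w > W || h < 1L || w < 1L) {
      stop("rectangle exceeds shape", call. = FALSE)
    }
    r0 <- (H - h) %/% 2L + 1L; c0 <- (W - w) %/% 2L + 1L
    m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
    if (kind == "frame" && h > 2L && w > 2L) {
      m[(r0 + 1L):(r0 + h - 2L), (c0 + 1L):(c0 + w - 2L)] <- 0L
    }
  } else if (kind == "checkerboard") {
    m <- (outer(seq_len(H), seq_len(W), "+") %% 2L == 0L) + 0L
    storage.mode(m) <- "integer"
  } else { # scattered_squares
    per_row <- ceiling(sqrt(k))
    pitch <- side + gap
    need <- gap + per_row * pitch
    if (need > min(H, W) + pitch - side - gap) {
      # last square ends at gap + (per_row-1)*pitch + side
      last <- gap + (per_row - 1L) * pitch + side
      if (last > min(H, W) - gap) {
        stop("scattered squares exceed shape", call. = FALSE)
      }
    }
    placed <- 0L
    for (i in seq_len(per_row)) {
      for (j in seq_len(per_row)) {
        if (placed >= k) break
        r0 <- gap + (i - 1L) * pitch + 1L
        c0 <- gap + (j - 1L) * pitch + 1L
        if (r0 + side - 1L > H - gap || c0 + side - 1L > W - gap) {
          stop("scattered squares exceed shape", call. = FALSE)
        }
        m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 1L
        placed <- placed + 1L
      }
    }
  }
  binary_raster(m, pixel_size_m)
}

#' Configuration of a synthetic forest-change scenario
#'
#' Parameters of the generator behind [generate_scenario()].  The defaults
#' describe a mid-elevation forested landscape observed at Landsat
#' resolution over a 14-year record: a 128 x 128 grid of 30 m pixels
#' (about 1,475 ha), 60% baseline tree cover, four loss events per year
#' with log-normally distributed patch sizes averaging roughly a dozen
#' pixels (about 1 ha, the size regime of reported forest-loss sites), an
#' even chance that a new loss patch extends an existing loss cluster, and
#' regeneration over 15% of the cumulative loss.
#'
#' @param shape `c(rows, cols)` of the rasters.
#' @param pixel_size_m Pixel side in metres.
#' @param n_years Number of loss years `T`.
#' @param cover_fraction Baseline tree-cover fraction in `(0, 1]`.
#' @param patches_per_year Loss patches placed each year.
#' @param patch_size_meanlog,patch_size_sdlog Log-normal patch-size
#'   distribution, in pixels.
#' @param clustering_prob Probability in `[0, 1]` that a new loss patch
#'   seeds adjacent to previously accumulated loss rather than at a fresh
#'   location.
#' @param gain_fraction Fraction in `[0, 1]` of cumulative loss regenerated
#'   by the end of the period.
#' @param min_gap Minimum Chebyshev distance (pixels) between a
#'   fresh-location patch seed and prior loss.
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(shape = c(128, 128), pixel_size_m = 30,
                            n_years = 14, cover_fraction = 0.6,
                            patches_per_year = 4,
                            patch_size_meanlog = log(12),
                            patch_size_sdlog = 0.7,
                            clustering_prob = 0.5, gain_fraction = 0.15,
                            min_gap = 3, seed = 1) {
  cfg <- list(shape = as.integer(shape), pixel_size_m = pixel_size_m,
              n_years = as.integer(n_years),
              cover_fraction = cover_fraction,
              patches_per_year = as.integer(patches_per_year),
              patch_size_meanlog = patch_size_meanlog,
              patch_size_sdlog = patch_size_sdlog,
              clustering_prob = clustering_prob,
              gain_fraction = gain_fraction,
              min_gap = as.integer(min_gap), seed = as.integer(seed))
  stopifnot(length(cfg$shape) == 2L, all(cfg$shape >= 8L),
            cfg$n_years >= 1L,
            cfg$cover_fraction > 0, cfg$cover_fraction <= 1,
            cfg$patches_per_year >= 1L,
            cfg$clustering_prob >= 0, cfg$clustering_prob <= 1,
            cfg$gain_fraction >= 0, cfg$gain_fraction <= 1,
            cfg$min_gap >= 1L)
  check_pixel_size(cfg$pixel_size_m)
  class(cfg) <- "scenario_config"
  cfg
}

# Smoothed standard-normal noise: separable moving-average smoothing with
# edge replication, applied three times (approximately Gaussian).
smooth_noise <- function(H, W, window = NULL) {
  if (is.null(window)) window <- max(3L, 2L * (min(H, W) %/% 16L) + 1L)
  z <- matrix(rnorm(H * W), H, W)
  blur1d <- function(mat, w) {
    h <- w %/% 2L
    padded <- rbind(mat[rep(1L, h), , drop = FALSE], mat,
                    mat[rep(nrow(mat), h), , drop = FALSE])
    sm <- apply(padded, 2, function(col)
      stats::filter(col, rep(1 / w, w), sides = 2))
    sm[(h + 1L):(h + nrow(mat)), , drop = FALSE]
  }
  for (i in 1:3) {
    z <- blur1d(z, window)
    z <- t(blur1d(t(z), window))
  }
  z
}

dilate_cheb <- function(m, k) {
  out <- m
  for (i in seq_len(k)) out <- dilate8(out)
  out
}

#' Generate a synthetic forest-change scenario with ground truth
#'
#' Builds a three-layer stack emulating a global forest-change dataset:
#' a compact baseline cover mask obtained by thresholding smoothed noise at
#' the configured cover fraction; `n_years` of loss patches grown as
#' connected blobs by random accretion inside the remaining cover, seeded
#' adjacent to prior loss with probability `clustering_prob` and at fresh
#' locations (at least `min_gap` pixels from prior loss) otherwise; and a
#' cumulative gain layer drawn as a random subset of the final loss.
#' Patches placed in the same year never touch each other, so per-year
#' patch counts and pixel areas are exact ground truth for the particle
#' statistics.  Fully reproducible from `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `layers` (a [forest_layer_set()]) and
#'   `truth`, where `truth` has `per_year` (data frame: `year`,
#'   `n_patches`, `loss_px`, `n_fresh`), `patches` (data frame: `year`,
#'   `size_px`, `fresh`), `baseline_px` and `gain_px`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  H <- config$shape[1]; W <- config$shape[2]
  withr::with_seed(config$seed, {
    field <- smooth_noise(H, W)
    thr <- quantile(field, 1 - config$cover_fraction, names = FALSE)
    cover <- field >= thr
    lost <- matrix(0L, H, W)
    patch_year <- integer(0); patch_size <- integer(0)
    patch_fresh <- logical(0)
    nbr_offsets <- expand.grid(dr = -1:1, dc = -1:1)
    nbr_offsets <- nbr_offsets[!(nbr_offsets$dr == 0 & nbr_offsets$dc == 0), ]

    for (y in seq_len(config$n_years)) {
      prior <- lost > 0L
      prior_halo <- dilate8(prior + 0L) > 0L       # prior loss + 1 px ring
      prior_far <- dilate_cheb(prior + 0L, config$min_gap) > 0L
      blocked <- matrix(FALSE, H, W)               # this year's patches + ring
      for (j in seq_len(config$patches_per_year)) {
        target <- max(1L, as.integer(round(
          rlnorm(1, config$patch_size_meanlog, config$patch_size_sdlog))))
        avail <- cover & lost == 0L & !blocked
        if (!any(avail)) {
          stop(sprintf("tree cover exhausted in year %d", y), call. = FALSE)
        }
        cluster_mode <- runif(1) < config$clustering_prob && any(prior)
        cand <- if (cluster_mode) which(avail & prior_halo & !prior) else
          which(avail & !prior_far)
        if (length(cand) == 0L) cand <- which(avail)
        seed_idx <- cand[sample.int(length(cand), 1L)]
        # grow a connected blob by random accretion within available cover
        in_patch <- rep(FALSE, H * W)
        in_patch[seed_idx] <- TRUE
        pixels <- seed_idx
        neighbors_of <- function(idx) {
          r <- (idx - 1L) %% H + 1L; c <- (idx - 1L) %/% H + 1L
          nr <- outer(r, nbr_offsets$dr, "+")
          nc <- outer(c, nbr_offsets$dc, "+")
          ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
          unique((nc[ok] - 1L) * H + nr[ok])
        }
        frontier <- setdiff(neighbors_of(seed_idx), seed_idx)
        frontier <- frontier[avail[frontier]]
        while (length(pixels) < target && length(frontier) > 0L) {
          pick <- frontier[sample.int(length(frontier), 1L)]
          in_patch[pick] <- TRUE
          pixels <- c(pixels, pick)
          frontier <- setdiff(frontier, pick)
          nb <- neighbors_of(pick)
          nb <- nb[avail[nb] & !in_patch[nb]]
          frontier <- unique(c(frontier, nb))
        }
        lost[pixels] <- y
        # keep same-year patches disjoint and non-adjacent
        ring <- unique(unlist(lapply(pixels, neighbors_of)))
        blocked[c(pixels, ring)] <- TRUE
        patch_year <- c(patch_year, y)
        patch_size <- c(patch_size, length(pixels))
        patch_fresh <- c(patch_fresh, !any(prior_halo[pixels]))
      }
    }

    loss_idx <- which(lost > 0L)
    n_gain <- as.integer(round(config$gain_fraction * length(loss_idx)))
    gain <- matrix(0L, H, W)
    if (n_gain > 0L) {
      gain[loss_idx[sample.int(length(loss_idx), n_gain)]] <- 1L
    }

    years <- seq_len(config$n_years)
    layers <- forest_layer_set(
      cover_baseline = binary_raster(cover + 0L, config$pixel_size_m),
      loss_year = grayscale_raster(lost, config$pixel_size_m),
      gain_cumulative = binary_raster(gain, config$pixel_size_m),
      years = years
    )
    per_year <- data.frame(
      year = years,
      n_patches = vapply(years, function(y) sum(patch_year == y),
                         integer(1)),
      loss_px = vapply(years, function(y) sum(patch_size[patch_year == y]),
                       integer(1)),
      n_fresh = vapply(years, function(y) sum(patch_fresh[patch_year == y]),
                       integer(1))
    )
    list(
      layers = layers,
      truth = list(
        per_year = per_year,
        patches = data.frame(year = patch_year, size_px = patch_size,
                             fresh = patch_fresh),
        baseline_px = sum(cover),
        gain_px = n_gain
      ),
      config = config
    )
  })
}

#' Write a scenario to a directory of TIFF layers plus truth tables
#'
#' Emits `cover.tif`, `loss_year.tif` and `gain.tif` alongside
#' `truth_per_year.csv`, `truth_patches.csv` and a key-value `config.txt`,
#' mimicking the on-disk layout of a real three-layer stack.
#'
#' @param scenario Result of [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(scenario$layers$cover_baseline, file.path(dir, "cover.tif"))
  write_raster(scenario$layers$loss_year, file.path(dir, "loss_year.tif"))
  write_raster(scenario$layers$gain_cumulative, file.path(dir, "gain.tif"))
  write.csv(scenario$truth$per_year, file.path(dir, "truth_per_year.csv"),
            row.names = FALSE)
  write.csv(scenario$truth$patches, file.path(dir, "truth_patches.csv"),
            row.names = FALSE)
  cfg <- scenario$config
  lines <- vapply(names(cfg), function(nm)
    sprintf("%s = %s", nm, paste(cfg[[nm]], collapse = ",")), character(1))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a scenario directory back into a layer stack
#'
#' @param dir Directory written by [write_scenario()] (or a real stack laid
#'   out the same way: `cover.tif`, `loss_year.tif`, `gain.tif`).
#' @param pixel_size_m Pixel size; default 30.
#' @param n_years Number of years; defaults to the maximum loss-year code.
#' @return A [forest_layer_set()].
#' @export
read_scenario <- function(dir, pixel_size_m = 30, n_years = NULL) {
  cover <- read_raster(file.path(dir, "cover.tif"), pixel_size_m)
  loss <- read_raster(file.path(dir, "loss_year.tif"), pixel_size_m)
  gain <- read_raster(file.path(dir, "gain.tif"), pixel_size_m)
  if (is.null(n_years)) n_years <- max(1L, max(loss$values))
  forest_layer_set(binarize(cover), loss, binarize(gain),
                   years = seq_len(n_years))
}
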