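#' Masks for one analysis year
#'
#' Derives the per-year binary masks from the three-layer stack:
#' `loss` (pixels whose loss-year code equals `t`), `cumulative_loss`
#' (codes in `1..t`) and `tree_cover` (baseline cover minus cumulative
#' loss).  Gain is analyzed only cumulatively and is never re-added to
#' yearly tree cover, so the tree-cover series declines monotonically.
#'
#' @param layers A [forest_layer_set()].
#' @param t Year index in `1..T`.
#' @return A list of [binary_raster()]s: `tree_cover`, `loss`,
#'   `cumulative_loss`.
#' @export
derive_yearly_masks <- function(layers, t) {
  stopifnot(inherits(layers, "forest_layer_set"))
  T_ <- length(layers$years)
  t <- as.integer(t)
  if (t < 1L || t > T_) stop("year index out of range", call. = FALSE)
  codes <- layers$loss_year$values
  if (max(codes) > T_) {
    stop("loss-year codes exceed the number of years", call. = FALSE)
  }
  px <- layers$cover_baseline$pixel_size_m
  loss <- (codes == t) + 0L
  cum <- (codes >= 1L & codes <= t) + 0L
  cover <- ((layers$cover_baseline$mask == 1L) & (cum == 0L)) + 0L
  list(tree_cover = binary_raster(cover, px),
       loss = binary_raster(loss, px),
       cumulative_loss = binary_raster(cum, px))
}

#' Time-series analysis configuration
#'
#' @param box_scales Box-counting scales; `NULL` for dyadic defaults per
#'   image ([default_box_scales()]).
#' @param lcfd_scales Window sides for the local connected fractal
#'   dimension; odd, increasing.  The default 3..21 keeps full maps fast on
#'   typical scene sizes.
#' @param lcfd_border Border policy for the LCFD scalar (`"exclude"`
#'   recommended).
#' @param lacunarity_scales Lacunarity box sides; `NULL` for dyadic
#'   defaults ([default_lacunarity_scales()]).
#' @param lacunarity_method `"exact"` or `"tug_of_war"`.
#' @param s1,s2 Tug-of-War sketch sizes.
#' @param seed Seed for the sketch estimator.
#' @param connectivity Patch connectivity, 4 or 8.
#' @return A `timeseries_config` list.
#' @export
timeseries_config <- function(box_scales = NULL,
                              lcfd_scales = seq(3L, 21L, 2L),
                              lcfd_border = "exclude",
                              lacunarity_scales = NULL,
                              lacunarity_method = c("exact", "tug_of_war"),
                              s1 = 100, s2 = 5, seed = 1,
                              connectivity = 8) {
  structure(
    list(box_scales = box_scales, lcfd_scales = as.integer(lcfd_scales),
         lcfd_border = match.arg(lcfd_border, c("exclude", "clip")),
         lacunarity_scales = lacunarity_scales,
         lacunarity_method = match.arg(lacunarity_method),
         s1 = s1, s2 = s2, seed = as.integer(seed),
         connectivity = check_connectivity(connectivity)),
    class = "timeseries_config"
  )
}

# All metrics for a single mask; empty or degenerate layers yield NA metrics
# plus log lines instead of aborting the run.
layer_metrics <- function(mask, config, seed_offset = 0L) {
  m <- mask$mask
  px <- mask$pixel_size_m
  log <- character(0)
  area_ha <- sum(m) * px^2 / 1e4
  lab <- label_components(mask, config$connectivity)
  ps <- summarize_particles(lab)
  out <- list(area_ha = area_ha, patch_count = ps$count,
              average_size_ha = ps$average_size_ha,
              ffi = NA_real_, d_area = NA_real_, d_perimeter = NA_real_,
              mean_lcfd = NA_real_, lambda_aggregate = NA_real_)
  if (sum(m) == 0L) {
    return(list(metrics = out, log = "empty mask: fractal metrics skipped"))
  }
  fb <- tryCatch(compute_ffi(mask, config$box_scales),
                 error = function(e) conditionMessage(e))
  if (is.character(fb)) log <- c(log, paste("ffi:", fb)) else {
    out$ffi <- fb$ffi; out$d_area <- fb$d_area
    out$d_perimeter <- fb$d_perimeter
  }
  lc <- tryCatch(
    lcfd_map(mask, scales = config$lcfd_scales,
             border_policy = config$lcfd_border),
    error = function(e) conditionMessage(e))
  if (is.character(lc)) log <- c(log, paste("lcfd:", lc)) else {
    if (lc$n_pixels == 0L) {
      log <- c(log, "lcfd: no pixels counted under border policy")
    } else out$mean_lcfd <- lc$mean
  }
  lp <- tryCatch(
    lacunarity_profile(mask, scales = config$lacunarity_scales,
                       method = config$lacunarity_method,
                       s1 = config$s1, s2 = config$s2,
                       seed = config$seed + seed_offset),
    error = function(e) conditionMessage(e))
  if (is.character(lp)) log <- c(log, paste("lacunarity:", lp)) else {
    out$lambda_aggregate <- lp$aggregate
  }
  list(metrics = out, log = log)
}

#' Run the yearly fragmentation time series
#'
#' For every year derives the tree-cover, yearly-loss and cumulative-loss
#' masks, computes the particle statistics and the three fractal indicators
#' for each, analyzes the cumulative gain layer once, standardizes every
#' metric series onto `[0, 1]` across years, and assembles the Spearman
#' rank-correlation matrix of the metric series.  Deterministic given the
#' configuration (the sketch estimator is seeded per layer and year).
#'
#' @param layers A [forest_layer_set()].
#' @param config A [timeseries_config()].
#' @return An object of class `timeseries_report`: `report` (long data
#'   frame with columns `year`, `layer`, `metric`, `value`,
#'   `standardized`), `spearman` (correlation matrix over complete,
#'   non-constant series), `config`, `log`.
#' @export
run_timeseries <- function(layers, config = timeseries_config()) {
  stopifnot(inherits(layers, "forest_layer_set"),
            inherits(config, "timeseries_config"))
  T_ <- length(layers$years)
  layer_names <- c("tree_cover", "loss", "cumulative_loss")
  rows <- list()
  log <- character(0)
  for (t in seq_len(T_)) {
    masks <- derive_yearly_masks(layers, t)
    for (ln in layer_names) {
      res <- layer_metrics(masks[[ln]], config,
                           seed_offset = t * 100L + match(ln, layer_names))
      if (length(res$log)) {
        log <- c(log, sprintf("year %s %s: %s", layers$years[t], ln,
                              res$log))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        year = layers$years[t], layer = ln,
        metric = names(res$metrics),
        value = unlist(res$metrics, use.names = FALSE))
    }
  }
  gres <- layer_metrics(layers$gain_cumulative, config, seed_offset = 9999L)
  if (length(gres$log)) log <- c(log, sprintf("gain: %s", gres$log))
  rows[[length(rows) + 1L]] <- data.frame(
    year = layers$years[T_], layer = "gain",
    metric = names(gres$metrics),
    value = unlist(gres$metrics, use.names = FALSE))
  report <- do.call(rbind, rows)
  report$standardized <- NA_real_

  # standardize each yearly (layer, metric) series across years
  for (ln in layer_names) {
    for (met in unique(report$metric)) {
      sel <- report$layer == ln & report$metric == met
      vals <- report$value[sel]
      if (sum(!is.na(vals)) < 2L) next
      std <- withCallingHandlers(
        standardize(vals),
        warning = function(w) {
          log <<- c(log, sprintf("standardize %s/%s: %s", ln, met,
                                 conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      report$standardized[sel] <- std
    }
  }

  # Spearman matrix over complete, non-constant yearly metric series
  wide <- list()
  for (ln in layer_names) {
    for (met in unique(report$metric)) {
      sel <- report$layer == ln & report$metric == met
      v <- report$value[sel][order(report$year[sel])]
      if (length(v) >= 3L && !anyNA(v) && sd(v) > 0) {
        wide[[paste(ln, met, sep = ".")]] <- v
      }
    }
  }
  spearman <- if (length(wide) >= 2L) {
    mat <- do.call(cbind, wide)
    cor(mat, method = "spearman")
  } else NULL

  structure(list(report = report, spearman = spearman, config = config,
                 years = layers$years, log = log),
            class = "timeseries_report")
}

#' @export
print.timeseries_report <- function(x, ...) {
  cat(sprintf("<timeseries_report> %d years, %d rows, %d log entries\n",
              length(x$years), nrow(x$report), length(x$log)))
  invisible(x)
}

#' Write a time-series report to CSV files
#'
#' Emits `report.csv` (long format: year, layer, metric, value,
#' standardized), `spearman.csv` (correlation matrix with series names as
#' headers), `run_config.txt` (key-value echo of the configuration) and
#' `run_log.txt`.
#'
#' @param x A `timeseries_report` from [run_timeseries()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "timeseries_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$report, file.path(dir, "report.csv"), row.names = FALSE)
  if (!is.null(x$spearman)) {
    write.csv(as.data.frame(x$spearman), file.path(dir, "spearman.csv"))
  }
  cfg <- x$config
  lines <- vapply(names(cfg), function(nm)
    sprintf("%s = %s", nm,
            if (is.null(cfg[[nm]])) "auto" else
              paste(cfg[[nm]], collapse = ",")), character(1))
  writeLines(lines, file.path(dir, "run_config.txt"))
  writeLines(if (length(x$log)) x$log else "clean run",
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
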