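# Independent brute-force oracles, deliberately written without reusing any
# package internals: plain loops and a literal transcription of the defining
# formulas.

# Box count by an exhaustive per-box scan.
naive_box_count <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  n <- 0L
  for (r0 in seq(1L, H, by = r)) {
    for (c0 in seq(1L, W, by = r)) {
      blk <- m[r0:min(H, r0 + r - 1L), c0:min(W, c0 + r - 1L), drop = FALSE]
      if (any(blk == 1L)) n <- n + 1L
    }
  }
  n
}

# Connected mass by breadth-first search restricted to the eps-window.
naive_connected_mass <- function(m, seed, eps) {
  H <- nrow(m); W <- ncol(m)
  h <- eps %/% 2L
  rlo <- max(1L, seed[1] - h); rhi <- min(H, seed[1] + h)
  clo <- max(1L, seed[2] - h); chi <- min(W, seed[2] + h)
  seen <- matrix(FALSE, H, W)
  seen[seed[1], seed[2]] <- TRUE
  queue <- list(seed)
  count <- 1L
  while (length(queue) > 0L) {
    px <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nr <- px[1] + dr; nc <- px[2] + dc
      if (nr < rlo || nr > rhi || nc < clo || nc > chi) next
      if (!seen[nr, nc] && m[nr, nc] == 1L) {
        seen[nr, nc] <- TRUE
        count <- count + 1L
        queue[[length(queue) + 1L]] <- c(nr, nc)
      }
    }
  }
  count
}

# Literal three-line transcription of the lacunarity definition:
# Lambda = N(r) * Z^2 / L^2 with Z^2 = sum p(r,i)^2, L^2 = (sum p(r,i))^2.
naive_lacunarity <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  p <- c()
  for (r0 in seq(1L, H, by = r)) {
    for (c0 in seq(1L, W, by = r)) {
      p <- c(p, sum(m[r0:min(H, r0 + r - 1L),
                      c0:min(W, c0 + r - 1L), drop = FALSE]))
    }
  }
  length(p) * sum(p^2) / sum(p)^2
}

# Log-log OLS slope, written out longhand.
naive_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

random_mask <- function(H, W, p = 0.3, seed = 1) {
  withr::with_seed(seed, matrix(as.integer(runif(H * W) < p), H, W))
}

expect_binary_raster <- function(x) {
  testthat::expect_s3_class(x, "binary_raster")
  testthat::expect_true(all(x$mask %in% c(0L, 1L)))
}
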