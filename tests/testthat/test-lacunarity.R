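test_that("box occupancies cover the fixed grid with partial edge boxes", {
  full4 <- matrix(1L, 4, 4)
  expect_equal(box_occupancy(full4, 2), rep(4L, 4))
  one <- matrix(0L, 4, 4); one[1, 1] <- 1L
  expect_equal(sort(box_occupancy(one, 2)), c(0L, 0L, 0L, 1L))
  m6 <- matrix(1L, 6, 6)
  occ <- box_occupancy(m6, 4)
  expect_length(occ, 4)                  # partial boxes of widths 4 and 2
  expect_equal(sort(occ), c(4L, 8L, 8L, 16L))
  expect_error(box_occupancy(m6, 7), "\\[1, min\\(dim\\)\\]")
})

test_that("exact lacunarity matches closed forms and the transcription", {
  full <- matrix(1L, 32, 32)
  for (r in c(2, 4, 8)) expect_equal(exact_lacunarity(full, r), 1.0)
  # all mass confined to one box of an N-box grid attains Lambda = N
  conf <- matrix(0L, 8, 8); conf[1:2, 1:2] <- 1L
  expect_equal(exact_lacunarity(conf, 4), 4.0)
  conf2 <- matrix(0L, 16, 16); conf2[1:3, 2:4] <- 1L
  expect_equal(exact_lacunarity(conf2, 4), 16.0)
  expect_error(exact_lacunarity(matrix(0L, 8, 8), 2), "empty")
  for (seed in 1:5) {
    m <- random_mask(32, 32, p = 0.3, seed = seed)
    for (r in c(2, 3, 5, 8)) {
      expect_equal(exact_lacunarity(m, r), naive_lacunarity(m, r))
    }
  }
})

test_that("lacunarity is at least 1 on non-empty masks", {
  for (seed in 1:100) {
    m <- random_mask(20, 20, p = runif(1, 0.02, 0.9), seed = seed)
    if (sum(m) == 0) next
    r <- sample(1:10, 1)
    expect_gte(exact_lacunarity(m, r), 1.0)
  }
})

test_that("tug-of-war sketch is exact for one box, seeded, and accurate", {
  for (s in c(1, 7, 99)) {
    expect_equal(tow_second_moment(5, 10, 3, seed = s), 25)
  }
  a <- tow_second_moment(c(3, 4), 1000, 5, seed = 42)
  b <- tow_second_moment(c(3, 4), 1000, 5, seed = 42)
  expect_identical(a, b)
  expect_lt(abs(a - 25) / 25, 0.05)
  # unbiasedness: average over many seeds converges to Z^2
  for (p in list(c(3, 4), c(1, 1, 1, 10), 0:6)) {
    z2 <- sum(p^2)
    est <- vapply(1:300, function(s) tow_second_moment(p, 20, 1, seed = s),
                  numeric(1))
    expect_lt(abs(mean(est) - z2) / z2, 0.1)
  }
})

test_that("profiles aggregate per-scale values and sketch tracks exact", {
  full <- matrix(1L, 32, 32)
  prof <- lacunarity_profile(full, c(2, 4, 8))
  expect_equal(prof$lambdas, c(1, 1, 1))
  expect_equal(prof$aggregate, 1.0)
  m <- random_mask(64, 64, p = 0.25, seed = 13)
  ex <- lacunarity_profile(m, c(2, 4, 8, 16))
  # the sketch's relative standard error is ~sqrt(2/s1) per group mean
  # (~2.5% at s1 = 2000 after the median of 5); 10% is a ~4-sigma band
  tw <- lacunarity_profile(m, c(2, 4, 8, 16), method = "tug_of_war",
                           s1 = 2000, s2 = 5, seed = 1)
  expect_true(all(abs(tw$lambdas - ex$lambdas) / ex$lambdas < 0.10))
  expect_identical(
    tw$lambdas,
    lacunarity_profile(m, c(2, 4, 8, 16), method = "tug_of_war",
                       s1 = 2000, s2 = 5, seed = 1)$lambdas)
})

test_that("concentrating fixed mass raises aggregate lacunarity", {
  # Lambda is a concentration functional: confining the same total area to
  # one compact square yields a higher aggregate than spreading it across
  # well-separated small squares (the confined-box closed form Lambda = N
  # is the extreme case).  Both values are cross-checked against the
  # literal transcription oracle.
  compact <- make_primitive("filled_rect", c(64, 64), height = 12,
                            width = 12)$mask
  scattered <- make_primitive("scattered_squares", c(64, 64), k = 9,
                              side = 4, gap = 8)$mask
  scales <- c(2, 4, 8, 16)
  agg <- function(m) mean(vapply(scales, function(r)
    naive_lacunarity(m, r), numeric(1)))
  expect_equal(lacunarity_profile(compact, scales)$aggregate, agg(compact))
  expect_equal(lacunarity_profile(scattered, scales)$aggregate,
               agg(scattered))
  expect_gt(lacunarity_profile(compact, scales)$aggregate,
            lacunarity_profile(scattered, scales)$aggregate)
})
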