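test_that("primitive fixtures have the advertised geometry", {
  l <- make_primitive("h_line", c(65, 65))
  expect_equal(sum(l$mask), 65)
  expect_equal(sum(rowSums(l$mask) > 0), 1)
  expect_equal(sum(make_primitive("filled_rect", c(12, 9))$mask), 12 * 9)
  sc <- make_primitive("scattered_squares", c(64, 64), k = 9, side = 4,
                       gap = 8)
  expect_equal(max(label_components(sc)$labels), 9)
  expect_true(all(summarize_particles(label_components(sc))$sizes_ha ==
                    16 * 900 / 1e4))
  cb <- make_primitive("checkerboard", c(8, 8))
  expect_equal(sum(cb$mask), 32)
  expect_error(make_primitive("filled_rect", c(8, 8), height = 20),
               "exceeds")
  expect_error(make_primitive("scattered_squares", c(16, 16), k = 9,
                              side = 4, gap = 8), "exceed")
})

test_that("scenarios are reproducible and hit the configured cover", {
  cfg <- scenario_config(shape = c(64, 64), n_years = 4, seed = 31,
                         patches_per_year = 3)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$layers$loss_year$values, b$layers$loss_year$values)
  expect_identical(a$layers$cover_baseline$mask, b$layers$cover_baseline$mask)
  expect_identical(a$truth$per_year, b$truth$per_year)
  frac <- sum(a$layers$cover_baseline$mask) / (64 * 64)
  expect_lt(abs(frac - cfg$cover_fraction), 0.02)
  # distinct seeds give distinct landscapes
  c_ <- generate_scenario(scenario_config(shape = c(64, 64), n_years = 4,
                                          seed = 32, patches_per_year = 3))
  expect_false(identical(a$layers$cover_baseline$mask,
                         c_$layers$cover_baseline$mask))
})

test_that("particle analysis reproduces scenario truth exactly", {
  for (seed in c(2, 17)) {
    scn <- generate_scenario(scenario_config(shape = c(96, 96), n_years = 5,
                                             seed = seed))
    codes <- scn$layers$loss_year$values
    for (t in seq_len(5)) {
      masks <- derive_yearly_masks(scn$layers, t)
      ps <- summarize_particles(label_components(masks$loss))
      expect_equal(ps$count, scn$truth$per_year$n_patches[t])
      expect_equal(sort(round(ps$sizes_ha / 0.09)),
                   sort(scn$truth$patches$size_px[
                     scn$truth$patches$year == t]))
      prev <- (codes >= 1L & codes < t) + 0L
      expect_equal(count_new_patches(prev, masks$loss),
                   scn$truth$per_year$n_fresh[t])
    }
    expect_equal(sum(scn$layers$gain_cumulative$mask), scn$truth$gain_px)
    expect_true(all(scn$layers$gain_cumulative$mask[codes == 0L] == 0L))
  }
})

test_that("clustering probability controls fresh-location placement", {
  scn0 <- generate_scenario(scenario_config(shape = c(96, 96), n_years = 5,
                                            clustering_prob = 0, seed = 5))
  expect_equal(scn0$truth$per_year$n_fresh, scn0$truth$per_year$n_patches)
  scn1 <- generate_scenario(scenario_config(shape = c(96, 96), n_years = 5,
                                            clustering_prob = 1, seed = 5))
  expect_true(all(scn1$truth$per_year$n_fresh[-1] <= 1))
})

test_that("scenario round-trips through its on-disk layout", {
  dir <- withr::local_tempdir()
  scn <- generate_scenario(scenario_config(shape = c(48, 48), n_years = 3,
                                           seed = 9))
  write_scenario(scn, dir)
  expect_true(all(file.exists(file.path(
    dir, c("cover.tif", "loss_year.tif", "gain.tif",
           "truth_per_year.csv", "config.txt")))))
  back <- read_scenario(dir)
  expect_identical(back$loss_year$values, scn$layers$loss_year$values)
  expect_identical(back$cover_baseline$mask, scn$layers$cover_baseline$mask)
  expect_equal(length(back$years), 3)
})
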