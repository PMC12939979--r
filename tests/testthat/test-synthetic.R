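test_that("the default generator reproduces the study geometry", {
  gen <- generate_spectra(synthetic_spec(seed = 1))
  expect_equal(dim(gen$dataset$reflectance), c(420, 351))
  expect_equal(gen$dataset$grid$values[c(1, 351)], c(400, 1800))
  expect_length(gen$truth$informative_wavelengths, 5)
  expect_true(all(gen$dataset$targets$tvbn > 0))
})

test_that("noise-free linear response is exactly affine in the amplitudes", {
  spec <- synthetic_spec(n_samples = 100, noise_sd = 0, scatter_slope_sd = 0,
                         scatter_offset_sd = 0, target_noise_frac = 0,
                         seed = 2)
  gen <- generate_spectra(spec)
  yv <- gen$dataset$targets$tvbn
  r2 <- function(fit) 1 - sum(residuals(fit)^2) / sum((yv - mean(yv))^2)
  s <- rowSums(gen$truth$latent_amplitudes[, gen$truth$informative_idx])
  expect_equal(r2(lm(yv ~ s)), 1, tolerance = 1e-12)
  # full-rank linear fit on the amplitude columns is perfect too
  expect_equal(r2(lm(yv ~ gen$truth$latent_amplitudes)), 1, tolerance = 1e-12)
  # the affine map hits the target range exactly
  expect_equal(range(gen$dataset$targets$tvbn), c(6.65, 66.05))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_spectra(synthetic_spec(n_samples = 50, seed = 7))
  b <- generate_spectra(synthetic_spec(n_samples = 50, seed = 7))
  expect_identical(a, b)
  c_ <- generate_spectra(synthetic_spec(n_samples = 50, seed = 8))
  expect_false(identical(a$dataset$reflectance, c_$dataset$reflectance))
})

test_that("planted bands dominate a univariate correlation screen", {
  for (s in c(1, 7)) {
    gen <- generate_spectra(synthetic_spec(seed = s))
    cors <- abs(cor(gen$dataset$reflectance, gen$dataset$targets$tvbn))
    rk <- rank(cors) / length(cors)
    wins <- informative_windows(gen$truth, gen$dataset$grid)
    for (w in wins) expect_gt(max(rk[w]), 0.9)
  }
})

test_that("storage series drift is monotone and widens combined ranges", {
  base <- synthetic_spec(n_samples = 240, noise_sd = 0, scatter_slope_sd = 0,
                         scatter_offset_sd = 0, target_noise_frac = 0,
                         seed = 4)
  days <- c(0, 1, 3, 5, 7, 8, 9, 10)

  # zero drift: per-day means identical by construction
  flat <- storage_series(base, days, drift_per_day = 0)
  means0 <- tapply(flat$dataset$targets$tvbn, flat$dataset$targets$day, mean)
  expect_true(max(means0) - min(means0) < 1e-12)

  # positive drift, no noise: strictly increasing per-day means
  drift <- storage_series(base, days, drift_per_day = 0.05)
  means <- tapply(drift$dataset$targets$tvbn, drift$dataset$targets$day, mean)
  expect_true(all(diff(means) > 0))

  # two storage temperatures: the pooled range exceeds each single range
  slow <- storage_series(base, days, drift_per_day = 0.02)
  fast <- storage_series(
    synthetic_spec(n_samples = 180, noise_sd = 0, scatter_slope_sd = 0,
                   scatter_offset_sd = 0, target_noise_frac = 0, seed = 5),
    days, drift_per_day = 0.08
  )
  r_slow <- range(slow$dataset$targets$tvbn)
  r_fast <- range(fast$dataset$targets$tvbn)
  pooled <- range(c(slow$dataset$targets$tvbn, fast$dataset$targets$tvbn))
  expect_gt(diff(pooled), diff(r_slow))
  expect_gt(diff(pooled), diff(r_fast))
})

test_that("generator rejects invalid specifications", {
  expect_error(synthetic_spec(bands = data.frame(center = 2000, width = 10,
                                                 amplitude = 0.1)),
               "outside")
  expect_error(synthetic_spec(target_range = c(5, 5)), "degenerate")
  expect_error(synthetic_spec(informative_idx = integer(0)), "non-empty")
  spec <- synthetic_spec(seed = 1)
  expect_error(storage_series(spec, c(0, 5), drift_per_day = -0.3),
               "non-positive")
})
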