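test_that("SNV standardizes every spectrum and is idempotent", {
  expect_equal(snv(rbind(c(1, 2, 3)))[1, ], c(-1, 0, 1))
  expect_error(snv(rbind(c(5, 5, 5), c(1, 2, 3))), "1")

  withr::with_seed(3, {
    X <- matrix(rnorm(20 * 51, mean = 5), 20)
    Z <- snv(X)
    expect_equal(dim(Z), dim(X))
    expect_true(all(abs(rowMeans(Z)) <= 1e-12))
    expect_true(all(abs(apply(Z, 1, sd) - 1) <= 1e-12))
    expect_equal(snv(Z), Z, tolerance = 1e-12)
  })
})

test_that("MSC uses the calibration mean and inverts affine scatter exactly", {
  r <- c(0.2, 0.4, 0.6, 0.5, 0.3)
  expect_equal(msc_fit(rbind(r, r))$reference, r)
  expect_equal(msc_fit(rbind(r, 3 * r))$reference, 2 * r)
  expect_error(msc_fit(rbind(r)), "2 calibration")

  fp <- msc_fit(rbind(r, r + 0.01))
  ref <- fp$reference
  expect_equal(msc_apply(fp, rbind(ref))[1, ], ref)
  expect_equal(msc_apply(fp, rbind(2 * ref + 5))[1, ], ref)

  # row orthogonal to the centred reference has OLS slope 0 -> degenerate.
  # Built by Gram-Schmidt; the closed-form slope sum(xc*rc)/sum(rc^2) is
  # checked independently before asserting the error.
  withr::with_seed(8, {
    x <- rnorm(5)
    rc <- ref - mean(ref)
    x_orth <- x - sum(x * rc) / sum(rc^2) * rc
    x_orth <- x_orth - mean(x_orth) + mean(ref)
    slope <- sum((x_orth - mean(x_orth)) * rc) / sum(rc^2)
    expect_lt(abs(slope), 1e-12)
    expect_error(msc_apply(fp, rbind(x_orth)), "slope")
  })
})

test_that("Savitzky-Golay reproduces polynomials and physical derivatives", {
  g <- make_grid(400, 600, 4)
  lam <- g$values
  # degree-2 rows are reproduced exactly by a polyorder-2 smoother
  X <- rbind(3 + 0.01 * lam + 1e-5 * lam^2, 1 - 0.002 * lam)
  expect_equal(savitzky_golay(X, 11, 2, 0, 4), X, tolerance = 1e-9)

  # first derivative of 0.5*lambda is 0.5 per nm at interior points
  d1 <- savitzky_golay(rbind(0.5 * lam), 11, 2, 1, 4)
  interior <- 6:(length(lam) - 5)
  expect_equal(d1[1, interior], rep(0.5, length(interior)), tolerance = 1e-9)

  # second derivative of lambda^2 is 2 per nm^2
  d2 <- savitzky_golay(rbind(lam^2), 11, 2, 2, 4)
  expect_equal(d2[1, interior], rep(2, length(interior)), tolerance = 1e-6)

  expect_error(savitzky_golay(X, 10, 2, 0, 4), "odd")
  expect_error(savitzky_golay(X[, 1:5, drop = FALSE], 11, 2, 0, 4), "window")
  # shape preserved by every method
  for (m in c("SNV", "MSC", "SG", "SG1D", "SG2D")) {
    fp <- fit_preprocessor(preprocess_method(m), X)
    expect_equal(dim(apply_preprocessor(fp, X, 4)), dim(X))
  }
})

test_that("bake-off ranks scatter correction above raw on scattered data", {
  # scatter-heavy, otherwise clean data: raw models must degrade while
  # MSC/SNV recover the band signal
  spec <- synthetic_spec(
    n_samples = 120, noise_sd = 0, scatter_slope_sd = 0.25,
    scatter_offset_sd = 0.1, target_noise_frac = 0, seed = 21
  )
  gen <- generate_spectra(spec)
  ds <- gen$dataset
  y <- ds$targets$tvbn
  split <- spxy_split(ds$reflectance, y, 0.75)
  tab <- bake_off(ds, "tvbn",
                  methods = list(preprocess_method("RAW"),
                                 preprocess_method("MSC"),
                                 preprocess_method("SNV")),
                  split = split)
  expect_true(which(tab$method == "RAW") >
                min(which(tab$method %in% c("MSC", "SNV"))))
  expect_error(bake_off(ds, "x", split = split), "\"x\"")
})

test_that("bake-off tie-break follows the canonical method order", {
  # identical spectra across samples: every method yields the same constant
  # predictor, so all RMSEPs tie and the canonical order decides
  g <- make_grid(400, 448, 4)
  row <- seq(0.3, 0.8, length.out = 13)
  refl <- matrix(rep(row, 24), 24, byrow = TRUE)
  withr::with_seed(2, {
    ds <- spectral_dataset(g, refl, data.frame(tvbn = runif(24, 10, 30)),
                           sprintf("S%02d", 1:24))
  })
  split <- list(calibration_idx = 1:18, prediction_idx = 19:24)
  tab <- bake_off(ds, "tvbn", split = split)
  expect_equal(tab$method, c("RAW", "SG", "SNV", "MSC", "SG1D", "SG2D"))
  expect_true(all(abs(diff(tab$rmse_pred)) < 1e-9))
})
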