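test_that("hyper grid enforces the boundary conditions", {
  g <- hyper_grid()
  expect_equal(g$gamma, 0)
  expect_equal(g$reg_lambda, 0)
  expect_equal(g$reg_alpha, 1)
  expect_error(hyper_grid(n_estimators = c(100, 600)), "100, 500")
  expect_error(hyper_grid(learning_rate = 0.5), "0.01, 0.3")
  expect_error(hyper_grid(max_depth = 2), "3, 8")
})

test_that("grid search returns the single candidate and separates good from bad", {
  tp <- toy_planted(n = 60, p = 5, k_true = 2, noise = 0, seed = 5)
  one <- hyper_grid(n_estimators = 100, learning_rate = 0.1, max_depth = 3)
  fit <- grid_search_fit(tp$X, tp$y, one, seed = 3)
  expect_equal(fit$best_params$n_estimators, 100)
  expect_equal(fit$best_params$learning_rate, 0.1)
  expect_equal(fit$best_params$max_depth, 3)

  # noise-free deterministic response: the best grid point clearly beats
  # the worst (a learning rate of 0.01 with 100 trees underfits)
  g <- hyper_grid(n_estimators = c(100, 300), learning_rate = c(0.01, 0.2),
                  max_depth = c(3, 5))
  fit2 <- grid_search_fit(tp$X, tp$y, g, seed = 3)
  expect_lt(min(fit2$cv_table$cv_rmse), max(fit2$cv_table$cv_rmse))
  expect_equal(fit2$cv_table$cv_rmse[1], min(fit2$cv_table$cv_rmse))
})

test_that("grid search is deterministic given a seed", {
  tp <- toy_planted(n = 50, p = 4, seed = 9)
  g <- hyper_grid(n_estimators = c(100, 200), learning_rate = 0.1,
                  max_depth = 3)
  f1 <- grid_search_fit(tp$X, tp$y, g, seed = 11)
  f2 <- grid_search_fit(tp$X, tp$y, g, seed = 11)
  expect_identical(f1$cv_table, f2$cv_table)
  expect_identical(f1$best_params, f2$best_params)
})

test_that("model evaluation reproduces the RPD identity and residual RMSE", {
  # controlled predictions through a deterministic stand-in model
  X_cal <- matrix(1:20, 10)
  y_cal <- c(1:10)
  mdl <- fake_model(function(M) M[, 1])
  # prediction set: SD(y_pred) = 8, residuals = 2 -> RPD = 4
  y_base <- c(2, 4, 6, 8, 10, 12, 14, 18, 26, 30)
  scale_f <- 8 / sd(y_base)
  y_pred <- y_base * scale_f
  X_pred <- cbind(y_pred + 2, y_pred)
  expect_equal(sd(y_pred), 8)
  r <- evaluate_model(mdl, X_cal, y_cal + 1e-6, X_pred, y_pred)
  expect_equal(r$rmse_pred, 2)
  expect_equal(r$rpd, 4)

  # residuals all equal to c give RMSE |c|
  r2 <- evaluate_model(mdl, X_cal, X_cal[, 1] - 3, X_pred, y_pred)
  expect_equal(r2$rmse_cal, 3)

  # perfect predictions make RPD a division by zero
  expect_error(evaluate_model(mdl, X_cal, X_cal[, 1], X_pred + 0, X_pred[, 1]),
               "division by zero")
  # constant reference values make R2 undefined
  expect_error(evaluate_model(mdl, X_cal, rep(1, 10), X_pred, y_pred),
               "SS_tot")
})

test_that("evaluation metrics are scale-equivariant", {
  withr::with_seed(6, {
    X_cal <- matrix(rnorm(40), 20)
    y_cal <- X_cal[, 1] + rnorm(20, 0, 0.3)
    X_pred <- matrix(rnorm(40), 20)
    y_pred <- X_pred[, 1] + rnorm(20, 0, 0.3)
  })
  mdl1 <- fake_model(function(M) M[, 1])
  mdlc <- fake_model(function(M) M[, 1] * 5)
  r1 <- evaluate_model(mdl1, X_cal, y_cal, X_pred, y_pred)
  rc <- evaluate_model(mdlc, X_cal * c(1), y_cal * 5,
                       X_pred, y_pred * 5)
  expect_equal(rc$rmse_cal, 5 * r1$rmse_cal)
  expect_equal(rc$rmse_pred, 5 * r1$rmse_pred)
  expect_equal(rc$r2_cal, r1$r2_cal)
  expect_equal(rc$r2_pred, r1$r2_pred)
  expect_equal(rc$rpd, r1$rpd)
})

test_that("relative change matches the reported full-spectrum comparisons", {
  expect_equal(relative_change(0.8322, 0.9504, "increase"), 14.2)
  expect_equal(relative_change(3.2601, 1.7726, "reduction"), 45.6)
  expect_equal(relative_change(2.5, 2.5, "increase"), 0)
  expect_error(relative_change(0, 1), "zero")
})
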