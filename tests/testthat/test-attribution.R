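fit_small <- function(X, y, nrounds, depth, eta = 0.5) {
  specswarm:::fit_xgb(X, y, nrounds = nrounds, eta = eta, max_depth = depth,
                      seed = 3)
}

test_that("constant and stump models attribute as the axioms demand", {
  withr::with_seed(1, {
    X <- matrix(rnorm(30 * 4), 30, 4)
    colnames(X) <- paste0("nm", c(400, 404, 408, 412))
  })
  # constant target -> single-leaf trees -> all attributions zero
  fit0 <- fit_small(X, rep(2, 30), nrounds = 3, depth = 2)
  am0 <- tree_shapley(fit0, X[1:5, ], background = X)
  expect_equal(max(abs(am0$values)), 0)

  # depth-1 stump on a dominant feature: only that feature is credited and
  # its attribution carries the whole prediction - base gap
  y <- ifelse(X[, 2] > 0, 5, -5)
  fit1 <- fit_small(X, y, nrounds = 1, depth = 1, eta = 1)
  am1 <- tree_shapley(fit1, X[1:10, ], background = X)
  expect_equal(max(abs(am1$values[, c(1, 3, 4)])), 0)
  expect_equal(am1$values[, 2], am1$predictions - am1$base_value,
               tolerance = 1e-10)
})

test_that("tree attributions match the exact enumeration oracle", {
  withr::with_seed(2, {
    X <- matrix(rnorm(20 * 6), 20, 6)
    colnames(X) <- paste0("nm", seq(400, 420, 4))
    y <- X[, 1] * 2 + X[, 3] - X[, 5]^2 + rnorm(20, 0, 0.1)
  })
  fit <- fit_small(X, y, nrounds = 3, depth = 2)
  bg <- X[1:12, ]
  am <- tree_shapley(fit, X[13:20, ], background = bg)
  for (i in 1:8) {
    ex <- exact_shapley(fit, X[12 + i, ], bg)
    expect_equal(unname(am$values[i, ]), ex, tolerance = 1e-6)
  }
})

test_that("local accuracy holds on every explained sample", {
  withr::with_seed(4, {
    X <- matrix(rnorm(120 * 10), 120, 10)
    colnames(X) <- paste0("nm", seq(400, 436, 4))
    y <- rowSums(X[, 1:3]) + rnorm(120, 0, 0.2)
  })
  fit <- fit_small(X, y, nrounds = 60, depth = 4, eta = 0.2)
  am <- tree_shapley(fit, X[101:120, ], background = X[1:100, ])
  expect_lt(max(abs(am$base_value + rowSums(am$values) - am$predictions)),
            1e-6)
})

test_that("unused features receive exactly zero attribution", {
  withr::with_seed(5, {
    X <- matrix(rnorm(40 * 5), 40, 5)
    colnames(X) <- paste0("nm", seq(400, 416, 4))
    y <- 3 * X[, 1] + rnorm(40, 0, 0.05)
  })
  fit <- fit_small(X, y, nrounds = 10, depth = 2, eta = 0.3)
  used <- unique(xgboost::xgb.model.dt.tree(model = fit$booster)$Feature)
  unused <- setdiff(colnames(X), c(used, "Leaf"))
  expect_gt(length(unused), 0)
  am <- tree_shapley(fit, X[1:10, ], background = X)
  expect_equal(max(abs(am$values[, unused, drop = FALSE])), 0)
})

test_that("exact enumeration satisfies the classical axioms", {
  withr::with_seed(6, bg <- matrix(rnorm(25 * 3), 25, 3))
  # additivity: for f = sum g_j, phi_j = g_j(x_j) - mean g_j(background)
  g1 <- function(v) v^2; g2 <- function(v) 3 * v; g3 <- function(v) sin(v)
  f <- function(M) g1(M[, 1]) + g2(M[, 2]) + g3(M[, 3])
  x <- c(0.7, -0.2, 1.1)
  phi <- exact_shapley(f, x, bg)
  expect_equal(phi, c(g1(x[1]) - mean(g1(bg[, 1])),
                      g2(x[2]) - mean(g2(bg[, 2])),
                      g3(x[3]) - mean(g3(bg[, 3]))), tolerance = 1e-12)

  # symmetry: exchangeable features with a symmetric background
  bg_sym <- cbind(bg[, 1], bg[, 1], bg[, 3])
  fs <- function(M) M[, 1] * M[, 2] + M[, 1] + M[, 2]
  phis <- exact_shapley(fs, c(0.4, 0.4, 2), bg_sym)
  expect_equal(phis[1], phis[2], tolerance = 1e-12)

  expect_error(exact_shapley(f, rnorm(13), matrix(rnorm(13 * 2), 2,
                                                  byrow = TRUE)), "12")
})

test_that("hand-enumerated three-player game reproduces the Shapley weights", {
  # v(S) induced by f and a single background row; all 8 coalition values
  # and the resulting Shapley attributions are recomputed longhand here
  z <- c(0, 0, 0)
  f <- function(M) 2 * M[, 1] + M[, 2] * M[, 3] + 0.5 * M[, 3]
  x <- c(1, 2, 3)
  v <- function(S) {
    h <- z; h[S] <- x[S]
    f(matrix(h, 1))
  }
  phi_hand <- numeric(3)
  weights <- c(`0` = 2 / 6, `1` = 1 / 6, `2` = 2 / 6)
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    subsets <- list(integer(0), others[1], others[2], others)
    for (S in subsets) {
      w <- weights[[as.character(length(S))]]
      phi_hand[i] <- phi_hand[i] + w * (v(c(S, i)) - v(S))
    }
  }
  phi <- exact_shapley(f, x, matrix(z, 1))
  expect_equal(phi, phi_hand, tolerance = 1e-12)
})

test_that("feature ranking orders by mean absolute attribution", {
  am <- structure(
    list(values = cbind(a = c(0.1, -0.1), b = c(2, -2), c = c(0, 0)),
         base_value = 0, feature_labels = c(500, 450, 400),
         predictions = c(0, 0)),
    class = "attribution_matrix"
  )
  rk <- rank_features(am, 3)
  expect_equal(rk$wavelength, c(450, 500, 400))

  # all-zero attributions: ties broken by ascending wavelength
  am$values[] <- 0
  expect_equal(rank_features(am, 3)$wavelength, c(400, 450, 500))
  expect_error(rank_features(am, 4), "top_k")
})

test_that("attribution rejects non-tree models", {
  expect_error(tree_shapley(lm(y ~ x, data.frame(x = 1:5, y = 1:5)),
                            matrix(1, 1, 1), background = matrix(1, 1, 1)),
               "non-tree")
})
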