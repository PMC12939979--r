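# Shared numeric helpers and RNG plumbing.

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("constant observed values: R-squared undefined (SS_tot = 0)")
  1 - sum((obs - pred)^2) / ss_tot
}

# Derive a child seed from a master seed and a fixed stream offset, staying
# inside 32-bit integer range. Each stochastic stage gets its own offset so
# adding one stage never perturbs another's draws.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 99991) %% 2147483629 + 1)
}

.stream_offsets <- c(
  synthetic = 1L, fitness = 2L, model = 3L,
  psoga = 11L, pso = 12L, ga = 13L, gwo = 14L, cars = 15L
)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# Small wrapper around xgboost training used by the bake-off and the final
# models. Single-threaded, fixed seed, Table-1 regularization constants.
fit_xgb <- function(X, y, nrounds = 100, eta = 0.1, max_depth = 3,
                    seed = 7, max_bin = 256, gamma = 0, reg_lambda = 0,
                    reg_alpha = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(
    objective = "reg:squarederror", eta = eta, max_depth = max_depth,
    gamma = gamma, lambda = reg_lambda, alpha = reg_alpha,
    tree_method = "hist", max_bin = max_bin, nthread = 1, seed = seed
  )
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(X),
                 params = params, nrounds = nrounds),
            class = "specswarm_xgb")
}

predict_xgb <- function(fit, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- fit$feature_names
  stats::predict(fit$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}
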