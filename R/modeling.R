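#' Hyperparameter grid for the final boosted-tree models
#'
#' Candidate values must stay inside the reference boundary conditions:
#' `n_estimators` in [100, 500], `learning_rate` in [0.01, 0.3], `max_depth`
#' in [3, 8]; `gamma = 0`, `reg_lambda = 0` and `reg_alpha = 1` are fixed.
#'
#' @param n_estimators Integer candidates for the number of trees.
#' @param learning_rate Numeric candidates for the shrinkage.
#' @param max_depth Integer candidates for tree depth.
#' @return Object of class `hyper_grid`.
#' @export
hyper_grid <- function(n_estimators = c(100, 200, 300, 400, 500),
                       learning_rate = c(0.01, 0.05, 0.1, 0.2, 0.3),
                       max_depth = 3:8) {
  if (any(n_estimators < 100 | n_estimators > 500)) {
    stop("n_estimators candidates must lie in [100, 500]")
  }
  if (any(learning_rate < 0.01 | learning_rate > 0.3)) {
    stop("learning_rate candidates must lie in [0.01, 0.3]")
  }
  if (any(max_depth < 3 | max_depth > 8)) {
    stop("max_depth candidates must lie in [3, 8]")
  }
  structure(
    list(n_estimators = sort(unique(as.integer(n_estimators))),
         learning_rate = sort(unique(learning_rate)),
         max_depth = sort(unique(as.integer(max_depth))),
         gamma = 0, reg_lambda = 0, reg_alpha = 1),
    class = "hyper_grid"
  )
}

#' Grid-searched boosted-tree regression
#'
#' Exhaustive search over the grid with `cv_folds`-fold cross-validated RMSE
#' as criterion (rows shuffled once by `seed` into contiguous folds). For a
#' given learning rate and depth, all `n_estimators` candidates are scored
#' from a single incremental fit per fold. Ties are resolved towards the
#' smaller `n_estimators`, then the smaller depth, then the smaller learning
#' rate. The winning parameters are refitted on the full calibration set
#' with the fixed regularization constants (`gamma = 0`, `reg_lambda = 0`,
#' `reg_alpha = 1`).
#'
#' @param X_cal Calibration matrix (columns = selected wavelengths).
#' @param y_cal Calibration target.
#' @param grid A [hyper_grid()].
#' @param cv_folds CV folds (default 3).
#' @param seed Integer seed for the fold shuffle and tree fitting.
#' @return Object of class `specswarm_model`: the fitted booster, the
#'   chosen `best_params`, the full CV table, and the calibration matrix
#'   (kept as the default attribution background).
#' @export
grid_search_fit <- function(X_cal, y_cal, grid = hyper_grid(), cv_folds = 3,
                            seed = 7) {
  stopifnot(inherits(grid, "hyper_grid"))
  X_cal <- as.matrix(X_cal)
  if (is.null(colnames(X_cal))) colnames(X_cal) <- paste0("f", seq_len(ncol(X_cal)))
  n <- nrow(X_cal)
  if (n < 2 * cv_folds) stop("a fold would have fewer than 2 samples")
  order_ <- with_seed(seed, sample.int(n))
  bounds <- round(seq(0, n, length.out = cv_folds + 1))
  max_rounds <- max(grid$n_estimators)
  combos <- expand.grid(learning_rate = grid$learning_rate,
                        max_depth = grid$max_depth)
  # per (lr, depth): matrix of fold RMSEs at each n_estimators candidate
  tab <- do.call(rbind, lapply(seq_len(nrow(combos)), function(ci) {
    lr <- combos$learning_rate[ci]
    depth <- combos$max_depth[ci]
    fold_rmse <- matrix(0, cv_folds, length(grid$n_estimators))
    for (f in seq_len(cv_folds)) {
      te <- order_[(bounds[f] + 1):bounds[f + 1]]
      tr <- setdiff(order_, te)
      dtrain <- xgboost::xgb.DMatrix(X_cal[tr, , drop = FALSE],
                                     label = y_cal[tr], nthread = 1)
      dtest <- xgboost::xgb.DMatrix(X_cal[te, , drop = FALSE],
                                    label = y_cal[te], nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = lr,
                      max_depth = depth, gamma = grid$gamma,
                      lambda = grid$reg_lambda, alpha = grid$reg_alpha,
                      tree_method = "hist", nthread = 1, seed = seed),
        data = dtrain, nrounds = max_rounds,
        evals = list(test = dtest), verbose = 0
      )
      log_ <- attributes(fit)$evaluation_log$test_rmse
      fold_rmse[f, ] <- log_[grid$n_estimators]
    }
    data.frame(n_estimators = grid$n_estimators, learning_rate = lr,
               max_depth = depth, cv_rmse = colMeans(fold_rmse))
  }))
  ord <- order(tab$cv_rmse, tab$n_estimators, tab$max_depth,
               tab$learning_rate)
  best <- tab[ord[1], ]
  final <- fit_xgb(X_cal, y_cal, nrounds = best$n_estimators,
                   eta = best$learning_rate, max_depth = best$max_depth,
                   seed = seed, gamma = grid$gamma,
                   reg_lambda = grid$reg_lambda, reg_alpha = grid$reg_alpha)
  structure(
    list(fit = final,
         best_params = list(n_estimators = best$n_estimators,
                            learning_rate = best$learning_rate,
                            max_depth = best$max_depth,
                            gamma = grid$gamma,
                            reg_lambda = grid$reg_lambda,
                            reg_alpha = grid$reg_alpha),
         cv_table = tab[ord, , drop = FALSE],
         X_cal = X_cal),
    class = "specswarm_model"
  )
}

#' @export
print.specswarm_model <- function(x, ...) {
  bp <- x$best_params
  cat(sprintf(
    "<specswarm_model> %d features; n_estimators=%d, learning_rate=%g, max_depth=%d (CV RMSE %.4g)\n",
    ncol(x$X_cal), bp$n_estimators, bp$learning_rate, bp$max_depth,
    x$cv_table$cv_rmse[1]
  ))
  invisible(x)
}

#' Predict from a grid-searched model
#'
#' @param object A [grid_search_fit()] result.
#' @param newdata Matrix with the same columns as the calibration matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.specswarm_model <- function(object, newdata, ...) {
  predict_xgb(object$fit, newdata)
}

#' Calibration/prediction performance report
#'
#' Computes the standard chemometric model summary: R2 and RMSE on the
#' calibration ("correction") and prediction sets, and the relative
#' prediction deviation `RPD = SD(y_pred) / RMSEP`, where the SD (sample,
#' `n - 1` denominator) is that of the prediction set's reference values.
#'
#' @param model A [grid_search_fit()] result (or any object with a
#'   `predict` method accepting a matrix).
#' @param X_cal,y_cal Calibration data.
#' @param X_pred,y_pred Prediction data.
#' @return Object of class `model_report` with elements `r2_cal`,
#'   `rmse_cal`, `r2_pred`, `rmse_pred`, `rpd`, `best_params`, `n_features`.
#' @export
evaluate_model <- function(model, X_cal, y_cal, X_pred, y_pred) {
  pc <- stats::predict(model, as.matrix(X_cal))
  pp <- stats::predict(model, as.matrix(X_pred))
  rmse_pred <- rmse(y_pred, pp)
  if (rmse_pred == 0) {
    stop("RMSEP is zero: RPD undefined (division by zero)")
  }
  structure(
    list(r2_cal = r_squared(y_cal, pc),
         rmse_cal = rmse(y_cal, pc),
         r2_pred = r_squared(y_pred, pp),
         rmse_pred = rmse_pred,
         rpd = stats::sd(y_pred) / rmse_pred,
         best_params = if (inherits(model, "specswarm_model")) model$best_params else NULL,
         n_features = ncol(as.matrix(X_cal))),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report> R2c %.4f RMSEC %.4f | R2p %.4f RMSEP %.4f | RPD %.4f (%d features)\n",
    x$r2_cal, x$rmse_cal, x$r2_pred, x$rmse_pred, x$rpd, x$n_features
  ))
  invisible(x)
}

#' Percent change between a baseline metric and an improved one
#'
#' For `type = "increase"`, `100 * (improved - baseline) / baseline`; for
#' `type = "reduction"`, `100 * (baseline - improved) / baseline`. Reported
#' to one decimal, the convention used when quoting gains such as a 14.2 %
#' R2p increase or a 45.6 % RMSEP reduction over a full-spectrum model.
#'
#' @param baseline Baseline metric value (non-zero).
#' @param improved Improved metric value.
#' @param type `"increase"` or `"reduction"`.
#' @return Percent change, rounded to one decimal.
#' @export
relative_change <- function(baseline, improved,
                            type = c("increase", "reduction")) {
  type <- match.arg(type)
  if (baseline == 0) stop("baseline metric is zero: relative change undefined")
  x <- switch(type,
    increase = 100 * (improved - baseline) / baseline,
    reduction = 100 * (baseline - improved) / baseline
  )
  round(x, 1)
}
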