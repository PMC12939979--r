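# Competitive adaptive reweighted sampling (CARS) baseline.
# Variable elimination guided by PLS regression-coefficient magnitudes under
# an exponentially decreasing retention schedule, with Monte-Carlo row
# sampling and adaptive reweighted sampling of variables.

# PLS1 fit via mixOmics; returns the regression coefficient vector at ncomp.
pls_coefficients <- function(X, y, ncomp) {
  fit <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                       scale = TRUE)
  pr <- stats::predict(fit, X[1:2, , drop = FALSE])
  as.numeric(pr$B.hat[, 1, ncomp])
}

# Cross-validated RMSE of a PLS model on columns `vars`, choosing the number
# of components (<= max_ncomp) that minimizes CV RMSE. Fold layout is fixed
# by the caller.
pls_cv_rmse <- function(X, y, vars, fold_id, max_ncomp = 10) {
  folds <- max(fold_id)
  nc <- min(max_ncomp, length(vars),
            min(tabulate(fold_id, folds)) * (folds - 1) - 2)
  nc <- max(nc, 1)
  press <- matrix(0, folds, nc)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    fit <- mixOmics::pls(X[tr, vars, drop = FALSE], y[tr], ncomp = nc,
                         mode = "regression", scale = TRUE)
    pr <- stats::predict(fit, X[te, vars, drop = FALSE])$predict
    for (c in seq_len(nc)) {
      press[f, c] <- mean((y[te] - pr[, 1, c])^2)
    }
  }
  mse <- colMeans(press)
  best <- which.min(mse)
  list(rmse = sqrt(mse[best]), ncomp = best)
}

#' CARS wavelength selection
#'
#' Canonical competitive adaptive reweighted sampling. At run i a PLS model
#' is fitted on a Monte-Carlo subset (80 % of the calibration rows) over the
#' currently retained variables; the exponentially decreasing function
#' `r_i = A exp(-k i)`, calibrated so that `r_1 = 1` and `r_runs = 2/p`,
#' fixes the fraction of variables force-kept by coefficient magnitude
#' (enforced descent of the retained count); adaptive reweighted sampling
#' then draws variables with probability proportional to the absolute PLS
#' coefficient. Each run's variable set is scored by cross-validated PLS
#' RMSE (components chosen up to `max_ncomp` by the same CV) and the set
#' with the minimal CV RMSE is returned.
#'
#' @param X_cal Calibration spectra.
#' @param y_cal Calibration target.
#' @param runs Number of sampling runs (>= 2); 50 by default.
#' @param cv_folds Folds for the per-run CV scoring.
#' @param seed Integer seed (Monte-Carlo rows and reweighted sampling).
#' @param max_ncomp Upper bound on PLS components.
#' @return Logical selection mask with attributes `log` (a `data.frame`
#'   with per-run EDF target counts, retained counts and CV RMSE) and
#'   `best_run`.
#' @export
cars_select <- function(X_cal, y_cal, runs = 50, cv_folds = 5, seed = 1,
                        max_ncomp = 10) {
  X_cal <- as.matrix(X_cal)
  if (is.null(colnames(X_cal))) {
    colnames(X_cal) <- paste0("f", seq_len(ncol(X_cal)))
  }
  n <- nrow(X_cal); p <- ncol(X_cal)
  if (runs < 2) stop("runs must be >= 2")
  if (p < 3) stop("CARS needs at least 3 variables")
  k_exp <- log(p / 2) / (runs - 1)
  A <- exp(k_exp)
  edf <- pmax(2L, as.integer(round(A * exp(-k_exp * seq_len(runs)) * p)))
  with_seed(derive_seed(seed, .stream_offsets["cars"]), {
    fold_id <- rep_len(sample.int(cv_folds), n)[sample.int(n)]
    # rep_len then shuffle gives balanced, seed-fixed folds
    retained <- seq_len(p)
    sets <- vector("list", runs)
    log_df <- data.frame(run = seq_len(runs), n_edf = edf,
                         n_retained = NA_integer_, cv_rmse = NA_real_)
    for (i in seq_len(runs)) {
      mc <- sort(sample.int(n, max(cv_folds + 1, round(0.8 * n))))
      nc <- max(1, min(max_ncomp, length(retained), length(mc) - 2))
      b <- tryCatch(
        pls_coefficients(X_cal[mc, retained, drop = FALSE], y_cal[mc], nc),
        error = function(e) {
          stop(sprintf("PLS failure at CARS run %d: %s", i,
                       conditionMessage(e)))
        }
      )
      ab <- abs(b)
      keep_n <- min(edf[i], length(retained))
      top <- order(-ab, seq_along(ab))[seq_len(keep_n)]
      weights <- ab[top]
      if (sum(weights) == 0) weights <- rep(1, length(top))
      drawn <- unique(top[sample.int(length(top), keep_n, replace = TRUE,
                                     prob = weights)])
      if (length(drawn) < 2) drawn <- top[1:2]
      retained <- sort(retained[drawn])
      sets[[i]] <- retained
      sc <- pls_cv_rmse(X_cal, y_cal, retained, fold_id, max_ncomp)
      log_df$n_retained[i] <- length(retained)
      log_df$cv_rmse[i] <- sc$rmse
    }
    best <- which.min(log_df$cv_rmse)
    mask <- rep(FALSE, p)
    mask[sets[[best]]] <- TRUE
    attr(mask, "log") <- log_df
    attr(mask, "best_run") <- best
    mask
  })
}
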