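# Shapley-value attribution of fitted tree ensembles.

# Pull the booster and metadata out of whatever model object we were given.
booster_of <- function(model) {
  if (inherits(model, "specswarm_model")) {
    list(booster = model$fit$booster, feature_names = model$fit$feature_names,
         background = model$X_cal)
  } else if (inherits(model, "specswarm_xgb")) {
    list(booster = model$booster, feature_names = model$feature_names,
         background = NULL)
  } else if (inherits(model, "xgb.Booster")) {
    list(booster = model, feature_names = NULL, background = NULL)
  } else {
    stop("non-tree model: Shapley attribution needs a boosted-tree model")
  }
}

# Parse an xgboost booster into flat per-tree arrays for the C++ walker.
parse_trees <- function(booster, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  dt <- as.data.frame(dt)
  feat_col <- dt$Feature
  is_leaf <- feat_col == "Leaf"
  idx <- rep(NA_integer_, nrow(dt))
  if (!is.null(feature_names) && any(feat_col[!is_leaf] %in% feature_names)) {
    idx[!is_leaf] <- match(feat_col[!is_leaf], feature_names) - 1L
  } else {
    raw <- sub("^f", "", feat_col[!is_leaf])
    idx[!is_leaf] <- suppressWarnings(as.integer(raw))
  }
  if (any(is.na(idx[!is_leaf]))) stop("could not map tree features to columns")
  lapply(split(seq_len(nrow(dt)), dt$Tree), function(rows) {
    sub <- dt[rows, , drop = FALSE]
    ord <- order(sub$Node)
    sub <- sub[ord, , drop = FALSE]
    node_of <- function(id) {
      out <- match(id, sub$ID) - 1L
      out[is.na(id)] <- -1L
      out
    }
    leaf <- sub$Feature == "Leaf"
    list(
      feature = ifelse(leaf, -1L, idx[rows][ord]),
      split = ifelse(leaf, 0, sub$Split),
      yes = node_of(sub$Yes),
      no = node_of(sub$No),
      value = ifelse(leaf, sub$Gain, 0)
    )
  })
}

#' Interventional TreeSHAP attributions on a prediction set
#'
#' Computes per-sample, per-feature Shapley values of a fitted boosted-tree
#' model under the interventional (background-marginal) value function: the
#' worth of a coalition S is the expected model output when the features in
#' S take the explained sample's values and the rest are drawn from a
#' background dataset (by default the calibration set the model was fitted
#' on). Local accuracy holds exactly: for every sample,
#' `base_value + sum(values) = prediction`. A feature never used by any tree
#' receives attribution zero.
#'
#' @param model A [grid_search_fit()] result, a fitted internal booster, or
#'   a raw `xgb.Booster`. Anything else is rejected as a non-tree model.
#' @param X_pred Matrix of samples to explain (selected-wavelength columns).
#' @param background Background matrix with the same columns; defaults to
#'   the model's calibration set when available.
#' @return Object of class `attribution_matrix`: list with `values`
#'   (n_samples x n_features, target units), `base_value` (mean background
#'   prediction), `feature_labels` (wavelengths in nm when the columns are
#'   named `nm<value>`), and `predictions`.
#' @export
tree_shapley <- function(model, X_pred, background = NULL) {
  info <- booster_of(model)
  if (is.null(background)) background <- info$background
  if (is.null(background)) {
    stop("a background matrix is required (no calibration set attached)")
  }
  X_pred <- as.matrix(X_pred)
  background <- as.matrix(background)
  if (ncol(X_pred) != ncol(background)) {
    stop("X_pred and background must share columns")
  }
  fn <- info$feature_names
  if (is.null(fn)) fn <- colnames(X_pred)
  trees <- parse_trees(info$booster, fn)
  values <- interv_treeshap_cpp(trees, X_pred, background)
  # intercept (base_score) recovered once, then all sums kept in double so
  # base_value + rowSums(values) reproduces the prediction to ~1e-12
  dt_bg <- xgboost::xgb.DMatrix(background, nthread = 1)
  ens_bg <- ens_predict_cpp(trees, background)
  intercept <- mean(stats::predict(info$booster, dt_bg) - ens_bg)
  preds <- ens_predict_cpp(trees, X_pred) + intercept
  base <- mean(ens_bg) + intercept
  labels <- fn
  if (!is.null(labels) && all(grepl("^nm[0-9.]+$", labels))) {
    labels <- as.numeric(sub("^nm", "", labels))
  }
  if (is.null(labels)) labels <- seq_len(ncol(X_pred))
  colnames(values) <- fn
  structure(
    list(values = values, base_value = base, feature_labels = labels,
         predictions = preds),
    class = "attribution_matrix"
  )
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf(
    "<attribution_matrix> %d samples x %d features, base value %.4g\n",
    nrow(x$values), ncol(x$values), x$base_value
  ))
  invisible(x)
}

#' Exact Shapley values by subset enumeration (test oracle)
#'
#' Classical Shapley attribution with the interventional value function
#' `v(S) = mean over background rows of f(x_S, z_{-S})`, evaluated by
#' enumerating all `2^p` coalitions with the exact combinatorial weights
#' `|S|! (p - |S| - 1)! / p!`. Exponential cost; refuses more than 12
#' features. Model-agnostic: `model` may be a fitted tree model or any
#' function mapping a matrix to a numeric vector.
#'
#' @param model Prediction model or function.
#' @param x Single sample (numeric vector, length p <= 12).
#' @param background Background matrix (columns = features).
#' @return Numeric attribution vector of length p.
#' @export
exact_shapley <- function(model, x, background) {
  background <- as.matrix(background)
  p <- length(x)
  if (p != ncol(background)) stop("x length must match background columns")
  if (p > 12) stop("refusing exact enumeration beyond 12 features (2^p subsets)")
  f <- if (is.function(model)) {
    model
  } else {
    info <- booster_of(model)
    function(M) {
      M <- as.matrix(M)
      colnames(M) <- info$feature_names
      stats::predict(info$booster, xgboost::xgb.DMatrix(M, nthread = 1))
    }
  }
  nbg <- nrow(background)
  nsub <- 2^p
  # batch all hybrid rows into one prediction call
  big <- matrix(0, nsub * nbg, p)
  for (s in seq_len(nsub)) {
    bits <- bitwAnd(bitwShiftR(s - 1L, 0:(p - 1)), 1L) == 1L
    block <- background
    block[, bits] <- matrix(x[bits], nbg, sum(bits), byrow = TRUE)
    big[((s - 1) * nbg + 1):(s * nbg), ] <- block
  }
  preds <- f(big)
  v <- vapply(seq_len(nsub), function(s) {
    mean(preds[((s - 1) * nbg + 1):(s * nbg)])
  }, 0)
  w <- factorial(0:(p - 1)) * factorial(p - 1 - 0:(p - 1)) / factorial(p)
  phi <- numeric(p)
  size_of <- vapply(seq_len(nsub) - 1L, function(s) {
    sum(bitwAnd(bitwShiftR(s, 0:(p - 1)), 1L))
  }, 0L)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(seq_len(nsub) - 1L, bit) == 0L)
    for (s in without) {
      sz <- size_of[s]
      phi[i] <- phi[i] + w[sz + 1] * (v[s + bit] - v[s])
    }
  }
  phi
}

#' Rank features by mean absolute attribution
#'
#' @param am An [tree_shapley()] attribution matrix.
#' @param top_k How many features to return.
#' @return `data.frame` with `wavelength` and `mean_abs_attribution`,
#'   descending; ties broken by the lower wavelength.
#' @export
rank_features <- function(am, top_k = 10) {
  stopifnot(inherits(am, "attribution_matrix"))
  k <- ncol(am$values)
  if (top_k > k) stop("top_k exceeds the number of features")
  score <- colMeans(abs(am$values))
  wl <- am$feature_labels
  ord <- order(-score, wl)
  data.frame(wavelength = wl[ord[seq_len(top_k)]],
             mean_abs_attribution = score[ord[seq_len(top_k)]],
             row.names = NULL)
}
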