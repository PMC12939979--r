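#' Threshold a continuous position into a wavelength mask
#'
#' Coordinates strictly above 0.5 are selected. If nothing survives the
#' threshold the single largest coordinate is rescued so the mask is never
#' empty (a total fitness function needs at least one column).
#'
#' @param position Numeric vector in `[0, 1]^p`.
#' @return Logical vector of the same length.
#' @export
binarize <- function(position) {
  flags <- position > 0.5
  if (!any(flags)) flags[which.max(position)] <- TRUE
  flags
}

#' Build a memoizing cross-validated fitness evaluator
#'
#' The fitness of a wavelength mask is the mean 3-fold cross-validated MSE of
#' a small fixed gradient-boosted-tree regressor restricted to the masked
#' columns. Rows are shuffled once by `seed` into `folds` contiguous folds;
#' the fold layout, and the quantized fold matrices, are then frozen for the
#' evaluator's lifetime, and results are memoized by mask bit-pattern.
#'
#' Column restriction is enforced through xgboost's per-tree column sampling
#' with zero feature weights outside the mask, which lets all masks share the
#' per-fold DMatrix objects instead of re-quantizing a column subset per
#' evaluation.
#'
#' @param X_cal Calibration spectra matrix.
#' @param y_cal Calibration target vector.
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed controlling the single row shuffle and the tree
#'   fitting.
#' @param nrounds,eta,max_depth,max_bin Inner fitness-model settings. These
#'   are deliberately modest: the fitness only has to rank masks, and the
#'   final reported models are grid-searched separately.
#' @return A function `f(mask) -> MSE` with attributes accessible via
#'   [evaluator_stats()].
#' @export
make_fitness_evaluator <- function(X_cal, y_cal, folds = 3, seed = 1,
                                   nrounds = 30, eta = 0.3, max_depth = 3,
                                   max_bin = 16) {
  X_cal <- as.matrix(X_cal)
  n <- nrow(X_cal); p <- ncol(X_cal)
  if (length(y_cal) != n) stop("y_cal length must match rows of X_cal")
  if (folds < 2) stop("folds must be >= 2")
  if (n < 2 * folds) stop("a fold would have fewer than 2 samples")
  order_ <- with_seed(seed, sample.int(n))
  bounds <- round(seq(0, n, length.out = folds + 1))
  fold_rows <- lapply(seq_len(folds), function(f) {
    order_[(bounds[f] + 1):bounds[f + 1]]
  })
  if (any(vapply(fold_rows, length, 1L) < 2)) {
    stop("a fold would have fewer than 2 samples")
  }
  prep <- lapply(seq_len(folds), function(f) {
    te <- fold_rows[[f]]
    tr <- setdiff(order_, te)
    dtrain <- xgboost::xgb.DMatrix(X_cal[tr, , drop = FALSE],
                                   label = y_cal[tr], nthread = 1)
    dtest <- xgboost::xgb.DMatrix(X_cal[te, , drop = FALSE], nthread = 1)
    list(dtrain = dtrain, dtest = dtest, y_test = y_cal[te])
  })
  cache <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  state$evaluations <- 0L
  base_params <- list(
    objective = "reg:squarederror", eta = eta, max_depth = max_depth,
    tree_method = "hist", max_bin = max_bin, nthread = 1, seed = seed
  )
  f <- function(mask) {
    mask <- as.logical(mask)
    if (length(mask) != p) stop("mask length does not match X_cal columns")
    if (!any(mask)) stop("empty mask passed to fitness evaluator")
    key <- paste(packBits(c(mask, rep(FALSE, (8 - p %% 8) %% 8))),
                 collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    k <- sum(mask)
    w <- as.numeric(mask)
    params <- c(base_params, list(colsample_bytree = min(1, (k + 0.5) / p)))
    mses <- vapply(prep, function(fold) {
      xgboost::setinfo(fold$dtrain, "feature_weights", w)
      bst <- xgboost::xgb.train(params = params, data = fold$dtrain,
                                nrounds = nrounds, verbose = 0)
      pr <- stats::predict(bst, fold$dtest)
      mean((fold$y_test - pr)^2)
    }, 0)
    out <- mean(mses)
    cache[[key]] <- out
    state$evaluations <- state$evaluations + 1L
    out
  }
  attr(f, "state") <- state
  attr(f, "cache") <- cache
  attr(f, "dims") <- c(n = n, p = p)
  f
}

#' Evaluation counters of a fitness evaluator
#'
#' @param evaluator A [make_fitness_evaluator()] function.
#' @return List with `evaluations` (cache misses, i.e. actual CV fits) and
#'   `cached` (distinct masks stored).
#' @export
evaluator_stats <- function(evaluator) {
  list(evaluations = attr(evaluator, "state")$evaluations,
       cached = length(ls(attr(evaluator, "cache"))))
}

#' Cross-validated mask fitness
#'
#' One-shot convenience around [make_fitness_evaluator()]: the mean `folds`-
#' fold CV MSE of the fixed inner boosted-tree model on the masked columns.
#' Repeated calls with the same data, fold settings and mask are served from
#' a per-dataset memo.
#'
#' @inheritParams make_fitness_evaluator
#' @param mask Logical selection vector (non-empty).
#' @param ... Passed to [make_fitness_evaluator()].
#' @return Mean squared error (target units squared).
#' @export
cv_fitness <- function(mask, X_cal, y_cal, folds = 3, seed = 1, ...) {
  key <- paste(nrow(X_cal), ncol(X_cal), folds, seed,
               format(sum(X_cal) + sum(y_cal), digits = 17), sep = "|")
  ev <- .cv_fitness_memo[[key]]
  if (is.null(ev)) {
    ev <- make_fitness_evaluator(X_cal, y_cal, folds = folds, seed = seed, ...)
    .cv_fitness_memo[[key]] <- ev
  }
  ev(mask)
}

.cv_fitness_memo <- new.env(parent = emptyenv())
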