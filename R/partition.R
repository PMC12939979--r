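#' SPXY calibration/prediction split
#'
#' Sample-set partitioning based on the joint x-y distance. Pairwise
#' Euclidean distances are computed separately on the spectra and on the
#' target, each normalized by its maximum, and summed:
#' `d = dx/max(dx) + dy/max(dy)`. Selection is Kennard-Stone max-min on `d`:
#' the pair attaining the global maximum seeds the calibration set, then the
#' sample whose minimum distance to the chosen set is largest is added until
#' `round(n * ratio)` samples are selected. The remaining samples form the
#' prediction set. The procedure is fully deterministic; distance ties are
#' broken by the lowest sample index.
#'
#' @param X Spectra matrix (samples in rows).
#' @param y Numeric target vector.
#' @param ratio Calibration share in (0, 1); 0.75 reproduces a 3:1 split.
#' @return Object of class `partition_result`: list with `calibration_idx`
#'   (in selection order), `prediction_idx` (ascending) and `ratio`.
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- rnorm(20)
#' sp <- spxy_split(X, y, 0.75)
#' length(sp$calibration_idx)  # 15
#' @export
spxy_split <- function(X, y, ratio = 0.75) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("SPXY needs at least 3 samples")
  if (length(y) != n) stop("y length must match the number of rows of X")
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n_cal <- round(n * ratio)
  if (n_cal < 2) stop("calibration share yields fewer than 2 samples")
  if (n_cal > n - 1) stop("calibration share leaves no prediction samples")

  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(matrix(y, ncol = 1)))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0) {
    stop("all samples identical in X and y: SPXY distance degenerate")
  }
  d <- (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)

  # seed: global max-distance pair, ties by lowest (i, j)
  flat <- which(d == max(d), arr.ind = TRUE)
  flat <- flat[order(flat[, 1], flat[, 2]), , drop = FALSE]
  seedp <- sort(unname(flat[1, ]))
  selected <- seedp
  remaining <- setdiff(seq_len(n), selected)
  # min distance of each remaining sample to the selected set
  mind <- pmin(d[remaining, selected[1]], d[remaining, selected[2]])
  while (length(selected) < n_cal) {
    pick <- remaining[which.max(mind)]  # which.max returns first = lowest index
    selected <- c(selected, pick)
    keep <- remaining != pick
    remaining <- remaining[keep]
    mind <- pmin(mind[keep], d[remaining, pick])
  }
  structure(
    list(calibration_idx = selected,
         prediction_idx = sort(setdiff(seq_len(n), selected)),
         ratio = ratio),
    class = "partition_result"
  )
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %d calibration / %d prediction (ratio %.2f)\n",
              length(x$calibration_idx), length(x$prediction_idx), x$ratio))
  invisible(x)
}
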