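# Shared fixtures and independent oracles, all built in code at test time.

# Small planted regression problem: y depends on `k_true` of `p` columns.
toy_planted <- function(n = 60, p = 12, k_true = 3, noise = 0.2, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    true_cols <- seq_len(k_true)
    beta <- seq(2, 1, length.out = k_true)
    y <- as.numeric(X[, true_cols, drop = FALSE] %*% beta) +
      stats::rnorm(n, 0, noise)
    list(X = X, y = y, true_cols = true_cols)
  })
}

# Independent brute-force SPXY: direct O(n^3) max-min loops, no shared code
# with the package implementation.
brute_spxy <- function(X, y, ratio) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
  }
  dy <- abs(outer(y, y, "-"))
  if (max(d) > 0) d <- d / max(d)
  if (max(dy) > 0) d <- d + dy / max(dy)
  best <- c(1, 2); bestv <- -Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > bestv) { bestv <- d[i, j]; best <- c(i, j) }
    }
  }
  sel <- best
  n_cal <- round(n * ratio)
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    score <- sapply(cand, function(i) min(d[i, sel]))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

# Writes a tiny spectra + references CSV pair; returns the two paths.
write_fixture_csvs <- function(dir, ids = c("S1", "S2", "S3"),
                               wl = c(400, 404, 408, 412, 416)) {
  sp_path <- file.path(dir, "spectra.csv")
  ref_path <- file.path(dir, "refs.csv")
  set.seed(42)
  refl <- matrix(round(runif(length(ids) * length(wl), 0.2, 0.9), 6),
                 length(ids))
  sp <- data.frame(sample_id = ids, check.names = FALSE)
  sp <- cbind(sp, as.data.frame(refl))
  names(sp)[-1] <- wl
  utils::write.csv(sp, sp_path, row.names = FALSE, quote = FALSE)
  refs <- data.frame(sample_id = ids,
                     tvbn = round(runif(length(ids), 10, 40), 2),
                     L = round(runif(length(ids), 35, 45), 2))
  utils::write.csv(refs, ref_path, row.names = FALSE, quote = FALSE)
  list(spectra = sp_path, references = ref_path)
}

# Deterministic linear "model" with a predict method, for metric tests where
# predictions must be controlled exactly.
fake_model <- function(fun) structure(list(fun = fun), class = "sw_fake")
registerS3method("predict", "sw_fake",
                 function(object, newdata, ...) object$fun(as.matrix(newdata)),
                 envir = asNamespace("stats"))
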