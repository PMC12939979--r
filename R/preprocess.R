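#' Standard normal variate transform
#'
#' Per-spectrum standardization: each row is centred to mean 0 and scaled to
#' sample standard deviation 1 (denominator `n - 1`). Corrects multiplicative
#' scatter and path-length variation without a reference spectrum.
#'
#' @param spectra Numeric matrix, samples in rows.
#' @return Matrix of the same shape.
#' @export
snv <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) < 2) stop("SNV needs rows of at least 2 points")
  mu <- rowMeans(spectra)
  sd_ <- apply(spectra, 1, stats::sd)
  bad <- which(sd_ == 0)
  if (length(bad)) {
    nm <- rownames(spectra)[bad[1]]
    stop(sprintf("constant spectrum (zero variance) for sample %s",
                 if (is.null(nm)) as.character(bad[1]) else nm))
  }
  out <- (spectra - mu) / sd_
  dimnames(out) <- dimnames(spectra)
  out
}

#' Fit a multiplicative scatter correction reference
#'
#' The reference is the column-wise mean of the calibration spectra. Fitting
#' on the calibration set only, then applying the frozen reference to
#' prediction spectra, avoids leaking prediction-set information into the
#' correction.
#'
#' @param calibration Matrix of calibration spectra (>= 2 rows).
#' @return Object of class `msc_fit` holding the reference spectrum.
#' @export
msc_fit <- function(calibration) {
  calibration <- as.matrix(calibration)
  if (nrow(calibration) < 2) {
    stop("MSC needs >= 2 calibration spectra (reference would equal the sample)")
  }
  structure(list(reference = colMeans(calibration)), class = "msc_fit")
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum x is regressed on the reference r by ordinary least squares,
#' `x = a + b * r`, and corrected to `(x - a) / b`. A spectrum equal to
#' `a + b * r` is therefore mapped exactly back to `r`.
#'
#' @param fp An [msc_fit()] object.
#' @param spectra Matrix with the same number of columns as the reference.
#' @return Corrected matrix.
#' @export
msc_apply <- function(fp, spectra) {
  stopifnot(inherits(fp, "msc_fit"))
  spectra <- as.matrix(spectra)
  r <- fp$reference
  if (ncol(spectra) != length(r)) {
    stop("spectra column count does not match the MSC reference")
  }
  rc <- r - mean(r)
  denom <- sum(rc^2)
  if (denom == 0) stop("MSC reference is constant")
  out <- spectra
  for (i in seq_len(nrow(spectra))) {
    x <- spectra[i, ]
    b <- sum((x - mean(x)) * rc) / denom
    if (abs(b) < 1e-12) {
      nm <- rownames(spectra)[i]
      stop(sprintf("degenerate MSC regression (slope ~ 0) for sample %s",
                   if (is.null(nm)) as.character(i) else nm))
    }
    a <- mean(x) - b * mean(r)
    out[i, ] <- (x - a) / b
  }
  out
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Row-wise local-polynomial filtering. Derivatives are reported in physical
#' units (per nm^deriv), i.e. the per-index derivative is divided by
#' `step_nm^deriv`. Edges use the asymmetric rows of the Savitzky-Golay
#' projection matrix (a polynomial fitted to the first and last window), so
#' the output keeps the input length and any polynomial of degree up to
#' `polyorder` is reproduced exactly everywhere, edges included.
#'
#' @param spectra Matrix, samples in rows.
#' @param window Odd window length (> polyorder).
#' @param polyorder Polynomial order (>= deriv).
#' @param deriv Derivative order: 0, 1 or 2.
#' @param step_nm Grid spacing in nm (used only for derivative scaling).
#' @return Matrix of the same shape.
#' @export
savitzky_golay <- function(spectra, window = 11, polyorder = 2, deriv = 0,
                           step_nm = 1) {
  spectra <- as.matrix(spectra)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (polyorder < deriv) stop("polyorder must be >= deriv")
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  p <- ncol(spectra)
  if (p < window) stop(sprintf("window %d exceeds row length %d", window, p))
  h <- (window - 1) / 2
  # Projection matrix: row h+1 holds the central (interior) coefficients,
  # rows 1..h and h+2..window the asymmetric leading/trailing edge fits.
  # signal::sgolay already includes the per-index derivative scaling.
  F_ <- unclass(signal::sgolay(p = polyorder, n = window, m = deriv))
  coef <- as.numeric(F_[h + 1, ])
  out <- matrix(0, nrow(spectra), p)
  for (j in seq_len(window)) {
    out[, (h + 1):(p - h)] <- out[, (h + 1):(p - h)] +
      coef[j] * spectra[, j:(j + p - window), drop = FALSE]
  }
  out[, 1:h] <- spectra[, 1:window, drop = FALSE] %*%
    t(F_[1:h, , drop = FALSE])
  out[, (p - h + 1):p] <- spectra[, (p - window + 1):p, drop = FALSE] %*%
    t(F_[(h + 2):window, , drop = FALSE])
  out <- out / step_nm^deriv
  dimnames(out) <- dimnames(spectra)
  out
}

#' Describe a preprocessing method
#'
#' @param name One of `"RAW"`, `"MSC"`, `"SNV"`, `"SG"`, `"SG1D"`, `"SG2D"`.
#' @param window,polyorder Savitzky-Golay settings (SG family only).
#' @return Object of class `preprocess_method`.
#' @export
preprocess_method <- function(name = c("RAW", "MSC", "SNV", "SG", "SG1D", "SG2D"),
                              window = 11, polyorder = 2) {
  name <- match.arg(name)
  deriv <- switch(name, SG1D = 1L, SG2D = 2L, 0L)
  if (name %in% c("SG", "SG1D", "SG2D")) {
    if (window %% 2 == 0 || window <= polyorder || polyorder < deriv) {
      stop("invalid Savitzky-Golay settings")
    }
  }
  structure(list(name = name, window = window, polyorder = polyorder,
                 deriv = deriv),
            class = "preprocess_method")
}

# canonical tie-break order in the bake-off
.pp_order <- c(RAW = 1, SG = 2, SNV = 3, MSC = 4, SG1D = 5, SG2D = 6)

#' Fit a preprocessor on calibration spectra
#'
#' Only MSC carries fitted state (its reference spectrum); the other methods
#' are stateless and the returned object simply records the method.
#'
#' @param method A [preprocess_method()].
#' @param calibration Calibration spectra matrix.
#' @return Object of class `fitted_preprocessor`.
#' @export
fit_preprocessor <- function(method, calibration) {
  stopifnot(inherits(method, "preprocess_method"))
  ref <- if (method$name == "MSC") msc_fit(calibration) else NULL
  structure(list(method = method, msc = ref), class = "fitted_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param fp A [fit_preprocessor()] object.
#' @param spectra Matrix to transform.
#' @param step_nm Grid spacing, for derivative scaling.
#' @return Transformed matrix.
#' @export
apply_preprocessor <- function(fp, spectra, step_nm = 1) {
  stopifnot(inherits(fp, "fitted_preprocessor"))
  m <- fp$method
  switch(m$name,
    RAW = as.matrix(spectra),
    SNV = snv(spectra),
    MSC = msc_apply(fp$msc, spectra),
    SG = ,
    SG1D = ,
    SG2D = savitzky_golay(spectra, m$window, m$polyorder, m$deriv, step_nm)
  )
}

#' Compare preprocessing methods on a fixed split
#'
#' Fits one full-spectrum boosted-tree model per preprocessing method on the
#' calibration rows (preprocessor fitted on calibration only) and evaluates
#' it on the prediction rows. The split is computed once on raw spectra and
#' reused for every method so the comparison is not confounded by
#' method-dependent partitions. Ranking is by ascending RMSEP, ties broken by
#' higher R2p, then by the canonical order RAW < SG < SNV < MSC < SG1D < SG2D.
#'
#' @param ds A [spectral_dataset()].
#' @param indicator Target column name.
#' @param methods List of [preprocess_method()] objects.
#' @param split A [spxy_split()] result computed on the raw spectra.
#' @param model_cfg Named list of boosted-tree settings for the comparison
#'   models: `nrounds`, `eta`, `max_depth`, `seed`.
#' @return `data.frame` with columns `method`, `r2_pred`, `rmse_pred`,
#'   ordered best first.
#' @export
bake_off <- function(ds, indicator, methods = default_bakeoff_methods(),
                     split, model_cfg = list()) {
  stopifnot(inherits(ds, "spectral_dataset"))
  iv <- indicator_values(ds, indicator)
  if (length(iv$rows) != nrow(ds$reflectance)) {
    stop("bake_off requires complete target values for the chosen indicator")
  }
  cfg <- utils::modifyList(
    list(nrounds = 100, eta = 0.1, max_depth = 3, seed = 7), model_cfg)
  cal <- split$calibration_idx
  pred <- split$prediction_idx
  y <- iv$y
  res <- lapply(methods, function(m) {
    fp <- fit_preprocessor(m, ds$reflectance[cal, , drop = FALSE])
    Xc <- apply_preprocessor(fp, ds$reflectance[cal, , drop = FALSE],
                             ds$grid$step_nm)
    Xp <- apply_preprocessor(fp, ds$reflectance[pred, , drop = FALSE],
                             ds$grid$step_nm)
    fit <- fit_xgb(Xc, y[cal], nrounds = cfg$nrounds, eta = cfg$eta,
                   max_depth = cfg$max_depth, seed = cfg$seed)
    pr <- predict_xgb(fit, Xp)
    data.frame(
      method = m$name,
      r2_pred = r_squared(y[pred], pr),
      rmse_pred = rmse(y[pred], pr),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, res)
  ord <- order(tab$rmse_pred, -tab$r2_pred, .pp_order[tab$method])
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' The five standard preprocessing candidates plus the raw spectra
#'
#' @param window,polyorder Savitzky-Golay settings shared by the SG family.
#' @return List of [preprocess_method()] objects.
#' @export
default_bakeoff_methods <- function(window = 11, polyorder = 2) {
  list(
    preprocess_method("RAW"),
    preprocess_method("MSC"),
    preprocess_method("SNV"),
    preprocess_method("SG", window, polyorder),
    preprocess_method("SG1D", window, polyorder),
    preprocess_method("SG2D", window, polyorder)
  )
}
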