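#' Specification of a synthetic Vis-NIR benchmark dataset
#'
#' Describes a generator for reflectance spectra with planted Gaussian
#' absorption bands and a reference target driven by a known subset of those
#' bands. The defaults emulate the acquisition geometry and variability of a
#' meat-freshness study: 420 samples on a 400--1800 nm grid at 4 nm
#' (351 variables), five absorption bands at chemically plausible centres
#' (myoglobin and O-H/N-H/C-H overtone regions), and a TVB-N-like target
#' spanning 6.65--66.05 mg/100 g.
#'
#' @param n_samples Number of samples.
#' @param grid A [make_grid()] object.
#' @param bands `data.frame` with columns `center` (nm), `width` (nm,
#'   Gaussian sigma) and `amplitude` (base absorption depth, reflectance
#'   units).
#' @param informative_idx Indices of the bands that drive the target.
#' @param response `"linear"` or `"saturating"` map from the summed
#'   informative amplitudes to the target.
#' @param noise_sd Additive spectral noise SD (reflectance units).
#' @param scatter_slope_sd,scatter_offset_sd Per-sample multiplicative and
#'   additive scatter SDs (slope ~ N(1, sd^2), offset ~ N(0, sd^2)).
#' @param target_range Target min/max in target units.
#' @param target_noise_frac Target noise SD as a fraction of the target
#'   range; set 0 for an exactly affine (noise-free) response.
#' @param indicator Name of the generated target column.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 420,
                           grid = make_grid(400, 1800, 4),
                           bands = default_bands(),
                           informative_idx = seq_len(nrow(bands)),
                           response = c("linear", "saturating"),
                           noise_sd = 0.003,
                           scatter_slope_sd = 0.02,
                           scatter_offset_sd = 0.01,
                           target_range = c(6.65, 66.05),
                           target_noise_frac = 0.02,
                           indicator = "tvbn",
                           seed = 1) {
  response <- match.arg(response)
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "amplitude") %in% names(bands)))
  if (any(bands$center < grid$start_nm | bands$center > grid$stop_nm)) {
    stop("band centre outside the wavelength grid")
  }
  if (!length(informative_idx)) stop("informative_idx must be non-empty")
  if (any(informative_idx < 1 | informative_idx > nrow(bands))) {
    stop("informative_idx out of range")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (diff(target_range) <= 0) stop("degenerate target_range")
  structure(
    list(n_samples = as.integer(n_samples), grid = grid, bands = bands,
         informative_idx = as.integer(informative_idx), response = response,
         noise_sd = noise_sd, scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         target_range = target_range,
         target_noise_frac = target_noise_frac,
         indicator = indicator, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default planted absorption bands
#'
#' Five Gaussian bands at centres echoing chemically meaningful regions of
#' meat Vis-NIR spectra (myoglobin around 576 nm, O-H third overtone near
#' 728 nm, N-H second overtone near 1080 nm, C-H second overtone near
#' 1236 nm, O-H/N-H first overtones near 1450 nm). Widths of 12--18 nm
#' (Gaussian sigma) keep the bands broad on the 4 nm grid yet separated
#' enough that a univariate correlation screen peaks at the centres, and
#' comparable amplitudes give every band a recoverable share of the
#' response. A demo convenience, not a claim of equivalence to real tissue.
#'
#' @return `data.frame` with `center`, `width`, `amplitude`.
#' @export
default_bands <- function() {
  data.frame(
    center = c(576, 728, 1080, 1236, 1450),
    width = c(12, 14, 16, 12, 18),
    amplitude = c(0.12, 0.12, 0.14, 0.12, 0.14)
  )
}

# gentle linear baseline ramp over the grid
.baseline <- function(values) 0.65 + 0.25 * (values - min(values)) / diff(range(values))

band_profiles <- function(spec) {
  vals <- spec$grid$values
  vapply(seq_len(nrow(spec$bands)), function(b) {
    exp(-(vals - spec$bands$center[b])^2 / (2 * spec$bands$width[b]^2))
  }, numeric(length(vals)))
}

assemble_dataset <- function(spec, amps, y, ids, extra_targets = NULL) {
  profiles <- band_profiles(spec)
  refl <- matrix(rep(.baseline(spec$grid$values), each = nrow(amps)),
                 nrow(amps)) - amps %*% t(profiles)
  slope <- stats::rnorm(nrow(amps), 1, spec$scatter_slope_sd)
  offset <- stats::rnorm(nrow(amps), 0, spec$scatter_offset_sd)
  refl <- refl * slope + offset
  if (spec$noise_sd > 0) {
    refl <- refl + matrix(stats::rnorm(length(refl), 0, spec$noise_sd),
                          nrow(refl))
  }
  targets <- data.frame(y)
  names(targets) <- spec$indicator
  if (!is.null(extra_targets)) targets <- cbind(targets, extra_targets)
  ds <- spectral_dataset(spec$grid, refl, targets, ids)
  truth <- structure(
    list(informative_wavelengths = spec$bands$center[spec$informative_idx],
         informative_idx = spec$informative_idx,
         latent_amplitudes = amps,
         band_centers = spec$bands$center),
    class = "ground_truth"
  )
  list(dataset = ds, truth = truth)
}

response_map <- function(spec, s) {
  if (spec$response == "saturating") s / (s + mean(s)) else s
}

#' Generate a synthetic spectral dataset with known ground truth
#'
#' Per-sample band amplitudes are drawn `U(0.5, 1.5) * base amplitude`;
#' reflectance is a gentle linear baseline minus the Gaussian band dips,
#' degraded by per-sample multiplicative/additive scatter and white noise.
#' The target is an affine map of the summed informative-band amplitudes
#' (optionally passed through a saturating transform first) whose observed
#' span is mapped exactly onto `target_range`, plus Gaussian noise of SD
#' `target_noise_frac * range`. Deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [spectral_dataset()]) and `truth` (the
#'   planted informative wavelengths and latent amplitudes, never shown to
#'   the selectors).
#' @export
generate_spectra <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, .stream_offsets["synthetic"]), {
    n <- spec$n_samples
    nb <- nrow(spec$bands)
    amps <- matrix(stats::runif(n * nb, 0.5, 1.5), n, nb)
    amps <- sweep(amps, 2, spec$bands$amplitude, `*`)
    s <- rowSums(amps[, spec$informative_idx, drop = FALSE])
    g <- response_map(spec, s)
    rng <- range(g)
    if (diff(rng) == 0) stop("degenerate informative signal")
    y <- spec$target_range[1] +
      diff(spec$target_range) * (g - rng[1]) / diff(rng)
    if (spec$target_noise_frac > 0) {
      y <- y + stats::rnorm(n, 0,
                            spec$target_noise_frac * diff(spec$target_range))
    }
    ids <- sprintf("S%04d", seq_len(n))
    assemble_dataset(spec, amps, y, ids)
  })
}

#' Generate a storage time series with drifting informative bands
#'
#' Emulates samples drawn on successive storage days: each day multiplies
#' the informative-band amplitudes by `1 + drift_per_day * day`, so the
#' spoilage-marker target increases with storage. The target affine map uses
#' the theoretical drift-free amplitude span, so drifted series can exceed
#' `target_range` (two series at different drift rates therefore span a
#' wider combined range than either alone). `floor(n_samples / n_days)`
#' samples are generated per day, with per-slot base amplitudes shared
#' across days so per-day mean targets are strictly monotone by
#' construction.
#'
#' @param spec A [synthetic_spec()].
#' @param days Non-decreasing numeric vector of storage days.
#' @param drift_per_day Fractional amplitude drift per day.
#' @return As [generate_spectra()], with a `day` column in the dataset's
#'   targets.
#' @export
storage_series <- function(spec, days = c(0, 1, 3, 5, 7, 8, 9, 10),
                           drift_per_day = 0.05) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.unsorted(days)) stop("days must be non-decreasing")
  growth <- 1 + drift_per_day * days
  if (any(growth <= 0)) stop("drift drives amplitudes non-positive")
  K <- length(days)
  n_per_day <- spec$n_samples %/% K
  if (n_per_day < 1) stop("need at least one sample per day")
  with_seed(derive_seed(spec$seed, .stream_offsets["synthetic"]), {
    nb <- nrow(spec$bands)
    base <- matrix(stats::runif(n_per_day * nb, 0.5, 1.5), n_per_day, nb)
    base <- sweep(base, 2, spec$bands$amplitude, `*`)
    amps <- do.call(rbind, lapply(seq_len(K), function(d) {
      a <- base
      a[, spec$informative_idx] <- a[, spec$informative_idx] * growth[d]
      a
    }))
    day_col <- rep(days, each = n_per_day)
    s <- rowSums(amps[, spec$informative_idx, drop = FALSE])
    g <- response_map(spec, s)
    # theoretical drift-free span of the response
    lo <- sum(spec$bands$amplitude[spec$informative_idx]) * 0.5
    hi <- sum(spec$bands$amplitude[spec$informative_idx]) * 1.5
    ref <- response_map(spec, c(lo, hi))
    y <- spec$target_range[1] +
      diff(spec$target_range) * (g - ref[1]) / (ref[2] - ref[1])
    if (spec$target_noise_frac > 0) {
      y <- y + stats::rnorm(length(y), 0,
                            spec$target_noise_frac * diff(spec$target_range))
    }
    ids <- sprintf("S%04d", seq_along(y))
    assemble_dataset(spec, amps, y, ids,
                     extra_targets = data.frame(day = day_col))
  })
}

#' Grid positions within one step of the planted band centres
#'
#' @param truth A `ground_truth` object.
#' @param grid The matching [make_grid()].
#' @return List of integer index vectors, one per informative band.
#' @export
informative_windows <- function(truth, grid) {
  lapply(truth$informative_wavelengths, function(ctr) {
    j <- which.min(abs(grid$values - ctr))
    intersect((j - 1):(j + 1), seq_along(grid$values))
  })
}

#' Fraction of planted bands covered by a selection mask
#'
#' A band counts as recovered when the mask selects at least one wavelength
#' within one grid step of its centre.
#'
#' @param mask Logical selection vector.
#' @param truth A `ground_truth` object.
#' @param grid The matching [make_grid()].
#' @return Fraction in [0, 1].
#' @export
band_recovery <- function(mask, truth, grid) {
  wins <- informative_windows(truth, grid)
  mean(vapply(wins, function(w) any(mask[w]), FALSE))
}
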