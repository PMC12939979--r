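# Metaheuristic building blocks shared by the selectors.

#' Chaotic logistic-map population initialization
#'
#' Each particle is seeded from a fresh logistic-map orbit
#' `x[k+1] = r * x[k] * (1 - x[k])`. The starting point is drawn uniformly
#' from (0.01, 0.99), rejecting the fixed points and period-2 seeds
#' {0.25, 0.5, 0.75}, and the first 100 iterates are discarded as burn-in.
#' At `r = 4` the orbit is chaotic with invariant density
#' `1 / (pi * sqrt(x (1 - x)))`, giving a diverse spread over (0, 1).
#'
#' @param N Population size.
#' @param p Dimensionality (number of wavelengths).
#' @param r Chaos parameter in (0, 4]; default 4.
#' @param seed Integer seed for the orbit starting points.
#' @param burn_in Iterates discarded before filling the row.
#' @return `N x p` matrix with entries in (0, 1).
#' @export
logistic_init <- function(N, p, r = 4, seed = 1, burn_in = 100) {
  if (r <= 0 || r > 4) stop("logistic-map parameter r must be in (0, 4]")
  with_seed(seed, {
    out <- matrix(0, N, p)
    for (i in seq_len(N)) {
      repeat {
        x <- stats::runif(1, 0.01, 0.99)
        if (min(abs(x - c(0.25, 0.5, 0.75))) > 1e-9) break
      }
      for (k in seq_len(burn_in)) x <- r * x * (1 - x)
      row <- numeric(p)
      for (j in seq_len(p)) {
        x <- r * x * (1 - x)
        row[j] <- x
      }
      out[i, ] <- row
    }
    out
  })
}

#' Nonlinear decreasing inertia weight
#'
#' Convex quadratic schedule
#' `w(t) = w_min + (w_max - w_min) * (1 - t/T)^2`, falling fast early
#' (exploration handed over to exploitation) and flattening near `w_min`.
#' `schedule = "exp"` offers the exponential alternative
#' `w_min * (w_max/w_min)^(1 - t/T)` for sensitivity checks, and
#' `"linear"` the straight line used by the canonical PSO baseline.
#'
#' @param t Iteration, `0 <= t <= T`.
#' @param cfg A [selector_config()].
#' @param schedule One of `"quadratic"`, `"exp"`, `"linear"`.
#' @return Inertia weight.
#' @export
inertia <- function(t, cfg, schedule = c("quadratic", "exp", "linear")) {
  schedule <- match.arg(schedule)
  if (t < 0 || t > cfg$max_iter) stop("t must lie in [0, T]")
  frac <- 1 - t / cfg$max_iter
  switch(schedule,
    quadratic = cfg$w_min + (cfg$w_max - cfg$w_min) * frac^2,
    exp = cfg$w_min * (cfg$w_max / cfg$w_min)^frac,
    linear = cfg$w_min + (cfg$w_max - cfg$w_min) * frac
  )
}

#' Split a population into elite and ordinary subpopulations
#'
#' The elite share interpolates linearly from `elite_share_start` at t = 0 to
#' `elite_share_end` at t = T; the `ceiling(share * N)` lowest-MSE particles
#' are elite, the rest ordinary. Fitness ties are resolved by particle index.
#'
#' @param fitnesses Vector of N current fitness values (MSE).
#' @param t Iteration.
#' @param cfg A [selector_config()].
#' @return List with integer vectors `elite_idx` and `ordinary_idx`.
#' @export
classify_population <- function(fitnesses, t, cfg) {
  N <- length(fitnesses)
  share <- cfg$elite_share_start +
    (cfg$elite_share_end - cfg$elite_share_start) * t / cfg$max_iter
  n_elite <- min(N, max(1L, ceiling(share * N)))
  ord <- order(fitnesses, seq_len(N))
  list(elite_idx = sort(ord[seq_len(n_elite)]),
       ordinary_idx = sort(ord[seq_len(N - n_elite) + n_elite]))
}

#' One particle-swarm velocity/position update
#'
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with r1, r2 ~ U(0,1)
#' per coordinate, velocity clamped to `[-v_clamp, v_clamp]`, position
#' clipped to `[0, 1]`.
#'
#' @param position,velocity,pbest Current state vectors.
#' @param gbest Global best position.
#' @param w Inertia weight for this iteration.
#' @param cfg A [selector_config()].
#' @return List with updated `position` and `velocity`.
#' @export
pso_update <- function(position, velocity, pbest, gbest, w, cfg) {
  p <- length(position)
  r1 <- stats::runif(p)
  r2 <- stats::runif(p)
  v <- w * velocity + cfg$c1 * r1 * (pbest - position) +
    cfg$c2 * r2 * (gbest - position)
  v <- pmin(pmax(v, -cfg$v_clamp), cfg$v_clamp)
  x <- pmin(pmax(position + v, 0), 1)
  list(position = x, velocity = v)
}

#' Uniform crossover of two parent vectors
#'
#' With probability `p_crossover` the parents exchange each coordinate
#' independently with probability 0.5; otherwise the children are copies.
#' The multiset of values at every coordinate is conserved. Child velocities
#' are reset to zero by the callers.
#'
#' @param parent_a,parent_b Equal-length numeric vectors.
#' @param p_crossover Probability that crossover happens at all.
#' @return List with `child_a`, `child_b`.
#' @export
crossover <- function(parent_a, parent_b, p_crossover) {
  stopifnot(length(parent_a) == length(parent_b))
  if (stats::runif(1) < p_crossover) {
    swap <- stats::runif(length(parent_a)) < 0.5
    tmp <- parent_a[swap]
    parent_a[swap] <- parent_b[swap]
    parent_b[swap] <- tmp
  }
  list(child_a = parent_a, child_b = parent_b)
}

#' Mantegna sigma for Levy-stable step generation
#'
#' Closed form
#' `sigma_u = [Gamma(1+b) sin(pi b/2) / (Gamma((1+b)/2) b 2^((b-1)/2))]^(1/b)`.
#'
#' @param beta Tail exponent in (1, 2).
#' @return Numeric scalar.
#' @export
levy_sigma <- function(beta) {
  if (beta <= 1 || beta >= 2) stop("levy beta must be in (1, 2)")
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Draw a Levy-flight step vector (Mantegna's algorithm)
#'
#' `step_j = scale * u_j / |v_j|^(1/beta)` with `u ~ N(0, sigma_u^2)` and
#' `v ~ N(0, 1)`. Heavy-tailed: occasional very long jumps let mutated
#' particles escape local optima.
#'
#' @param p Dimensionality.
#' @param beta Tail exponent in (1, 2).
#' @param scale Step scale; 0 gives the zero vector.
#' @return Numeric vector of length `p`.
#' @export
levy_step <- function(p, beta = 1.5, scale = 0.1) {
  sigma <- levy_sigma(beta)
  u <- stats::rnorm(p, 0, sigma)
  v <- stats::rnorm(p)
  scale * u / abs(v)^(1 / beta)
}

#' Polynomial mutation with Levy amplification
#'
#' Each coordinate mutates with probability `p_mutation`. The perturbation
#' delta follows Deb's polynomial-mutation distribution with index `eta_m`
#' on bounds [0, 1] (`delta = (2u)^(1/(eta+1)) - 1` for `u < 0.5`, mirrored
#' above), is amplified by `1 + |levy_j|`, and the result is clipped back to
#' [0, 1]. Large `eta_m` concentrates delta near zero.
#'
#' @param x Vector in `[0, 1]^p`.
#' @param eta_m Distribution index (> 0).
#' @param p_mutation Per-coordinate mutation probability.
#' @param levy Amplification vector (e.g. from [levy_step()]); recycled.
#' @return Mutated vector in `[0, 1]^p`.
#' @export
polynomial_mutation <- function(x, eta_m = 20, p_mutation = 1 / length(x),
                                levy = 0) {
  p <- length(x)
  levy <- rep_len(levy, p)
  hit <- stats::runif(p) < p_mutation
  if (!any(hit)) return(x)
  u <- stats::runif(sum(hit))
  delta <- ifelse(u < 0.5,
                  (2 * u)^(1 / (eta_m + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta_m + 1)))
  x[hit] <- x[hit] + delta * (1 + abs(levy[hit]))
  pmin(pmax(x, 0), 1)
}

# k=2 tournament: pick the better (lower fitness) of two random candidates.
tournament_pick <- function(candidates, fitnesses) {
  pair <- candidates[sample.int(length(candidates), 2, replace = TRUE)]
  pair[which.min(fitnesses[pair])]
}

# Mask comparator used for the global best: lower fitness wins; equal
# fitness -> fewer selected wavelengths; then lower lexicographic bit
# pattern (0 before 1 at the first differing coordinate).
mask_better <- function(fit_new, mask_new, fit_old, mask_old) {
  if (is.null(mask_old) || fit_new < fit_old) return(TRUE)
  if (fit_new > fit_old) return(FALSE)
  k_new <- sum(mask_new); k_old <- sum(mask_old)
  if (k_new != k_old) return(k_new < k_old)
  d <- which(mask_new != mask_old)
  if (!length(d)) return(FALSE)
  !mask_new[d[1]]
}
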