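#' Configuration for the metaheuristic wavelength selectors
#'
#' Collects every constant the selectors use, with conventional defaults.
#' `p_mutation = NULL` means `2/p` per coordinate, resolved once the problem
#' dimension is known. The mutation defaults (`eta_m`, `levy_scale`,
#' `p_mutation`) are deliberately aggressive: with threshold binarization at
#' 0.5, perturbations must be large enough to carry a coordinate across the
#' threshold, or the genetic phase cannot flip any wavelength in or out.
#'
#' @param pop_size Population size N (>= 4). The reference study setting is
#'   50; desk-scale runs typically use less.
#' @param max_iter Iteration budget T (>= 1); reference setting 100.
#' @param w_max,w_min Inertia bounds, `0 < w_min < w_max <= 1`.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param elite_share_start,elite_share_end Elite fraction at t = 0 and
#'   t = T (linear interpolation), both in (0, 1).
#' @param p_crossover Probability a mated pair is crossed over.
#' @param p_mutation Per-coordinate mutation probability (NULL -> 1/p).
#' @param levy_beta Levy tail exponent in (1, 2).
#' @param levy_scale Levy step scale.
#' @param eta_m Polynomial-mutation distribution index.
#' @param logistic_r Logistic-map chaos parameter.
#' @param v_clamp Velocity bound.
#' @param cv_folds Folds of the cross-validated fitness.
#' @param seed Master seed of the selector run.
#' @param fitness_seed Seed of the fitness fold shuffle (default derived
#'   from `seed`); hold it fixed to compare runs on an identical fitness
#'   landscape.
#' @param inertia_schedule `"quadratic"` (default) or `"exp"`.
#' @param fitness_nrounds,fitness_eta,fitness_depth,fitness_max_bin Inner
#'   fitness-model settings (see [make_fitness_evaluator()]).
#' @return Object of class `selector_config`.
#' @export
selector_config <- function(pop_size = 50, max_iter = 100,
                            w_max = 0.9, w_min = 0.4, c1 = 2, c2 = 2,
                            elite_share_start = 0.5, elite_share_end = 0.2,
                            p_crossover = 0.9, p_mutation = NULL,
                            levy_beta = 1.5, levy_scale = 1, eta_m = 2,
                            logistic_r = 4, v_clamp = 0.5, cv_folds = 3,
                            seed = 1, fitness_seed = NULL,
                            inertia_schedule = c("quadratic", "exp"),
                            fitness_nrounds = 30, fitness_eta = 0.3,
                            fitness_depth = 3, fitness_max_bin = 16) {
  inertia_schedule <- match.arg(inertia_schedule)
  if (pop_size < 4) stop("pop_size must be >= 4")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (!(0 < w_min && w_min < w_max && w_max <= 1)) {
    stop("inertia bounds must satisfy 0 < w_min < w_max <= 1")
  }
  if (!(elite_share_start > 0 && elite_share_start < 1 &&
        elite_share_end > 0 && elite_share_end < 1)) {
    stop("elite shares must lie in (0, 1)")
  }
  if (levy_beta <= 1 || levy_beta >= 2) stop("levy_beta must be in (1, 2)")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (is.null(fitness_seed)) fitness_seed <- derive_seed(seed, .stream_offsets["fitness"])
  structure(
    list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
         w_max = w_max, w_min = w_min, c1 = c1, c2 = c2,
         elite_share_start = elite_share_start,
         elite_share_end = elite_share_end,
         p_crossover = p_crossover, p_mutation = p_mutation,
         levy_beta = levy_beta, levy_scale = levy_scale, eta_m = eta_m,
         logistic_r = logistic_r, v_clamp = v_clamp,
         cv_folds = as.integer(cv_folds), seed = as.integer(seed),
         fitness_seed = as.integer(fitness_seed),
         inertia_schedule = inertia_schedule,
         fitness_nrounds = fitness_nrounds, fitness_eta = fitness_eta,
         fitness_depth = fitness_depth, fitness_max_bin = fitness_max_bin),
    class = "selector_config"
  )
}

new_trace <- function(best, n_sel, mask, evaluations, method) {
  structure(
    list(best_fitness_per_iter = best, n_selected_per_iter = n_sel,
         best_mask = mask, evaluations = evaluations, method = method),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "<selection_trace> %s: %d iterations, final MSE %.6g, %d wavelengths, %d evaluations\n",
    x$method, length(x$best_fitness_per_iter),
    x$best_fitness_per_iter[length(x$best_fitness_per_iter)],
    sum(x$best_mask), x$evaluations
  ))
  invisible(x)
}

selector_setup <- function(X_cal, y_cal, cfg, evaluator, method) {
  X_cal <- as.matrix(X_cal)
  if (nrow(X_cal) < 2 * cfg$cv_folds) {
    stop("need at least 2 samples per cross-validation fold")
  }
  if (is.null(evaluator)) {
    evaluator <- make_fitness_evaluator(
      X_cal, y_cal, folds = cfg$cv_folds, seed = cfg$fitness_seed,
      nrounds = cfg$fitness_nrounds, eta = cfg$fitness_eta,
      max_depth = cfg$fitness_depth, max_bin = cfg$fitness_max_bin
    )
  }
  list(X = X_cal, evaluator = evaluator,
       p = ncol(X_cal),
       pm = if (is.null(cfg$p_mutation)) 2 / ncol(X_cal) else cfg$p_mutation,
       sel_seed = derive_seed(cfg$seed, .stream_offsets[method]),
       eval0 = evaluator_stats(evaluator)$evaluations)
}

# Evaluate every row of a position matrix, update personal/global bests.
# Returns the updated best bookkeeping.
eval_population <- function(pos, evaluator, pbest_fit, gbest) {
  N <- nrow(pos)
  fits <- numeric(N)
  masks <- vector("list", N)
  for (i in seq_len(N)) {
    masks[[i]] <- binarize(pos[i, ])
    fits[i] <- evaluator(masks[[i]])
    if (fits[i] < pbest_fit$fit[i]) {
      pbest_fit$fit[i] <- fits[i]
      pbest_fit$pos[i, ] <- pos[i, ]
    }
    if (mask_better(fits[i], masks[[i]], gbest$fit, gbest$mask)) {
      gbest$fit <- fits[i]
      gbest$mask <- masks[[i]]
      gbest$pos <- pos[i, ]
    }
  }
  list(fits = fits, pbest = pbest_fit, gbest = gbest)
}

#' Hybrid particle-swarm / genetic-algorithm wavelength selection
#'
#' The improved hybrid selector. Particles hold continuous positions in
#' `[0, 1]^p`, thresholded at 0.5 into wavelength masks whose fitness is the
#' cross-validated boosted-tree MSE on the calibration set. The population is
#' initialized from chaotic logistic-map orbits. Each iteration the particles
#' are ranked and split into an elite subpopulation (share shrinking linearly
#' from `elite_share_start` to `elite_share_end`) that performs particle-swarm
#' updates under a nonlinear (convex quadratic) decreasing inertia weight, and
#' an ordinary subpopulation that undergoes tournament selection, uniform
#' crossover and polynomial mutation whose perturbations are amplified by
#' Levy-flight draws. The best-so-far fitness curve is non-increasing, the
#' returned mask is never empty, and a fixed seed reproduces the trace
#' bit for bit. Equal-fitness masks are resolved towards fewer selected
#' wavelengths, then the lower lexicographic bit pattern.
#'
#' @param X_cal Calibration spectra (rows = samples).
#' @param y_cal Calibration target values.
#' @param cfg A [selector_config()].
#' @param evaluator Optional prebuilt [make_fitness_evaluator()]; by default
#'   a fresh evaluator (with a fresh memo) is created per run.
#' @return A `selection_trace` with `best_fitness_per_iter`,
#'   `n_selected_per_iter`, `best_mask` and the evaluation count.
#' @export
psoga_select <- function(X_cal, y_cal, cfg = selector_config(),
                         evaluator = NULL) {
  st <- selector_setup(X_cal, y_cal, cfg, evaluator, "psoga")
  N <- cfg$pop_size; T_ <- cfg$max_iter; p <- st$p
  pos <- logistic_init(N, p, cfg$logistic_r,
                       seed = derive_seed(st$sel_seed, 1))
  with_seed(st$sel_seed, {
    vel <- matrix(0, N, p)
    pbest <- list(fit = rep(Inf, N), pos = pos)
    gbest <- list(fit = Inf, mask = NULL, pos = NULL)
    best_curve <- numeric(T_)
    nsel_curve <- integer(T_)
    for (t in seq_len(T_)) {
      ev <- eval_population(pos, st$evaluator, pbest, gbest)
      pbest <- ev$pbest; gbest <- ev$gbest
      best_curve[t] <- gbest$fit
      nsel_curve[t] <- sum(gbest$mask)
      if (t == T_) break
      w <- inertia(t, cfg, cfg$inertia_schedule)
      cls <- classify_population(ev$fits, t, cfg)
      for (i in cls$elite_idx) {
        up <- pso_update(pos[i, ], vel[i, ], pbest$pos[i, ], gbest$pos, w, cfg)
        pos[i, ] <- up$position
        vel[i, ] <- up$velocity
      }
      ord <- cls$ordinary_idx
      all_idx <- seq_len(N)  # tournament parents drawn from the whole swarm
      if (length(ord) >= 2) {
        slots <- ord
        while (length(slots) >= 2) {
          a <- tournament_pick(all_idx, ev$fits)
          b <- tournament_pick(all_idx, ev$fits)
          ch <- crossover(pos[a, ], pos[b, ], cfg$p_crossover)
          ca <- polynomial_mutation(ch$child_a, cfg$eta_m, st$pm,
                                    levy_step(p, cfg$levy_beta, cfg$levy_scale))
          cb <- polynomial_mutation(ch$child_b, cfg$eta_m, st$pm,
                                    levy_step(p, cfg$levy_beta, cfg$levy_scale))
          i <- slots[1]; j <- slots[2]; slots <- slots[-(1:2)]
          pos[i, ] <- ca; vel[i, ] <- 0
          pos[j, ] <- cb; vel[j, ] <- 0
        }
        if (length(slots) == 1) {
          a <- tournament_pick(all_idx, ev$fits)
          b <- tournament_pick(all_idx, ev$fits)
          ch <- crossover(pos[a, ], pos[b, ], cfg$p_crossover)
          pos[slots, ] <- polynomial_mutation(
            ch$child_a, cfg$eta_m, st$pm,
            levy_step(p, cfg$levy_beta, cfg$levy_scale))
          vel[slots, ] <- 0
        }
      } else if (length(ord) == 1) {
        pos[ord, ] <- polynomial_mutation(
          pos[ord, ], cfg$eta_m, st$pm,
          levy_step(p, cfg$levy_beta, cfg$levy_scale))
        vel[ord, ] <- 0
      }
    }
    new_trace(best_curve, nsel_curve, gbest$mask,
              evaluator_stats(st$evaluator)$evaluations - st$eval0, "psoga")
  })
}

#' Canonical global-best binary PSO baseline
#'
#' Uniform random initialization, linear inertia decrease from `w_max` to
#' `w_min`, velocity clamping, and the shared threshold binarization and
#' cross-validated fitness. Same determinism and tie-break contracts as
#' [psoga_select()].
#'
#' @inheritParams psoga_select
#' @return A `selection_trace`.
#' @export
pso_select <- function(X_cal, y_cal, cfg = selector_config(),
                       evaluator = NULL) {
  st <- selector_setup(X_cal, y_cal, cfg, evaluator, "pso")
  N <- cfg$pop_size; T_ <- cfg$max_iter; p <- st$p
  with_seed(st$sel_seed, {
    pos <- matrix(stats::runif(N * p), N, p)
    vel <- matrix(0, N, p)
    pbest <- list(fit = rep(Inf, N), pos = pos)
    gbest <- list(fit = Inf, mask = NULL, pos = NULL)
    best_curve <- numeric(T_)
    nsel_curve <- integer(T_)
    for (t in seq_len(T_)) {
      ev <- eval_population(pos, st$evaluator, pbest, gbest)
      pbest <- ev$pbest; gbest <- ev$gbest
      best_curve[t] <- gbest$fit
      nsel_curve[t] <- sum(gbest$mask)
      if (t == T_) break
      w <- inertia(t, cfg, "linear")
      for (i in seq_len(N)) {
        up <- pso_update(pos[i, ], vel[i, ], pbest$pos[i, ], gbest$pos, w, cfg)
        pos[i, ] <- up$position
        vel[i, ] <- up$velocity
      }
    }
    new_trace(best_curve, nsel_curve, gbest$mask,
              evaluator_stats(st$evaluator)$evaluations - st$eval0, "pso")
  })
}

#' Binary-chromosome genetic algorithm baseline
#'
#' Tournament (k = 2) selection, uniform crossover with probability
#' `p_crossover`, bit-flip mutation at rate `1/p`, elitism of one.
#'
#' @inheritParams psoga_select
#' @return A `selection_trace`.
#' @export
ga_select <- function(X_cal, y_cal, cfg = selector_config(),
                      evaluator = NULL) {
  st <- selector_setup(X_cal, y_cal, cfg, evaluator, "ga")
  N <- cfg$pop_size; T_ <- cfg$max_iter; p <- st$p
  with_seed(st$sel_seed, {
    pop <- matrix(as.numeric(stats::runif(N * p) < 0.5), N, p)
    gbest <- list(fit = Inf, mask = NULL, pos = NULL)
    best_curve <- numeric(T_)
    nsel_curve <- integer(T_)
    for (t in seq_len(T_)) {
      fits <- numeric(N)
      masks <- vector("list", N)
      for (i in seq_len(N)) {
        masks[[i]] <- binarize(pop[i, ])
        fits[i] <- st$evaluator(masks[[i]])
        if (mask_better(fits[i], masks[[i]], gbest$fit, gbest$mask)) {
          gbest$fit <- fits[i]; gbest$mask <- masks[[i]]
        }
      }
      best_curve[t] <- gbest$fit
      nsel_curve[t] <- sum(gbest$mask)
      if (t == T_) break
      elite <- pop[order(fits, seq_len(N))[1], ]
      nxt <- matrix(0, N, p)
      nxt[1, ] <- elite
      filled <- 1L
      while (filled < N) {
        a <- tournament_pick(seq_len(N), fits)
        b <- tournament_pick(seq_len(N), fits)
        ch <- crossover(pop[a, ], pop[b, ], cfg$p_crossover)
        for (child in list(ch$child_a, ch$child_b)) {
          if (filled >= N) break
          flip <- stats::runif(p) < 1 / p
          child[flip] <- 1 - child[flip]
          filled <- filled + 1L
          nxt[filled, ] <- child
        }
      }
      pop <- nxt
    }
    new_trace(best_curve, nsel_curve, gbest$mask,
              evaluator_stats(st$evaluator)$evaluations - st$eval0, "ga")
  })
}

#' Grey wolf optimizer baseline
#'
#' Canonical GWO: the three best wolves (alpha, beta, delta) pull every wolf
#' through encircling updates with the control coefficient `a` decreasing
#' linearly from 2 to 0 over the run; continuous positions in `[0, 1]^p` are
#' thresholded through the shared binarization for fitness.
#'
#' @inheritParams psoga_select
#' @return A `selection_trace`.
#' @export
gwo_select <- function(X_cal, y_cal, cfg = selector_config(),
                       evaluator = NULL) {
  st <- selector_setup(X_cal, y_cal, cfg, evaluator, "gwo")
  N <- cfg$pop_size; T_ <- cfg$max_iter; p <- st$p
  with_seed(st$sel_seed, {
    pos <- matrix(stats::runif(N * p), N, p)
    gbest <- list(fit = Inf, mask = NULL, pos = NULL)
    best_curve <- numeric(T_)
    nsel_curve <- integer(T_)
    for (t in seq_len(T_)) {
      fits <- numeric(N)
      for (i in seq_len(N)) {
        m <- binarize(pos[i, ])
        fits[i] <- st$evaluator(m)
        if (mask_better(fits[i], m, gbest$fit, gbest$mask)) {
          gbest$fit <- fits[i]; gbest$mask <- m; gbest$pos <- pos[i, ]
        }
      }
      best_curve[t] <- gbest$fit
      nsel_curve[t] <- sum(gbest$mask)
      if (t == T_) break
      lead <- pos[order(fits, seq_len(N))[1:3], , drop = FALSE]
      a <- 2 * (1 - t / T_)
      for (i in seq_len(N)) {
        xk <- matrix(0, 3, p)
        for (k in 1:3) {
          A <- 2 * a * stats::runif(p) - a
          C <- 2 * stats::runif(p)
          D <- abs(C * lead[k, ] - pos[i, ])
          xk[k, ] <- lead[k, ] - A * D
        }
        pos[i, ] <- pmin(pmax(colMeans(xk), 0), 1)
      }
    }
    new_trace(best_curve, nsel_curve, gbest$mask,
              evaluator_stats(st$evaluator)$evaluations - st$eval0, "gwo")
  })
}
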