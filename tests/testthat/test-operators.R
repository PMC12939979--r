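test_that("logistic initialization produces chaotic orbits in (0,1)", {
  P <- logistic_init(50, 351, r = 4, seed = 5)
  expect_true(all(P > 0 & P < 1))
  # every row follows the map x[k+1] = 4 x[k] (1 - x[k]) exactly
  # (one step from 0.3 gives 0.84, and so on along the orbit)
  for (i in c(1, 25, 50)) {
    x <- P[i, ]
    expect_equal(x[-1], 4 * x[-351] * (1 - x[-351]), tolerance = 1e-12)
  }
  # invariant density of the r=4 map has mean 1/2
  expect_gt(mean(P), 0.3)
  expect_lt(mean(P), 0.7)
  expect_error(logistic_init(5, 10, r = 4.5), "r must be")
})

test_that("inertia schedules hit their boundaries and midpoints", {
  cfg <- selector_config(pop_size = 10, max_iter = 100, w_max = 0.9,
                         w_min = 0.4)
  expect_equal(inertia(0, cfg), 0.9)
  expect_equal(inertia(100, cfg), 0.4)
  expect_equal(inertia(50, cfg), 0.4 + 0.5 * 0.25)  # quadratic: 0.525
  expect_equal(inertia(0, cfg, "exp"), 0.9)
  expect_equal(inertia(100, cfg, "exp"), 0.4)
  expect_error(inertia(101, cfg), "\\[0, T\\]")
})

test_that("population classification splits by adaptive elite share", {
  cfg <- selector_config(pop_size = 4, max_iter = 10,
                         elite_share_start = 0.5, elite_share_end = 0.2)
  cl <- classify_population(c(3, 1, 2, 4), 0, cfg)
  expect_equal(cl$elite_idx, c(2, 3))
  expect_equal(cl$ordinary_idx, c(1, 4))
  # at t = 0 the share is elite_share_start
  expect_length(classify_population(rep(1, 4), 0, cfg)$elite_idx, 2)
  # ties resolved towards lower particle indices
  expect_equal(classify_population(rep(1, 4), 0, cfg)$elite_idx, c(1, 2))
})

test_that("PSO updates respect fixed points, clamping and clipping", {
  cfg <- selector_config(pop_size = 10, max_iter = 10, v_clamp = 0.5)
  x <- c(0.2, 0.8, 0.5)
  up <- withr::with_seed(1, pso_update(x, rep(0, 3), x, x, 0.7, cfg))
  expect_equal(up$position, x)
  expect_equal(up$velocity, rep(0, 3))

  withr::with_seed(2, {
    for (i in 1:20) {
      up <- pso_update(runif(3), runif(3, -1, 1), runif(3), runif(3),
                       0.9, cfg)
      expect_true(all(up$position >= 0 & up$position <= 1))
      expect_true(all(abs(up$velocity) <= cfg$v_clamp + 1e-12))
    }
  })
})

test_that("uniform crossover conserves coordinate multisets", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  b <- c(0.9, 0.8, 0.7, 0.6)
  expect_equal(withr::with_seed(1, crossover(a, a, 1)),
               list(child_a = a, child_b = a))
  expect_equal(withr::with_seed(1, crossover(a, b, 0)),
               list(child_a = a, child_b = b))
  withr::with_seed(3, {
    for (i in 1:10) {
      ch <- crossover(a, b, 1)
      for (j in 1:4) {
        expect_setequal(c(ch$child_a[j], ch$child_b[j]), c(a[j], b[j]))
      }
    }
  })
})

test_that("Levy steps follow Mantegna's construction with heavy tails", {
  # closed-form sigma_u evaluated independently from the gamma expression
  beta <- 1.5
  sigma_ref <- (gamma(1 + beta) * sin(pi * beta / 2) /
                  (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  expect_equal(levy_sigma(1.5), sigma_ref)
  expect_equal(levy_sigma(1.5), 0.6966, tolerance = 1e-4)

  expect_equal(withr::with_seed(1, levy_step(10, 1.5, 0)), rep(0, 10))
  s <- withr::with_seed(9, levy_step(1e5, 1.5, 1))
  kurt <- mean((s - mean(s))^4) / var(s)^2 - 3
  expect_gt(kurt, 10)
  expect_error(levy_step(5, 2.5), "beta")
})

test_that("polynomial mutation shrinks with the distribution index", {
  x <- runif(100)
  expect_identical(withr::with_seed(1, polynomial_mutation(x, 20, 0, 0)), x)
  withr::with_seed(2, {
    for (i in 1:20) {
      y <- polynomial_mutation(runif(50), 20, 0.5, levy_step(50, 1.5, 0.1))
      expect_true(all(y >= 0 & y <= 1))
    }
  })
  # eta_m -> Inf concentrates delta at zero: with eta = 1e6 and no Levy
  # amplification, perturbations stay below 1e-3 over 1e4 coordinates
  withr::with_seed(7, {
    x <- runif(1e4)
    y <- polynomial_mutation(x, 1e6, 1, 0)
    expect_lte(max(abs(y - x)), 1e-3)
  })
})
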