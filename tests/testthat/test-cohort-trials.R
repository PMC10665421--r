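test_that("effect size and pooled t-test match hand computation and t.test", {
  expect_equal(abs(cohens_d(c(1, 2, 3), c(4, 5, 6))), 3)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(0, 0), c(1, 1)), "pooled standard deviation")
  expect_error(cohens_d(1, 1:3), "at least 2")

  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(tt$t), 3 * sqrt(9 / 6), tolerance = 1e-12)
  expect_equal(abs(tt$t), 3.674, tolerance = 2e-4)
  expect_identical(tt$df, 4)
  expect_equal(tt$p, 0.0213, tolerance = 2e-3)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), mean = 0.4)
    mine <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    w <- two_sample_t(x, y, welch = TRUE)
    refw <- t.test(x, y)
    expect_equal(w$t, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-9)
    expect_equal(w$p, refw$p.value, tolerance = 1e-12)
  }
})

test_that("t and Cohen's d obey t = d * sqrt(n1 n2 / (n1 + n2))", {
  set.seed(23)
  for (i in 1:20) {
    n1 <- sample(4:30, 1); n2 <- sample(4:30, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    d <- cohens_d(x, y)
    t <- two_sample_t(x, y)$t
    expect_equal(t, d * sqrt(n1 * n2 / (n1 + n2)), tolerance = 1e-12)
  }
  # equal sizes: t / d = sqrt(n / 2)
  x <- rnorm(16); y <- rnorm(16, 1)
  expect_equal(two_sample_t(x, y)$t / cohens_d(x, y), sqrt(8),
               tolerance = 1e-12)
})

test_that("algorithm A returns disjoint cohorts satisfying its own stopping rule", {
  av <- generate_population(n = 300, seed = 31)
  res <- algorithm_a(av, parameter = "bmi", cohort_size = 30, d_min = 0.3,
                     alpha = 0.05, max_iter = 50000, seed = 31)
  expect_true(res$converged)
  expect_identical(length(res$cohort1_ids), 30L)
  expect_identical(length(res$cohort2_ids), 30L)
  expect_length(intersect(res$cohort1_ids, res$cohort2_ids), 0)
  # independent re-computation of the stopping conditions from the ids
  x <- av$bmi[match(res$cohort1_ids, av$id)]
  y <- av$bmi[match(res$cohort2_ids, av$id)]
  expect_equal(cohens_d(x, y), res$d, tolerance = 1e-12)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_lt(res$p, 0.05)
  expect_gte(abs(res$d), 0.3)
})

test_that("algorithm A reports non-termination explicitly", {
  av <- data.frame(id = 1:100, bmi = rep(25, 100))
  expect_warning(
    res <- algorithm_a(av, parameter = "bmi", cohort_size = 10,
                       d_min = 0.9, max_iter = 25, seed = 1),
    "no cohort pair")
  expect_false(res$converged)
  expect_true(is.na(res$iteration_found))
  expect_error(algorithm_a(av, cohort_size = 60), "smaller than")
})

test_that("algorithm B mean iterations match the geometric-law oracle", {
  set.seed(37)
  pop <- rnorm(20000)
  n <- 10
  res <- algorithm_b(pop, trial_sizes = n, d_grid = 0.8, repeats = 100,
                     seed = 37)
  # independent direct Monte Carlo of the stopping probability
  set.seed(12345)
  hits <- replicate(4000, {
    idx <- sample.int(length(pop), 2 * n)
    x <- pop[idx[1:n]]; y <- pop[idx[(n + 1):(2 * n)]]
    tt <- two_sample_t(x, y)
    tt$p < 0.05 && abs(cohens_d(x, y)) >= 0.8
  })
  p_hat <- mean(hits)
  se <- res$sd_iterations / sqrt(res$repeats)
  # also allow for the oracle's own Monte-Carlo error on 1/p
  se_oracle <- sqrt(p_hat * (1 - p_hat) / length(hits)) / p_hat^2
  expect_lt(abs(res$mean_iterations - 1 / p_hat),
            3 * sqrt(se^2 + se_oracle^2))
  expect_identical(res$censored_runs, 0L)
})

test_that("algorithm B iteration counts are pathwise monotone in the threshold", {
  pop <- generate_population(n = 20000, seed = 41)$bmi
  res <- algorithm_b(pop, trial_sizes = 20, d_grid = c(0.3, 0.5, 0.7),
                     repeats = 30, seed = 41)
  expect_true(all(diff(res$mean_iterations) >= 0))
  # reproducibility under the seed
  res2 <- algorithm_b(pop, trial_sizes = 20, d_grid = c(0.3, 0.5, 0.7),
                      repeats = 30, seed = 41)
  expect_identical(res, res2)
})

test_that("algorithm B flags censored runs at the iteration cap", {
  set.seed(43)
  pop <- rnorm(5000)
  res <- algorithm_b(pop, trial_sizes = 40, d_grid = 2.5, repeats = 5,
                     max_iter = 3, seed = 43)
  expect_identical(res$censored_runs, 5L)
  expect_true(is.nan(res$mean_iterations))
  expect_error(algorithm_b(rnorm(50), trial_sizes = 60), "smaller")
})
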