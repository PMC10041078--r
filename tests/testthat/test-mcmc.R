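test_that("control presets give the documented draw counts", {
  ctl <- brownie_control("full")
  expect_equal(ctl$n_retained_per_chain, 4000L)
  expect_equal(ctl$n_retained_total, 16000L)  # 4 x (50000 - 10000) / 10
  ctl <- brownie_control("desk")
  expect_equal(ctl$n_retained_total,
               ctl$n_chains * (ctl$n_iterations - ctl$burn_in) %/% ctl$thin)
  expect_error(brownie_control(n_iterations = 100, burn_in = 200))
})

test_that("fits are seed-deterministic and draw shapes are correct", {
  tp <- toy_population(Y = 5, n_HY = 300, n_AHY = 300, seed = 2)
  ctl <- brownie_control(n_chains = 2, n_iterations = 600, burn_in = 200,
                         thin = 2, seed = 99)
  f1 <- fit_brownie(tp$pop$marray, "uniform", ctl)
  f2 <- fit_brownie(tp$pop$marray, "uniform", ctl)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_brownie(tp$pop$marray, "uniform", ctl, seed = 100)
  expect_false(identical(f1$draws, f3$draws))
  expect_equal(dim(f1$draws), c(200L, 2L, 17L + 4L * 5L))
  flat <- as.matrix(f1)
  expect_true(all(flat[, "rho_HY"] >= -1 & flat[, "rho_HY"] <= 1))
  expect_true(all(flat[, "mean_S_AHY"] > 0.10 & flat[, "mean_S_AHY"] < 0.99))
  long <- as.data.frame(f1)
  expect_equal(nrow(long), 200 * 2 * (17 + 20))
  expect_setequal(unique(long$chain), 1:2)
})

test_that("split-chain R-hat behaves and matches the textbook formula", {
  set.seed(1)
  white <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat(white), 1.01)
  off <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(rhat(off), 1.1)
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "two chains")

  # independent implementation of split-chain PSRF
  ref_rhat <- function(m) {
    n <- nrow(m) %/% 2
    sub <- cbind(m[1:n, , drop = FALSE], m[(n + 1):(2 * n), , drop = FALSE])
    W <- mean(apply(sub, 2, var))
    B <- n * var(colMeans(sub))
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  for (i in 1:5) {
    m <- matrix(rnorm(600, sd = runif(1, 0.5, 2)), ncol = 3) +
      rep(rnorm(3, sd = 0.2), each = 200)
    expect_equal(rhat(m), ref_rhat(m), tolerance = 1e-12)
  }
})

test_that("posterior summaries are quantile-consistent", {
  tp <- toy_population(Y = 4, n_HY = 300, n_AHY = 300, seed = 3)
  fit <- fit_brownie(tp$pop$marray, "uniform",
                     brownie_control(n_chains = 2, n_iterations = 500,
                                     burn_in = 100, thin = 2, seed = 5))
  s <- summary(fit)
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5, na.rm = TRUE))
  flat <- as.matrix(fit)
  expect_equal(s$median[s$parameter == "rho_HY"],
               median(flat[, "rho_HY"]))
  expect_equal(s$sd[s$parameter == "mean_S_HY"], sd(flat[, "mean_S_HY"]))
  expect_named(coef(fit), c("mean_S_HY", "mean_f_HY", "mean_S_AHY",
                            "mean_f_AHY", "sigma_S_HY", "sigma_f_HY",
                            "rho_HY", "sigma_S_AHY", "sigma_f_AHY",
                            "rho_AHY"))
})

test_that("zero-information data reproduce the prior on the means", {
  M0 <- matrix(0L, 5, 6)
  mz <- marray_pair(M0, M0)
  fit <- fit_brownie(mz, "uniform", brownie_control("desk", seed = 3),
                     store_eps = FALSE)
  flat <- as.matrix(fit)
  # mean_S ~ Uniform(0.10, 0.99): mean 0.545, quartiles 0.3225 / 0.7675
  expect_lt(abs(mean(flat[, "mean_S_HY"]) - 0.545), 0.03)
  qs <- quantile(flat[, "mean_S_HY"], c(0.25, 0.5, 0.75), names = FALSE)
  expect_lt(max(abs(qs - c(0.3225, 0.545, 0.7675))), 0.05)
  # mean_f ~ Uniform(0.01, 0.30): mean 0.155
  expect_lt(abs(mean(flat[, "mean_f_AHY"]) - 0.155), 0.01)
  # correlation prior is flat: median near 0
  expect_lt(abs(median(flat[, "rho_HY"])), 0.15)
})

test_that("posterior matches the conjugate Beta on a one-year toy", {
  # one year, adults only, covariance fixed at ~0 so f is constant: the
  # direct-recovery count is Binomial(R, f) and a flat prior on f gives a
  # Beta(x + 1, R - x + 1) posterior (mean_f bounds are far from the mass)
  n <- 400L; x <- 37L
  mz <- marray_pair(matrix(c(0L, 0L), 1, 2), matrix(c(x, n - x), 1, 2))
  pr <- brownie_prior("uniform",
                      fixed_cov = c(sigma_S = 1e-3, sigma_f = 1e-3, rho = 0))
  fit <- fit_brownie(mz, pr, brownie_control("desk", seed = 4),
                     store_eps = FALSE)
  f_draws <- as.matrix(fit)[, "mean_f_AHY"]
  expect_equal(mean(f_draws), (x + 1) / (n + 2), tolerance = 0.002)
  expect_equal(sd(f_draws), sqrt((x + 1) * (n - x + 1) /
                                   ((n + 2)^2 * (n + 3))),
               tolerance = 0.15)
  ks <- suppressWarnings(
    stats::ks.test(f_draws, function(q) pbeta(q, x + 1, n - x + 1)))
  expect_gt(ks$p.value, 1e-4)
})

test_that("sampler recovers strongly negative correlation from rich data", {
  set.seed(606)
  tr <- draw_annual_rates(sim_hyperparams())
  pop <- simulate_population(tr, 10000, 10000)
  fit <- fit_brownie(pop$marray, "uniform", brownie_control("desk", seed = 1),
                     store_eps = FALSE)
  truth <- realized_correlation(pop, "HY")
  est <- summary(fit)
  rho_med <- est$median[est$parameter == "rho_HY"]
  lo <- est$q2.5[est$parameter == "rho_HY"]
  hi <- est$q97.5[est$parameter == "rho_HY"]
  expect_lt(abs(rho_med - truth), 0.25)
  expect_true(truth > lo - 0.1 && truth < hi + 0.1)
  # hierarchical means recovered
  expect_lt(abs(est$median[est$parameter == "mean_S_HY"] - 0.574), 0.05)
  expect_lt(abs(est$median[est$parameter == "mean_f_AHY"] - 0.032), 0.01)
})

test_that("credible intervals are calibrated at reduced scale", {
  # simulation-based check: over replicates of (draw rates, simulate,
  # fit), the 95% CrI for mean_S_AHY should cover the generating value
  # 0.571 at close to nominal rate
  n_rep <- 40
  hits <- 0L
  ctl <- brownie_control(n_chains = 2, n_iterations = 1500, burn_in = 500,
                         thin = 2)
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    tr <- draw_annual_rates(sim_hyperparams(Y = 8))
    pop <- simulate_population(tr, 800, 1200)
    fit <- fit_brownie(pop$marray, "uniform", ctl, seed = 7000 + r,
                       store_eps = FALSE)
    flat <- as.matrix(fit)
    ci <- quantile(flat[, "mean_S_AHY"], c(0.025, 0.975), names = FALSE)
    if (ci[1] <= 0.571 && 0.571 <= ci[2]) hits <- hits + 1L
  }
  # binomial(40, 0.95): P(hits >= 34) > 0.999
  expect_gte(hits, 34L)
})

test_that("initialisation failure raises an explicit error", {
  # bounds forced onto a sliver where every starting state gives
  # never-recovered row sums above 1 (f / (1 - S) >> 1 over six years)
  Y <- 6
  M <- matrix(0L, Y, Y + 1)
  M[1, 1] <- 5L; M[1, Y + 1] <- 95L
  pr <- brownie_prior("uniform", mean_S_bounds = c(0.95, 0.99),
                      mean_f_bounds = c(0.28, 0.30))
  m <- marray_pair(M, M)
  expect_error(
    fit_brownie(m, pr, brownie_control(n_chains = 1, n_iterations = 200,
                                       burn_in = 50, thin = 1, seed = 1)),
    "initialise")
})
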