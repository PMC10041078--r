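test_that("cell probabilities match hand products", {
  p <- brownie_cell_probs(S_HY = 0.6, f_HY = 0.08,
                          S_AHY = 0.5, f_AHY = 0.04, Y = 3)
  expect_equal(p$alpha[1, ], c(0.08, 0.6 * 0.04, 0.6 * 0.5 * 0.04, 0.884))
  p <- brownie_cell_probs(S_HY = 0.6, f_HY = 0.1,
                          S_AHY = 0.5, f_AHY = 0.1, Y = 2)
  expect_equal(p$beta[1, ], c(0.1, 0.05, 0.85))
})

test_that("cell-probability rows are simplexes and match the chain oracle", {
  set.seed(31)
  for (rep in 1:5) {
    Y <- 8
    S_H <- runif(Y, 0.3, 0.7); f_H <- runif(Y, 0.01, 0.15)
    S_A <- runif(Y, 0.3, 0.7); f_A <- runif(Y, 0.01, 0.15)
    p <- brownie_cell_probs(S_H, f_H, S_A, f_A)
    expect_true(all(abs(rowSums(p$alpha) - 1) < 1e-12))
    expect_true(all(abs(rowSums(p$beta) - 1) < 1e-12))
    o <- oracle_cell_probs(S_H, f_H, S_A, f_A)
    expect_equal(p$alpha, o$alpha, tolerance = 1e-12)
    expect_equal(p$beta, o$beta, tolerance = 1e-12)
  }
})

test_that("cell probabilities reject inconsistent rates naming the year", {
  expect_error(brownie_cell_probs(c(0.5, 0.9), c(0.05, 0.2), 0.5, 0.05),
               "S_HY \\+ f_HY > 1 in year 2")
  expect_error(brownie_cell_probs(0.5, 1.2, 0.5, 0.05), "strictly in")
})

test_that("multinomial log-likelihood matches its closed forms and oracle", {
  # all releases unrecovered with never-recovery probability 1 contributes 0
  m0 <- marray_pair(rbind(c(0L, 10L)), rbind(c(0L, 5L)))
  expect_equal(brownie_loglik(m0, list(alpha = rbind(c(0, 1)),
                                       beta = rbind(c(0, 1)))), 0)

  m <- marray_pair(rbind(c(0L, 10L)), rbind(c(1L, 9L)))
  p <- brownie_cell_probs(0.6, 0.08, 0.5, 0.1, Y = 1)
  expect_equal(brownie_loglik(m, p),
               10 * log(1 - 0.08) + log(0.1) + 9 * log(0.9))

  # single release, direct recovery, f = 0.1
  m1 <- marray_pair(rbind(c(0L, 0L)), rbind(c(1L, 0L)))
  expect_equal(brownie_loglik(m1, p), log(0.1), tolerance = 1e-12)
  expect_equal(log(0.1), -2.302585, tolerance = 1e-6)

  # random 4-year m-array: equals dmultinom summed over cohorts
  set.seed(7)
  tp <- toy_population(Y = 4, n_HY = 400, n_AHY = 400, seed = 7)
  m <- tp$pop$marray
  p <- brownie_cell_probs(tp$rates)
  ref <- 0
  for (i in 1:4) {
    ref <- ref + dmultinom(m$M_HY[i, ], prob = p$alpha[i, ], log = TRUE) +
      dmultinom(m$M_AHY[i, ], prob = p$beta[i, ], log = TRUE)
  }
  expect_equal(brownie_loglik(m, p, include_const = TRUE), ref,
               tolerance = 1e-10)

  # likelihood factorises over cohorts (constants dropped)
  per_cohort <- vapply(1:4, function(i) {
    sum(m$M_HY[i, ][m$M_HY[i, ] > 0] * log(p$alpha[i, ][m$M_HY[i, ] > 0])) +
      sum(m$M_AHY[i, ][m$M_AHY[i, ] > 0] * log(p$beta[i, ][m$M_AHY[i, ] > 0]))
  }, 0)
  expect_equal(brownie_loglik(m, p), sum(per_cohort), tolerance = 1e-10)
})

test_that("zero cell probability with a nonzero count yields -Inf", {
  m <- marray_pair(rbind(c(1L, 9L)), rbind(c(0L, 10L)))
  p <- list(alpha = rbind(c(0, 1)), beta = rbind(c(0.1, 0.9)))
  expect_identical(brownie_loglik(m, p), -Inf)
})

test_that("compiled likelihood agrees with the R implementation", {
  set.seed(11)
  for (Y in c(1, 2, 9)) {
    tp <- toy_population(Y = Y, n_HY = 300, n_AHY = 500, seed = Y)
    m <- tp$pop$marray
    p <- brownie_cell_probs(tp$rates)
    expect_equal(
      tagcor:::brownie_loglik_cpp(m$M_HY, m$M_AHY, tp$rates$HY$S,
                                  tp$rates$HY$f, tp$rates$AHY$S,
                                  tp$rates$AHY$f),
      brownie_loglik(m, p), tolerance = 1e-9)
  }
})

test_that("precision-matrix correlation inverts correctly", {
  expect_equal(rho_from_precision(diag(2)), 0)
  P <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(rho_from_precision(P), -0.6)
  set.seed(3)
  for (i in 1:20) {
    A <- matrix(rnorm(4), 2)
    P <- crossprod(A) + diag(0.1, 2)
    Sig <- solve(P)  # numerical-inversion oracle
    expect_equal(rho_from_precision(P),
                 Sig[1, 2] / sqrt(Sig[1, 1] * Sig[2, 2]), tolerance = 1e-10)
  }
  expect_error(rho_from_precision(matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
  expect_error(rho_from_precision(matrix(c(1, 0.5, -0.5, 1), 2)), "symmetric")
})

test_that("prior log-densities respect their supports", {
  pr <- brownie_prior("uniform")
  inside <- prior_logdensity(pr, list(sigma_S = 1, sigma_f = 1, rho = 0))
  expect_true(is.finite(inside))
  expect_equal(prior_logdensity(pr, list(sigma_S = 2, sigma_f = 0.3,
                                         rho = -0.9)),
               inside)  # flat inside the support
  expect_identical(prior_logdensity(pr, list(sigma_S = 6, sigma_f = 1,
                                             rho = 0)), -Inf)
  expect_identical(prior_logdensity(pr, list(sigma_S = 1, sigma_f = 1,
                                             rho = 1)), -Inf)
  expect_identical(
    prior_logdensity(pr, list(sigma_S = 1, sigma_f = 1, rho = 0,
                              mean_S = 0.05)), -Inf)
  pg <- brownie_prior("gamma")
  expect_true(is.finite(prior_logdensity(
    pg, list(tau_S = 10, tau_f = 50, rho_star = 0.5))))
  expect_identical(prior_logdensity(
    pg, list(tau_S = -1, tau_f = 50, rho_star = 0.5)), -Inf)
})

test_that("Wishart prior density matches the textbook formula", {
  # independently coded density: |W|^((df-p-1)/2) exp(-tr(V^-1 W)/2) /
  #   (2^(df p / 2) |V|^(df/2) Gamma_p(df/2))
  ref_dwish <- function(W, df, V) {
    p <- nrow(W)
    gammap <- pi^(p * (p - 1) / 4) *
      prod(gamma(df / 2 + (1 - seq_len(p)) / 2))
    log(det(W)) * (df - p - 1) / 2 -
      sum(diag(solve(V) %*% W)) / 2 -
      df * p / 2 * log(2) - df / 2 * log(det(V)) - log(gammap)
  }
  pr <- brownie_prior("wishart")
  set.seed(9)
  for (i in 1:10) {
    A <- matrix(rnorm(4), 2)
    W <- crossprod(A) + diag(0.05, 2)
    expect_equal(prior_logdensity(pr, list(Prec = W)),
                 ref_dwish(W, 3, diag(2)), tolerance = 1e-9)
  }
  expect_error(prior_logdensity(pr, list(Prec = matrix(c(1, 0.4, -0.2, 1),
                                                       2))),
               "symmetric")
})

test_that("gamma parameterisation satisfies rho = -rho_star exactly", {
  set.seed(5)
  for (i in 1:50) {
    tau_S <- rexp(1, 0.1); tau_f <- rexp(1, 0.1)
    rs <- runif(1, -0.99, 0.99)
    P <- matrix(c(tau_S, rs * sqrt(tau_S * tau_f),
                  rs * sqrt(tau_S * tau_f), tau_f), 2)
    expect_equal(rho_from_precision(P), -rs, tolerance = 1e-12)
  }
})

test_that("Wishart(3, I) prior-predictive correlation is uniform on (-1,1)", {
  set.seed(2024)
  W <- stats::rWishart(1e5, df = 3, Sigma = diag(2))
  rho <- -W[1, 2, ] / sqrt(W[1, 1, ] * W[2, 2, ])
  u <- (rho + 1) / 2
  D <- suppressWarnings(stats::ks.test(u, "punif")$statistic)
  expect_lt(D, 0.01)
})
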