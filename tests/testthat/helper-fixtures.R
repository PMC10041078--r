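# Shared fixture builders: everything is generated in code at test time.

# A small simulated population at the default hyperparameters, for reuse.
toy_population <- function(Y = 8, n_HY = 1000, n_AHY = 1500, seed = 123) {
  set.seed(seed)
  tr <- draw_annual_rates(sim_hyperparams(Y = Y))
  list(rates = tr, pop = simulate_population(tr, n_HY, n_AHY))
}

# Random recovery-record table with internally consistent years.
random_records <- function(n, Y, seed = 1) {
  set.seed(seed)
  release <- sample.int(Y, n, replace = TRUE)
  age <- sample(c("HY", "AHY"), n, replace = TRUE)
  recovered <- stats::runif(n) < 0.4
  recovery <- ifelse(recovered,
                     release + vapply(release,
                                      function(r) sample.int(Y - r + 1L, 1),
                                      1L) - 1L,
                     NA_integer_)
  data.frame(release_year = release, age = age, recovery_year = recovery)
}

# Independent O(Y^2) cell-probability oracle built on explicit survival
# chains (recursive products), deliberately sharing no code with the package
# implementation.
oracle_cell_probs <- function(S_H, f_H, S_A, f_A) {
  Y <- length(S_H)
  chain <- function(S, from, to) {  # prod of S over years from..to
    if (from > to) return(1)
    out <- 1
    for (k in from:to) out <- out * S[k]
    out
  }
  alpha <- matrix(0, Y, Y + 1)
  beta <- matrix(0, Y, Y + 1)
  for (i in seq_len(Y)) {
    for (j in i:Y) {
      if (j == i) {
        alpha[i, j] <- f_H[i]
        beta[i, j] <- f_A[i]
      } else {
        alpha[i, j] <- S_H[i] * chain(S_A, i + 1, j - 1) * f_A[j]
        beta[i, j] <- chain(S_A, i, j - 1) * f_A[j]
      }
    }
    alpha[i, Y + 1] <- 1 - sum(alpha[i, 1:Y])
    beta[i, Y + 1] <- 1 - sum(beta[i, 1:Y])
  }
  list(alpha = alpha, beta = beta)
}
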