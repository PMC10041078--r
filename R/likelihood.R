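#' Brownie cell probabilities for two age classes
#'
#' Computes the multinomial cell probabilities of the Brownie band-recovery
#' model.  For an adult cohort released in year `i`, the diagonal cell is the
#' direct-recovery probability `f_AHY[i]`; an indirect recovery in year
#' `j > i` requires surviving years `i..j-1` at adult rates and being
#' recovered in year `j`:
#' `beta[i, j] = f_AHY[j] * prod(S_AHY[i..j-1])`.
#' A juvenile cohort is recovered directly with `f_HY[i]`, survives its first
#' year with `S_HY[i]`, and thereafter lives (and is recovered) at adult
#' rates:
#' `alpha[i, j] = S_HY[i] * prod(S_AHY[(i+1)..(j-1)]) * f_AHY[j]`.
#' The last column of each matrix is the never-recovered probability, one
#' minus the row sum, so every row is an exact probability simplex.
#'
#' The constraint `S + f <= 1` is what makes these cell probabilities
#' consistent with an individual-level fate process (recovered / die
#' unrecovered / survive); it is checked here (`check = TRUE`) because this
#' function also drives the simulator.  The MCMC sampler does not impose it:
#' any parameter value whose rows fail to be a simplex simply has zero
#' likelihood.
#'
#' @param S_HY,f_HY,S_AHY,f_AHY Numeric vectors of length `Y` with annual
#'   survival and recovery probabilities in (0, 1), or pass a
#'   [draw_annual_rates()] trajectory as the first argument.
#' @param check Validate `S + f <= 1` per age class (error names the year).
#' @return A list with matrices `alpha` (HY) and `beta` (AHY), each
#'   `Y x (Y + 1)`.
#' @examples
#' p <- brownie_cell_probs(S_HY = 0.6, f_HY = 0.08,
#'                         S_AHY = 0.5, f_AHY = 0.04, Y = 3)
#' p$alpha[1, ]  # 0.080 0.024 0.012 0.884
#' @param Y Number of years; only needed when rates are given as scalars.
#' @export
brownie_cell_probs <- function(S_HY, f_HY, S_AHY, f_AHY, Y = NULL,
                               check = TRUE) {
  if (inherits(S_HY, "rate_trajectory")) {
    tr <- S_HY
    S_HY <- tr$HY$S; f_HY <- tr$HY$f
    S_AHY <- tr$AHY$S; f_AHY <- tr$AHY$f
  }
  if (is.null(Y)) Y <- max(length(S_HY), length(f_HY),
                           length(S_AHY), length(f_AHY))
  S_HY <- rep_len(S_HY, Y); f_HY <- rep_len(f_HY, Y)
  S_AHY <- rep_len(S_AHY, Y); f_AHY <- rep_len(f_AHY, Y)
  rates <- list(S_HY = S_HY, f_HY = f_HY, S_AHY = S_AHY, f_AHY = f_AHY)
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (any(!is.finite(r)) || any(r <= 0) || any(r >= 1)) {
      stop(nm, " must lie strictly in (0, 1)")
    }
  }
  if (check) {
    bad <- which(S_HY + f_HY > 1)
    if (length(bad)) stop("S_HY + f_HY > 1 in year ", bad[1],
                          ": no trinomial fate process exists")
    bad <- which(S_AHY + f_AHY > 1)
    if (length(bad)) stop("S_AHY + f_AHY > 1 in year ", bad[1],
                          ": no trinomial fate process exists")
  }
  alpha <- matrix(0, Y, Y + 1L)
  beta <- matrix(0, Y, Y + 1L)
  for (i in seq_len(Y)) {
    beta[i, i] <- f_AHY[i]
    alpha[i, i] <- f_HY[i]
    if (i < Y) {
      for (j in (i + 1L):Y) {
        chain_a <- if (j > i + 1L) prod(S_AHY[(i + 1L):(j - 1L)]) else 1
        beta[i, j] <- f_AHY[j] * prod(S_AHY[i:(j - 1L)])
        alpha[i, j] <- S_HY[i] * chain_a * f_AHY[j]
      }
    }
  }
  alpha[, Y + 1L] <- 1 - rowSums(alpha[, seq_len(Y), drop = FALSE])
  beta[, Y + 1L] <- 1 - rowSums(beta[, seq_len(Y), drop = FALSE])
  list(alpha = alpha, beta = beta)
}

#' Joint multinomial log-likelihood of an m-array pair
#'
#' Sums the multinomial log-probability over all cohorts of both age classes.
#' Multinomial normalising constants are dropped by default (they do not
#' involve the parameters, so MCMC is unaffected); set
#' `include_const = TRUE` to obtain the full log-pmf for comparison against
#' generic multinomial implementations.  A zero cell probability paired with
#' a nonzero count yields `-Inf`, not an error.
#'
#' @param marrays A [marray_pair()].
#' @param cellprobs A list with `alpha` and `beta` as returned by
#'   [brownie_cell_probs()].
#' @param include_const Include the log multinomial coefficients.
#' @return A single numeric log-likelihood.
#' @examples
#' m <- marray_pair(rbind(c(0, 0, 10)), rbind(c(1, 0, 9)))
#' p <- brownie_cell_probs(0.6, 0.08, 0.5, 0.1, Y = 1)
#' brownie_loglik(m, p)  # 9 * log(0.9) + log(0.1)
#' @export
brownie_loglik <- function(marrays, cellprobs, include_const = FALSE) {
  stopifnot(inherits(marrays, "marray_pair"))
  ll <- 0
  for (part in list(list(M = marrays$M_HY, P = cellprobs$alpha),
                    list(M = marrays$M_AHY, P = cellprobs$beta))) {
    M <- part$M; P <- part$P
    if (!all(dim(M) == dim(P))) {
      stop("m-array and cell-probability dimensions differ")
    }
    nz <- M > 0
    logp <- ifelse(P[nz] > 0, log(P[nz]), -Inf)
    ll <- ll + sum(M[nz] * logp)
    if (include_const) {
      R <- rowSums(M)
      ll <- ll + sum(lgamma(R + 1)) - sum(lgamma(M + 1))
    }
  }
  ll
}

#' Correlation implied by a 2x2 precision matrix
#'
#' Inverts the precision matrix and returns the covariance-scale correlation
#' `rho = Sigma[1,2] / sqrt(Sigma[1,1] * Sigma[2,2])`.  For the 2x2 case this
#' equals minus the precision-matrix correlation analogue `rho*`, a useful
#' identity when working with the Gamma prior parameterisation.
#'
#' @param Prec A symmetric positive-definite 2x2 matrix.
#' @return Correlation in (-1, 1).
#' @examples
#' rho_from_precision(diag(2))       # 0
#' P <- matrix(c(1, 0.6, 0.6, 1), 2) # rho* = 0.6
#' rho_from_precision(P)             # -0.6
#' @export
rho_from_precision <- function(Prec) {
  Prec <- as.matrix(Prec)
  if (!all(dim(Prec) == c(2L, 2L))) stop("Prec must be 2x2")
  if (abs(Prec[1, 2] - Prec[2, 1]) > 1e-8 * (abs(Prec[1, 2]) + 1)) {
    stop("Prec must be symmetric")
  }
  det <- Prec[1, 1] * Prec[2, 2] - Prec[1, 2] * Prec[2, 1]
  if (!is.finite(det) || det <= 0 || Prec[1, 1] <= 0 || Prec[2, 2] <= 0) {
    stop("Prec must be positive definite")
  }
  Sigma <- matrix(c(Prec[2, 2], -Prec[1, 2], -Prec[2, 1], Prec[1, 1]),
                  2, 2) / det
  Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2])
}

#' Assemble a 2x2 covariance matrix from SDs and a correlation
#'
#' @param sigma_S,sigma_f Logit-scale standard deviations (non-negative).
#' @param rho Correlation in `[-1, 1]`.
#' @return A 2x2 covariance matrix (survival first, recovery second).
#' @export
cov_matrix <- function(sigma_S, sigma_f, rho) {
  stopifnot(sigma_S >= 0, sigma_f >= 0, abs(rho) <= 1)
  matrix(c(sigma_S^2, rho * sigma_S * sigma_f,
           rho * sigma_S * sigma_f, sigma_f^2), 2, 2)
}
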