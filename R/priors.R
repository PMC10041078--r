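#' Prior specification for the hierarchical Brownie model
#'
#' Three alternative priors for the covariance structure of the annual
#' random effects, applied independently to each age class:
#'
#' * `"wishart"`: the precision matrix gets `Wishart(df = 3, scale = I)`
#'   (so the prior mean of the precision is `3 * I`, the convention of the
#'   common Gibbs-sampling software).  This is conjugate and heavy-tailed
#'   toward large random-effect variances.
#' * `"uniform"`: `sigma_S, sigma_f ~ Uniform(0, 5)` on the logit-scale SDs
#'   and a flat prior on the correlation, `rho = 2 * Beta(1, 1) - 1`.
#' * `"gamma"`: `Gamma(shape = 1.001, rate = 0.001)` on each diagonal of the
#'   precision matrix (`1 / sigma^2`) and a flat prior on the
#'   precision-matrix correlation analogue, `rho* = 2 * Beta(1, 1) - 1`
#'   (which maps to covariance-scale correlation `rho = -rho*`).
#'
#' All three share vague but bounded priors on the natural-scale hierarchical
#' means: `mean_S ~ Uniform(0.10, 0.99)` and `mean_f ~ Uniform(0.01, 0.30)`,
#' ranges wide relative to plausible waterfowl survival and recovery but
#' bounded away from 0 and 1 to avoid start-up failures.
#'
#' @param kind One of `"uniform"`, `"wishart"`, `"gamma"`.
#' @param wishart_df,wishart_scale Wishart hyperparameters (default df 3,
#'   identity scale).
#' @param sigma_upper Upper bound of the Uniform prior on SDs.
#' @param gamma_shape,gamma_rate Gamma hyperparameters on precision diagonals.
#' @param mean_S_bounds,mean_f_bounds Uniform bounds for the natural-scale
#'   hierarchical means.
#' @param fixed_cov Optional named vector `c(sigma_S=, sigma_f=, rho=)` fixing
#'   the random-effect covariance (the covariance block is then not sampled);
#'   mainly for validation runs against conjugate posteriors.
#' @return An object of class `brownie_prior`.
#' @examples
#' brownie_prior("uniform")
#' brownie_prior("gamma", gamma_shape = 1.1, gamma_rate = 0.1)
#' @export
brownie_prior <- function(kind = c("uniform", "wishart", "gamma"),
                          wishart_df = 3, wishart_scale = diag(2),
                          sigma_upper = 5,
                          gamma_shape = 1.001, gamma_rate = 0.001,
                          mean_S_bounds = c(0.10, 0.99),
                          mean_f_bounds = c(0.01, 0.30),
                          fixed_cov = NULL) {
  kind <- match.arg(kind)
  stopifnot(wishart_df > 1, sigma_upper > 0, gamma_shape > 0, gamma_rate > 0,
            length(mean_S_bounds) == 2, length(mean_f_bounds) == 2,
            mean_S_bounds[1] > 0, mean_S_bounds[2] < 1,
            mean_f_bounds[1] > 0, mean_f_bounds[2] < 1)
  if (!is.null(fixed_cov)) {
    need <- c("sigma_S", "sigma_f", "rho")
    if (!all(need %in% names(fixed_cov))) {
      stop("fixed_cov needs named entries ", paste(need, collapse = ", "))
    }
    stopifnot(fixed_cov[["sigma_S"]] > 0, fixed_cov[["sigma_f"]] > 0,
              abs(fixed_cov[["rho"]]) < 1)
  }
  structure(
    list(kind = kind, wishart_df = wishart_df,
         wishart_scale = as.matrix(wishart_scale),
         sigma_upper = sigma_upper,
         gamma_shape = gamma_shape, gamma_rate = gamma_rate,
         mean_S_bounds = as.numeric(mean_S_bounds),
         mean_f_bounds = as.numeric(mean_f_bounds),
         fixed_cov = fixed_cov),
    class = "brownie_prior"
  )
}

#' @export
print.brownie_prior <- function(x, ...) {
  cat("Brownie covariance prior:", x$kind, "\n")
  switch(x$kind,
    wishart = cat("  Prec ~ Wishart(", x$wishart_df, ", scale)\n"),
    uniform = cat("  sigma ~ Uniform(0,", x$sigma_upper,
                  "), rho ~ flat on (-1, 1)\n"),
    gamma = cat("  1/sigma^2 ~ Gamma(", x$gamma_shape, ",", x$gamma_rate,
                "), rho* ~ flat on (-1, 1)\n"))
  cat(sprintf("  mean_S ~ Uniform(%.2f, %.2f), mean_f ~ Uniform(%.2f, %.2f)\n",
              x$mean_S_bounds[1], x$mean_S_bounds[2],
              x$mean_f_bounds[1], x$mean_f_bounds[2]))
  if (!is.null(x$fixed_cov)) cat("  covariance fixed, not sampled\n")
  invisible(x)
}

#' Log prior density of one age class's hyperparameters
#'
#' Evaluates the joint log prior density of the covariance-structure
#' parameters (in the parameterisation matching `prior$kind`) and,
#' optionally, the natural-scale hierarchical means.  Returns `-Inf` outside
#' the support (SD outside its Uniform range, correlation magnitude at or
#' above 1, means outside their bounds, non-positive-definite matrices);
#' normalising constants are included.
#'
#' @param prior A [brownie_prior()].
#' @param params A named list: for `"wishart"` supply `Prec` (2x2 symmetric
#'   PD); for `"uniform"` supply `sigma_S`, `sigma_f`, `rho`; for `"gamma"`
#'   supply `tau_S`, `tau_f` (precision diagonals) and `rho_star`.  Optional
#'   `mean_S` and `mean_f` add their Uniform log densities.
#' @return Log density (finite inside support, `-Inf` outside).
#' @examples
#' pr <- brownie_prior("uniform")
#' prior_logdensity(pr, list(sigma_S = 1, sigma_f = 1, rho = 0))
#' prior_logdensity(pr, list(sigma_S = 6, sigma_f = 1, rho = 0))  # -Inf
#' @export
prior_logdensity <- function(prior, params) {
  stopifnot(inherits(prior, "brownie_prior"))
  ld <- 0
  if (!is.null(params$mean_S)) {
    b <- prior$mean_S_bounds
    ld <- ld + stats::dunif(params$mean_S, b[1], b[2], log = TRUE)
  }
  if (!is.null(params$mean_f)) {
    b <- prior$mean_f_bounds
    ld <- ld + stats::dunif(params$mean_f, b[1], b[2], log = TRUE)
  }
  if (!is.finite(ld)) return(-Inf)
  cov_ld <- switch(prior$kind,
    uniform = {
      s1 <- params$sigma_S; s2 <- params$sigma_f; r <- params$rho
      if (is.null(s1) || is.null(s2) || is.null(r)) {
        stop("uniform prior needs sigma_S, sigma_f, rho")
      }
      if (s1 <= 0 || s1 >= prior$sigma_upper ||
          s2 <= 0 || s2 >= prior$sigma_upper || abs(r) >= 1) {
        -Inf
      } else {
        # two Uniform(0, upper) SDs and rho = 2 Beta(1,1) - 1 (density 1/2)
        -2 * log(prior$sigma_upper) + log(0.5)
      }
    },
    gamma = {
      t1 <- params$tau_S; t2 <- params$tau_f; rs <- params$rho_star
      if (is.null(t1) || is.null(t2) || is.null(rs)) {
        stop("gamma prior needs tau_S, tau_f, rho_star")
      }
      if (t1 <= 0 || t2 <= 0 || abs(rs) >= 1) {
        -Inf
      } else {
        stats::dgamma(t1, prior$gamma_shape, rate = prior$gamma_rate,
                      log = TRUE) +
          stats::dgamma(t2, prior$gamma_shape, rate = prior$gamma_rate,
                        log = TRUE) + log(0.5)
      }
    },
    wishart = {
      W <- params$Prec
      if (is.null(W)) stop("wishart prior needs Prec")
      W <- as.matrix(W)
      if (abs(W[1, 2] - W[2, 1]) > 1e-8 * (abs(W[1, 2]) + 1)) {
        stop("Prec must be symmetric")
      }
      detW <- W[1, 1] * W[2, 2] - W[1, 2]^2
      if (W[1, 1] <= 0 || detW <= 0) {
        -Inf
      } else {
        dwishart_log(W, prior$wishart_df, prior$wishart_scale)
      }
    })
  ld + cov_ld
}

# Wishart(df, V) log density at 2x2 matrix W, scale convention E[W] = df * V.
dwishart_log <- function(W, df, V) {
  p <- 2
  detW <- W[1, 1] * W[2, 2] - W[1, 2]^2
  detV <- V[1, 1] * V[2, 2] - V[1, 2]^2
  Vinv <- matrix(c(V[2, 2], -V[1, 2], -V[2, 1], V[1, 1]), 2, 2) / detV
  tr <- sum(diag(Vinv %*% W))
  lmvgamma <- (p * (p - 1) / 4) * log(pi) +
    sum(lgamma(df / 2 + (1 - seq_len(p)) / 2))
  (df - p - 1) / 2 * log(detW) - tr / 2 -
    df * p / 2 * log(2) - df / 2 * log(detV) - lmvgamma
}
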