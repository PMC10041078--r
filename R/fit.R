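#' MCMC configuration
#'
#' Two named presets: `"full"` runs 4 chains of 50,000 iterations with a
#' 10,000-iteration burn-in and thinning by 10, retaining 4,000 draws per
#' chain (16,000 in total), the configuration used for full replication runs.
#' `"desk"` is a lighter default for interactive work and reduced-scale power
#' analyses: 4 chains of 6,000 iterations, burn-in 1,000, thinning by 5
#' (4,000 retained in total).
#'
#' @param preset `"desk"` or `"full"`, or `NULL` when giving fields directly.
#' @param n_chains,n_iterations,burn_in,thin Override individual fields.
#' @param seed Integer master seed; chain seeds are derived from it.
#' @return An object of class `brownie_control`.
#' @examples
#' brownie_control("full")$n_retained_total  # 16000
#' @export
brownie_control <- function(preset = c("desk", "full"), n_chains = NULL,
                            n_iterations = NULL, burn_in = NULL, thin = NULL,
                            seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    desk = list(n_chains = 4L, n_iterations = 6000L, burn_in = 1000L,
                thin = 5L),
    full = list(n_chains = 4L, n_iterations = 50000L, burn_in = 10000L,
                thin = 10L))
  x <- list(
    n_chains = as.integer(n_chains %||% def$n_chains),
    n_iterations = as.integer(n_iterations %||% def$n_iterations),
    burn_in = as.integer(burn_in %||% def$burn_in),
    thin = as.integer(thin %||% def$thin),
    seed = as.integer(seed),
    preset = preset)
  stopifnot(x$n_chains >= 1, x$burn_in >= 0, x$thin >= 1,
            x$n_iterations > x$burn_in)
  x$n_retained_per_chain <- (x$n_iterations - x$burn_in) %/% x$thin
  x$n_retained_total <- x$n_retained_per_chain * x$n_chains
  structure(x, class = "brownie_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.brownie_control <- function(x, ...) {
  cat(sprintf(
    "MCMC control (%s): %d chains x %d iterations, burn-in %d, thin %d\n",
    x$preset, x$n_chains, x$n_iterations, x$burn_in, x$thin))
  cat(sprintf("retained draws: %d per chain, %d total; seed %d\n",
              x$n_retained_per_chain, x$n_retained_total, x$seed))
  invisible(x)
}

# Deterministic stream of sub-seeds below 2^31 derived from a master seed.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 69621) %% 2147483399) + 1L
}

#' Fit the hierarchical Brownie model to an m-array pair
#'
#' Samples the joint posterior of the two-age-class Brownie band-recovery
#' model: annual survival and recovery on the logit scale are a hierarchical
#' mean plus a correlated bivariate-normal annual random effect, with age
#' classes sharing neither means nor random effects (adult rates do enter the
#' indirect-recovery cells of juvenile cohorts, so the two m-arrays are fitted
#' jointly).  The covariance structure of the random effects gets one of the
#' three priors in [brownie_prior()].
#'
#' The sampler is an adaptive Metropolis-within-Gibbs scheme: random-walk
#' updates for the hierarchical means and each year's random-effect pair, a
#' likelihood-invariant translation move between each mean and its random
#' effects (which removes the mean/effect ridge), random-walk updates for the
#' covariance parameters under the Uniform and Gamma priors, and a conjugate
#' Gibbs draw of the precision matrix under the Wishart prior.  Proposal
#' scales adapt during burn-in only.  Chains are initialised from the
#' interior of the prior support; initialisation is retried and then fails
#' with an explicit error if no valid starting state is found.
#'
#' @param data A [marray_pair()].
#' @param prior A [brownie_prior()] or one of `"uniform"`, `"wishart"`,
#'   `"gamma"`.
#' @param control A [brownie_control()].
#' @param seed Optional integer overriding `control$seed`.
#' @param store_eps Keep the per-year random-effect draws (needed by
#'   [annual_rates()] and [plot.brownie_fit()]; switch off to save memory in
#'   large batch runs).
#' @return An object of class `brownie_fit` with elements `draws` (array of
#'   retained iterations x chains x parameters), `prior`, `control`, `data_Y`
#'   and `store_eps`.  Methods: `print`, `summary`, `coef`, `plot`,
#'   `as.matrix`, `as.data.frame`, [rhat()], [annual_rates()].
#' @examples
#' \donttest{
#' hyper <- sim_hyperparams(Y = 10)
#' rates <- draw_annual_rates(hyper)
#' pop <- simulate_population(rates, n_HY = 2000, n_AHY = 2000)
#' fit <- fit_brownie(marray_pair(pop$marray$M_HY, pop$marray$M_AHY),
#'                    prior = "uniform",
#'                    control = brownie_control(n_iterations = 2000,
#'                                              burn_in = 500, seed = 1))
#' coef(fit)["rho_HY"]
#' }
#' @export
fit_brownie <- function(data, prior = "uniform",
                        control = brownie_control(), seed = NULL,
                        store_eps = TRUE) {
  stopifnot(inherits(data, "marray_pair"))
  if (is.character(prior)) prior <- brownie_prior(prior)
  stopifnot(inherits(prior, "brownie_prior"),
            inherits(control, "brownie_control"))
  if (!is.null(seed)) control$seed <- as.integer(seed)
  Y <- data$Y
  kind <- match(prior$kind, c("uniform", "wishart", "gamma")) - 1L

  sc <- prior$wishart_scale
  det <- sc[1, 1] * sc[2, 2] - sc[1, 2] * sc[2, 1]
  sc_inv <- matrix(c(sc[2, 2], -sc[1, 2], -sc[2, 1], sc[1, 1]), 2, 2) / det
  prior_list <- list(
    mean_S_lo = prior$mean_S_bounds[1], mean_S_hi = prior$mean_S_bounds[2],
    mean_f_lo = prior$mean_f_bounds[1], mean_f_hi = prior$mean_f_bounds[2],
    sigma_upper = prior$sigma_upper,
    gamma_shape = prior$gamma_shape, gamma_rate = prior$gamma_rate,
    wishart_df = prior$wishart_df, wishart_scale_inv = sc_inv,
    fixed_cov = !is.null(prior$fixed_cov))

  ctrl_list <- list(n_iter = control$n_iterations, burn_in = control$burn_in,
                    thin = control$thin, store_eps = store_eps, adapt = TRUE)

  par_names <- c("mean_S_HY", "mean_f_HY", "mean_S_AHY", "mean_f_AHY",
                 "mu_S_HY", "mu_f_HY", "mu_S_AHY", "mu_f_AHY",
                 "sigma_S_HY", "sigma_f_HY", "rho_HY",
                 "sigma_S_AHY", "sigma_f_AHY", "rho_AHY",
                 "rho_star_HY", "rho_star_AHY", "loglik")
  if (store_eps) {
    par_names <- c(par_names,
                   paste0("eps_S_HY[", seq_len(Y), "]"),
                   paste0("eps_f_HY[", seq_len(Y), "]"),
                   paste0("eps_S_AHY[", seq_len(Y), "]"),
                   paste0("eps_f_AHY[", seq_len(Y), "]"))
  }

  draws <- array(NA_real_,
                 dim = c(control$n_retained_per_chain, control$n_chains,
                         length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(control$n_chains)) {
    set.seed(derive_seed(control$seed, ch))
    res <- NULL
    for (try in seq_len(100)) {
      init <- random_init(prior, Y)
      res <- brownie_mcmc_chain(data$M_HY, data$M_AHY, kind, prior_list,
                                init, ctrl_list)
      if (isTRUE(res$ok)) break
      res <- NULL
    }
    if (is.null(res)) {
      stop("failed to initialise chain ", ch,
           " inside the prior support after 100 attempts")
    }
    draws[, ch, ] <- res$draws
  }

  structure(
    list(draws = draws, prior = prior, control = control,
         data_Y = Y, store_eps = store_eps,
         releases = c(HY = sum(data$R_HY), AHY = sum(data$R_AHY))),
    class = "brownie_fit")
}

# Starting values drawn from the interior of the prior support; the narrow
# recovery range keeps initial never-recovered row sums clearly below 1.
random_init <- function(prior, Y) {
  span <- function(bounds, lo, hi) {
    lo <- max(bounds[1], lo); hi <- min(bounds[2], hi)
    if (hi <= lo) bounds else c(lo, hi)
  }
  bS <- span(prior$mean_S_bounds, 0.30, 0.75)
  bf <- span(prior$mean_f_bounds, 0.02, 0.12)
  mS <- stats::runif(2, bS[1], bS[2])
  mf <- stats::runif(2, bf[1], bf[2])
  if (!is.null(prior$fixed_cov)) {
    cov <- rbind(unlist(prior$fixed_cov)[c("sigma_S", "sigma_f", "rho")],
                 unlist(prior$fixed_cov)[c("sigma_S", "sigma_f", "rho")])
  } else {
    cov <- cbind(stats::runif(2, 0.05, 0.5), stats::runif(2, 0.05, 0.5),
                 stats::runif(2, -0.6, 0.6))
  }
  list(mean_S = mS, mean_f = mf,
       eps_S = matrix(stats::rnorm(2 * Y, 0, 0.05), 2, Y),
       eps_f = matrix(stats::rnorm(2 * Y, 0, 0.05), 2, Y),
       cov = cov)
}

#' Extract draws
#'
#' `as.matrix` stacks all chains into one draws-by-parameters matrix;
#' `as.data.frame` returns the long columnar form (`parameter`, `chain`,
#' `iteration`, `value`).
#'
#' @param x A `brownie_fit`.
#' @param ... Unused.
#' @return A matrix or data frame of posterior draws.
#' @export
as.matrix.brownie_fit <- function(x, ...) {
  d <- x$draws
  out <- matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3])
  colnames(out) <- dimnames(d)[[3]]
  out
}

#' @rdname as.matrix.brownie_fit
#' @export
as.data.frame.brownie_fit <- function(x, ...) {
  d <- x$draws
  n <- dim(d)[1]; ch <- dim(d)[2]; p <- dim(d)[3]
  data.frame(
    parameter = rep(dimnames(d)[[3]], each = n * ch),
    chain = rep(rep(seq_len(ch), each = n), times = p),
    iteration = rep(seq_len(n), times = ch * p),
    value = as.vector(d))
}

#' @export
print.brownie_fit <- function(x, ...) {
  cat("Hierarchical Brownie tag-recovery model fit\n")
  cat(sprintf("  prior: %s | %d years | releases HY %d, AHY %d\n",
              x$prior$kind, x$data_Y, x$releases["HY"], x$releases["AHY"]))
  cat(sprintf("  %d retained draws (%d chains)\n",
              dim(x$draws)[1] * dim(x$draws)[2], dim(x$draws)[2]))
  s <- summary(x)
  core <- s[s$parameter %in% c("mean_S_HY", "mean_f_HY", "rho_HY",
                               "mean_S_AHY", "mean_f_AHY", "rho_AHY"), ]
  for (i in seq_len(nrow(core))) {
    cat(sprintf("  %-11s %7.3f (%6.3f, %6.3f)  Rhat %.3f\n",
                core$parameter[i], core$median[i], core$q2.5[i],
                core$q97.5[i], core$rhat[i]))
  }
  invisible(x)
}

#' Posterior summary table
#'
#' Median, mean, Bayesian standard deviation, central 95% credible interval
#' and split-chain potential scale reduction for every monitored parameter.
#'
#' @param object A `brownie_fit`.
#' @param ... Unused.
#' @return A data frame with one row per parameter.
#' @export
summary.brownie_fit <- function(object, ...) {
  d <- object$draws
  pars <- dimnames(d)[[3]]
  flat <- as.matrix(object)
  rh <- rhat(object)
  out <- data.frame(
    parameter = pars,
    median = apply(flat, 2, stats::median),
    mean = colMeans(flat),
    sd = apply(flat, 2, stats::sd),
    q2.5 = apply(flat, 2, stats::quantile, probs = 0.025, names = FALSE,
                 na.rm = TRUE),
    q97.5 = apply(flat, 2, stats::quantile, probs = 0.975, names = FALSE,
                  na.rm = TRUE),
    rhat = rh[pars],
    row.names = NULL)
  out
}

#' @export
coef.brownie_fit <- function(object, ...) {
  flat <- as.matrix(object)
  keep <- c("mean_S_HY", "mean_f_HY", "mean_S_AHY", "mean_f_AHY",
            "sigma_S_HY", "sigma_f_HY", "rho_HY",
            "sigma_S_AHY", "sigma_f_AHY", "rho_AHY")
  apply(flat[, keep, drop = FALSE], 2, stats::median)
}

#' Posterior annual survival and recovery
#'
#' Reconstructs the derived annual rates `S_y = plogis(mu_S + eps_S[y])` and
#' `f_y` from the stored draws and summarises them.
#'
#' @param fit A `brownie_fit` fitted with `store_eps = TRUE`.
#' @param age `"HY"` or `"AHY"`.
#' @return A data frame with one row per year: posterior median and 95%
#'   credible bounds for `S` and `f`.
#' @export
annual_rates <- function(fit, age = c("HY", "AHY")) {
  stopifnot(inherits(fit, "brownie_fit"))
  if (!fit$store_eps) stop("fit was run with store_eps = FALSE")
  age <- match.arg(age)
  flat <- as.matrix(fit)
  Y <- fit$data_Y
  out <- data.frame(year = seq_len(Y))
  for (comp in c("S", "f")) {
    mu <- flat[, paste0("mu_", comp, "_", age)]
    q <- vapply(seq_len(Y), function(y) {
      r <- stats::plogis(mu + flat[, sprintf("eps_%s_%s[%d]", comp, age, y)])
      stats::quantile(r, c(0.5, 0.025, 0.975), names = FALSE)
    }, numeric(3))
    out[[comp]] <- q[1, ]
    out[[paste0(comp, "_lo")]] <- q[2, ]
    out[[paste0(comp, "_hi")]] <- q[3, ]
  }
  out
}

#' @export
plot.brownie_fit <- function(x, pars = c("rho_HY", "rho_AHY"), ...) {
  d <- x$draws
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    m <- d[, , p, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    graphics::matplot(m, type = "l", lty = 1, ylab = p,
                      main = paste("trace:", p), ...)
  }
  invisible(x)
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half and the standard between/within variance-ratio
#' statistic is computed over the resulting half-chains; values below 1.1 are
#' the conventional convergence bar for this model family.
#'
#' @param x A `brownie_fit`, or a matrix of draws with one column per chain.
#' @param ... Unused.
#' @return Named vector of R-hat values (`brownie_fit` method) or a single
#'   value (matrix method).
#' @examples
#' set.seed(1)
#' rhat(matrix(rnorm(2000), ncol = 2))  # ~1.00
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @rdname rhat
#' @export
rhat.brownie_fit <- function(x, ...) {
  d <- x$draws
  pars <- dimnames(d)[[3]]
  out <- vapply(pars, function(p) {
    m <- matrix(d[, , p], nrow = dim(d)[1])
    if (anyNA(m)) return(NA_real_)
    rhat.default(m)
  }, numeric(1))
  names(out) <- pars
  out
}

#' @rdname rhat
#' @export
rhat.default <- function(x, ...) {
  m <- as.matrix(x)
  if (ncol(m) < 2) stop("R-hat needs at least two chains")
  n <- nrow(m) %/% 2L
  if (n < 2) stop("chains too short to split")
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(n), j], m[n + seq_len(n), j])
  }))
  mns <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence gate
#'
#' @param fit A `brownie_fit`.
#' @param threshold R-hat threshold (1.1 by convention).
#' @param pars Parameters to gate on; defaults to the core hyperparameters.
#' @return Logical: `TRUE` when every gated parameter has R-hat below the
#'   threshold.
#' @export
converged <- function(fit, threshold = 1.1,
                      pars = c("mean_S_HY", "mean_f_HY", "mean_S_AHY",
                               "mean_f_AHY", "sigma_S_HY", "sigma_f_HY",
                               "rho_HY", "sigma_S_AHY", "sigma_f_AHY",
                               "rho_AHY")) {
  rh <- rhat(fit)[pars]
  all(is.finite(rh)) && all(rh < threshold)
}
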