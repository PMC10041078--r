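#' Additivity interpretation bins for survival-recovery correlation
#'
#' The conventional breakpoints mapping correlation between annual survival
#' and recovery to harvest-mortality interpretations: strongly additive
#' (rho < -0.7), moderately additive (-0.7 to -0.5), weakly additive
#' (-0.5 to -0.3), compensatory (-0.3 to 0.3), and positive (rho > 0.3).
#'
#' @return Numeric vector of interior breakpoints.
#' @export
additivity_breaks <- function() c(-0.7, -0.5, -0.3, 0.3)

#' Bin proportions of correlation draws
#'
#' Fraction of draws falling in each additivity bin.  Draws exactly on a
#' breakpoint are assigned to the more-negative bin (a measure-zero,
#' documented tie-break).
#'
#' @param rho_draws Numeric vector of correlation draws in `[-1, 1]`.
#' @param breaks Interior breakpoints, default [additivity_breaks()].
#' @return Named numeric vector of five proportions summing to 1.
#' @examples
#' bin_proportions(c(-0.9, -0.9, 0.1, 0.5))
#' @export
bin_proportions <- function(rho_draws, breaks = additivity_breaks()) {
  if (length(rho_draws) == 0) stop("no correlation draws supplied")
  stopifnot(all(rho_draws >= -1 & rho_draws <= 1))
  edges <- c(-1, breaks, 1)
  n <- length(rho_draws)
  props <- numeric(length(edges) - 1)
  for (b in seq_along(props)) {
    lo <- edges[b]; hi <- edges[b + 1]
    props[b] <- if (b == 1) {
      sum(rho_draws <= hi) / n          # [-1, -0.7]
    } else {
      sum(rho_draws > lo & rho_draws <= hi) / n
    }
  }
  names(props) <- names(empty_bins())
  props
}

empty_bins <- function() {
  c(strongly_additive = NA_real_, moderately_additive = NA_real_,
    weakly_additive = NA_real_, compensatory = NA_real_,
    positive = NA_real_)
}

#' Compensatory-conclusion rate
#'
#' Fraction of realizations whose central 95% credible interval for the
#' survival-recovery correlation contains 0 — the rate at which a study
#' design would (wrongly, when true correlation is strongly negative) fail
#' to reject compensatory harvest.
#'
#' @param cri A two-column matrix or data frame of per-realization credible
#'   bounds (lower, upper).
#' @return Fraction in `[0, 1]`.
#' @examples
#' compensatory_rate(rbind(c(-0.9, -0.5), c(-0.6, 0.2)))  # 0.5
#' @export
compensatory_rate <- function(cri) {
  cri <- as.matrix(cri)
  if (nrow(cri) < 1) stop("need at least one realization")
  mean(cri[, 1] <= 0 & cri[, 2] >= 0)
}

#' Run the simulation power analysis
#'
#' For each monitoring scenario, draws `n_realizations` independent
#' tag-recovery data sets from the simulated population, fits the Brownie
#' model under each requested prior, and summarises the posterior
#' survival-recovery correlation per (scenario, prior, age class): the median
#' of the pooled posterior draws across realizations, the additivity-bin
#' proportions of the pooled draws (and of the per-realization medians), the
#' per-realization medians and 95% credible intervals, and the
#' compensatory-conclusion rate.  Fits whose gated R-hat reaches the
#' threshold are flagged and excluded from the summaries (the count is
#' reported).
#'
#' All randomness derives from `seed` through a counter-based sub-seed
#' scheme, so any subset of the grid is reproducible independently.
#'
#' @param pop A [simulate_population()] result (the population truth).
#' @param scenarios A list of [monitoring_scenario()]s (or preset names).
#' @param priors Character vector from `"wishart"`, `"uniform"`, `"gamma"`.
#' @param n_realizations Realized data sets per scenario (50 in the full
#'   design; reduced runs are flagged in the output).
#' @param control A [brownie_control()] for the per-realization fits.
#' @param seed Master seed.
#' @param rhat_threshold Convergence gate for inclusion (default 1.1).
#' @param progress Print one line per fit.
#' @return An object of class `power_result`.
#' @export
run_power_analysis <- function(pop,
                               scenarios = list("modest", "modest_episodic",
                                                "intermediate", "intensive"),
                               priors = c("wishart", "uniform", "gamma"),
                               n_realizations = 50,
                               control = brownie_control("desk"),
                               seed = 1, rhat_threshold = 1.1,
                               progress = FALSE) {
  stopifnot(inherits(pop, "known_fate_pop"))
  priors <- match.arg(priors, c("wishart", "uniform", "gamma"),
                      several.ok = TRUE)
  scenarios <- lapply(scenarios, function(s) {
    if (is.character(s)) monitoring_scenario(s, Y = pop$Y) else s
  })
  truth <- list(
    rho_R_HY = realized_correlation(pop, "HY"),
    rho_R_AHY = realized_correlation(pop, "AHY"))

  cells <- list()
  counter <- 0L
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    real_seed <- derive_seed(seed, 100000L + si)
    rs <- sample_realizations(pop, sc, n = n_realizations, seed = real_seed)
    store <- list()
    for (pr in priors) {
      store[[pr]] <- list(
        HY = list(draws = list(), med = numeric(0),
                  cri = matrix(numeric(0), 0, 2)),
        AHY = list(draws = list(), med = numeric(0),
                   cri = matrix(numeric(0), 0, 2)),
        excluded = 0L, n_fit = 0L)
    }
    for (ri in seq_len(n_realizations)) {
      m <- rs$realizations[[ri]]
      for (pr in priors) {
        counter <- counter + 1L
        fit <- fit_brownie(m, prior = pr, control = control,
                           seed = derive_seed(seed, counter),
                           store_eps = FALSE)
        ok <- converged(fit, threshold = rhat_threshold)
        if (progress) {
          cat(sprintf("scenario %-16s realization %2d prior %-8s %s\n",
                      sc$name, ri, pr,
                      if (ok) "ok" else "excluded (Rhat)"))
        }
        store[[pr]]$n_fit <- store[[pr]]$n_fit + 1L
        if (!ok) {
          store[[pr]]$excluded <- store[[pr]]$excluded + 1L
          next
        }
        flat <- as.matrix(fit)
        for (a in c("HY", "AHY")) {
          rho <- flat[, paste0("rho_", a)]
          st <- store[[pr]][[a]]
          st$draws[[length(st$draws) + 1L]] <- rho
          st$med <- c(st$med, stats::median(rho))
          st$cri <- rbind(st$cri, stats::quantile(rho, c(0.025, 0.975),
                                                  names = FALSE))
          store[[pr]][[a]] <- st
        }
      }
    }
    for (pr in priors) {
      for (a in c("HY", "AHY")) {
        st <- store[[pr]][[a]]
        pooled <- unlist(st$draws)
        cells[[paste(sc$name, pr, a, sep = ".")]] <- list(
          scenario = sc$name, prior = pr, age = a,
          n_realizations = length(st$draws),
          n_excluded = store[[pr]]$excluded,
          pooled_median = if (length(pooled)) stats::median(pooled)
                          else NA_real_,
          pooled_bins = if (length(pooled)) bin_proportions(pooled)
                        else empty_bins(),
          median_bins = if (length(st$med)) bin_proportions(st$med)
                        else empty_bins(),
          realization_medians = st$med,
          realization_cri = st$cri,
          compensatory_rate = if (nrow(st$cri)) compensatory_rate(st$cri)
                              else NA_real_)
      }
    }
  }

  structure(
    list(cells = cells, truth = truth,
         scenarios = vapply(scenarios, `[[`, "", "name"),
         priors = priors, n_realizations = n_realizations,
         control = control, seed = seed,
         reduced_scale = n_realizations < 50),
    class = "power_result")
}

#' Tabulate a power analysis
#'
#' One row per (scenario, prior, age class) in declaration order: the median
#' of the pooled posterior correlation draws, the five additivity-bin
#' proportions, the compensatory-conclusion rate and bookkeeping counts.
#' `type = "realization"` bins the per-realization posterior medians instead
#' of the pooled draws (the table's two natural readings).
#'
#' @param x A `power_result`.
#' @param type `"pooled"` or `"realization"`.
#' @return A data frame.
#' @export
power_table <- function(x, type = c("pooled", "realization")) {
  stopifnot(inherits(x, "power_result"))
  type <- match.arg(type)
  rows <- lapply(x$cells, function(cell) {
    bins <- if (type == "pooled") cell$pooled_bins else cell$median_bins
    d <- data.frame(scenario = cell$scenario, prior = cell$prior,
                    age = cell$age, median = cell$pooled_median)
    for (nm in names(bins)) d[[nm]] <- unname(bins[nm])
    d$compensatory_rate <- cell$compensatory_rate
    d$n_realizations <- cell$n_realizations
    d$n_excluded <- cell$n_excluded
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat("power analysis:", length(x$scenarios), "scenarios x",
      length(x$priors), "priors x", x$n_realizations, "realizations",
      if (x$reduced_scale) "(reduced scale)" else "", "\n")
  cat(sprintf("true realized correlation: HY %.3f, AHY %.3f\n",
              x$truth$rho_R_HY, x$truth$rho_R_AHY))
  print(power_table(x), digits = 3)
  invisible(x)
}

#' Write power-analysis tables
#'
#' Writes the pooled-draw table as CSV and a machine-readable JSON twin
#' including per-realization medians and credible intervals.
#'
#' @param x A `power_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the table data frame.
#' @export
write_power_tables <- function(x, csv_path = NULL, json_path = NULL) {
  tab <- power_table(x)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- list(truth = x$truth, table = tab,
                    cells = lapply(x$cells, function(cell) {
                      cell$realization_cri <- unname(
                        split(cell$realization_cri,
                              seq_len(nrow(cell$realization_cri))))
                      cell
                    }))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}
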