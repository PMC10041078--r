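#' Monitoring scenarios
#'
#' A monitoring scenario fixes how many individuals of each age class are
#' tagged in each study year.  Four presets span the realistic range of
#' waterfowl banding programmes:
#'
#' * `"modest"`: constant 250 juveniles and 800 adults per year (comparable
#'   to lesser scaup monitoring).
#' * `"modest_episodic"`: 3-year cycles starting low, 125/375 juveniles and
#'   550/1050 adults, averaging to the constant modest effort.
#' * `"intermediate"`: 2,000 of each age class per year (northern pintail
#'   scale).
#' * `"intensive"`: 10,000 of each age class per year (mallard scale).
#'
#' @param name Preset name, or any label when `n_HY`/`n_AHY` are given.
#' @param Y Number of study years.
#' @param n_HY,n_AHY Optional explicit annual cohort sizes (recycled to
#'   length `Y`), overriding the preset.
#' @return An object of class `monitoring_scenario` with per-year cohort
#'   sizes.
#' @examples
#' monitoring_scenario("modest_episodic", Y = 6)$n_HY  # 125 125 125 375 375 375
#' @export
monitoring_scenario <- function(name = c("modest", "modest_episodic",
                                         "intermediate", "intensive"),
                                Y = 36, n_HY = NULL, n_AHY = NULL) {
  if (is.null(n_HY) != is.null(n_AHY)) {
    stop("give both n_HY and n_AHY or neither")
  }
  if (is.null(n_HY)) {
    name <- match.arg(name)
    preset <- switch(name,
      modest = list(HY = 250, AHY = 800),
      modest_episodic = list(HY = rep(c(125, 375), each = 3),
                             AHY = rep(c(550, 1050), each = 3)),
      intermediate = list(HY = 2000, AHY = 2000),
      intensive = list(HY = 10000, AHY = 10000))
    n_HY <- preset$HY
    n_AHY <- preset$AHY
  } else {
    name <- as.character(name)[1]
  }
  structure(
    list(name = name, Y = as.integer(Y),
         n_HY = rep_len(as.integer(n_HY), Y),
         n_AHY = rep_len(as.integer(n_AHY), Y)),
    class = "monitoring_scenario")
}

#' @export
print.monitoring_scenario <- function(x, ...) {
  fmt <- function(v) {
    if (length(unique(v)) == 1) format(v[1], big.mark = ",")
    else paste0(format(min(v), big.mark = ","), "-",
                format(max(v), big.mark = ","))
  }
  cat(sprintf("monitoring scenario \"%s\": %s HY, %s AHY per year, %d years\n",
              x$name, fmt(x$n_HY), fmt(x$n_AHY), x$Y))
  invisible(x)
}

#' Sample one tag-recovery realization from a simulated population
#'
#' Draws, for every year and age class, a simple random sample without
#' replacement of the scenario's cohort size from that cohort's observed
#' capture histories.  Because a cohort's observed history is fully described
#' by its recovery year (or never-recovered status), this is a multivariate
#' hypergeometric draw from the cohort's m-array row, which is exactly
#' equivalent to sampling individual histories without replacement.
#'
#' @param pop A [simulate_population()] result.
#' @param scenario A [monitoring_scenario()].
#' @return A [marray_pair()] with the scenario's release totals.
#' @examples
#' set.seed(1)
#' tr <- rate_trajectory(0.57, 0.06, 0.57, 0.03, Y = 4)
#' pop <- simulate_population(tr, 500, 500)
#' m <- sample_realization(pop, monitoring_scenario("modest", Y = 4,
#'                                                  n_HY = 100, n_AHY = 100))
#' rowSums(m$M_HY)  # 100 100 100 100
#' @export
sample_realization <- function(pop, scenario) {
  stopifnot(inherits(pop, "known_fate_pop"),
            inherits(scenario, "monitoring_scenario"))
  if (scenario$Y != pop$Y) stop("scenario and population years differ")
  Y <- pop$Y
  out <- list()
  for (a in c("HY", "AHY")) {
    n_want <- scenario[[paste0("n_", a)]]
    n_have <- pop[[paste0("n_", a)]]
    bad <- which(n_want > n_have)
    if (length(bad)) {
      stop("scenario cohort (", a, ", year ", bad[1], ") of ",
           n_want[bad[1]], " exceeds the simulated population cohort of ",
           n_have[bad[1]])
    }
    Mpop <- pop$marray[[paste0("M_", a)]]
    M <- matrix(0L, Y, Y + 1L)
    for (i in seq_len(Y)) {
      M[i, ] <- rmvhyper(Mpop[i, ], n_want[i])
    }
    out[[a]] <- M
  }
  marray_pair(out$HY, out$AHY)
}

# Multivariate hypergeometric draw: sample k items without replacement from a
# population whose category counts are `counts`, via sequential univariate
# hypergeometric draws.
rmvhyper <- function(counts, k) {
  stopifnot(k <= sum(counts))
  n_cat <- length(counts)
  out <- integer(n_cat)
  remaining <- sum(counts)
  for (c in seq_len(n_cat)) {
    if (k == 0L) break
    if (c == n_cat) {
      out[c] <- k
      break
    }
    x <- stats::rhyper(1, counts[c], remaining - counts[c], k)
    out[c] <- x
    k <- k - x
    remaining <- remaining - counts[c]
  }
  out
}

#' Sample a set of independent realizations
#'
#' Realizations are sampled independently of one another (with replacement
#' among data sets, without replacement within each data set).
#'
#' @param pop A [simulate_population()] result.
#' @param scenario A [monitoring_scenario()].
#' @param n Number of realizations (50 in the full design).
#' @param seed Optional seed; each realization gets a derived sub-seed so
#'   subsets are reproducible.
#' @return An object of class `realization_set`: a list of [marray_pair()]s
#'   plus the scenario and seeds.
#' @export
sample_realizations <- function(pop, scenario, n = 50, seed = NULL) {
  seeds <- if (is.null(seed)) rep(NA_integer_, n) else
    vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  sets <- lapply(seq_len(n), function(i) {
    if (!is.na(seeds[i])) set.seed(seeds[i])
    sample_realization(pop, scenario)
  })
  structure(list(realizations = sets, scenario = scenario, seeds = seeds,
                 n = n),
            class = "realization_set")
}

#' @export
print.realization_set <- function(x, ...) {
  cat(sprintf("%d tag-recovery realizations of scenario \"%s\"\n",
              x$n, x$scenario$name))
  invisible(x)
}

#' Summarise realizations in the style of a sample-size table
#'
#' Means and standard deviations across realizations of the known-fate-year
#' statistics and recovery totals, one row per age class: total known-fate
#' years, known-fate years per study year, known-fate years per released
#' individual, direct recoveries, indirect recoveries.
#'
#' @param rs A `realization_set`, or a plain list of [marray_pair()]s.
#' @param scenario_label Optional label column.
#' @return A data frame with columns `scenario`, `age`, and `<stat>_mean` /
#'   `<stat>_sd` for each statistic.
#' @export
summarize_realizations <- function(rs, scenario_label = NULL) {
  if (inherits(rs, "realization_set")) {
    if (is.null(scenario_label)) scenario_label <- rs$scenario$name
    rs <- rs$realizations
  }
  if (is.null(scenario_label)) scenario_label <- ""
  stopifnot(length(rs) >= 1)
  rows <- list()
  for (a in c("HY", "AHY")) {
    stats_mat <- vapply(rs, function(m) {
      k <- known_fate_summary(m, a)
      c(known_fate_years = k$total_known_fate_years,
        per_year = k$per_year, per_release = k$per_release,
        direct = k$direct, indirect = k$indirect)
    }, numeric(5))
    mean_v <- rowMeans(stats_mat)
    sd_v <- if (ncol(stats_mat) >= 2) apply(stats_mat, 1, stats::sd)
            else rep(NA_real_, 5)
    row <- data.frame(scenario = scenario_label, age = a)
    for (s in rownames(stats_mat)) {
      row[[paste0(s, "_mean")]] <- mean_v[s]
      row[[paste0(s, "_sd")]] <- sd_v[s]
    }
    rows[[a]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
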