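#' Paired m-arrays for two age classes
#'
#' An m-array summarises tag-recovery data for one release age class: rows are
#' release cohorts (study years 1..Y), the first Y columns count recoveries by
#' recovery year, and a final column counts individuals never recovered.  Cells
#' strictly below the main diagonal are structurally zero (an individual cannot
#' be recovered before release) and every row sums to the cohort's release
#' total.  A `marray_pair` holds one m-array per age class, juvenile (HY,
#' hatch-year) and adult (AHY, after-hatch-year), which the Brownie model fits
#' jointly.
#'
#' @param M_HY,M_AHY Integer matrices of dimension `Y x (Y + 1)`: recoveries by
#'   cohort (rows) and recovery year (columns), with never-recovered counts in
#'   the last column.
#' @param R_HY,R_AHY Optional integer release totals per cohort; defaults to
#'   the row sums of the corresponding m-array.  Supplying them asserts the
#'   row-sum invariant explicitly.
#'
#' @return An object of class `marray_pair` with elements `M_HY`, `M_AHY`,
#'   `R_HY`, `R_AHY` and `Y`.
#' @examples
#' M <- rbind(c(1, 1, 8), c(0, 2, 8))
#' x <- marray_pair(M, M)
#' x$Y
#' @export
marray_pair <- function(M_HY, M_AHY, R_HY = NULL, R_AHY = NULL) {
  M_HY <- validate_marray_matrix(M_HY, "M_HY")
  M_AHY <- validate_marray_matrix(M_AHY, "M_AHY")
  if (nrow(M_HY) != nrow(M_AHY)) {
    stop("M_HY and M_AHY must cover the same study years (",
         nrow(M_HY), " vs ", nrow(M_AHY), " rows)")
  }
  Y <- nrow(M_HY)
  if (is.null(R_HY)) R_HY <- rowSums(M_HY)
  if (is.null(R_AHY)) R_AHY <- rowSums(M_AHY)
  for (age in c("HY", "AHY")) {
    M <- if (age == "HY") M_HY else M_AHY
    R <- if (age == "HY") R_HY else R_AHY
    if (length(R) != Y || any(R < 0)) {
      stop("release totals for ", age, " must be ", Y, " non-negative counts")
    }
    bad <- which(abs(rowSums(M) - R) > 0.5)
    if (length(bad)) {
      stop("row ", bad[1], " of M_", age, " sums to ", rowSums(M)[bad[1]],
           " but the release total is ", R[bad[1]])
    }
  }
  structure(
    list(M_HY = M_HY, M_AHY = M_AHY,
         R_HY = as.integer(round(R_HY)), R_AHY = as.integer(round(R_AHY)),
         Y = Y),
    class = "marray_pair"
  )
}

validate_marray_matrix <- function(M, name) {
  M <- as.matrix(M)
  if (ncol(M) != nrow(M) + 1L) {
    stop(name, " must have Y rows and Y + 1 columns, got ",
         nrow(M), " x ", ncol(M))
  }
  if (any(!is.finite(M)) || any(M < 0)) {
    bad <- which(!is.finite(M) | M < 0, arr.ind = TRUE)[1, ]
    stop(name, "[", bad[1], ",", bad[2], "] is negative or missing")
  }
  if (any(abs(M - round(M)) > 1e-8)) {
    stop(name, " must contain integer counts")
  }
  Y <- nrow(M)
  for (i in seq_len(Y)) {
    j <- which(M[i, seq_len(Y)] != 0)
    if (length(j) && any(j < i)) {
      stop(name, "[", i, ",", min(j[j < i]),
           "]: nonzero count below the main diagonal (recovery before release)")
    }
  }
  storage.mode(M) <- "integer"
  dimnames(M) <- NULL
  M
}

#' @export
print.marray_pair <- function(x, ...) {
  cat("m-array pair:", x$Y, "study years\n")
  for (age in c("HY", "AHY")) {
    M <- x[[paste0("M_", age)]]
    Y <- x$Y
    rec <- sum(M[, seq_len(Y)])
    cat(sprintf("  %-3s releases %d, recoveries %d (direct %d, indirect %d)\n",
                age, sum(x[[paste0("R_", age)]]), rec,
                sum(diag(M[, seq_len(Y), drop = FALSE])),
                rec - sum(diag(M[, seq_len(Y), drop = FALSE]))))
  }
  invisible(x)
}

#' Build an m-array pair from individual recovery records
#'
#' Each record is one released individual (or release cohort member) with a
#' release year, an age class at release, and either the year it was recovered
#' by a hunter or `NA` if it was never recovered.  Records are tallied into
#' the `Y x (Y + 1)` m-array layout; individuals released but absent from
#' `records` are counted as never recovered via `releases_HY` / `releases_AHY`.
#'
#' @param records A data frame with columns `release_year` (integer in 1..Y),
#'   `age` (`"HY"` or `"AHY"`), and `recovery_year` (integer in 1..Y or `NA`).
#'   Rows with `recovery_year = NA` may be omitted when release totals are
#'   given.
#' @param Y Number of study years.
#' @param releases_HY,releases_AHY Release totals per cohort year (length `Y`).
#'   Default: counts of records per cohort (every released individual has a
#'   record row).
#' @return A [marray_pair()].
#' @examples
#' rec <- data.frame(release_year = 1, age = "AHY", recovery_year = 2)
#' build_marray(rec, Y = 3, releases_HY = rep(0, 3), releases_AHY = c(1, 0, 0))
#' @export
build_marray <- function(records, Y, releases_HY = NULL, releases_AHY = NULL) {
  stopifnot(is.data.frame(records), Y >= 1)
  need <- c("release_year", "age", "recovery_year")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  age <- as.character(records$age)
  if (!all(age %in% c("HY", "AHY"))) {
    stop("record ", which(!age %in% c("HY", "AHY"))[1],
         ": age must be \"HY\" or \"AHY\"")
  }
  ry <- records$release_year
  cy <- records$recovery_year
  bad <- which(!is.finite(ry) | ry < 1 | ry > Y)
  if (length(bad)) {
    stop("record ", bad[1], ": release_year ", ry[bad[1]],
         " outside study years 1..", Y)
  }
  bad <- which(!is.na(cy) & (cy < 1 | cy > Y))
  if (length(bad)) {
    stop("record ", bad[1], ": recovery_year ", cy[bad[1]],
         " outside study years 1..", Y)
  }
  bad <- which(!is.na(cy) & cy < ry)
  if (length(bad)) {
    stop("record ", bad[1], ": recovered in year ", cy[bad[1]],
         " before release in year ", ry[bad[1]])
  }
  out <- list()
  for (a in c("HY", "AHY")) {
    sel <- age == a
    R <- if (a == "HY") releases_HY else releases_AHY
    if (is.null(R)) R <- tabulate(ry[sel], nbins = Y)
    if (length(R) != Y) stop("releases_", a, " must have length ", Y)
    M <- matrix(0L, Y, Y + 1L)
    rec <- sel & !is.na(cy)
    if (any(rec)) {
      tab <- table(factor(ry[rec], levels = seq_len(Y)),
                   factor(cy[rec], levels = seq_len(Y)))
      M[, seq_len(Y)] <- as.integer(tab)
    }
    recovered <- rowSums(M[, seq_len(Y), drop = FALSE])
    if (any(recovered > R)) {
      i <- which(recovered > R)[1]
      stop("cohort ", i, " (", a, "): ", recovered[i],
           " recoveries exceed ", R[i], " releases")
    }
    M[, Y + 1L] <- as.integer(R - recovered)
    out[[a]] <- M
  }
  marray_pair(out$HY, out$AHY)
}

#' Known-fate-year summary of an m-array
#'
#' Total known-fate years is the number of years tagged individuals are known
#' to have been alive before being recovered: a recovery at lag `L` (recovery
#' year minus release year) contributes `L` years, so direct recoveries (the
#' m-array diagonal, lag 0) contribute nothing, and never-recovered
#' individuals, whose fate is unknown, also contribute nothing.  This is a
#' more honest measure of the information content of a tag-recovery data set
#' than the number of individuals tagged.
#'
#' @param x A [marray_pair()].
#' @param age `"HY"` or `"AHY"`: which age class to summarise.
#' @return An object of class `known_fate_summary`: a list with `releases`,
#'   `direct`, `indirect`, `total_known_fate_years`, `per_year`
#'   (years per study year) and `per_release` (years per released individual).
#' @examples
#' M <- rbind(c(2, 1, 7), c(0, 3, 7))
#' known_fate_summary(marray_pair(M, M), "HY")
#' @export
known_fate_summary <- function(x, age = c("HY", "AHY")) {
  stopifnot(inherits(x, "marray_pair"))
  age <- match.arg(age)
  M <- x[[paste0("M_", age)]]
  Y <- x$Y
  lag <- outer(seq_len(Y), seq_len(Y), function(i, j) j - i)
  Mrec <- M[, seq_len(Y), drop = FALSE]
  total <- sum(Mrec * pmax(lag, 0L))
  direct <- sum(diag(Mrec))
  indirect <- sum(Mrec) - direct
  releases <- sum(x[[paste0("R_", age)]])
  structure(
    list(age = age, releases = releases, direct = direct, indirect = indirect,
         total_known_fate_years = total,
         per_year = total / Y,
         per_release = if (releases > 0) total / releases else NA_real_,
         Y = Y),
    class = "known_fate_summary"
  )
}

#' @export
print.known_fate_summary <- function(x, ...) {
  cat(sprintf(
    "%s: %d releases, %d direct + %d indirect recoveries\n",
    x$age, x$releases, x$direct, x$indirect))
  cat(sprintf(
    "known-fate years: %d total, %.1f per year, %.3f per release\n",
    x$total_known_fate_years, x$per_year, x$per_release))
  invisible(x)
}

#' Read and write m-array pairs as CSV
#'
#' One file per age class.  The layout is `Y` rows by `Y + 2` columns: the
#' release total, then the `Y` recovery-year cells, then the never-recovered
#' column, with a header row of labels (`release`, `y1`..`yY`, `never`).
#'
#' @param path_HY,path_AHY File paths for the juvenile and adult m-arrays.
#' @return `read_marray_csv()` returns a [marray_pair()];
#'   `write_marray_csv()` invisibly returns the input.
#' @examples
#' x <- marray_pair(rbind(c(1, 0, 9), c(0, 1, 9)),
#'                  rbind(c(2, 1, 7), c(0, 2, 8)))
#' fh <- tempfile(); fa <- tempfile()
#' write_marray_csv(x, fh, fa)
#' identical(read_marray_csv(fh, fa)$M_AHY, x$M_AHY)
#' @export
read_marray_csv <- function(path_HY, path_AHY) {
  read_one <- function(path) {
    d <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    Y <- nrow(d)
    if (ncol(d) != Y + 2L) {
      stop("malformed m-array file ", path, ": ", Y, " rows need ",
           Y + 2L, " columns (release, y1..y", Y, ", never), found ", ncol(d))
    }
    R <- d[[1]]
    M <- as.matrix(d[, -1, drop = FALSE])
    list(M = M, R = R)
  }
  hy <- read_one(path_HY)
  ahy <- read_one(path_AHY)
  marray_pair(hy$M, ahy$M, hy$R, ahy$R)
}

#' @rdname read_marray_csv
#' @param x A [marray_pair()] to write.
#' @export
write_marray_csv <- function(x, path_HY, path_AHY) {
  stopifnot(inherits(x, "marray_pair"))
  write_one <- function(M, R, path) {
    d <- data.frame(release = R, M, check.names = FALSE)
    names(d) <- c("release", paste0("y", seq_len(x$Y)), "never")
    utils::write.csv(d, path, row.names = FALSE)
  }
  write_one(x$M_HY, x$R_HY, path_HY)
  write_one(x$M_AHY, x$R_AHY, path_AHY)
  invisible(x)
}

#' Read a flat recovery-record table
#'
#' Reads a CSV with columns `release_year`, `age` (`HY` or `AHY`) and
#' `recovery_year` (empty for never-recovered individuals), the generic
#' pre-filtered exchange format for banding-laboratory extracts.
#'
#' @param path CSV file path.
#' @return A data frame suitable for [build_marray()].
#' @export
read_recovery_records <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  need <- c("release_year", "age", "recovery_year")
  if (!all(need %in% names(d))) {
    stop("record table must have columns ", paste(need, collapse = ", "))
  }
  d$release_year <- as.integer(d$release_year)
  d$recovery_year <- suppressWarnings(as.integer(d$recovery_year))
  d$age <- as.character(d$age)
  d
}
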