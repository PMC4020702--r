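#' Known-fate interval records from radio-marked animals
#'
#' Builds and validates a staggered-entry known-fate series: for each
#' stratum and year, a sequence of monthly intervals with the number of
#' animals at risk at the start of the interval (`n`), deaths (`d`),
#' censored animals (`c`) and new entries (`e`, animals radio-marked at the
#' start of that interval). The bookkeeping identity
#' `n[g+1] == n[g] - d[g] - c[g] + e[g+1]` must hold within every
#' (stratum, year) series, and `d + c <= n` in every interval.
#'
#' @param x A data frame with columns `month`, `n`, `d`, `c` and optionally
#'   `stratum`, `year`, `e`. Missing `stratum`/`year` are filled with a
#'   single level; a missing `e` column is inferred from the identity
#'   (first interval gets `e = n`).
#' @return A validated tibble of class `known_fate`, ordered by stratum,
#'   year, month.
#' @examples
#' known_fate(data.frame(month = 1:2, n = c(10, 7), d = c(2, 1), c = c(1, 0)))
#' @export
known_fate <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"stratum" %in% names(x)) x$stratum <- "all"
  if (!"year" %in% names(x)) x$year <- 1L
  need <- c("stratum", "year", "month", "n", "d", "c")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("known_fate: missing columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("year", "month", "n", "d", "c")) {
    x[[col]] <- check_count(x[[col]], col, "known_fate")
  }
  x <- dplyr::arrange(x, .data$stratum, .data$year, .data$month)
  if ("e" %in% names(x)) {
    x$e <- check_count(x$e, "e", "known_fate", allow_na = TRUE)
  } else {
    x$e <- NA_integer_
  }
  x <- dplyr::group_modify(
    dplyr::group_by(x, .data$stratum, .data$year),
    function(df, key) {
      g <- nrow(df)
      if (anyDuplicated(df$month) > 0) {
        stop("known_fate: duplicated month in series (",
             key$stratum, ", year ", key$year, ")")
      }
      implied <- c(df$n[1L],
                   if (g > 1) df$n[-1L] - (df$n - df$d - df$c)[-g])
      df$e[is.na(df$e)] <- implied[is.na(df$e)]
      df
    }
  )
  x <- dplyr::ungroup(x)
  validate_known_fate(structure(x, class = c("known_fate", class(x))))
}

#' Validate a known-fate series
#'
#' Checks every `known_fate` invariant: non-negative integer counts,
#' `d + c <= n` in each interval, and the staggered-entry bookkeeping
#' identity `n[g+1] == n[g] - d[g] - c[g] + e[g+1]` within each
#' (stratum, year) series. The first offending interval is named in the
#' error.
#'
#' @param series A `known_fate` object (or data frame with its columns).
#' @return The validated series, invisibly unchanged.
#' @export
validate_known_fate <- function(series) {
  bad <- series$d + series$c > series$n
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("known_fate: d + c > n at (", series$stratum[i], ", year ",
         series$year[i], ", month ", series$month[i], ")")
  }
  split_idx <- split(seq_len(nrow(series)),
                     paste(series$stratum, series$year, sep = "\r"))
  for (idx in split_idx) {
    g <- length(idx)
    if (g < 2) next
    n <- series$n[idx]; d <- series$d[idx]
    cc <- series$c[idx]; e <- series$e[idx]
    expect_n <- n[-g] - d[-g] - cc[-g] + e[-1L]
    off <- which(n[-1L] != expect_n)
    if (length(off) > 0) {
      i <- idx[off[1L] + 1L]
      stop("known_fate: inconsistent at-risk count at (", series$stratum[i],
           ", year ", series$year[i], ", month ", series$month[i],
           "): n = ", series$n[i], " but previous interval implies ",
           expect_n[off[1L]])
    }
  }
  invisible(series)
}

#' Release and dead-recovery cohorts for a Brownie tag-recovery model
#'
#' Pairs a table of tagged releases with the upper-triangular matrix of
#' year-of-recovery counts. Cohorts are keyed by release year, entry month,
#' age class, unit and tag type; recoveries can only occur in the release
#' year or later, and only in years in which releases occurred, and the
#' recovered total can never exceed the cohort's releases.
#'
#' @param releases Data frame with columns `year`, `released` and optionally
#'   `entry_month` (default 1), `age`, `unit`, `tag_type`.
#' @param recoveries Data frame with columns `year_released`,
#'   `year_recovered`, `count` and the same optional cohort keys.
#' @return A list of class `recovery_data` with elements `releases`,
#'   `recoveries` (tibbles) and `years` (the ordered recovery years).
#' @examples
#' recovery_data(
#'   data.frame(year = 1, released = 100),
#'   data.frame(year_released = 1, year_recovered = 1, count = 6)
#' )
#' @export
recovery_data <- function(releases, recoveries) {
  releases <- tibble::as_tibble(releases)
  recoveries <- tibble::as_tibble(recoveries)
  releases <- fill_cohort_cols(releases)
  recoveries <- fill_cohort_cols(recoveries)
  if (!all(c("year", "released") %in% names(releases))) {
    stop("recovery_data: releases needs columns year, released")
  }
  need <- c("year_released", "year_recovered", "count")
  if (!all(need %in% names(recoveries))) {
    stop("recovery_data: recoveries needs columns ",
         paste(need, collapse = ", "))
  }
  releases$year <- check_count(releases$year, "year", "releases")
  releases$released <- check_count(releases$released, "released", "releases")
  for (col in need) {
    recoveries[[col]] <- check_count(recoveries[[col]], col, "recoveries")
  }
  keys <- cohort_keys()
  releases <- dplyr::arrange(releases,
                             dplyr::across(dplyr::all_of(c("year", keys))))
  obj <- structure(
    list(releases = releases, recoveries = recoveries,
         years = sort(unique(releases$year))),
    class = "recovery_data"
  )
  validate_recoveries(obj)
}

#' Validate Brownie release/recovery cohorts
#'
#' Checks the `recovery_data` invariants: no recovery before release, no
#' recovery in a year without releases, every recovery row matching a
#' release cohort, and per-cohort recovered totals not exceeding releases.
#'
#' @param data A `recovery_data` object.
#' @return The validated object, invisibly unchanged.
#' @export
validate_recoveries <- function(data) {
  rec <- data$recoveries
  rel <- data$releases
  early <- rec$year_recovered < rec$year_released & rec$count > 0
  if (any(early)) {
    i <- which(early)[1L]
    stop("recovery_data: recovery before release (released ",
         rec$year_released[i], ", recovered ", rec$year_recovered[i], ")")
  }
  bad_year <- !(rec$year_recovered %in% data$years) & rec$count > 0
  if (any(bad_year)) {
    stop("recovery_data: recoveries in year ",
         rec$year_recovered[which(bad_year)[1L]],
         ", a year with no releases")
  }
  keys <- cohort_keys()
  rec_tot <- dplyr::summarise(
    dplyr::group_by(rec, .data$year_released,
                    dplyr::across(dplyr::all_of(keys))),
    recovered = sum(.data$count), .groups = "drop"
  )
  joined <- dplyr::left_join(
    rec_tot, rel,
    by = c(year_released = "year", keys)
  )
  if (anyNA(joined$released)) {
    i <- which(is.na(joined$released))[1L]
    stop("recovery_data: recoveries from unknown cohort (year ",
         joined$year_released[i], ", ", joined$age[i], ", ",
         joined$unit[i], ", ", joined$tag_type[i], ")")
  }
  over <- joined$recovered > joined$released
  if (any(over)) {
    i <- which(over)[1L]
    stop("recovery_data: cohort (year ", joined$year_released[i],
         ") has ", joined$recovered[i], " recoveries but only ",
         joined$released[i], " releases")
  }
  invisible(data)
}

#' Seasonal harvest counts of transmitter-fitted animals
#'
#' Per (year, unit, age) counts of radio-marked animals available to be
#' harvested (`available`) and harvested (`harvested`), modelled as a
#' binomial with the radio harvest rate. Rows with `available = 0` are
#' retained but their harvest rate is structurally fixed at 0 and excluded
#' from the free parameters.
#'
#' @param x Data frame with columns `year`, `available`, `harvested` and
#'   optionally `unit`, `age`.
#' @return A validated tibble of class `radio_harvest`.
#' @export
radio_harvest <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"unit" %in% names(x)) x$unit <- "all"
  if (!"age" %in% names(x)) x$age <- "all"
  need <- c("year", "unit", "age", "available", "harvested")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("radio_harvest: missing columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("year", "available", "harvested")) {
    x[[col]] <- check_count(x[[col]], col, "radio_harvest")
  }
  bad <- x$harvested > x$available
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("radio_harvest: harvested > available at (year ", x$year[i],
         ", ", x$unit[i], ", ", x$age[i], ")")
  }
  structure(x, class = c("radio_harvest", class(x)))
}

#' Bundle the data streams for a joint fit
#'
#' @param known_fate A [known_fate()] series, or `NULL` when no
#'   radio-telemetry monitoring data exist (the monthly survival rates must
#'   then be fixed in the model specification).
#' @param recovery A [recovery_data()] object, or `NULL` for a
#'   known-fate-only analysis.
#' @param radio A [radio_harvest()] series, or `NULL` when transmitter
#'   harvest counts are not used.
#' @return A list of class `harvest_data`.
#' @export
harvest_data <- function(known_fate = NULL, recovery = NULL, radio = NULL) {
  if (!is.null(known_fate) && !inherits(known_fate, "known_fate")) {
    known_fate <- known_fate(known_fate)
  }
  if (!is.null(recovery) && !inherits(recovery, "recovery_data")) {
    stop("harvest_data: `recovery` must be a recovery_data object")
  }
  if (!is.null(radio) && !inherits(radio, "radio_harvest")) {
    radio <- radio_harvest(radio)
  }
  if (is.null(known_fate) && is.null(recovery) && is.null(radio)) {
    stop("harvest_data: at least one data stream is required")
  }
  structure(list(known_fate = known_fate, recovery = recovery, radio = radio),
            class = "harvest_data")
}

#' @export
print.harvest_data <- function(x, ...) {
  cat("<harvest_data>\n")
  if (!is.null(x$known_fate)) {
    cat("  known-fate: ", nrow(x$known_fate), " intervals, ",
        sum(total_entries(x$known_fate)), " animals\n", sep = "")
  }
  if (!is.null(x$recovery)) {
    cat("  recoveries: ", nrow(x$recovery$releases), " cohorts, ",
        sum(x$recovery$releases$released), " released, ",
        sum(x$recovery$recoveries$count), " recovered\n", sep = "")
  }
  if (!is.null(x$radio)) {
    cat("  radio harvest: ", nrow(x$radio), " year-strata, ",
        sum(x$radio$available), " available\n", sep = "")
  }
  invisible(x)
}

cohort_keys <- function() c("entry_month", "age", "unit", "tag_type")

fill_cohort_cols <- function(x) {
  if (!"entry_month" %in% names(x)) x$entry_month <- 1L
  if (!"age" %in% names(x)) x$age <- "all"
  if (!"unit" %in% names(x)) x$unit <- "all"
  if (!"tag_type" %in% names(x)) x$tag_type <- "tag"
  x$entry_month <- as.integer(x$entry_month)
  x
}

check_count <- function(v, name, where, allow_na = FALSE) {
  if (!allow_na && anyNA(v)) stop(where, ": NA in column ", name)
  ok <- is.na(v) | (is.finite(v) & v >= 0 & v == round(v))
  if (!all(ok)) {
    stop(where, ": column ", name,
         " must contain non-negative integers (row ",
         which(!ok)[1L], ")")
  }
  as.integer(v)
}

# number of distinct animals entering each (stratum, year) series
total_entries <- function(kf) {
  out <- dplyr::summarise(
    dplyr::group_by(kf, .data$stratum, .data$year),
    animals = sum(.data$e), .groups = "drop"
  )
  out$animals
}
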