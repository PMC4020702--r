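#' Kaplan-Meier known-fate interval log-likelihood
#'
#' The binomial kernel summed over intervals:
#' `sum((n - d - c) * log(s) + d * log(1 - s))`. Binomial coefficients are
#' dropped, so values are comparable only across models fitted to the same
#' data. Censored animals contribute neither a survival nor a death term
#' in the interval in which they are censored.
#'
#' @param series A [known_fate()] series.
#' @param s Monthly survival rate(s) in `[0, 1]`: a single value, a vector
#'   with one value per interval row, or a data frame with columns
#'   `stratum`, `year`, `month`, `s` to be matched to the series.
#' @return The log-likelihood kernel. `-Inf` (with a warning) when some
#'   `s` is 0 with survivors present or 1 with deaths present.
#' @export
km_loglik <- function(series, s) {
  if (is.data.frame(s)) {
    m <- dplyr::left_join(tibble::as_tibble(series), s,
                          by = intersect(c("stratum", "year", "month"),
                                         names(s)))
    if (anyNA(m$s)) stop("km_loglik: survival values missing for some intervals")
    s <- m$s
  }
  if (any(s < 0 | s > 1)) stop("km_loglik: s must lie in [0, 1]")
  s <- rep_len(s, nrow(series))
  succ <- series$n - series$d - series$c
  fail <- series$d
  bad <- (s == 0 & succ > 0) | (s == 1 & fail > 0)
  if (any(bad)) {
    warning("km_loglik: boundary survival rate contradicts the data; -Inf")
    return(-Inf)
  }
  sum(ifelse(succ > 0, succ * log(s), 0) +
        ifelse(fail > 0, fail * log1p(-s), 0))
}

#' Cumulative tagging-to-harvest survival
#'
#' The product of consecutive monthly survival rates from an animal's
#' entry month through the last pre-season month: an animal radio-marked
#' or tagged in month `g0` must survive months `g0..G` to be alive when
#' the hunting season opens.
#'
#' @param s Monthly survival rates indexed by month (element `m` is the
#'   rate for month `m`).
#' @param entry_month First month the animal is at risk.
#' @param season_month Last pre-season month `G`.
#' @return The cumulative survival `prod(s[entry_month:season_month])`.
#' @examples
#' cumulative_survival(rep(0.9, 9), 3, 9) # March entry: 7 monthly terms
#' @export
cumulative_survival <- function(s, entry_month, season_month = length(s)) {
  if (entry_month > season_month) {
    stop("cumulative_survival: empty month range (entry_month > season_month)")
  }
  if (season_month > length(s)) {
    stop("cumulative_survival: s has no value for month ", season_month)
  }
  ss <- s[entry_month:season_month]
  if (any(ss < 0 | ss > 1)) stop("cumulative_survival: rates must lie in [0, 1]")
  prod(ss)
}

#' Expected dead recoveries of a joint known-fate tag-recovery model
#'
#' For a one-age-class design with one release cohort per year, the
#' expected number of recoveries in year `j` of the `N[i]` animals tagged
#' in year `i` is `N[i] * S_G[i] * H[i]` on the diagonal and
#' `N[i] * S_G[i] * prod(S[i..j-1]) * H[j]` above it, where `S_G[i]` is
#' the cumulative tagging-to-harvest survival of cohort `i`, `H` the
#' annual harvest rates and `S` the annual survival rates. Setting
#' `S_G = 1` recovers the classical Brownie expectations.
#'
#' @param releases Numbers released per year, `N[i]`, `i = 1..J`.
#' @param S_G Cumulative tagging-to-harvest survival per cohort (recycled).
#' @param H Harvest rate per year (recycled to length `J`).
#' @param S Annual survival rate per year (recycled; only years
#'   `1..J-1` are used).
#' @return A `J x J` upper-triangular matrix of expected recoveries.
#' @examples
#' brownie_expected_recoveries(100, S_G = 0.9, H = 0.6) # 54 expected
#' @export
brownie_expected_recoveries <- function(releases, S_G = 1, H, S = 1) {
  j_n <- length(releases)
  S_G <- rep_len(S_G, j_n)
  H <- rep_len(H, j_n)
  S <- rep_len(S, j_n)
  stopifnot(all(c(S_G, H, S) >= 0), all(c(S_G, H, S) <= 1))
  out <- matrix(0, j_n, j_n)
  for (i in seq_len(j_n)) {
    for (j in i:j_n) {
      surv <- if (j > i) prod(S[i:(j - 1L)]) else 1
      out[i, j] <- releases[i] * S_G[i] * surv * H[j]
    }
  }
  out
}

#' Brownie tag-recovery multinomial log-likelihood
#'
#' The multinomial kernel over recovery cells: for each cohort,
#' `sum(U[i, j] * log(p[i, j])) + (a[i] - sum(U[i, ])) * log(1 - sum(p[i, ]))`
#' with cell probabilities `p[i, j] = E[R[i, j]] / N[i]` from
#' [brownie_expected_recoveries()] and a final never-recovered cell. The
#' multinomial coefficient is dropped. This simple interface covers
#' designs with one cohort per release year; factor-structured cohorts are
#' handled by [fit_joint_model()].
#'
#' @param data A [recovery_data()] object with one cohort per year.
#' @param S_G,H,S Real-scale rates as in [brownie_expected_recoveries()],
#'   indexed by position in `data$years`.
#' @return The log-likelihood kernel; `-Inf` (with a warning) when a cell
#'   with a non-zero count has non-positive probability.
#' @export
brownie_loglik <- function(data, S_G = 1, H, S = 1) {
  stopifnot(inherits(data, "recovery_data"))
  rel <- data$releases
  if (nrow(rel) != length(data$years)) {
    stop("brownie_loglik: expected one cohort per year; use ",
         "fit_joint_model() for factor-structured cohorts")
  }
  years <- data$years
  j_n <- length(years)
  p <- brownie_expected_recoveries(rep(1, j_n), S_G = S_G, H = H, S = S)
  u <- matrix(0, j_n, j_n)
  for (r in seq_len(nrow(data$recoveries))) {
    i <- match(data$recoveries$year_released[r], years)
    j <- match(data$recoveries$year_recovered[r], years)
    u[i, j] <- u[i, j] + data$recoveries$count[r]
  }
  a <- rel$released[match(years, rel$year)]
  ll <- 0
  for (i in seq_len(j_n)) {
    pij <- p[i, i:j_n]
    uij <- u[i, i:j_n]
    pnever <- 1 - sum(pij)
    rnever <- a[i] - sum(uij)
    if (any(uij > 0 & pij <= 0) || (rnever > 0 && pnever <= 0)) {
      warning("brownie_loglik: zero-probability cell with non-zero count; -Inf")
      return(-Inf)
    }
    ll <- ll + sum(ifelse(uij > 0, uij * log(pij), 0)) +
      ifelse(rnever > 0, rnever * log(pnever), 0)
  }
  ll
}

#' Radio-harvest binomial log-likelihood
#'
#' The binomial kernel for transmitter-fitted animals over hunting
#' seasons: `sum(h * log(H_r) + (m - h) * log(1 - H_r))`. Year-strata
#' with no animals available (`m = 0`) contribute 0.
#'
#' @param data A [radio_harvest()] series.
#' @param H_r Radio harvest rate(s) in `[0, 1]`: single value or one per
#'   row.
#' @return The log-likelihood kernel; `-Inf` (with a warning) at a
#'   boundary rate contradicting the counts.
#' @export
radio_harvest_loglik <- function(data, H_r) {
  stopifnot(inherits(data, "radio_harvest"))
  if (any(H_r < 0 | H_r > 1)) stop("radio_harvest_loglik: H_r must lie in [0, 1]")
  H_r <- rep_len(H_r, nrow(data))
  h <- data$harvested
  f <- data$available - data$harvested
  bad <- (H_r == 0 & h > 0) | (H_r == 1 & f > 0)
  if (any(bad)) {
    warning("radio_harvest_loglik: boundary harvest rate contradicts the data; -Inf")
    return(-Inf)
  }
  sum(ifelse(h > 0, h * log(H_r), 0) + ifelse(f > 0, f * log1p(-H_r), 0))
}

#' Joint known-fate tag-recovery log-likelihood
#'
#' Because the three data streams are independent, the joint likelihood is
#' the product of the component likelihoods, i.e. the sum of the component
#' log-likelihoods. The cumulative tagging-to-harvest survival inside the
#' Brownie term is computed from the same monthly survival rates the
#' known-fate term uses, which is what makes `S_G` and the harvest rate
#' separately estimable. Absent components contribute 0.
#'
#' This simple interface indexes monthly survival by month only (shared
#' across years and strata) and covers one cohort per release year;
#' factor-structured models go through [fit_joint_model()].
#'
#' @param data A [harvest_data()] bundle.
#' @param s Monthly survival rates indexed by month `1..season_month`.
#' @param H,S Annual harvest and survival rates indexed by position in the
#'   recovery years.
#' @param H_r Radio harvest rates (defaults to `H`, the shared-rate
#'   constraint).
#' @param season_month Last pre-season month `G`.
#' @return The joint log-likelihood kernel.
#' @export
joint_loglik <- function(data, s = 1, H, S = 1, H_r = NULL,
                         season_month = 9L) {
  data <- as_harvest_data(data)
  ll <- 0
  if (!is.null(data$known_fate)) {
    sv <- rep_len(s, max(season_month, max(data$known_fate$month)))
    ll <- ll + km_loglik(data$known_fate, sv[data$known_fate$month])
  }
  if (!is.null(data$recovery)) {
    sv <- rep_len(s, season_month)
    sg <- vapply(data$recovery$releases$entry_month,
                 function(m) cumulative_survival(sv, m, season_month),
                 numeric(1))
    ll <- ll + brownie_loglik(data$recovery, S_G = sg, H = H, S = S)
  }
  if (!is.null(data$radio)) {
    years <- sort(unique(data$radio$year))
    hr <- rep_len(if (is.null(H_r)) H else H_r, length(years))
    ll <- ll + radio_harvest_loglik(
      data$radio, hr[match(data$radio$year, years)])
  }
  ll
}

# ---- internal evaluator on a param_map --------------------------------

# log-likelihood (and optionally its gradient on the real scale) at a
# real-scale free-parameter vector theta. Cell probabilities are pure
# products of parameters, stored as integer exponent rows, so both value
# and gradient are matrix operations. When a cohort's cell probabilities
# sum past 1 (feasible region boundary) a smooth quadratic penalty keeps
# the objective finite for the line search.
map_eval <- function(map, theta, grad = FALSE) {
  ll <- map$km_fixed_ll
  g <- if (grad) numeric(map$k)
  for (part in list(map$km, map$radio)) {
    if (is.null(part)) next
    th <- theta[part$par]
    ll <- ll + sum(part$succ * log(th) + part$fail * log1p(-th))
    if (grad) {
      g[part$par] <- g[part$par] + part$succ / th - part$fail / (1 - th)
    }
  }
  br <- map$brownie
  if (!is.null(br)) {
    logp <- as.vector(br$exponents %*% log(theta)) + br$offset
    p <- exp(logp)
    ptot <- as.vector(br$agg %*% p)
    cap <- 1 - 1e-9
    over <- pmax(ptot - cap, 0)
    pc <- pmin(ptot, cap)
    ll <- ll + sum(br$u * logp) + sum(br$never * log1p(-pc)) -
      1e6 * sum(over^2)
    if (grad) {
      q <- ifelse(over > 0, 2e6 * over,
                  br$never / (1 - pc))
      w <- br$u - q[br$cohort] * p
      g <- g + as.vector(crossprod(br$exponents, w)) / theta
    }
  }
  if (grad) list(value = ll, grad = g) else ll
}

# objective/gradient on the logit scale for the optimizer
map_obj_logit <- function(map) {
  list(
    fn = function(eta) {
      v <- map_eval(map, stats::plogis(eta))
      if (!is.finite(v)) 1e12 else -v
    },
    gr = function(eta) {
      th <- stats::plogis(eta)
      -map_eval(map, th, grad = TRUE)$grad * th * (1 - th)
    }
  )
}
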