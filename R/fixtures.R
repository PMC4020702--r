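#' Generate a synthetic case-study dataset
#'
#' Builds a fully synthetic dataset emulating one of two study designs,
#' at realistic sample sizes, with known true rates (attached as
#' attribute `"truth"`):
#'
#' * `"turkey"` — a hen wild-turkey-style design: 3 years of winter
#'   captures staggered over entry months January-March, two age classes
#'   (adult, juvenile), reward leg bands on all birds and radio
#'   transmitters on a subset, an autumn season after pre-season month 9.
#'   Low tagging-to-harvest survival (about 0.45 adult / 0.51 juvenile
#'   over January-September) and low harvest rates. No radio-harvest
#'   stream (transmitters monitor pre-season fates only).
#' * `"deer"` — a white-tailed-deer-style design: 3 years, 4 management
#'   units, two age classes, ear-tag cohorts plus a radio-harvest stream
#'   of transmitter-fitted animals, high monthly survival and moderate,
#'   unit-specific harvest rates. `hr_ratio` scales the radio harvest rate
#'   relative to the ear-tag rate (1 = no transmitter effect), so the
#'   fixture can generate data with or without a true tag effect.
#'
#' @param design `"turkey"` or `"deer"`.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param hr_ratio Deer design only: ratio of the radio-marked harvest
#'   rate to the ear-tag harvest rate.
#' @return A [harvest_data()] bundle with attribute `"truth"` (a list of
#'   the generating rates).
#' @export
make_case_study_fixture <- function(design = c("turkey", "deer"),
                                    seed = 1L, hr_ratio = 1) {
  design <- match.arg(design)
  withr::local_seed(seed)
  if (design == "turkey") turkey_fixture() else deer_fixture(hr_ratio)
}

# staggered-entry known-fate series: entries[m] animals enter at month m,
# all monitored through month g at a constant monthly rate
sim_km_series <- function(entries, monthly, g, stratum, year) {
  alive <- 0L
  n <- d <- e <- integer(g)
  for (m in seq_len(g)) {
    e[m] <- if (m <= length(entries)) entries[m] else 0L
    alive <- alive + e[m]
    n[m] <- alive
    d[m] <- stats::rbinom(1L, alive, 1 - monthly)
    alive <- alive - d[m]
  }
  tibble::tibble(stratum = stratum, year = year, month = seq_len(g),
                 n = n, d = d, c = 0L, e = e)
}

# multinomial recovery draw for one cohort released in year i
sim_cohort_recoveries <- function(n, year, jmax, S_G, H, S) {
  js <- year:jmax
  p <- S_G * H[js] * c(1, cumprod(S[seq(year, length.out = jmax - year)]))
  counts <- stats::rmultinom(1L, n, c(p, 1 - sum(p)))[, 1L]
  keep <- counts[seq_along(js)] > 0
  tibble::tibble(year_recovered = js[keep],
                 count = counts[seq_along(js)][keep])
}

turkey_fixture <- function() {
  g <- 9L
  years <- 1:3
  truth <- list(
    s = c(adult = 0.452^(1 / 9), juvenile = 0.514^(1 / 9)),
    H = c(0.054, 0.088, 0.022), S = c(0.40, 0.40, 0.40),
    season_month = g
  )
  banded <- list(adult = c(162L, 167L, 169L),
                 juvenile = c(74L, 128L, 109L))
  radios <- list(adult = c(55L, 42L, 32L), juvenile = c(6L, 11L, 15L))
  entry_split <- function(total) {
    m1 <- round(total * 0.4)
    m2 <- round(total * 0.35)
    c(m1, m2, total - m1 - m2)
  }
  kf <- rel <- rec <- list()
  for (age in c("adult", "juvenile")) {
    for (i in years) {
      kf[[paste(age, i)]] <- sim_km_series(entry_split(radios[[age]][i]),
                                           truth$s[[age]], g, age, i)
      for (m in 1:3) {
        n_rel <- entry_split(banded[[age]][i])[m]
        if (n_rel == 0) next
        sg <- truth$s[[age]]^(g - m + 1)
        key <- tibble::tibble(year = i, entry_month = m, age = age,
                              unit = "all", tag_type = "band")
        rel[[paste(age, i, m)]] <- dplyr::mutate(key, released = n_rel)
        draws <- sim_cohort_recoveries(n_rel, i, max(years), sg,
                                       truth$H, truth$S)
        if (nrow(draws) > 0) {
          rec[[paste(age, i, m)]] <- dplyr::bind_cols(
            dplyr::rename(key[rep(1, nrow(draws)), ],
                          year_released = "year"),
            draws
          )
        }
      }
    }
  }
  out <- harvest_data(
    known_fate = known_fate(dplyr::bind_rows(kf)),
    recovery = recovery_data(dplyr::bind_rows(rel),
                             dplyr::bind_rows(rec))
  )
  attr(out, "truth") <- truth
  out
}

deer_fixture <- function(hr_ratio) {
  g <- 9L
  years <- 1:3
  units <- c("2D", "2G", "3C", "4B")
  truth <- list(
    s = c(adult = 0.9905, juvenile = 0.9799),
    H = c(`2D` = 0.138, `2G` = 0.116, `3C` = 0.111, `4B` = 0.133),
    S = c(adult = 0.55, juvenile = 0.55),
    hr_ratio = hr_ratio, season_month = g
  )
  entry_w <- c(0.30, 0.30, 0.25, 0.15)
  rel <- rec <- radio <- list()
  radio_entries <- list(adult = integer(0), juvenile = integer(0))
  n_radio_year <- list(adult = integer(3), juvenile = integer(3))
  for (i in years) {
    for (u in units) {
      for (age in c("adult", "juvenile")) {
        n_rel <- if (age == "adult") sample(39:82, 1L) else sample(7:50, 1L)
        entries <- c(stats::rmultinom(1L, n_rel, entry_w))
        sgm <- truth$s[[age]]
        for (m in which(entries > 0)) {
          key <- tibble::tibble(year = i, entry_month = m, age = age,
                                unit = u, tag_type = "ear")
          rel[[paste(i, u, age, m)]] <- dplyr::mutate(key,
                                                      released = entries[m])
          draws <- sim_cohort_recoveries(
            entries[m], i, max(years), sgm^(g - m + 1),
            rep(truth$H[[u]], 3), rep(truth$S[[age]], 3))
          if (nrow(draws) > 0) {
            rec[[paste(i, u, age, m)]] <- dplyr::bind_cols(
              dplyr::rename(key[rep(1, nrow(draws)), ],
                            year_released = "year"),
              draws
            )
          }
        }
        avail <- if (age == "adult") sample(10:55, 1L) else sample(0:15, 1L)
        hr <- min(1, hr_ratio * truth$H[[u]])
        radio[[paste(i, u, age)]] <- tibble::tibble(
          year = i, unit = u, age = age, available = avail,
          harvested = stats::rbinom(1L, avail, hr)
        )
        n_radio_year[[age]][i] <- n_radio_year[[age]][i] + avail
      }
    }
  }
  kf <- list()
  for (age in c("adult", "juvenile")) {
    for (i in years) {
      entries <- c(stats::rmultinom(1L, n_radio_year[[age]][i], entry_w))
      kf[[paste(age, i)]] <- sim_km_series(entries, truth$s[[age]], g,
                                           age, i)
    }
  }
  out <- harvest_data(
    known_fate = known_fate(dplyr::bind_rows(kf)),
    recovery = recovery_data(dplyr::bind_rows(rel),
                             dplyr::bind_rows(rec)),
    radio = radio_harvest(dplyr::bind_rows(radio))
  )
  attr(out, "truth") <- truth
  out
}
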