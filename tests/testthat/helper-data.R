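# shared in-code fixtures for the test suite

# single-stratum known-fate series with entries only in month 1
toy_kf <- function(n1, d, c = 0L, year = 1L, stratum = "all") {
  g <- length(d)
  c <- rep_len(c, g)
  n <- integer(g)
  alive <- n1
  for (m in seq_len(g)) {
    n[m] <- alive
    alive <- alive - d[m] - c[m]
  }
  known_fate(tibble::tibble(stratum = stratum, year = year,
                            month = seq_len(g), n = n, d = d, c = c))
}

# one release year, one cohort: the smallest joint design (J = 1, G = 1)
one_cohort_joint <- function(a = 200L, u = 70L, n_radio = 100L,
                             d_radio = 20L) {
  harvest_data(
    known_fate = toy_kf(n_radio, d_radio),
    recovery = recovery_data(
      tibble::tibble(year = 1L, released = a),
      tibble::tibble(year_released = 1L, year_recovered = 1L, count = u))
  )
}

# J=1, G=1 joint log-likelihood, vectorized over (s, H) for grid oracles
joint_ll_1cohort <- function(s, H, a, u, n_radio, d_radio) {
  succ <- n_radio - d_radio
  succ * log(s) + d_radio * log(1 - s) +
    u * log(s * H) + (a - u) * log(1 - s * H)
}

# simulate a 3-year recovery + radio-harvest dataset with no pre-season
# mortality (for transmitter-effect simulations)
sim_tag_effect_data <- function(n_tags, m_radio, H_tag, H_radio, S,
                                seed) {
  withr::local_seed(seed)
  p <- H_tag * S^(0:2)
  rec_rows <- list()
  for (i in 1:3) {
    cells <- p[seq_len(3 - i + 1)]
    cnt <- stats::rmultinom(1, n_tags, c(cells, 1 - sum(cells)))[, 1]
    js <- i:3
    keep <- cnt[seq_along(js)] > 0
    rec_rows[[i]] <- tibble::tibble(year_released = i,
                                    year_recovered = js[keep],
                                    count = cnt[seq_along(js)][keep])
  }
  harvest_data(
    recovery = recovery_data(tibble::tibble(year = 1:3, released = n_tags),
                             dplyr::bind_rows(rec_rows)),
    radio = radio_harvest(tibble::tibble(
      year = 1:3, available = m_radio,
      harvested = stats::rbinom(3, m_radio, H_radio)))
  )
}
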