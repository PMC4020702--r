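test_that("known-fate bookkeeping is validated with named offenders", {
  expect_s3_class(
    known_fate(tibble::tibble(month = 1, n = 10, d = 0, c = 0)),
    "known_fate")
  ok <- known_fate(tibble::tibble(month = 1:2, n = c(10, 7),
                                  d = c(2, 1), c = c(1, 0)))
  expect_equal(ok$e, c(10, 0))
  expect_error(
    known_fate(tibble::tibble(month = 1:2, n = c(10, 9), d = c(2, 0),
                              c = c(0, 0), e = c(10, 0))),
    "month 2")
  expect_error(
    known_fate(tibble::tibble(month = 1, n = 5, d = 4, c = 3)),
    "d \\+ c > n")
  expect_error(
    known_fate(tibble::tibble(month = 1, n = -1, d = 0, c = 0)),
    "non-negative")
})

test_that("recovery cohorts reject impossible recovery patterns", {
  expect_s3_class(
    recovery_data(tibble::tibble(year = 1, released = 100),
                  tibble::tibble(year_released = 1, year_recovered = 1,
                                 count = 6)),
    "recovery_data")
  expect_error(
    recovery_data(tibble::tibble(year = 1, released = 100),
                  tibble::tibble(year_released = 1, year_recovered = 1,
                                 count = 101)),
    "101 recoveries")
  expect_error(
    recovery_data(tibble::tibble(year = 1:3, released = 100),
                  tibble::tibble(year_released = 2, year_recovered = 1,
                                 count = 1)),
    "before release")
})

test_that("radio-harvest series require harvested <= available", {
  expect_s3_class(
    radio_harvest(tibble::tibble(year = 1, available = 10, harvested = 3)),
    "radio_harvest")
  expect_error(
    radio_harvest(tibble::tibble(year = 1, available = 2, harvested = 3)),
    "harvested > available")
})

test_that("free-parameter counts match the canonical model structures", {
  # staggered-entry two-age design, month x age survival pooled over years
  kf <- dplyr::bind_rows(lapply(c("adult", "juv"), function(a) {
    dplyr::bind_rows(lapply(1:3, function(y) {
      tibble::tibble(stratum = a, year = y, month = 1:9, n = 30, d = 1,
                     c = 0, e = c(30, rep(1, 8)))
    }))
  }))
  rel <- expand.grid(year = 1:3, entry_month = 1:3,
                     age = c("adult", "juv"))
  rel$released <- 50
  dat <- harvest_data(
    known_fate(kf),
    recovery_data(rel, tibble::tibble(year_released = 1, entry_month = 1,
                                      age = "adult", year_recovered = 1,
                                      count = 2)))
  k_year <- build_parameter_map(
    model_spec(survival_by = c("month", "stratum"), harvest_by = "year",
               annual_by = "year"), dat)$k
  expect_identical(k_year, 23L) # 18 monthly + 3 harvest + 2 annual
  k_const <- build_parameter_map(
    model_spec(survival_by = c("month", "stratum"),
               harvest_by = character(0), annual_by = character(0)),
    dat)$k
  expect_identical(k_const, 20L) # 18 + 1 + 1
})

test_that("dead-recovery component always yields J harvest and J-1 annual parameters", {
  for (j in 2:5) {
    rec <- recovery_data(
      tibble::tibble(year = seq_len(j), released = 100),
      tibble::tibble(year_released = 1, year_recovered = 1, count = 5))
    k <- build_parameter_map(model_spec(survival_fixed = 1), rec)$k
    expect_identical(k, j + (j - 1L))
    # the final-year annual survival never appears in any cell
    nm <- build_parameter_map(model_spec(survival_fixed = 1),
                              rec)$params$name
    expect_false(paste0("S[year=", j, "]") %in% nm)
  }
})

test_that("parameter counting is additive over factor crossings", {
  # rich dataset: 2 strata/ages x 2 units x 3 years x 9 months, radio
  # stream covering every year-unit-age cell
  kf <- known_fate(dplyr::bind_rows(lapply(c("ad", "jv"), function(a) {
    dplyr::bind_rows(lapply(1:3, function(y) {
      tibble::tibble(stratum = a, year = y, month = 1:9, n = 40, d = 1,
                     c = 0, e = c(40, rep(1, 8)))
    }))
  })))
  rel <- expand.grid(year = 1:3, age = c("ad", "jv"),
                     unit = c("U1", "U2"))
  rel$released <- 60
  rec <- recovery_data(rel,
                       tibble::tibble(year_released = 1, age = "ad",
                                      unit = "U1", year_recovered = 1,
                                      count = 1))
  rad <- radio_harvest(within(expand.grid(year = 1:3,
                                          unit = c("U1", "U2"),
                                          age = c("ad", "jv")), {
    available <- 20
    harvested <- 2
  }))
  dat <- harvest_data(kf, rec, rad)
  lev <- c(month = 9L, year = 3L, stratum = 2L, age = 2L, unit = 2L,
           tag_type = 2L)
  withr::with_seed(99, {
    for (rep in 1:12) {
      s_by <- sample(c("month", "year", "stratum"),
                     sample(0:3, 1))
      h_by <- sample(c("year", "age", "unit", "tag_type"), sample(0:4, 1))
      a_by <- sample(c("year", "age", "unit"), sample(0:3, 1))
      k <- build_parameter_map(
        model_spec(survival_by = s_by, harvest_by = h_by,
                   annual_by = a_by), dat)$k
      k_s <- prod(lev[s_by])
      k_h <- prod(lev[h_by])
      # with year-varying annual survival the final year drops out
      k_a <- if ("year" %in% a_by) {
        2L * prod(lev[setdiff(a_by, "year")])
      } else {
        prod(lev[a_by])
      }
      expect_identical(k, as.integer(k_s + k_h + k_a))
    }
  })
})

test_that("radio harvest rates with no animals available are removed from K", {
  rec <- recovery_data(tibble::tibble(year = 1:2, released = 100),
                       tibble::tibble(year_released = 1,
                                      year_recovered = 1, count = 10))
  rad <- radio_harvest(tibble::tibble(year = 1:2, available = c(10, 0),
                                      harvested = c(2, 0)))
  map <- build_parameter_map(
    model_spec(survival_fixed = 1, harvest_by = c("year", "tag_type")),
    harvest_data(recovery = rec, radio = rad))
  expect_true("H[year=1,tag_type=radio]" %in% map$params$name)
  expect_false("H[year=2,tag_type=radio]" %in% map$params$name)
  expect_identical(map$k, 2L + 1L + 1L) # 2 tag H + 1 radio H + 1 annual S
})

test_that("confounded specifications are rejected", {
  rec <- recovery_data(tibble::tibble(year = 1:2, released = 100),
                       tibble::tibble(year_released = 1,
                                      year_recovered = 1, count = 10))
  expect_error(build_parameter_map(model_spec(survival_by = "month"), rec),
               "confounded")
})

test_that("model-spec and scenario configs round-trip through YAML", {
  spec <- model_spec(survival_by = c("month", "stratum"),
                     harvest_by = c("year", "unit"), annual_by = "year",
                     season_month = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  expect_equal(read_model_spec(path), spec)
  expect_error(read_model_spec({
    p2 <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(survival_by = "month", typo_key = 1), p2)
    p2
  }), "unknown config keys")

  scn <- species_a_scenario(reps = 10)
  p3 <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn, p3)
  expect_equal(read_scenario(p3), scn)
})
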