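test_that("scenario defaults encode the two study life histories", {
  a <- species_a_scenario()
  expect_equal(a$monthly^a$season_month, 0.90, tolerance = 1e-12)
  b <- species_b_scenario()
  expect_equal(b$monthly^b$season_month, 0.69, tolerance = 1e-12)
  expect_equal(a$radios, c(0L, 10L, 25L, 50L, 75L, 100L, 150L, 200L))
  expect_equal(a$tags, c(50L, 100L, 200L, 300L, 400L, 500L, 600L))
  expect_error(scenario(S_G = 1, H = 0.9, S = 0.9), "exceed 1")
})

test_that("simulated datasets are deterministic in the seed and valid", {
  scn <- species_a_scenario()
  d1 <- simulate_dataset(scn, 100, 25, seed = 7)
  d2 <- simulate_dataset(scn, 100, 25, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(scn, 100, 25, seed = 8)
  expect_false(identical(d1, d3))
  expect_silent(validate_known_fate(d1$known_fate))
  expect_silent(validate_recoveries(d1$recovery))
  # no radios -> no known-fate stream
  expect_null(simulate_dataset(scn, 100, 0, seed = 1)$known_fate)
})

test_that("degenerate certain-harvest scenario recovers everyone in year 1", {
  scn <- scenario(S_G = 1, H = 1, S = 0, years = 3)
  d <- simulate_dataset(scn, 50, 0, seed = 2)
  rec <- d$recovery$recoveries
  expect_true(all(rec$year_released == rec$year_recovered))
  expect_equal(sum(rec$count), 150)
})

test_that("first-year recovery frequency matches its expected cell probability", {
  scn <- species_a_scenario()
  u11 <- vapply(1:2000, function(r) {
    d <- simulate_dataset(scn, 100, 0, seed = 100000 + r)
    rec <- d$recovery$recoveries
    sum(rec$count[rec$year_released == 1 & rec$year_recovered == 1])
  }, numeric(1))
  p <- scn$S_G * scn$H
  se <- sqrt(p * (1 - p) / (2000 * 100))
  expect_lt(abs(mean(u11) / 100 - p), 3 * se)
})

test_that("simulated cell frequencies fit the recovery-cell model", {
  scn <- species_b_scenario()
  d <- simulate_dataset(scn, 100000, 0, seed = 31)
  rec <- d$recovery$recoveries
  p <- brownie_expected_recoveries(rep(1, 3), S_G = scn$S_G, H = scn$H,
                                   S = scn$S)
  for (i in 1:3) {
    obs <- vapply(i:3, function(j) {
      sum(rec$count[rec$year_released == i & rec$year_recovered == j])
    }, numeric(1))
    obs <- c(obs, 100000 - sum(obs))
    expected <- c(p[i, i:3], 1 - sum(p[i, i:3]))
    gof <- suppressWarnings(stats::chisq.test(obs, p = expected))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("bias, CV and CV(RMSE) follow their closed forms", {
  expect_equal(bias_summary(rep(0.6, 4), 0.6)$mean, c(0, 0))
  bs <- bias_summary(0.54, 0.60)
  expect_equal(bs$mean, c(-0.06, -0.10), tolerance = 1e-9)
  bs2 <- bias_summary(c(0.5, 0.58, 0.66), 0.6)
  expect_true(all(bs2$min <= bs2$mean & bs2$mean <= bs2$max))

  expect_equal(cv(c(0.6, 0.6, 0.6)), 0)
  expect_equal(cv(c(0.5, 0.7)), 100 * stats::sd(c(0.5, 0.7)) / 0.6)
  expect_equal(round(cv(c(0.5, 0.7)), 1), 23.6)

  expect_equal(cv_rmse(rep(0.6, 5), 0.6), 0)
  # pure bias b with no variance: 100 * |b| / truth
  expect_equal(cv_rmse(rep(0.54, 5), 0.6), 100 * 0.06 / 0.6)
})

test_that("CV(RMSE) decomposes into truth-scaled CV and relative bias", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      x <- runif(50, 0.2, 0.8)
      truth <- 0.6
      cvr <- cv_rmse(x, truth)
      sd_n <- sqrt(mean((x - mean(x))^2))
      cv_t <- 100 * sd_n / truth
      bias_t <- 100 * (mean(x) - truth) / truth
      expect_equal(cvr^2, cv_t^2 + bias_t^2, tolerance = 1e-9)
    }
  })
})

test_that("with no pre-season mortality the joint and Brownie fits agree", {
  scn <- scenario(S_G = 1, H = 0.4, S = 0.5)
  d <- simulate_dataset(scn, 400, 50, seed = 12)
  f_joint <- fit_joint_model(model_spec(survival_fixed = 1), d,
                             se = FALSE)
  f_brownie <- fit_joint_model(model_spec(survival_fixed = 1),
                               harvest_data(recovery = d$recovery),
                               se = FALSE)
  h <- function(f) f$estimates$estimate[f$estimates$family == "harvest"]
  expect_equal(h(f_joint), h(f_brownie), tolerance = 1e-6)
})

test_that("the allocation grid reports bias, precision and the Brownie baseline gap", {
  scn <- species_a_scenario()
  m <- run_grid(scn, seed = 5, reps = 40, radios = c(0, 50),
                tags = c(100, 400))
  expect_setequal(m$metrics$model, c("brownie", "joint"))
  # Brownie rows carry the tagging-to-harvest bias, joint rows do not
  br <- m$summary[m$summary$model == "brownie" &
                    m$summary$metric == "absolute", ]
  jt <- m$summary[m$summary$model == "joint" &
                    m$summary$metric == "absolute", ]
  expect_lt(br$mean, -0.03)
  expect_lt(abs(jt$mean), 0.03)
  # CV decreases with the number of tags at fixed radio allocation
  mm <- m$metrics[m$metrics$model == "joint", ]
  cv_by_tags <- tapply(mm$cv, mm$tags, mean)
  expect_lt(cv_by_tags["400"], cv_by_tags["100"])
  # baseline difference defined for joint rows only
  expect_true(all(is.na(m$metrics$diff_vs_baseline[
    m$metrics$model == "brownie"])))
  expect_true(all(is.finite(m$metrics$diff_vs_baseline[
    m$metrics$model == "joint"])))
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
})

test_that("case-study fixtures are reproducible and structurally valid", {
  t1 <- make_case_study_fixture("turkey", seed = 3)
  t2 <- make_case_study_fixture("turkey", seed = 3)
  expect_identical(t1, t2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(t1, d1)
  write_dataset(t2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_silent(validate_known_fate(t1$known_fate))
  expect_silent(validate_recoveries(t1$recovery))
  deer <- make_case_study_fixture("deer", seed = 3)
  expect_s3_class(deer$radio, "radio_harvest")
  expect_setequal(unique(deer$recovery$releases$unit),
                  c("2D", "2G", "3C", "4B"))
})

test_that("the turkey fixture fit recovers its generating harvest rates", {
  tk <- make_case_study_fixture("turkey", seed = 20)
  truth <- attr(tk, "truth")
  fit <- suppressWarnings(fit_joint_model(
    model_spec(survival_by = c("month", "stratum")), tk))
  h <- fit$estimates[fit$estimates$family == "harvest", ]
  for (i in 1:3) {
    expect_lt(abs(h$estimate[i] - truth$H[i]), 3 * h$se[i] + 0.01)
  }
  sg <- cumulative_survival_se(fit, 1, 9, stratum = "adult")
  expect_lt(abs(sg$S_G - 0.452), 3 * sg$se + 0.02)
})

test_that("the deer fixture without a tag effect prefers the shared-rate model", {
  spec <- model_spec(survival_by = "stratum", harvest_by = "unit",
                     annual_by = "unit")
  wins <- 0L
  for (s in 1:10) {
    deer <- make_case_study_fixture("deer", seed = 200 + s)
    tt <- suppressWarnings(tag_effect_test(deer, spec, n_starts = 1,
                                           se = FALSE))
    if (tt$comparison$model[1] == "common harvest rate") wins <- wins + 1L
  }
  expect_gte(wins, 7)
})
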