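test_that("saturated known-fate fit reproduces the closed-form interval MLEs", {
  kf <- toy_kf(60, d = c(5, 3, 4), c = c(2, 0, 1))
  fit <- fit_joint_model(model_spec(survival_by = "month",
                                    season_month = 3), kf)
  shat <- fit$estimates$estimate[match(paste0("s[month=", 1:3, "]"),
                                       fit$estimates$name)]
  expect_equal(shat, c(1 - 5 / 58, 1 - 3 / 53, 1 - 4 / 49),
               tolerance = 1e-6)
})

test_that("radio-only fit reproduces h/m with the binomial SE", {
  rad <- radio_harvest(tibble::tibble(year = 1:2, available = c(50, 40),
                                      harvested = c(10, 6)))
  fit <- fit_joint_model(model_spec(survival_fixed = 1), rad)
  est <- fit$estimates
  expect_equal(est$estimate, c(10 / 50, 6 / 40), tolerance = 1e-6)
  expect_equal(est$se, sqrt(est$estimate * (1 - est$estimate) / c(50, 40)),
               tolerance = 1e-4)
})

test_that("one-cohort joint fit matches the 2-D grid-search oracle", {
  a <- 200L; u <- 70L; n_radio <- 100L; d_radio <- 20L
  dat <- one_cohort_joint(a, u, n_radio, d_radio)
  fit <- fit_joint_model(model_spec(survival_by = "month",
                                    season_month = 1), dat)
  gr <- seq(0.005, 0.995, by = 0.001)
  ll <- outer(gr, gr, joint_ll_1cohort, a = a, u = u, n_radio = n_radio,
              d_radio = d_radio)
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(fit$loglik, max(ll), tolerance = 1e-4)
  expect_equal(fit$estimates$estimate[1], gr[best[1]], tolerance = 2e-3)
  # factorization: H-hat = (U/a) / S_G-hat with S_G-hat from the KM MLE
  sg_hat <- 1 - d_radio / n_radio
  expect_equal(fit$estimates$estimate[2], (u / a) / sg_hat,
               tolerance = 1e-5)
})

test_that("optimizer matches grid search on random 2-parameter instances", {
  gr <- seq(0.005, 0.995, by = 0.001)
  withr::with_seed(21, {
    for (rep in 1:5) {
      n_radio <- sample(30:150, 1)
      d_radio <- rbinom(1, n_radio, 0.25)
      a <- sample(100:400, 1)
      u <- rbinom(1, a, 0.35)
      dat <- one_cohort_joint(a, u, n_radio, d_radio)
      fit <- fit_joint_model(model_spec(survival_by = "month",
                                        season_month = 1), dat,
                             n_starts = 1, se = FALSE)
      ll <- outer(gr, gr, joint_ll_1cohort, a = a, u = u,
                  n_radio = n_radio, d_radio = d_radio)
      expect_equal(fit$loglik, max(ll), tolerance = 1e-4)
    }
  })
})

test_that("jittered restarts land on the same optimum", {
  dat <- simulate_dataset(species_a_scenario(), 300, 50, seed = 17)
  spec <- model_spec(survival_by = c("month", "year"))
  f1 <- fit_joint_model(spec, dat, n_starts = 1, se = FALSE)
  f5 <- fit_joint_model(spec, dat, n_starts = 5, se = FALSE)
  expect_lt(abs(f1$loglik - f5$loglik), 1e-4)
})

test_that("standard errors shrink as 1/sqrt(n) under count scaling", {
  kf1 <- toy_kf(60, d = c(5, 3, 4))
  kf4 <- toy_kf(240, d = c(20, 12, 16))
  spec <- model_spec(survival_by = "month", season_month = 3)
  se1 <- fit_joint_model(spec, kf1)$estimates$se
  se4 <- fit_joint_model(spec, kf4)$estimates$se
  expect_equal(se4, se1 / 2, tolerance = 0.05)
})

test_that("delta-method cumulative survival SE matches a parametric bootstrap", {
  kf <- toy_kf(200, d = c(12, 9, 14))
  fit <- fit_joint_model(model_spec(survival_by = "month",
                                    season_month = 3), kf)
  out <- cumulative_survival_se(fit, 1, 3)
  shat <- fit$estimates$estimate
  expect_equal(out$S_G, prod(shat), tolerance = 1e-8)
  # bootstrap the product of independent interval binomials
  n_at_risk <- c(200, 188, 179)
  boots <- withr::with_seed(42, {
    replicate(10000, prod(stats::rbinom(3, n_at_risk, shat) / n_at_risk))
  })
  expect_equal(out$se, stats::sd(boots), tolerance = 0.1)
  # single month: the product SE is that month's SE
  one <- cumulative_survival_se(fit, 2, 2)
  expect_equal(one$se, fit$estimates$se[2], tolerance = 1e-8)
})

test_that("AICc, ranking and Akaike weights behave as defined", {
  expect_equal(aicc(-100, 5, 200),
               200 + 10 + 2 * 5 * 6 / (200 - 5 - 1))
  expect_warning(v <- aicc(-100, 5, 6), "undefined")
  expect_true(is.na(v))

  # Two models one AICc step apart split the weight nearly evenly
  # (the null-vs-age pattern of a dead-recovery candidate set)
  n <- 5000
  a1 <- aicc(-328.7, 10, n)
  a2 <- aicc(-320.8, 18, n)
  delta <- a2 - a1
  expect_gt(delta, 0.1)
  expect_lt(delta, 0.5)
  w <- exp(-c(0, delta) / 2)
  w <- w / sum(w)
  expect_lt(abs(w[1] - 0.5), 0.05)
  expect_gt(w[1], w[2])
})

test_that("compare_models sorts, normalises weights and breaks ties by K", {
  rad <- radio_harvest(tibble::tibble(year = 1:2, available = c(50, 40),
                                      harvested = c(10, 6)))
  f_year <- fit_joint_model(model_spec(survival_fixed = 1,
                                       harvest_by = "year"), rad)
  f_const <- fit_joint_model(model_spec(survival_fixed = 1,
                                        harvest_by = character(0)), rad)
  cmp <- compare_models(year = f_year, constant = f_const)
  expect_equal(cmp$delta_aicc[1], 0)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
  expect_equal(cmp$model[1], "constant") # near-equal rates: fewer K wins
  single <- compare_models(only = f_const)
  expect_equal(single$weight, 1)
})

test_that("transmitter-effect test identifies shared and distinct harvest rates", {
  spec <- model_spec(survival_fixed = 1, harvest_by = "year",
                     annual_by = "year")
  # truth: common harvest rate -> the constrained model should win AICc
  wins <- 0L
  for (r in 1:200) {
    dat <- sim_tag_effect_data(n_tags = 150, m_radio = 100, H_tag = 0.3,
                               H_radio = 0.3, S = 0.5, seed = 3000 + r)
    tt <- suppressWarnings(tag_effect_test(dat, spec, n_starts = 1,
                                           se = FALSE))
    expect_identical(tt$unconstrained$k - tt$constrained$k, 3L)
    if (tt$comparison$model[1] == "common harvest rate") wins <- wins + 1L
  }
  expect_gte(wins, 160)
  # truth: radios harvested at twice the rate -> unconstrained wins
  wins2 <- 0L
  for (r in 1:50) {
    dat <- sim_tag_effect_data(n_tags = 500, m_radio = 300, H_tag = 0.2,
                               H_radio = 0.4, S = 0.5, seed = 5000 + r)
    tt <- suppressWarnings(tag_effect_test(dat, spec, n_starts = 1,
                                           se = FALSE))
    if (tt$comparison$model[1] == "tag-type effect") wins2 <- wins2 + 1L
  }
  expect_gt(wins2, 25)
})

test_that("fit output tidiers and writers expose the same numbers", {
  rad <- radio_harvest(tibble::tibble(year = 1, available = 50,
                                      harvested = 10))
  fit <- fit_joint_model(model_spec(survival_fixed = 1), rad)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate, 0.2, tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$aicc, fit$aicc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_csv(fit, path)
  back <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  expect_equal(back$estimate, td$estimate)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
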