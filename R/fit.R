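#' Fit a joint known-fate tag-recovery model by maximum likelihood
#'
#' Maximizes the joint log-likelihood (known-fate binomial intervals +
#' Brownie multinomial recoveries + radio-harvest binomials) over the free
#' parameters implied by the model specification. Optimization is
#' quasi-Newton (BFGS) on the logit scale with analytic gradients, seeded
#' from closed-form-informed starting values plus deterministic jittered
#' restarts; the best of all starts is kept.
#'
#' @param spec A [model_spec()].
#' @param data A [harvest_data()] bundle (or single data-stream object).
#' @param n_starts Number of starts (1 informed + `n_starts - 1`
#'   deterministic jitters).
#' @param n_eff Override for the AICc effective sample size; defaults to
#'   the total number of marked individuals across data streams.
#' @param se Compute the observed-information variance-covariance matrix
#'   and standard errors (set `FALSE` to skip, e.g. in large simulation
#'   grids where only point estimates are needed).
#' @return An object of class `joint_fit` with elements `estimates`
#'   (tibble: `name`, `family`, `estimate`, `se`, `lower`, `upper`,
#'   `boundary`), `loglik`, `k`, `n`, `aicc`, `vcov` (real scale),
#'   `vcov_logit`, `convergence` (0 = converged) and the `spec` and
#'   parameter `map` used.
#' @examples
#' rec <- recovery_data(data.frame(year = 1:2, released = c(100, 80)),
#'                      data.frame(year_released = c(1, 1, 2),
#'                                 year_recovered = c(1, 2, 2),
#'                                 count = c(40, 10, 30)))
#' fit <- fit_joint_model(model_spec(survival_fixed = 1), rec)
#' tidy(fit)
#' @export
fit_joint_model <- function(spec, data, n_starts = 5, n_eff = NULL,
                            se = TRUE) {
  data <- as_harvest_data(data)
  map <- build_parameter_map(spec, data)
  fit_map(map, n_starts = n_starts, n_eff = n_eff, se = se)
}

# maximize the likelihood of an assembled param_map (internal: lets
# simulation grids reuse one map across replicates via
# refresh_map_counts)
fit_map <- function(map, n_starts = 5, n_eff = NULL, se = TRUE) {
  n <- if (is.null(n_eff)) map$n_eff else n_eff
  if (map$k == 0) {
    ll <- map_eval(map, numeric(0))
    return(new_joint_fit(map, numeric(0), ll, n, convergence = 0L,
                         vcov_logit = matrix(0, 0, 0)))
  }
  eta0 <- stats::qlogis(start_values(map))
  obj <- map_obj_logit(map)
  best <- NULL
  for (k in seq_len(max(1, n_starts))) {
    start <- if (k == 1) eta0 else
      eta0 + withr::with_seed(6000 + k, stats::rnorm(map$k, 0, 0.7))
    res <- tryCatch(
      stats::optim(start, obj$fn, obj$gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("fit_joint_model: all optimizer starts failed")
  eta <- best$par
  theta <- stats::plogis(eta)
  ll <- map_eval(map, theta)
  conv <- best$convergence
  if (conv != 0) {
    warning("fit_joint_model: optimizer did not report convergence ",
            "(code ", conv, "); partial results returned")
  }
  vcov_logit <- if (se) observed_vcov(obj, eta) else NULL
  new_joint_fit(map, eta, ll, n, convergence = conv,
                vcov_logit = vcov_logit)
}

# Inverse observed information on the logit scale. Parameters carrying
# (numerically) no information -- e.g. a monthly survival estimated at 1
# because no deaths were observed -- are dropped before inversion and get
# NA rows/columns, so the remaining parameters keep usable SEs.
observed_vcov <- function(obj, eta) {
  k <- length(eta)
  info <- pracma::jacobian(obj$gr, eta)
  info <- (info + t(info)) / 2
  keep <- diag(info) > 1e-6
  v <- tryCatch(solve(info[keep, keep, drop = FALSE]),
                error = function(e) NULL)
  if (is.null(v)) {
    warning("fit_joint_model: observed information is singular (rank ",
            qr(info)$rank, " of ", k, "); standard errors unavailable")
    return(NULL)
  }
  out <- matrix(NA_real_, k, k)
  out[keep, keep] <- v
  if (any(!keep)) {
    warning("fit_joint_model: ", sum(!keep), " parameter(s) carry no ",
            "information at the optimum; their SEs are unavailable")
  }
  out
}

# Closed-form-informed starting values: monthly survival from the
# known-fate interval MLEs, harvest rates from diagonal recovery cells
# corrected by the starting cumulative survival (moment estimator),
# annual survival from first-superdiagonal cells, radio rates from h/m.
start_values <- function(map) {
  theta0 <- numeric(map$k)
  fam <- substr(map$params$name, 1L, 1L)
  theta0[fam == "s"] <- 0.9
  theta0[fam == "S"] <- 0.5
  theta0[fam == "H"] <- 0.2
  if (!is.null(map$km)) {
    tot <- map$km$succ + map$km$fail
    theta0[map$km$par] <- ifelse(tot > 0, map$km$succ / tot, 0.9)
  }
  theta0 <- pmin(pmax(theta0, 0.01), 0.99)
  br <- map$brownie
  if (!is.null(br)) {
    s_cols <- which(fam == "s")
    sg0 <- exp(as.vector(br$exponents[, s_cols, drop = FALSE] %*%
                           log(theta0[s_cols])) + br$offset)
    ac <- br$a[br$cohort]
    dg <- is.na(br$super_s_par) & br$u >= 0 &
      rowSums(br$exponents[, fam == "S", drop = FALSE]) == 0
    for (hp in unique(br$h_par)) {
      cells <- which(dg & br$h_par == hp)
      if (length(cells) == 0) next
      h0 <- sum(br$u[cells]) / sum(ac[cells] * sg0[cells])
      theta0[hp] <- min(max(h0, 0.01), 0.99)
    }
    sup <- which(!is.na(br$super_s_par))
    for (sp in unique(br$super_s_par[sup])) {
      cells <- sup[br$super_s_par[sup] == sp]
      denom <- sum(ac[cells] * sg0[cells] * theta0[br$h_par[cells]])
      if (denom > 0) {
        theta0[sp] <- min(max(sum(br$u[cells]) / denom, 0.01), 0.99)
      }
    }
  }
  if (!is.null(map$radio)) {
    tot <- map$radio$succ + map$radio$fail
    theta0[map$radio$par] <- ifelse(tot > 0, map$radio$succ / tot, 0.2)
  }
  pmin(pmax(theta0, 0.01), 0.99)
}

new_joint_fit <- function(map, eta, loglik, n, convergence, vcov_logit) {
  theta <- stats::plogis(eta)
  k <- map$k
  boundary <- theta < 1e-6 | theta > 1 - 1e-6
  se_eta <- rep(NA_real_, k)
  vcov_real <- NULL
  if (!is.null(vcov_logit) && k > 0) {
    d <- diag(vcov_logit)
    se_eta <- ifelse(d >= 0, sqrt(pmax(d, 0)), NA_real_)
    scale <- theta * (1 - theta)
    vcov_real <- vcov_logit * tcrossprod(scale)
    dimnames(vcov_real) <- list(map$params$name, map$params$name)
  }
  se_real <- se_eta * theta * (1 - theta)
  se_real[boundary] <- NA_real_
  est <- tibble::tibble(
    name = map$params$name,
    family = map$params$family,
    estimate = theta,
    se = se_real,
    lower = ifelse(boundary, NA_real_,
                   stats::plogis(eta - 1.96 * se_eta)),
    upper = ifelse(boundary, NA_real_,
                   stats::plogis(eta + 1.96 * se_eta)),
    boundary = boundary
  )
  structure(
    list(estimates = est, loglik = loglik, k = k, n = n,
         aicc = aicc(loglik, k, n), vcov = vcov_real,
         vcov_logit = vcov_logit, eta = eta, convergence = convergence,
         map = map, spec = map$spec),
    class = "joint_fit"
  )
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("Joint known-fate tag-recovery model fit\n")
  cat("  log-likelihood:", format(x$loglik, digits = 6),
      "  K:", x$k, "  n:", x$n,
      "  AICc:", format(x$aicc, digits = 6), "\n")
  if (x$convergence != 0) cat("  WARNING: convergence code", x$convergence, "\n")
  print(x$estimates, n = 20)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameter estimates of a joint fit
#'
#' @param x A `joint_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `name`, `family`,
#'   `estimate`, `se`, `lower`, `upper` (95% intervals, normal theory on
#'   the logit scale back-transformed) and `boundary`.
#' @method tidy joint_fit
#' @export
tidy.joint_fit <- function(x, ...) x$estimates

#' One-row model summary of a joint fit
#'
#' @param x A `joint_fit`.
#' @param ... Unused.
#' @return A tibble with `loglik`, `k`, `n`, `aicc`, `converged`.
#' @method glance joint_fit
#' @export
glance.joint_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, k = x$k, n = x$n, aicc = x$aicc,
                 converged = x$convergence == 0)
}

#' Per-parameter standard errors and variance-covariance of a fit
#'
#' Standard errors are square roots of the diagonal of the inverse
#' observed information, transformed to the real (probability) scale by
#' the delta method for the logit link. Parameters estimated at a
#' boundary (0 or 1) have no usable normal-theory standard error and are
#' reported as `NA`.
#'
#' @param fitted A `joint_fit`.
#' @return A tibble (`name`, `estimate`, `se`, `boundary`) with the
#'   real-scale variance-covariance matrix in attribute `"vcov"`.
#' @export
standard_errors <- function(fitted) {
  stopifnot(inherits(fitted, "joint_fit"))
  out <- fitted$estimates[, c("name", "estimate", "se", "boundary")]
  attr(out, "vcov") <- fitted$vcov
  out
}

#' Cumulative tagging-to-harvest survival with a delta-method SE
#'
#' Computes `S_G = prod(s_g)` over months `entry_month..season_month` from
#' a fitted model's monthly survival estimates, with a first-order
#' delta-method standard error using the fitted variance-covariance of the
#' monthly rates (`d S_G / d s_g` is the product of the other monthly
#' rates, so the result is well defined even when an estimate is 0).
#' Monthly rates without usable standard errors (boundary estimates, e.g.
#' a month with no observed deaths) contribute zero estimated variance to
#' the product, so the reported SE is a lower bound in that case.
#'
#' @param fitted A `joint_fit` whose model estimates monthly survival.
#' @param entry_month,season_month Month range of the product.
#' @param year,stratum Factor levels identifying the monthly rates when
#'   the model's survival structure varies by year or stratum.
#' @return A tibble with `S_G` and `se`.
#' @export
cumulative_survival_se <- function(fitted, entry_month = 1,
                                   season_month = NULL,
                                   year = NULL, stratum = NULL) {
  stopifnot(inherits(fitted, "joint_fit"))
  spec <- fitted$spec
  if (is.null(season_month)) season_month <- spec$season_month
  if (entry_month > season_month) stop("empty month range")
  months <- seq(entry_month, season_month)
  if (!is.null(spec$survival_fixed)) {
    return(tibble::tibble(S_G = spec$survival_fixed^length(months), se = 0))
  }
  labs <- param_label("s", spec$survival_by,
                      list(month = months, year = year, stratum = stratum))
  idx <- match(unique(labs), fitted$estimates$name)
  if (anyNA(idx)) {
    stop("cumulative_survival_se: no fitted monthly rate named ",
         unique(labs)[which(is.na(idx))[1L]],
         " (is the month range inside the fitted months, and are year/",
         "stratum supplied when survival varies by them?)")
  }
  mult <- as.vector(table(labs)[unique(labs)]) # months per parameter
  sg <- fitted$estimates$estimate[idx]
  S_G <- prod(sg^mult)
  # gradient wrt s_j: mult_j * s_j^(mult_j - 1) * prod of the others
  grad <- vapply(seq_along(idx), function(j) {
    mult[j] * sg[j]^(mult[j] - 1) * prod(sg[-j]^mult[-j])
  }, numeric(1))
  if (is.null(fitted$vcov)) {
    return(tibble::tibble(S_G = S_G, se = NA_real_))
  }
  v <- fitted$vcov[idx, idx, drop = FALSE]
  # months estimated at a boundary with no information (NA vcov rows)
  # contribute no estimated variance to the product
  v[is.na(v)] <- 0
  tibble::tibble(S_G = S_G, se = sqrt(max(0, drop(t(grad) %*% v %*% grad))))
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 * loglik + 2K + 2K(K + 1)/(n - K - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Effective sample size.
#' @return The AICc; `NA` with a warning when `n <= k + 1`.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    warning("aicc: undefined for n <= K + 1 (n = ", n, ", K = ", k, ")")
    return(NA_real_)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare fitted models by AICc
#'
#' Ranks models by AICc and computes Akaike weights
#' `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))`. Ties are broken by
#' smaller `K`, then input order. All models should be fitted to the same
#' data; differing effective sample sizes draw a warning.
#'
#' @param ... Named `joint_fit` objects, or a single list of them.
#' @return A tibble sorted by AICc with columns `model`, `k`, `loglik`,
#'   `aicc`, `delta_aicc`, `weight`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "joint_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "joint_fit")))
  nm <- names(fits)
  if (is.null(nm) || any(nm == "")) {
    nm <- paste0("model", seq_along(fits))
  }
  if (length(unique(vapply(fits, `[[`, numeric(1), "n"))) > 1) {
    warning("compare_models: models have different effective sample sizes; ",
            "were they fitted to the same data?")
  }
  out <- tibble::tibble(
    model = nm,
    k = unname(vapply(fits, `[[`, numeric(1), "k")),
    loglik = unname(vapply(fits, `[[`, numeric(1), "loglik")),
    aicc = unname(vapply(fits, `[[`, numeric(1), "aicc")),
    .order = seq_along(fits)
  )
  out <- out[order(out$aicc, out$k, out$.order), ]
  out$delta_aicc <- out$aicc - out$aicc[1L]
  out$weight <- exp(-out$delta_aicc / 2) / sum(exp(-out$delta_aicc / 2))
  out$.order <- NULL
  out
}

#' Test whether transmitter-fitted animals share the tag harvest rate
#'
#' Fits two joint models: one constraining radio-marked and tag-only
#' animals to a common harvest rate (`tag_type` absent from the harvest
#' factor structure, so both data streams alias the same free parameters)
#' and one estimating separate rates, and compares them by AICc. Support
#' for the unconstrained model is evidence that the visible transmitter is
#' associated with a different probability of being harvested.
#'
#' @param data A [harvest_data()] bundle containing both recovery and
#'   radio-harvest streams.
#' @param spec The constrained [model_spec()] (without `"tag_type"` in
#'   `harvest_by`); the unconstrained model adds it.
#' @param ... Passed to [fit_joint_model()].
#' @return A list of class `tag_effect_test` with elements `constrained`,
#'   `unconstrained` (both `joint_fit`) and `comparison` (AICc table).
#' @export
tag_effect_test <- function(data, spec, ...) {
  data <- as_harvest_data(data)
  if (is.null(data$recovery) || is.null(data$radio)) {
    stop("tag_effect_test: needs both recovery and radio-harvest data")
  }
  harvest_by <- setdiff(spec$harvest_by, "tag_type")
  spec_c <- spec
  spec_c$harvest_by <- harvest_by
  spec_u <- spec
  spec_u$harvest_by <- c(harvest_by, "tag_type")
  fit_c <- fit_joint_model(spec_c, data, ...)
  fit_u <- fit_joint_model(spec_u, data, ...)
  structure(
    list(constrained = fit_c, unconstrained = fit_u,
         comparison = compare_models(`common harvest rate` = fit_c,
                                     `tag-type effect` = fit_u)),
    class = "tag_effect_test"
  )
}

#' @export
print.tag_effect_test <- function(x, ...) {
  cat("Transmitter-effect test (H_i = H_ri vs separate rates)\n")
  print(x$comparison)
  invisible(x)
}

#' Plot estimates from a joint fit
#'
#' Point estimates with 95% intervals, faceted by parameter family.
#'
#' @param object A `joint_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot joint_fit
#' @export
autoplot.joint_fit <- function(object, ...) {
  est <- object$estimates
  est$name <- factor(est$name, levels = rev(est$name))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate, y = .data$name)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$family),
                        scales = "free_y", space = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "estimate (real scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
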