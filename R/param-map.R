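#' Map a model specification onto the free parameters for a dataset
#'
#' Enumerates every likelihood cell implied by the data (known-fate
#' intervals, Brownie release-cohort recovery cells, radio-harvest
#' binomials), labels each with the real-scale parameters it involves
#' under the factor structure in `spec`, and returns the resulting free
#' parameter vector layout together with the free-parameter count `K`.
#'
#' A parameter is free iff it appears in at least one likelihood cell.
#' This single rule implements the structural constraints of the model:
#' the final-year annual survival (which never appears in any expected
#' recovery of a dead-recovery model) is excluded rather than fixed, and
#' radio harvest rates for year-strata with no animals available are
#' structurally fixed at 0 and removed. The equality constraint that
#' tag-only and radio-marked animals share a harvest rate is index
#' aliasing: radio-harvest cells carry `tag_type = "radio"`, so whenever
#' `"tag_type"` is absent from `harvest_by` both data streams point at the
#' same free parameters.
#'
#' @param spec A [model_spec()].
#' @param data A [harvest_data()] bundle (or a single data-stream object,
#'   which is wrapped).
#' @return A list of class `param_map` with elements `params` (tibble with
#'   columns `name`, `family`), `k` (the free-parameter count) and `n_eff`
#'   (effective sample size for AICc: tagged releases plus known-fate
#'   entries, plus radio-harvest availability only when no known-fate
#'   stream is present), plus internal evaluation structures.
#' @export
build_parameter_map <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as_harvest_data(data)
  kf <- data$known_fate
  rec <- data$recovery
  radio <- data$radio

  free_s <- is.null(spec$survival_fixed)
  if (free_s && is.null(kf) && !is.null(rec)) {
    stop("build_parameter_map: tagging-to-harvest survival and harvest ",
         "rate are confounded: no known-fate data and monthly survival ",
         "not fixed. Supply known-fate data or set survival_fixed.")
  }

  s_label <- function(month, year, stratum) {
    param_label("s", spec$survival_by,
                list(month = month, year = year, stratum = stratum))
  }
  h_label <- function(year, age, unit, tag_type) {
    param_label("H", spec$harvest_by,
                list(year = year, age = age, unit = unit,
                     tag_type = tag_type))
  }
  ann_label <- function(year, age, unit) {
    param_label("S", spec$annual_by,
                list(year = year, age = age, unit = unit))
  }

  # -- known-fate binomial terms ------------------------------------------
  km <- NULL
  km_fixed_ll <- 0
  if (!is.null(kf)) {
    succ <- kf$n - kf$d - kf$c
    fail <- kf$d
    keep <- succ + fail > 0
    if (free_s) {
      km <- tibble::tibble(
        label = s_label(kf$month[keep], kf$year[keep], kf$stratum[keep]),
        succ = succ[keep], fail = fail[keep]
      )
      km <- dplyr::summarise(dplyr::group_by(km, .data$label),
                             succ = sum(.data$succ), fail = sum(.data$fail),
                             .groups = "drop")
    } else {
      sf <- spec$survival_fixed
      km_fixed_ll <- sum(ifelse(succ[keep] > 0, succ[keep] * log(sf), 0) +
                           ifelse(fail[keep] > 0,
                                  fail[keep] * log(1 - sf), 0))
    }
  }

  # -- Brownie recovery cells ---------------------------------------------
  cells <- NULL
  cohorts <- NULL
  if (!is.null(rec)) {
    years <- rec$years
    jmax <- max(years)
    rel <- rec$releases[rec$releases$released > 0, , drop = FALSE]
    recov <- dplyr::summarise(
      dplyr::group_by(rec$recoveries, .data$year_released,
                      .data$year_recovered,
                      dplyr::across(dplyr::all_of(cohort_keys()))),
      count = sum(.data$count), .groups = "drop"
    )
    cell_rows <- vector("list", nrow(rel))
    for (ci in seq_len(nrow(rel))) {
      co <- rel[ci, ]
      if (co$entry_month > spec$season_month) {
        stop("build_parameter_map: cohort entry month ", co$entry_month,
             " is after the last pre-season month ", spec$season_month)
      }
      months <- seq(co$entry_month, spec$season_month)
      sg_terms <- if (free_s) {
        s_label(months, co$year, co$age)
      } else character(0)
      sg_offset <- if (free_s) 0 else
        length(months) * log(spec$survival_fixed)
      js <- years[years >= co$year]
      rows <- lapply(js, function(j) {
        h_lab <- h_label(j, co$age, co$unit, co$tag_type)
        terms <- c(sg_terms, h_lab,
                   if (j > co$year)
                     ann_label(seq(co$year, j - 1L), co$age, co$unit))
        u <- recov$count[recov$year_released == co$year &
                           recov$year_recovered == j &
                           recov$entry_month == co$entry_month &
                           recov$age == co$age &
                           recov$unit == co$unit &
                           recov$tag_type == co$tag_type]
        list(cohort = ci, terms = terms, offset = sg_offset,
             u = if (length(u) == 0) 0L else sum(u),
             key = paste(co$year, co$entry_month, co$age, co$unit,
                         co$tag_type, j),
             h_lab = h_lab,
             super_s = if (j == co$year + 1L)
               ann_label(co$year, co$age, co$unit) else NA_character_)
      })
      cell_rows[[ci]] <- rows
    }
    cells <- unlist(cell_rows, recursive = FALSE)
    cohorts <- tibble::tibble(
      a = rel$released,
      recovered = vapply(cell_rows, function(rows)
        sum(vapply(rows, `[[`, integer(1), "u")), integer(1))
    )
    cohorts$never <- cohorts$a - cohorts$recovered
  }

  # -- radio-harvest binomial terms ---------------------------------------
  rad <- NULL
  if (!is.null(radio)) {
    use <- radio[radio$available > 0, , drop = FALSE]
    if (nrow(use) > 0) {
      rad <- tibble::tibble(
        label = h_label(use$year, use$age, use$unit, "radio"),
        succ = use$harvested, fail = use$available - use$harvested
      )
      rad <- dplyr::summarise(dplyr::group_by(rad, .data$label),
                              succ = sum(.data$succ),
                              fail = sum(.data$fail), .groups = "drop")
    }
  }

  # -- assemble the free-parameter vector ---------------------------------
  cell_labels <- if (is.null(cells)) character(0) else
    unique(unlist(lapply(cells, `[[`, "terms")))
  labels <- unique(c(if (!is.null(km)) km$label,
                     cell_labels,
                     if (!is.null(rad)) rad$label))
  family <- substr(labels, 1L, 1L)
  ord <- order(match(family, c("s", "H", "S")), labels)
  labels <- labels[ord]
  family <- family[ord]
  k <- length(labels)
  idx_of <- stats::setNames(seq_len(k), labels)

  exponents <- NULL
  if (!is.null(cells)) {
    exponents <- matrix(0L, nrow = length(cells), ncol = k,
                        dimnames = list(NULL, labels))
    for (i in seq_along(cells)) {
      tab <- table(cells[[i]]$terms)
      exponents[i, idx_of[names(tab)]] <- as.integer(tab)
    }
  }

  n_eff <- 0L
  if (!is.null(rec)) n_eff <- n_eff + sum(rec$releases$released)
  if (!is.null(kf)) {
    n_eff <- n_eff + sum(total_entries(kf))
  } else if (!is.null(radio)) {
    n_eff <- n_eff + sum(radio$available)
  }

  structure(
    list(
      params = tibble::tibble(
        name = labels,
        family = c(s = "monthly survival", H = "harvest",
                   S = "annual survival")[family]
      ),
      k = k,
      n_eff = n_eff,
      spec = spec,
      km = if (!is.null(km))
        list(par = unname(idx_of[km$label]), succ = km$succ,
             fail = km$fail),
      km_fixed_ll = km_fixed_ll,
      radio = if (!is.null(rad))
        list(par = unname(idx_of[rad$label]), succ = rad$succ,
             fail = rad$fail),
      brownie = if (!is.null(cells)) list(
        exponents = exponents,
        u = vapply(cells, `[[`, numeric(1), "u"),
        offset = vapply(cells, `[[`, numeric(1), "offset"),
        cohort = vapply(cells, `[[`, numeric(1), "cohort"),
        a = cohorts$a,
        never = cohorts$never,
        agg = outer(seq_len(nrow(cohorts)),
                    vapply(cells, `[[`, numeric(1), "cohort"), `==`) * 1,
        key = vapply(cells, `[[`, character(1), "key"),
        h_par = unname(idx_of[vapply(cells, `[[`, character(1),
                                     "h_lab")]),
        super_s_par = unname(idx_of[vapply(cells, `[[`, character(1),
                                           "super_s")])
      )
    ),
    class = "param_map"
  )
}

#' @export
print.param_map <- function(x, ...) {
  cat("<param_map> K =", x$k, "free parameters, effective n =",
      x$n_eff, "\n")
  print(dplyr::count(x$params, .data$family))
  invisible(x)
}

param_label <- function(family, by, values) {
  if (length(by) == 0) return(rep(family, max(lengths(values))))
  by <- intersect(c("month", "year", "stratum", "age", "unit", "tag_type"),
                  by)
  parts <- lapply(by, function(f) paste0(f, "=", values[[f]]))
  paste0(family, "[", do.call(paste, c(parts, sep = ",")), "]")
}

as_harvest_data <- function(data) {
  if (inherits(data, "harvest_data")) return(data)
  if (inherits(data, "known_fate")) return(harvest_data(known_fate = data))
  if (inherits(data, "recovery_data")) return(harvest_data(recovery = data))
  if (inherits(data, "radio_harvest")) return(harvest_data(radio = data))
  if (is.list(data) &&
      any(c("known_fate", "recovery", "radio") %in% names(data))) {
    return(harvest_data(known_fate = data$known_fate,
                        recovery = data$recovery, radio = data$radio))
  }
  stop("expected a harvest_data bundle or a single data-stream object")
}

# Refresh the count statistics of an existing param_map from a new
# dataset with the same design (same strata, cohort structure and
# months). Reuses the enumerated cells and exponent matrix, which is what
# makes large replicate simulation grids cheap. Internal.
refresh_map_counts <- function(map, data) {
  spec <- map$spec
  if (!is.null(map$km)) {
    kf <- data$known_fate
    lab <- param_label("s", spec$survival_by,
                       list(month = kf$month, year = kf$year,
                            stratum = kf$stratum))
    succ <- kf$n - kf$d - kf$c
    fail <- kf$d
    f <- factor(lab, levels = map$params$name[map$km$par])
    if (any(is.na(f) & succ + fail > 0)) {
      stop("refresh_map_counts: known-fate stratum/month not in the map")
    }
    ok <- !is.na(f)
    map$km$succ <- as.vector(tapply(succ[ok], f[ok], sum, default = 0))
    map$km$fail <- as.vector(tapply(fail[ok], f[ok], sum, default = 0))
  }
  if (!is.null(map$brownie)) {
    rec <- data$recovery$recoveries
    key <- paste(rec$year_released, rec$entry_month, rec$age, rec$unit,
                 rec$tag_type, rec$year_recovered)
    f <- factor(key, levels = map$brownie$key)
    if (any(is.na(f) & rec$count > 0)) {
      stop("refresh_map_counts: recovery cell not in the map")
    }
    ok <- !is.na(f)
    u <- as.vector(tapply(rec$count[ok], f[ok], sum, default = 0))
    map$brownie$u <- u
    map$brownie$never <- map$brownie$a -
      as.vector(rowsum(u, map$brownie$cohort))
  }
  if (!is.null(map$radio)) {
    use <- data$radio[data$radio$available > 0, , drop = FALSE]
    lab <- param_label("H", spec$harvest_by,
                       list(year = use$year, age = use$age,
                            unit = use$unit,
                            tag_type = rep("radio", nrow(use))))
    f <- factor(lab, levels = map$params$name[map$radio$par])
    if (anyNA(f)) {
      stop("refresh_map_counts: radio-harvest stratum not in the map")
    }
    map$radio$succ <- as.vector(tapply(use$harvested, f, sum, default = 0))
    map$radio$fail <- as.vector(tapply(use$available - use$harvested, f,
                                       sum, default = 0))
  }
  map
}
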