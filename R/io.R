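#' Read a dataset directory into validated domain objects
#'
#' Expects comma-delimited UTF-8 files with fixed headers inside `dir`:
#' `known_fate.csv` (`stratum, year, month, n, d, c, e`), `releases.csv`
#' (`year, entry_month, age, unit, tag_type, released`), `recoveries.csv`
#' (`year_released, entry_month, age, unit, tag_type, year_recovered,
#' count`) and `radio_harvest.csv` (`year, unit, age, available,
#' harvested`). Absent optional files yield absent components: a dataset
#' with no `known_fate.csv` needs a model with fixed monthly survival; no
#' `radio_harvest.csv` drops the radio binomial component. Lines starting
#' with `#` are treated as comments.
#'
#' @param dir Directory containing the CSV files.
#' @return A [harvest_data()] bundle.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  kf <- rec <- radio <- NULL
  if (file.exists(p("known_fate.csv"))) {
    kf <- known_fate(read_schema(p("known_fate.csv"),
                                 c("stratum", "year", "month", "n", "d",
                                   "c", "e"),
                                 "ciiiiii"))
  }
  if (file.exists(p("releases.csv"))) {
    if (!file.exists(p("recoveries.csv"))) {
      stop("read_dataset: releases.csv present but recoveries.csv missing")
    }
    rec <- recovery_data(
      read_schema(p("releases.csv"),
                  c("year", "entry_month", "age", "unit", "tag_type",
                    "released"), "iiccci"),
      read_schema(p("recoveries.csv"),
                  c("year_released", "entry_month", "age", "unit",
                    "tag_type", "year_recovered", "count"), "iicccii")
    )
  }
  if (file.exists(p("radio_harvest.csv"))) {
    radio <- radio_harvest(read_schema(p("radio_harvest.csv"),
                                       c("year", "unit", "age",
                                         "available", "harvested"),
                                       "iccii"))
  }
  harvest_data(known_fate = kf, recovery = rec, radio = radio)
}

read_schema <- function(path, header, types) {
  found <- names(readr::read_csv(path, n_max = 0, comment = "#",
                                 show_col_types = FALSE))
  if (!identical(found, header)) {
    stop("read_dataset: ", basename(path), " header mismatch\n  expected: ",
         paste(header, collapse = ", "), "\n  found:    ",
         paste(found, collapse = ", "))
  }
  x <- suppressWarnings(readr::read_csv(path, col_types = types,
                                        comment = "#"))
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    stop("read_dataset: ", basename(path), " row ", pr$row[1L],
         ": expected ", pr$expected[1L], ", got '", pr$actual[1L], "'")
  }
  x
}

#' Write a dataset to a directory of schema CSV files
#'
#' Inverse of [read_dataset()]: writes only the streams present.
#'
#' @param data A [harvest_data()] bundle.
#' @param dir Output directory (created if needed).
#' @param provenance Optional comment line written at the top of each
#'   file.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, provenance = NULL) {
  data <- as_harvest_data(data)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f, cols) {
    write_commented_csv(x[, cols], file.path(dir, f), provenance)
  }
  if (!is.null(data$known_fate)) {
    w(data$known_fate, "known_fate.csv",
      c("stratum", "year", "month", "n", "d", "c", "e"))
  }
  if (!is.null(data$recovery)) {
    w(data$recovery$releases, "releases.csv",
      c("year", "entry_month", "age", "unit", "tag_type", "released"))
    w(data$recovery$recoveries, "recoveries.csv",
      c("year_released", "entry_month", "age", "unit", "tag_type",
        "year_recovered", "count"))
  }
  if (!is.null(data$radio)) {
    w(data$radio, "radio_harvest.csv",
      c("year", "unit", "age", "available", "harvested"))
  }
  invisible(dir)
}

write_commented_csv <- function(x, path, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(if (!is.null(provenance)) paste0("# ", provenance),
               sub("\n$", "", readr::format_csv(x))),
             con)
  invisible(path)
}

#' Write fitted parameter estimates to CSV
#'
#' Columns: `parameter`, `family`, `estimate`, `se`, `lower95`, `upper95`
#' on the real scale (normal-theory intervals on the logit scale,
#' back-transformed).
#'
#' @param fit A `joint_fit`.
#' @param path Output file.
#' @param provenance Optional comment line.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path, provenance = NULL) {
  stopifnot(inherits(fit, "joint_fit"))
  out <- fit$estimates
  names(out) <- c("parameter", "family", "estimate", "se", "lower95",
                  "upper95", "boundary")
  write_commented_csv(out, path, provenance)
}

#' Write a JSON fit report
#'
#' @param fit A `joint_fit`.
#' @param path Output file.
#' @param provenance Optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, provenance = NULL) {
  stopifnot(inherits(fit, "joint_fit"))
  report <- c(list(loglik = fit$loglik, K = fit$k, n = fit$n,
                   AICc = fit$aicc,
                   converged = fit$convergence == 0),
              provenance)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write design-study metrics to CSV
#'
#' Writes `metrics.csv` (per allocation-year: mean estimate, bias,
#' relative bias, CV, CV(RMSE), difference vs the 0-radio baseline) and
#' `summary.csv` (bias summarised across allocation-years per model).
#'
#' @param x A `sim_metrics` object from [run_grid()].
#' @param dir Output directory.
#' @param provenance Optional comment line.
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(x, dir, provenance = NULL) {
  stopifnot(inherits(x, "sim_metrics"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_commented_csv(x$metrics, file.path(dir, "metrics.csv"), provenance)
  write_commented_csv(x$summary, file.path(dir, "summary.csv"), provenance)
  invisible(dir)
}

#' Read or write a simulation scenario config
#'
#' The scenario config is a YAML file with keys `S_G`, `H`, `S`, `years`,
#' `season_month`, `radios`, `tags`, `reps`, `label`; unknown keys are an
#' error.
#'
#' @param path Config file path.
#' @return [read_scenario()] returns a [scenario()]; [write_scenario()]
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- c("S_G", "H", "S", "years", "season_month", "radios", "tags",
             "reps", "label")
  extra <- setdiff(names(lst), known)
  if (length(extra) > 0) {
    stop("read_scenario: unknown config keys: ",
         paste(extra, collapse = ", "))
  }
  args <- lst[intersect(names(lst), known)]
  args$radios <- unlist(args$radios)
  args$tags <- unlist(args$tags)
  do.call(scenario, args)
}

#' @rdname read_scenario
#' @param scn A [scenario()].
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  yaml::write_yaml(
    list(S_G = scn$S_G, H = scn$H, S = scn$S, years = scn$years,
         season_month = scn$season_month, radios = as.list(scn$radios),
         tags = as.list(scn$tags), reps = scn$reps, label = scn$label),
    path)
  invisible(path)
}
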