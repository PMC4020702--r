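#' Specify the factor structure of a joint known-fate tag-recovery model
#'
#' A model specification says which factors each parameter family varies
#' by. The three families are the monthly (pre-season) survival rates `s`,
#' the annual harvest rates `H`, and the annual survival rates `S`. Factor
#' structures are full crossings of the listed factors over the levels
#' present in the data; an empty factor set means a single constant rate.
#'
#' Harvest counts of transmitter-fitted animals enter the harvest family
#' with `tag_type = "radio"`. Including `"tag_type"` in `harvest_by`
#' therefore estimates separate harvest rates for radio-marked and
#' tag-only animals; excluding it imposes the equality constraint that both
#' marking types share a harvest rate (the two parameter families alias to
#' the same free parameters).
#'
#' @param survival_by Factors the monthly survival rate varies by, a subset
#'   of `c("month", "year", "stratum")`. Ignored when `survival_fixed` is
#'   given.
#' @param survival_fixed Optional fixed value for all monthly survival
#'   rates (e.g. `1` for a standard Brownie model that assumes no mortality
#'   between tagging and the hunting season). `NULL` (default) estimates
#'   them.
#' @param harvest_by Factors the harvest rate varies by, subset of
#'   `c("year", "age", "unit", "tag_type")`.
#' @param annual_by Factors the annual survival rate varies by, subset of
#'   `c("year", "age", "unit")`. When `"year"` is included, the final-year
#'   annual survival never appears in any expected recovery and is excluded
#'   from the parameter space.
#' @param season_month Last pre-season month `G`: an animal entering in
#'   month `g0` must survive months `g0..G` to reach the hunting season.
#' @return A list of class `model_spec`.
#' @examples
#' # harvest and annual survival varying by year, monthly survival by
#' # month crossed with stratum (e.g. age class):
#' model_spec(survival_by = c("month", "stratum"),
#'            harvest_by = "year", annual_by = "year")
#' # standard Brownie model (no pre-season mortality):
#' model_spec(survival_fixed = 1, harvest_by = "year", annual_by = "year")
#' @export
model_spec <- function(survival_by = "month",
                       survival_fixed = NULL,
                       harvest_by = "year",
                       annual_by = "year",
                       season_month = 9L) {
  check_factors <- function(by, allowed, what) {
    by <- as.character(by)
    bad <- setdiff(by, allowed)
    if (length(bad) > 0) {
      stop("model_spec: ", what, " cannot vary by ",
           paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
    }
    by
  }
  if (!is.null(survival_fixed)) {
    if (length(survival_fixed) != 1 || !is.finite(survival_fixed) ||
        survival_fixed < 0 || survival_fixed > 1) {
      stop("model_spec: survival_fixed must be a single value in [0, 1]")
    }
    survival_by <- character(0)
  } else {
    survival_by <- check_factors(survival_by, c("month", "year", "stratum"),
                                 "monthly survival")
  }
  harvest_by <- check_factors(harvest_by,
                              c("year", "age", "unit", "tag_type"),
                              "harvest rate")
  annual_by <- check_factors(annual_by, c("year", "age", "unit"),
                             "annual survival")
  season_month <- as.integer(season_month)
  if (season_month < 1) stop("model_spec: season_month must be >= 1")
  structure(
    list(survival_by = survival_by,
         survival_fixed = survival_fixed,
         harvest_by = harvest_by,
         annual_by = annual_by,
         season_month = season_month),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  fmt <- function(by) if (length(by) == 0) "constant" else
    paste(by, collapse = " x ")
  cat("<model_spec>\n")
  if (is.null(x$survival_fixed)) {
    cat("  monthly survival s:", fmt(x$survival_by), "\n")
  } else {
    cat("  monthly survival s: fixed at", x$survival_fixed, "\n")
  }
  cat("  harvest rate H:    ", fmt(x$harvest_by), "\n")
  cat("  annual survival S: ", fmt(x$annual_by), "\n")
  cat("  pre-season months: 1..", x$season_month, "\n", sep = "")
  invisible(x)
}

#' Write a model specification to a YAML config file
#'
#' @param spec A [model_spec()].
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  lst <- list(
    survival_by = as.list(spec$survival_by),
    survival_fixed = spec$survival_fixed,
    harvest_by = as.list(spec$harvest_by),
    annual_by = as.list(spec$annual_by),
    season_month = spec$season_month
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a model specification from a YAML config file
#'
#' Unknown keys are an error so that typos in configs fail fast.
#'
#' @param path File path of a config written by [write_model_spec()] (or by
#'   hand, with the same keys).
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- c("survival_by", "survival_fixed", "harvest_by", "annual_by",
             "season_month")
  extra <- setdiff(names(lst), known)
  if (length(extra) > 0) {
    stop("read_model_spec: unknown config keys: ",
         paste(extra, collapse = ", "))
  }
  model_spec(
    survival_by = unlist(lst$survival_by) %||% character(0),
    survival_fixed = lst$survival_fixed,
    harvest_by = unlist(lst$harvest_by) %||% character(0),
    annual_by = unlist(lst$annual_by) %||% character(0),
    season_month = lst$season_month %||% 9L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
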