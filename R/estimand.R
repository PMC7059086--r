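#' Declare an analysis estimand
#'
#' An `estimand_spec` names a target quantity and the variables it is
#' computed from, in one of five estimator families covering the common
#' measures of observational hospital research:
#'
#' * `proportion` — a success proportion of a boolean outcome, Wilson 95% CI.
#' * `odds_ratio` — a 2x2 exposure-outcome odds ratio; Woolf logit CI and
#'   Fisher exact p unmatched, Mantel-Haenszel common OR with
#'   Robins-Breslow-Greenland CI when matched sets are present.
#' * `km_survival` — Kaplan-Meier survival at a horizon, Greenwood variance,
#'   log-log 95% band.
#' * `cox_hr` — hazard ratios from a Cox proportional-hazards fit
#'   (Efron tie handling), Wald CIs.
#' * `logistic_risk` — predicted risk at a covariate profile from an
#'   AIC-stepwise logistic model with interaction hierarchy.
#'
#' @param id Identifier for the estimand (used in reports).
#' @param family One of `"proportion"`, `"odds_ratio"`, `"km_survival"`,
#'   `"cox_hr"`, `"logistic_risk"`.
#' @param outcome Boolean outcome variable (proportion / odds_ratio /
#'   logistic_risk).
#' @param exposure Boolean exposure or group variable (odds_ratio; for
#'   cox_hr, the coefficient reported as the headline result).
#' @param covariates Character vector of adjustment covariates.
#' @param time,event Survival time and event-indicator variables
#'   (km_survival / cox_hr).
#' @param horizon Time at which `km_survival` reports its point estimate.
#' @param group Optional variable and `group_level` value restricting the
#'   analysis to one subgroup before estimation.
#' @param group_level Level of `group` defining the subgroup.
#' @param matching `NULL`, or `list(method = "nearest_neighbor", ratio = r)`
#'   to propensity-match before an odds-ratio analysis.
#' @param risk_profile Named list assigning covariate values at which
#'   `logistic_risk` predicts (the exposure variable may be included).
#' @param term For `cox_hr`, the model term whose hazard ratio is the
#'   headline estimate; defaults to `exposure`.
#' @return An object of class `estimand_spec`.
#' @export
estimand_spec <- function(id, family, outcome = NULL, exposure = NULL,
                          covariates = character(0), time = NULL, event = NULL,
                          horizon = NULL, group = NULL, group_level = NULL,
                          matching = NULL, risk_profile = NULL, term = NULL) {
  families <- c("proportion", "odds_ratio", "km_survival", "cox_hr", "logistic_risk")
  family <- match.arg(family, families)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_parameter("estimand id must be a non-empty string")
  if (!is.null(matching)) {
    if (is.null(matching$ratio) || matching$ratio < 1)
      stop_parameter(sprintf("estimand '%s': matching ratio must be >= 1", id))
    matching$ratio <- as.integer(matching$ratio)
    if (is.null(matching$method)) matching$method <- "nearest_neighbor"
  }
  structure(list(
    id = id, family = family, outcome = outcome, exposure = exposure,
    covariates = as.character(covariates), time = time, event = event,
    horizon = horizon, group = group, group_level = group_level,
    matching = matching, risk_profile = risk_profile,
    term = if (is.null(term)) exposure else term
  ), class = "estimand_spec")
}

# check that every referenced variable exists with a compatible kind
validate_estimand <- function(spec, schema) {
  nms <- schema_names(schema)
  need <- function(v, kinds, what) {
    if (is.null(v)) return(invisible(NULL))
    if (!(v %in% nms))
      stop_schema(sprintf("estimand '%s': %s variable '%s' not in schema",
                          spec$id, what, v))
    if (!(schema[[v]]$kind %in% kinds))
      stop_schema(sprintf("estimand '%s': %s variable '%s' must be %s",
                          spec$id, what, v, paste(kinds, collapse = "/")))
  }
  switch(spec$family,
    proportion = need(spec$outcome, "boolean", "outcome"),
    odds_ratio = { need(spec$outcome, "boolean", "outcome")
                   need(spec$exposure, "boolean", "exposure") },
    km_survival = { need(spec$time, "continuous", "time")
                    need(spec$event, "boolean", "event") },
    cox_hr = { need(spec$time, "continuous", "time")
               need(spec$event, "boolean", "event") },
    logistic_risk = need(spec$outcome, "boolean", "outcome")
  )
  for (v in spec$covariates)
    need(v, c("categorical", "boolean", "continuous"), "covariate")
  need(spec$group, c("categorical", "boolean"), "group")
  invisible(spec)
}

# apply the optional subgroup filter
apply_group_filter <- function(x, spec) {
  if (is.null(spec$group)) return(x)
  col <- x[[spec$group]]
  keep <- if (is.logical(col)) {
    lvl <- spec$group_level
    if (is.null(lvl)) lvl <- TRUE
    if (is.character(lvl)) lvl <- identical(tolower(lvl), "true")
    !is.na(col) & col == lvl
  } else {
    !is.na(col) & as.character(col) == as.character(spec$group_level)
  }
  sub <- as.data.frame(x)[keep, , drop = FALSE]
  cohort(sub, get_schema(x))
}

#' Read an analysis specification file
#'
#' The file (JSON or YAML, decided by extension) holds a list of estimand
#' definitions with the same field names as [estimand_spec()].
#'
#' @param path Path to the analysis spec (.json, .yaml or .yml).
#' @return A list of `estimand_spec`s.
#' @export
read_analysis_spec <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("analysis spec not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(raw) || length(raw) == 0L)
    stop_parameter(sprintf("analysis spec '%s' must be a non-empty list", path))
  lapply(raw, function(e) {
    do.call(estimand_spec, e[intersect(names(e), names(formals(estimand_spec)))])
  })
}
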