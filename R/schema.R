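#' Define a cohort variable
#'
#' A `variable_spec` describes one column of a cohort table: its name, its
#' statistical kind, the role it plays in downstream analyses, and (for
#' categorical variables) the ordered set of admissible labels.
#'
#' @param name Variable name; must be unique within a schema.
#' @param kind One of `"categorical"`, `"boolean"`, `"continuous"`.
#' @param role One of `"covariate"`, `"outcome"`, `"event_time"`,
#'   `"event_indicator"`, `"group"`, `"stratum"`. `event_time` requires a
#'   continuous kind with non-negative values; `event_indicator` requires a
#'   boolean kind.
#' @param categories Character vector of ordered category labels. Required
#'   exactly when `kind = "categorical"`.
#' @param units Optional free-text units (e.g. `"days"`, `"mg/dL"`).
#'
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind, role = "covariate",
                          categories = NULL, units = NULL) {
  kinds <- c("categorical", "boolean", "continuous")
  roles <- c("covariate", "outcome", "event_time", "event_indicator",
             "group", "stratum")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_schema("variable name must be a non-empty string")
  kind <- match.arg(kind, kinds)
  role <- match.arg(role, roles)
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) == 0L)
      stop_schema(sprintf("variable '%s': categorical kind requires non-empty categories", name))
    categories <- as.character(categories)
    if (anyDuplicated(categories))
      stop_schema(sprintf("variable '%s': duplicated category labels", name))
  } else if (!is.null(categories)) {
    stop_schema(sprintf("variable '%s': categories are only allowed for categorical kind", name))
  }
  if (role == "event_time" && kind != "continuous")
    stop_schema(sprintf("variable '%s': role event_time requires continuous kind", name))
  if (role == "event_indicator" && kind != "boolean")
    stop_schema(sprintf("variable '%s': role event_indicator requires boolean kind", name))
  structure(
    list(name = name, kind = kind, role = role,
         categories = categories, units = units),
    class = "variable_spec"
  )
}

#' Assemble a cohort schema
#'
#' @param ... `variable_spec` objects (or a single list of them).
#' @return An object of class `cohort_schema`: a named list of
#'   `variable_spec`s in column order.
#' @export
cohort_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "variable_spec"))
    specs <- specs[[1L]]
  if (length(specs) == 0L) stop_schema("schema must contain at least one variable")
  ok <- vapply(specs, inherits, logical(1), "variable_spec")
  if (!all(ok)) stop_schema("all schema entries must be variable_spec objects")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop_schema(sprintf("duplicated variable name(s): %s",
                        paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  names(specs) <- nms
  structure(specs, class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat(sprintf("cohort schema: %d variables\n", length(x)))
  for (v in x) {
    extra <- if (v$kind == "categorical")
      sprintf(" {%s}", paste(v$categories, collapse = ", ")) else ""
    cat(sprintf("  %-20s %-12s %-16s%s\n", v$name, v$kind, v$role, extra))
  }
  invisible(x)
}

schema_names <- function(schema) unname(vapply(schema, `[[`, character(1), "name"))
schema_kinds <- function(schema) unname(vapply(schema, `[[`, character(1), "kind"))

#' Read a schema from a JSON file
#'
#' The file holds a JSON array of objects with fields `name`, `kind`, `role`,
#' and optionally `categories` and `units`.
#'
#' @param path Path to the JSON schema file.
#' @return A `cohort_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("schema file not found: %s", path))
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e) stop_schema(sprintf(
                    "cannot parse schema '%s': %s", path, conditionMessage(e))))
  if (!is.list(raw) || length(raw) == 0L)
    stop_schema(sprintf("schema '%s' must be a non-empty JSON array", path))
  specs <- lapply(raw, function(v) {
    variable_spec(
      name = v$name, kind = v$kind,
      role = if (is.null(v$role)) "covariate" else v$role,
      categories = if (is.null(v$categories)) NULL else unlist(v$categories),
      units = v$units
    )
  })
  cohort_schema(specs)
}

#' Write a schema to a JSON file
#'
#' @param schema A `cohort_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cohort_schema"))
  out <- lapply(unname(schema), function(v) {
    x <- list(name = v$name, kind = v$kind, role = v$role)
    if (!is.null(v$categories)) x$categories <- as.list(v$categories)
    if (!is.null(v$units)) x$units <- v$units
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# error taxonomy used across the package (and mapped to CLI exit codes)
stop_schema <- function(msg) stop(errorCondition(msg, class = c("synthcohort_schema_error", "synthcohort_error")))
stop_parameter <- function(msg) stop(errorCondition(msg, class = c("synthcohort_parameter_error", "synthcohort_error")))
stop_estimation <- function(msg) stop(errorCondition(msg, class = c("synthcohort_estimation_error", "synthcohort_error")))
stop_io <- function(msg) stop(errorCondition(msg, class = c("synthcohort_io_error", "synthcohort_error")))
stop_parse <- function(msg) stop(errorCondition(msg, class = c("synthcohort_parse_error", "synthcohort_error")))
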