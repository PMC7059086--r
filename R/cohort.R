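#' Construct a validated cohort
#'
#' A cohort is a rectangular patient-by-variable table tied to a
#' [cohort_schema()]. Every non-missing value must conform to its variable's
#' kind: categorical values must be one of the declared categories, boolean
#' values are logical, continuous values are finite reals (non-negative for
#' `event_time` variables). `NA` is the missing sentinel throughout. The data
#' model is identifier-free by construction: there is no patient-ID column,
#' and validation rejects any column not declared in the schema.
#'
#' @param data A data.frame whose columns match the schema names exactly
#'   (same order).
#' @param schema A `cohort_schema`.
#' @return An object of class `cohort`: the data.frame with the schema
#'   attached as an attribute, columns coerced to canonical types
#'   (factor with schema levels / logical / double).
#' @export
cohort <- function(data, schema) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  nms <- schema_names(schema)
  if (!identical(names(data), nms))
    stop_schema(sprintf(
      "column names do not match schema: data has [%s], schema has [%s]",
      paste(names(data), collapse = ", "), paste(nms, collapse = ", ")))
  out <- data
  for (v in schema) {
    out[[v$name]] <- coerce_column(data[[v$name]], v)
  }
  rownames(out) <- NULL
  structure(out, schema = schema, class = c("cohort", "data.frame"))
}

coerce_column <- function(x, v) {
  n <- length(x)
  switch(v$kind,
    categorical = {
      if (is.factor(x)) x <- as.character(x)
      x <- as.character(x)
      bad <- which(!is.na(x) & !(x %in% v$categories))
      if (length(bad))
        stop_parse(sprintf(
          "variable '%s', row %d: value '%s' is not an admissible category",
          v$name, bad[1L], x[bad[1L]]))
      factor(x, levels = v$categories)
    },
    boolean = {
      if (is.character(x) || is.factor(x)) {
        xc <- tolower(as.character(x))
        y <- rep(NA, n)
        y[xc %in% "true"] <- TRUE
        y[xc %in% "false"] <- FALSE
        bad <- which(!is.na(xc) & !(xc %in% c("true", "false")))
        if (length(bad))
          stop_parse(sprintf(
            "variable '%s', row %d: value '%s' is not a boolean (true/false)",
            v$name, bad[1L], as.character(x)[bad[1L]]))
        as.logical(y)
      } else if (is.logical(x)) x
      else if (is.numeric(x) && all(x %in% c(0, 1, NA))) as.logical(x)
      else stop_parse(sprintf("variable '%s': cannot interpret column as boolean", v$name))
    },
    continuous = {
      if (is.character(x)) {
        y <- suppressWarnings(as.numeric(x))
        bad <- which(!is.na(x) & nzchar(x) & is.na(y))
        if (length(bad))
          stop_parse(sprintf(
            "variable '%s', row %d: value '%s' is not numeric",
            v$name, bad[1L], x[bad[1L]]))
        x <- y
      }
      x <- as.numeric(x)
      bad <- which(!is.na(x) & !is.finite(x))
      if (length(bad))
        stop_parse(sprintf("variable '%s', row %d: non-finite value", v$name, bad[1L]))
      if (v$role == "event_time") {
        neg <- which(!is.na(x) & x < 0)
        if (length(neg))
          stop_parse(sprintf(
            "variable '%s', row %d: event_time value %g is negative",
            v$name, neg[1L], x[neg[1L]]))
      }
      x
    }
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d records x %d variables\n", nrow(x), ncol(x)))
  NextMethod()
}

#' Retrieve the schema attached to a cohort
#' @param x A `cohort`.
#' @return The `cohort_schema`.
#' @export
get_schema <- function(x) {
  s <- attr(x, "schema", exact = TRUE)
  if (is.null(s)) stop_schema("object carries no cohort schema")
  s
}

#' Read a cohort from CSV + JSON schema
#'
#' The CSV dialect is RFC 4180 with UTF-8 encoding and `.` decimal separator;
#' the missing sentinel is the empty field. Booleans are serialized as the
#' literals `true`/`false`. The CSV header must match the schema variable
#' names exactly and in order.
#'
#' @param path Path to the cohort CSV.
#' @param schema_path Path to the JSON schema, or a `cohort_schema` object.
#' @return A validated `cohort`.
#' @export
read_cohort <- function(path, schema_path) {
  schema <- if (inherits(schema_path, "cohort_schema")) schema_path
            else read_schema(schema_path)
  if (!file.exists(path)) stop_io(sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL, fileEncoding = "UTF-8")
  if (nrow(df) > 0L) {
    for (j in seq_along(df)) df[[j]][df[[j]] == ""] <- NA_character_
  }
  if (!identical(names(df), schema_names(schema)))
    stop_schema(sprintf(
      "CSV header [%s] does not match schema [%s]",
      paste(names(df), collapse = ", "),
      paste(schema_names(schema), collapse = ", ")))
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(schema)),
                                 schema_names(schema)))
  }
  cohort(df, schema)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c), schema)` is the
#' identity on values and schema. Missing values become empty fields; booleans
#' become `true`/`false`.
#'
#' @param x A `cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  schema <- get_schema(x)
  out <- as.data.frame(x)
  for (v in schema) {
    col <- out[[v$name]]
    out[[v$name]] <- switch(v$kind,
      categorical = as.character(col),
      boolean = ifelse(is.na(col), NA_character_, ifelse(col, "true", "false")),
      continuous = ifelse(is.na(col), NA_character_,
                          format(col, digits = 15, trim = TRUE, scientific = FALSE))
    )
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

# column name vectors by kind, in schema order
vars_of_kind <- function(schema, kinds) {
  nms <- schema_names(schema)
  nms[schema_kinds(schema) %in% kinds]
}
categorical_like_vars <- function(schema) vars_of_kind(schema, c("categorical", "boolean"))
continuous_vars <- function(schema) vars_of_kind(schema, "continuous")
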