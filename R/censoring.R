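#' Censor identifying categorical combinations
#'
#' Scans the full cross-classification of all categorical and boolean
#' variables (missing counted as its own level) and blanks values for
#' records falling in cells with fewer than `k` members, so that no rare
#' categorical pattern that could single out a patient survives into the
#' statistics extracted for synthesis. Continuous variables are never
#' modified.
#'
#' The procedure is iterative and greedy: while an offending cell exists,
#' the categorical variable with the largest number of schema levels among
#' the cell's non-missing variables is set to missing for the cell's records
#' (blanking high-cardinality variables merges cells fastest), then the
#' cross-classification is rebuilt and rescanned. Ties are broken by schema
#' order; the algorithm is fully deterministic. A record all of whose
#' categorical values are already missing cannot be censored further and is
#' left as the all-missing cell whatever its size.
#'
#' @param x A `cohort`.
#' @param k Minimum cell size (privacy threshold), an integer >= 2.
#'   Default 5, the usual small-cell suppression convention.
#' @return A list with components `cohort` (the censored cohort) and
#'   `report` (a `censoring_report`: threshold, per-variable censoring rate,
#'   number of cells blanked and records touched).
#' @export
censor_unique_cells <- function(x, k = 5L) {
  stopifnot(inherits(x, "cohort"))
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop_parameter("k must be a single integer >= 2")
  k <- as.integer(k)
  schema <- get_schema(x)
  cat_vars <- categorical_like_vars(schema)
  n <- nrow(x)

  cells_censored <- 0L
  touched <- rep(FALSE, n)
  blanked <- setNames(integer(length(cat_vars)), cat_vars)

  # schema-declared cardinality; missing level not counted (it is the target)
  cardinality <- vapply(cat_vars, function(v) {
    sp <- schema[[v]]
    if (sp$kind == "boolean") 2L else length(sp$categories)
  }, integer(1))

  out <- x
  if (length(cat_vars) > 0L && n > 0L) {
    repeat {
      key <- cell_key(out, cat_vars)
      tab <- table(key)
      small <- names(tab)[tab < k]
      progressed <- FALSE
      for (cell in small) {
        rows <- which(key == cell)
        # variables still non-missing within this cell
        open <- cat_vars[vapply(cat_vars, function(v) !is.na(out[[v]][rows[1L]]),
                                logical(1))]
        if (length(open) == 0L) next
        victim <- open[which.max(cardinality[open])]
        out[[victim]][rows] <- NA
        blanked[victim] <- blanked[victim] + length(rows)
        cells_censored <- cells_censored + 1L
        touched[rows] <- TRUE
        progressed <- TRUE
      }
      if (!progressed) break
    }
  }

  report <- structure(list(
    k_threshold = k,
    per_variable_rate = if (n > 0L)
      setNames(as.numeric(blanked) / n, cat_vars)
    else setNames(rep(0, length(cat_vars)), cat_vars),
    cells_censored = cells_censored,
    records_touched = sum(touched)
  ), class = "censoring_report")

  list(cohort = out, report = report)
}

# joint cell key over the given categorical/boolean variables, NA as a level
cell_key <- function(x, vars) {
  if (length(vars) == 0L) return(rep("", nrow(x)))
  cols <- lapply(vars, function(v) {
    col <- as.character(x[[v]])
    col[is.na(col)] <- "∅"  # explicit missing level
    col
  })
  do.call(paste, c(cols, sep = "\x1f"))
}

#' @export
print.censoring_report <- function(x, ...) {
  cat(sprintf("censoring report (k = %d): %d cell-blankings, %d records touched\n",
              x$k_threshold, x$cells_censored, x$records_touched))
  if (length(x$per_variable_rate)) {
    for (v in names(x$per_variable_rate))
      cat(sprintf("  %-20s censored %.3f\n", v, x$per_variable_rate[[v]]))
  }
  invisible(x)
}

#' Serialize a censoring report to JSON
#' @param report A `censoring_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_censoring_report <- function(report, path) {
  stopifnot(inherits(report, "censoring_report"))
  jsonlite::write_json(list(
    k_threshold = report$k_threshold,
    per_variable_rate = as.list(report$per_variable_rate),
    cells_censored = report$cells_censored,
    records_touched = report$records_touched
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

empty_censoring_report <- function(schema, k = 5L) {
  cat_vars <- categorical_like_vars(schema)
  structure(list(
    k_threshold = as.integer(k),
    per_variable_rate = setNames(rep(0, length(cat_vars)), cat_vars),
    cells_censored = 0L,
    records_touched = 0L
  ), class = "censoring_report")
}
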