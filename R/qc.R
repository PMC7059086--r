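#' Quality-control comparison of a synthetic cohort against the original
#'
#' Produces the three-part reliability report that accompanies every
#' synthesis run: (1) the censoring rate for each variable (passed through
#' from [censor_unique_cells()]), (2) a side-by-side summary of each
#' variable's distribution in the original versus the synthetic data, and
#' (3) a comparison of all pairwise correlations.
#'
#' Pairwise association measures are chosen by variable kind:
#' Spearman rank correlation for continuous-continuous pairs, a point-biserial
#' correlation on ranks for boolean-continuous pairs (equivalent to Spearman
#' with the boolean coded 0/1), and Cramer's V for pairs of categorical
#' and/or boolean variables. All are computed pairwise-complete. Pairs of a
#' multi-level categorical with a continuous variable have no single standard
#' correlation and are reported as `NA`.
#'
#' @param real The original `cohort`.
#' @param synthetic A synthetic `cohort` with the identical schema.
#' @param censoring Optional `censoring_report` to embed; defaults to an
#'   empty (all-zero) report.
#' @return An object of class `qc_report` with components `censoring`,
#'   `per_variable` (per-variable real/synthetic marginal summaries),
#'   `correlation_real`, `correlation_synthetic`, `correlation_delta`, and
#'   `max_abs_correlation_delta`.
#' @export
qc_report <- function(real, synthetic, censoring = NULL) {
  stopifnot(inherits(real, "cohort"), inherits(synthetic, "cohort"))
  schema <- get_schema(real)
  if (!identical(schema_names(schema), schema_names(get_schema(synthetic))) ||
      !identical(schema_kinds(schema), schema_kinds(get_schema(synthetic))))
    stop_schema("real and synthetic cohorts must share an identical schema")
  if (is.null(censoring)) censoring <- empty_censoring_report(schema)

  per_variable <- lapply(setNames(schema_names(schema), schema_names(schema)),
    function(v) {
      sp <- schema[[v]]
      list(kind = sp$kind,
           real = marginal_summary(real[[v]], sp),
           synthetic = marginal_summary(synthetic[[v]], sp))
    })

  cr <- pairwise_correlations(real)
  cs <- pairwise_correlations(synthetic)
  delta <- cs - cr
  diag(delta) <- 0

  structure(list(
    censoring = censoring,
    per_variable = per_variable,
    correlation_real = cr,
    correlation_synthetic = cs,
    correlation_delta = delta,
    max_abs_correlation_delta = max(abs(delta), na.rm = TRUE)
  ), class = "qc_report")
}

marginal_summary <- function(col, sp) {
  if (sp$kind == "continuous") {
    obs <- col[!is.na(col)]
    if (length(obs) == 0L)
      return(list(n = 0L, missing_fraction = 1, mean = NA, sd = NA,
                  min = NA, q25 = NA, median = NA, q75 = NA, max = NA))
    q <- unname(stats::quantile(obs, c(0.25, 0.5, 0.75)))
    list(n = length(obs), missing_fraction = mean(is.na(col)),
         mean = mean(obs), sd = if (length(obs) > 1L) stats::sd(obs) else 0,
         min = min(obs), q25 = q[1L], median = q[2L], q75 = q[3L], max = max(obs))
  } else {
    levs <- if (sp$kind == "boolean") c("false", "true") else sp$categories
    x <- if (sp$kind == "boolean")
      factor(ifelse(is.na(col), NA, ifelse(col, "true", "false")), levels = levs)
    else factor(as.character(col), levels = levs)
    n <- length(x)
    freq <- as.list(table(x) / max(n, 1L))
    list(n = n, missing_fraction = mean(is.na(col)), frequencies = freq)
  }
}

#' Pairwise association matrix of a cohort
#'
#' Kind-aware association matrix (see [qc_report()] for the measure chosen
#' per pair); unit diagonal.
#'
#' @param x A `cohort`.
#' @return A symmetric numeric matrix over all schema variables.
#' @export
pairwise_correlations <- function(x) {
  schema <- get_schema(x)
  nms <- schema_names(schema)
  kinds <- schema_kinds(schema)
  p <- length(nms)
  r <- diag(p)
  dimnames(r) <- list(nms, nms)
  if (p < 2L) return(r)
  for (i in 1:(p - 1L)) for (j in (i + 1L):p) {
    r[i, j] <- r[j, i] <- pair_association(
      x[[nms[i]]], kinds[i], x[[nms[j]]], kinds[j], schema[[i]], schema[[j]])
  }
  r
}

pair_association <- function(a, ka, b, kb, spa, spb) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (ka == "continuous" && kb == "continuous") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    return(stats::cor(a, b, method = "spearman"))
  }
  if ((ka == "boolean" && kb == "continuous") ||
      (ka == "continuous" && kb == "boolean")) {
    x <- if (ka == "boolean") as.numeric(a) else as.numeric(b)
    y <- if (ka == "boolean") rank(b) else rank(a)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    return(stats::cor(x, y))
  }
  if (ka %in% c("categorical", "boolean") && kb %in% c("categorical", "boolean")) {
    return(cramers_v(as.character(a), as.character(b)))
  }
  NA_real_  # multi-level categorical vs continuous
}

# bias-uncorrected Cramer's V from the Pearson chi-square statistic
cramers_v <- function(a, b) {
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  sqrt(as.numeric(chi2) / (n * (min(nrow(tab), ncol(tab)) - 1L)))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d variables, max |delta correlation| = %.4f\n",
              length(x$per_variable), x$max_abs_correlation_delta))
  print(x$censoring)
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(list(
    censoring = list(
      k_threshold = report$censoring$k_threshold,
      per_variable_rate = as.list(report$censoring$per_variable_rate),
      cells_censored = report$censoring$cells_censored,
      records_touched = report$censoring$records_touched
    ),
    per_variable = report$per_variable,
    correlation_delta = as.data.frame(report$correlation_delta),
    max_abs_correlation_delta = report$max_abs_correlation_delta
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}
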