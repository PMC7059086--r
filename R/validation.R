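#' Replicate-based validation of synthetic-data results
#'
#' The core protocol: censor the real cohort, fit the synthesis model once,
#' draw `K` synthetic replicates on a deterministic seed schedule, run every
#' declared estimand on the real cohort and on each replicate, and quantify
#' per estimand
#'
#' * **bias** — the mean of the replicate point estimates minus the real
#'   point estimate, on the estimand's natural scale (log scale for odds
#'   and hazard ratios);
#' * **stability** — the range (min, max) of replicate-minus-real
#'   differences;
#' * **containment** — the fraction of replicate points falling inside the
#'   real-data 95% confidence interval, and for survival estimands the
#'   fraction of time-grid points at which the mean replicate curve lies
#'   inside the real confidence band.
#'
#' A replicate on which an estimator fails (e.g. non-convergence on a small
#' draw) is recorded as failed and excluded from the summaries; the run
#' never aborts.
#'
#' @param real The originating `cohort`.
#' @param specs A list of `estimand_spec`s (a single spec is accepted).
#' @param k_privacy Censoring threshold passed to [censor_unique_cells()].
#' @param K Number of synthetic replicates.
#' @param seed Master seed; replicate r uses [replicate_seed()]`(seed, r)`.
#' @param count_mode,small_cell_min Passed to [fit_synthesis_model()].
#' @param generator Function `(model, seed) -> cohort` used to draw each
#'   replicate; defaults to [sample_synthetic()]. Substituting the identity
#'   generator (ignore the model, return the real cohort) turns the harness
#'   into its own oracle: bias 0, range (0, 0), containment 1.
#' @return A list of `validation_report`s, one per estimand.
#' @export
run_validation <- function(real, specs, k_privacy = 5L, K = 5L, seed = 1L,
                           count_mode = c("exact", "multinomial"),
                           small_cell_min = 10L,
                           generator = sample_synthetic) {
  stopifnot(inherits(real, "cohort"))
  count_mode <- match.arg(count_mode)
  if (inherits(specs, "estimand_spec")) specs <- list(specs)
  if (!is.numeric(K) || K < 1) stop_parameter("K must be >= 1")
  K <- as.integer(K)
  schema <- get_schema(real)
  for (sp in specs) validate_estimand(sp, schema)

  cen <- censor_unique_cells(real, k = k_privacy)
  model <- fit_synthesis_model(cen$cohort, small_cell_min = small_cell_min,
                               count_mode = count_mode)

  real_results <- lapply(specs, function(sp) run_estimator(real, sp, seed = seed))

  replicate_results <- vector("list", K)
  for (r in seq_len(K)) {
    rseed <- replicate_seed(seed, r)
    syn <- generator(model, rseed)
    replicate_results[[r]] <- lapply(seq_along(specs), function(i) {
      tryCatch(run_estimator(syn, specs[[i]], seed = rseed),
               error = function(e) structure(
                 list(message = conditionMessage(e)), class = "failed_replicate"))
    })
  }

  reports <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    real_res <- real_results[[i]]
    reps <- lapply(replicate_results, `[[`, i)
    failed <- vapply(reps, inherits, logical(1), "failed_replicate")
    ok <- reps[!failed]
    pts <- vapply(ok, `[[`, numeric(1), "point")
    diffs <- pts - real_res$point
    contain <- mean(pts >= real_res$ci_low & pts <= real_res$ci_high)
    curve_contain <- NA_real_
    if (!is.null(real_res$curve) && length(ok) > 0L &&
        all(vapply(ok, function(r) !is.null(r$curve), logical(1)))) {
      curve_contain <- compare_curves(real_res, ok)$containment
    }
    structure(list(
      estimand_id = sp$id,
      real = real_res,
      replicates = reps,
      bias = if (length(diffs)) mean(diffs) else NA_real_,
      range_low = if (length(diffs)) min(diffs) else NA_real_,
      range_high = if (length(diffs)) max(diffs) else NA_real_,
      containment = contain,
      curve_containment = curve_contain,
      K = K,
      n_failed = sum(failed),
      seed = as.integer(seed),
      censoring = cen$report
    ), class = "validation_report")
  })
  names(reports) <- vapply(specs, `[[`, character(1), "id")
  reports
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "%s: real %.4f (%.4f, %.4f) | K=%d bias %.5f range (%.5f, %.5f) containment %.2f%s%s\n",
    x$estimand_id, x$real$point, x$real$ci_low, x$real$ci_high,
    x$K, x$bias, x$range_low, x$range_high, x$containment,
    if (!is.na(x$curve_containment))
      sprintf(" curve %.2f", x$curve_containment) else "",
    if (x$n_failed > 0L) sprintf(" [%d failed]", x$n_failed) else ""))
  invisible(x)
}

#' Compare replicate survival curves against the real curve
#'
#' Step curves are re-evaluated on the union of all time grids; the summary
#' is the pointwise mean replicate curve, its pointwise min/max envelope,
#' and the fraction of grid points at which the mean curve lies inside the
#' real confidence band.
#'
#' @param real An `estimate_result` carrying a curve.
#' @param replicates A list of `estimate_result`s carrying curves.
#' @return A list with `grid`, `mean_curve`, `env_low`, `env_high`,
#'   `real_curve`, and `containment`.
#' @export
compare_curves <- function(real, replicates) {
  if (is.null(real$curve)) stop_parameter("real result carries no curve")
  if (length(replicates) == 0L ||
      any(vapply(replicates, function(r) is.null(r$curve), logical(1))))
    stop_parameter("every replicate must carry a curve")
  grid <- sort(unique(c(real$curve$time,
                        unlist(lapply(replicates, function(r) r$curve$time)))))
  # right-continuous step evaluation; before the first event time the
  # survival (and its band) is 1 with certainty
  eval_step <- function(curve, col) {
    i <- findInterval(grid, curve$time)
    c(1, curve[[col]])[i + 1L]
  }
  rep_mat <- vapply(replicates, function(r) eval_step(r$curve, "survival"),
                    numeric(length(grid)))
  rep_mat <- matrix(rep_mat, nrow = length(grid))
  mean_curve <- rowMeans(rep_mat)
  real_s <- eval_step(real$curve, "survival")
  real_lo <- eval_step(real$curve, "band_low")
  real_hi <- eval_step(real$curve, "band_high")
  containment <- mean(mean_curve >= real_lo - 1e-12 & mean_curve <= real_hi + 1e-12)
  list(grid = grid, mean_curve = mean_curve,
       env_low = apply(rep_mat, 1L, min), env_high = apply(rep_mat, 1L, max),
       real_curve = real_s, containment = containment)
}

#' Tabulate validation reports
#'
#' One row per estimand: the real point and CI, bias, replicate range,
#' containment, curve containment and failure count. The table serializes
#' cleanly to CSV or JSON.
#'
#' @param reports A list of `validation_report`s from [run_validation()].
#' @return A data.frame.
#' @export
summarize_validation <- function(reports) {
  if (inherits(reports, "validation_report")) reports <- list(reports)
  if (length(reports) == 0L) stop_parameter("no reports to summarize")
  rows <- lapply(reports, function(x) data.frame(
    estimand_id = x$estimand_id,
    scale = x$real$scale,
    real_point = x$real$point,
    real_ci_low = x$real$ci_low,
    real_ci_high = x$real$ci_high,
    K = x$K,
    bias = x$bias,
    range_low = x$range_low,
    range_high = x$range_high,
    containment = x$containment,
    curve_containment = x$curve_containment,
    n_failed = x$n_failed,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize validation reports to JSON
#'
#' @param reports A list of `validation_report`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(reports, path) {
  if (inherits(reports, "validation_report")) reports <- list(reports)
  out <- lapply(reports, function(x) list(
    estimand_id = x$estimand_id,
    real = list(point = x$real$point, ci_low = x$real$ci_low,
                ci_high = x$real$ci_high, scale = x$real$scale),
    replicate_points = vapply(
      Filter(function(r) !inherits(r, "failed_replicate"), x$replicates),
      `[[`, numeric(1), "point"),
    bias = x$bias, range_low = x$range_low, range_high = x$range_high,
    containment = x$containment,
    curve_containment = if (is.na(x$curve_containment)) NULL else x$curve_containment,
    K = x$K, n_failed = x$n_failed, seed = x$seed))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
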