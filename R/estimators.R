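#' Estimate results: the common container
#'
#' Every estimator returns an `estimate_result`: a point estimate with a 95%
#' confidence interval on a declared scale, optionally a survival curve with
#' a confidence band, plus free-form diagnostics (sample size, events,
#' matched sets, warnings).
#'
#' @param estimand_id Identifier echoed from the `estimand_spec`.
#' @param point,ci_low,ci_high Point estimate and 95% CI on `scale`.
#' @param scale One of `"proportion"`, `"log_odds_ratio"`,
#'   `"log_hazard_ratio"`, `"risk"`.
#' @param curve Optional data.frame with columns `time`, `survival`,
#'   `band_low`, `band_high`.
#' @param diagnostics Named list of auxiliary quantities.
#' @return An object of class `estimate_result`.
#' @export
estimate_result <- function(estimand_id, point, ci_low, ci_high, scale,
                            curve = NULL, diagnostics = list()) {
  scale <- match.arg(scale, c("proportion", "log_odds_ratio",
                              "log_hazard_ratio", "risk"))
  if (is.finite(ci_low) && is.finite(ci_high) && is.finite(point)) {
    if (ci_low > point + 1e-10 || ci_high < point - 1e-10)
      stop_estimation(sprintf(
        "estimand '%s': CI (%g, %g) does not bracket point %g",
        estimand_id, ci_low, ci_high, point))
  }
  structure(list(estimand_id = estimand_id, point = point,
                 ci_low = ci_low, ci_high = ci_high, scale = scale,
                 curve = curve, diagnostics = diagnostics),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %.4f (95%% CI %.4f, %.4f)\n",
              x$estimand_id, x$scale, x$point, x$ci_low, x$ci_high))
  invisible(x)
}

#' Proportion with Wilson score interval
#'
#' Point estimate successes/n for a boolean outcome, 95% CI by the Wilson
#' score method (well-behaved at 0 and 1, unlike the Wald interval).
#'
#' @param x A `cohort`.
#' @param spec An `estimand_spec` with `family = "proportion"`.
#' @return An `estimate_result` on the proportion scale.
#' @export
estimate_proportion <- function(x, spec) {
  validate_estimand(spec, get_schema(x))
  x <- apply_group_filter(x, spec)
  y <- x[[spec$outcome]]
  y <- y[!is.na(y)]
  n <- length(y)
  if (n == 0L) stop_estimation(sprintf("estimand '%s': no records", spec$id))
  s <- sum(y)
  ci <- wilson_ci(s, n)
  estimate_result(spec$id, s / n, ci[1L], ci[2L], "proportion",
                  diagnostics = list(n = n, successes = s))
}

# Wilson score interval at z = qnorm(0.975)
wilson_ci <- function(s, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- s / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Odds ratio for a 2x2 exposure-outcome table
#'
#' Unmatched data: sample odds ratio with the Woolf logit-scale CI and the
#' Fisher exact p-value in diagnostics. When the cohort carries a
#' `matched_set` stratum column (as produced by [propensity_match()]), the
#' Mantel-Haenszel common odds ratio is computed across matched sets with
#' the Robins-Breslow-Greenland confidence interval instead. A zero margin
#' triggers the Haldane-Anscombe 0.5 continuity correction (flagged in
#' diagnostics).
#'
#' @param x A `cohort` (optionally matched).
#' @param spec An `estimand_spec` with `family = "odds_ratio"`.
#' @return An `estimate_result` on the log-odds-ratio scale (point and CI
#'   are log OR; `diagnostics$or` carries the ratio scale).
#' @export
estimate_odds_ratio <- function(x, spec) {
  validate_estimand(spec, get_schema(x))
  x <- apply_group_filter(x, spec)
  df <- as.data.frame(x)
  keep <- !is.na(df[[spec$outcome]]) & !is.na(df[[spec$exposure]])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop_estimation(sprintf("estimand '%s': no records", spec$id))
  y <- df[[spec$outcome]]
  e <- df[[spec$exposure]]
  matched <- "matched_set" %in% names(df) && !all(is.na(df$matched_set))

  if (matched) {
    strata <- factor(df$matched_set)
    tab <- table(exposure = factor(e, levels = c(TRUE, FALSE)),
                 outcome = factor(y, levels = c(TRUE, FALSE)),
                 strata)
    mh <- stats::mantelhaen.test(tab, exact = FALSE, correct = FALSE)
    lor <- log(unname(mh$estimate))
    ci <- log(mh$conf.int)
    return(estimate_result(spec$id, lor, ci[1L], ci[2L], "log_odds_ratio",
      diagnostics = list(or = exp(lor), n = nrow(df),
                         matched_sets = nlevels(strata),
                         method = "mantel_haenszel_rbg",
                         p_value = unname(mh$p.value))))
  }

  a <- sum(e & y); b <- sum(e & !y); c <- sum(!e & y); d <- sum(!e & !y)
  corrected <- FALSE
  if (min(a, b, c, d) == 0L) { # Haldane-Anscombe
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(0.975)
  fisher_p <- stats::fisher.test(matrix(c(sum(e & y), sum(!e & y),
                                          sum(e & !y), sum(!e & !y)), 2L))$p.value
  estimate_result(spec$id, lor, lor - z * se, lor + z * se, "log_odds_ratio",
    diagnostics = list(or = exp(lor), n = nrow(df),
                       table = c(a = a, b = b, c = c, d = d),
                       haldane_corrected = corrected,
                       method = "woolf", fisher_p = fisher_p))
}

#' Propensity-score nearest-neighbour matching
#'
#' Fits a logistic propensity model of the boolean exposure on the spec's
#' covariates, then greedily matches each exposed record to its `ratio`
#' nearest controls on the logit propensity scale, without replacement,
#' processing exposed records in a random order determined by `seed`.
#' Matched records are returned as a cohort carrying a `matched_set`
#' stratum variable; unmatched records are dropped. If controls run short,
#' as many as possible are matched and the shortfall is recorded.
#'
#' @param x A `cohort`.
#' @param spec An `estimand_spec` with an `exposure` and `covariates`;
#'   `spec$matching$ratio` controls the 1:ratio (default 1).
#' @param seed Integer seed for the processing order.
#' @param caliper Optional maximum logit-scale distance; `NULL` (default)
#'   imposes none.
#' @return A `cohort` with an added `matched_set` categorical variable;
#'   attribute `match_diagnostics` carries counts and flags.
#' @export
propensity_match <- function(x, spec, seed, caliper = NULL) {
  schema <- get_schema(x)
  validate_estimand(spec, schema)
  if (is.null(spec$exposure)) stop_parameter("matching requires an exposure variable")
  ratio <- if (!is.null(spec$matching)) spec$matching$ratio else 1L
  df <- as.data.frame(x)
  use <- stats::complete.cases(df[, c(spec$exposure, spec$covariates), drop = FALSE])
  df <- df[use, , drop = FALSE]
  e <- df[[spec$exposure]]
  if (sum(e) == 0L || sum(!e) == 0L)
    stop_estimation(sprintf("estimand '%s': need both exposed and controls", spec$id))

  fml <- stats::reformulate(spec$covariates, response = spec$exposure)
  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::binomial()))
  ps <- stats::predict(fit, type = "link")  # logit scale
  separation <- any(abs(ps) > 15) || !fit$converged

  exposed_idx <- which(e)
  control_idx <- which(!e)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  order_exposed <- sample(exposed_idx)

  available <- rep(TRUE, nrow(df))
  available[exposed_idx] <- FALSE
  set_id <- rep(NA_character_, nrow(df))
  shortfall <- 0L
  set_no <- 0L
  for (i in order_exposed) {
    cand <- control_idx[available[control_idx]]
    if (length(cand) == 0L) { shortfall <- shortfall + ratio; next }
    d <- abs(ps[cand] - ps[i])
    if (!is.null(caliper)) {
      cand <- cand[d <= caliper]; d <- d[d <= caliper]
      if (length(cand) == 0L) { shortfall <- shortfall + ratio; next }
    }
    take <- cand[order(d)][seq_len(min(ratio, length(cand)))]
    shortfall <- shortfall + (ratio - length(take))
    set_no <- set_no + 1L
    lab <- sprintf("set_%05d", set_no)
    set_id[i] <- lab
    set_id[take] <- lab
    available[take] <- FALSE
  }

  keep <- !is.na(set_id)
  out_df <- df[keep, , drop = FALSE]
  out_df$matched_set <- set_id[keep]
  new_schema <- cohort_schema(c(unname(schema), list(
    variable_spec("matched_set", "categorical", role = "stratum",
                  categories = sort(unique(set_id[keep]))))))
  out <- cohort(out_df, new_schema)
  attr(out, "match_diagnostics") <- list(
    n_exposed = length(exposed_idx), n_controls = length(control_idx),
    matched_sets = set_no, ratio = ratio, shortfall = shortfall,
    separation = separation)
  out
}

#' Kaplan-Meier survival at a horizon
#'
#' Product-limit estimate with Greenwood variance and a log-log transformed
#' 95% confidence band; the point estimate is survival at `spec$horizon`
#' (the last observed time if no horizon is declared).
#'
#' @param x A `cohort`.
#' @param spec An `estimand_spec` with `family = "km_survival"`.
#' @return An `estimate_result` on the proportion scale, with `curve`.
#' @export
estimate_km <- function(x, spec) {
  validate_estimand(spec, get_schema(x))
  x <- apply_group_filter(x, spec)
  df <- as.data.frame(x)
  keep <- !is.na(df[[spec$time]]) & !is.na(df[[spec$event]])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop_estimation(sprintf("estimand '%s': no records", spec$id))
  sv <- survival::Surv(df[[spec$time]], as.numeric(df[[spec$event]]))
  fit <- survival::survfit(sv ~ 1, conf.type = "log-log")
  curve <- data.frame(time = fit$time, survival = fit$surv,
                      band_low = ifelse(is.na(fit$lower), 0, fit$lower),
                      band_high = ifelse(is.na(fit$upper), 1, fit$upper))
  horizon <- if (!is.null(spec$horizon)) spec$horizon else max(df[[spec$time]])
  at <- step_lookup(curve, horizon)
  estimate_result(spec$id, at$survival, at$band_low, at$band_high, "proportion",
    curve = curve,
    diagnostics = list(n = nrow(df), events = sum(df[[spec$event]]),
                       horizon = horizon))
}

# right-continuous step-function lookup on a KM curve (S = 1 before first event)
step_lookup <- function(curve, t) {
  i <- findInterval(t, curve$time)
  if (i == 0L) return(list(survival = 1, band_low = 1, band_high = 1))
  list(survival = curve$survival[i], band_low = curve$band_low[i],
       band_high = curve$band_high[i])
}

#' Cox proportional-hazards fit
#'
#' Multivariate Cox regression with Efron handling of ties; one
#' `estimate_result` per coefficient, each a hazard ratio with a Wald 95%
#' CI reported on the log-hazard-ratio scale. Categorical covariates enter
#' as reference-level dummies (the first schema category is the reference).
#'
#' @param x A `cohort`.
#' @param spec An `estimand_spec` with `family = "cox_hr"`; model terms are
#'   `spec$covariates` (plus `spec$exposure` if given and not already
#'   listed).
#' @return A named list of `estimate_result`s, one per coefficient;
#'   attribute `headline` names the term matching `spec$term`.
#' @export
fit_cox <- function(x, spec) {
  validate_estimand(spec, get_schema(x))
  x <- apply_group_filter(x, spec)
  df <- as.data.frame(x)
  terms <- unique(c(if (!is.null(spec$exposure)) spec$exposure, spec$covariates))
  if (length(terms) == 0L) stop_parameter(sprintf("estimand '%s': no model terms", spec$id))
  keep <- stats::complete.cases(df[, c(spec$time, spec$event, terms), drop = FALSE])
  df <- df[keep, , drop = FALSE]
  if (sum(df[[spec$event]]) < 1L)
    stop_estimation(sprintf("estimand '%s': no events", spec$id))
  fml <- stats::as.formula(paste0(
    "survival::Surv(", spec$time, ", ", spec$event, ") ~ ",
    paste(terms, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    error = function(e) stop_estimation(sprintf(
      "estimand '%s': Cox fit failed: %s", spec$id, conditionMessage(e))),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        stop_estimation(sprintf(
          "estimand '%s': Cox fit unstable (%s); check covariates [%s]",
          spec$id, conditionMessage(w), paste(terms, collapse = ", ")))
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  sm <- summary(fit)
  z <- stats::qnorm(0.975)
  co <- sm$coefficients
  res <- lapply(rownames(co), function(nm) {
    beta <- co[nm, "coef"]; se <- co[nm, "se(coef)"]
    if (!is.finite(beta) || !is.finite(se) || se > 100)
      stop_estimation(sprintf(
        "estimand '%s': non-identified coefficient '%s'", spec$id, nm))
    estimate_result(paste0(spec$id, ":", nm), beta, beta - z * se, beta + z * se,
                    "log_hazard_ratio",
                    diagnostics = list(hr = exp(beta), n = nrow(df),
                                       events = sum(df[[spec$event]]),
                                       concordance = unname(sm$concordance[1L])))
  })
  names(res) <- rownames(co)
  headline <- if (!is.null(spec$term)) {
    hit <- grep(paste0("^", spec$term), rownames(co), value = TRUE)
    if (length(hit)) hit[1L] else rownames(co)[1L]
  } else rownames(co)[1L]
  attr(res, "headline") <- headline
  res
}

#' Stepwise-AIC logistic model and risk prediction
#'
#' Starts from the main-effects logistic model of the boolean outcome on
#' the spec's covariates and performs bidirectional stepwise selection
#' minimizing AIC over a scope spanning all main effects and all pairwise
#' interactions. Marginality (interaction hierarchy) is enforced by the
#' formula-based scope: an interaction can only enter while both its main
#' effects are present, and a main effect cannot leave while one of its
#' interactions remains. The returned estimate is the predicted outcome
#' risk at `spec$risk_profile` with a delta-method 95% CI on the risk scale.
#'
#' @param x A `cohort`.
#' @param spec An `estimand_spec` with `family = "logistic_risk"`,
#'   covariates, and a `risk_profile`.
#' @return A list with `model` (a compact model description: selected
#'   formula, coefficients, AIC trace) and `estimate` (an
#'   `estimate_result` on the risk scale).
#' @export
fit_logistic_stepwise <- function(x, spec) {
  validate_estimand(spec, get_schema(x))
  if (is.null(spec$risk_profile) || length(spec$risk_profile) == 0L)
    stop_parameter(sprintf("estimand '%s': risk_profile is required", spec$id))
  x <- apply_group_filter(x, spec)
  df <- as.data.frame(x)
  terms <- unique(c(spec$covariates, if (!is.null(spec$exposure)) spec$exposure))
  keep <- stats::complete.cases(df[, c(spec$outcome, terms), drop = FALSE])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop_estimation(sprintf("estimand '%s': no records", spec$id))

  base_fml <- stats::reformulate(terms, response = spec$outcome)
  upper_fml <- stats::as.formula(paste0(
    spec$outcome, " ~ (", paste(terms, collapse = " + "), ")^2"))
  fit0 <- suppressWarnings(stats::glm(base_fml, data = df, family = stats::binomial()))
  if (any(abs(stats::coef(fit0)[-1L]) > 15, na.rm = TRUE))
    stop_estimation(sprintf("estimand '%s': separation in logistic model", spec$id))
  fit <- suppressWarnings(stats::step(
    fit0, scope = list(lower = ~1, upper = upper_fml),
    direction = "both", trace = 0))

  profile <- as.data.frame(spec$risk_profile, stringsAsFactors = FALSE)
  for (v in names(profile)) {
    sp <- get_schema(x)[[v]]
    if (!is.null(sp) && sp$kind == "categorical")
      profile[[v]] <- factor(profile[[v]], levels = sp$categories)
    if (!is.null(sp) && sp$kind == "boolean" && is.character(profile[[v]]))
      profile[[v]] <- tolower(profile[[v]]) == "true"
  }
  pr <- stats::predict(fit, newdata = profile, type = "response", se.fit = TRUE)
  z <- stats::qnorm(0.975)
  est <- estimate_result(
    spec$id, unname(pr$fit),
    max(0, unname(pr$fit - z * pr$se.fit)),
    min(1, unname(pr$fit + z * pr$se.fit)), "risk",
    diagnostics = list(n = nrow(df), events = sum(df[[spec$outcome]]),
                       aic = stats::AIC(fit)))
  list(model = list(formula = stats::formula(fit),
                    coefficients = stats::coef(fit),
                    aic = stats::AIC(fit),
                    anova = fit$anova),
       estimate = est)
}

#' Run the estimator an estimand declares
#'
#' Dispatches to the family-specific estimator, applying propensity
#' matching first when the spec asks for it. For `cox_hr` the headline
#' coefficient's result is returned (the full coefficient list rides along
#' in `diagnostics$all_terms`).
#'
#' @param x A `cohort`.
#' @param spec An `estimand_spec`.
#' @param seed Seed used only by matching (the only stochastic estimator).
#' @return An `estimate_result`.
#' @export
run_estimator <- function(x, spec, seed = 1L) {
  switch(spec$family,
    proportion = estimate_proportion(x, spec),
    odds_ratio = {
      if (!is.null(spec$matching)) x <- propensity_match(x, spec, seed)
      estimate_odds_ratio(x, spec)
    },
    km_survival = estimate_km(x, spec),
    cox_hr = {
      all <- fit_cox(x, spec)
      head <- all[[attr(all, "headline")]]
      head$diagnostics$all_terms <- lapply(all, function(r)
        c(point = r$point, ci_low = r$ci_low, ci_high = r$ci_high))
      head
    },
    logistic_risk = fit_logistic_stepwise(x, spec)$estimate
  )
}
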