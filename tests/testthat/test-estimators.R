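test_that("proportion estimates use the Wilson score interval", {
  sp <- estimand_spec("p", "proportion", outcome = "y")

  r0 <- estimate_proportion(make_outcome_cohort(0, 20), sp)
  expect_equal(r0$point, 0)
  expect_equal(r0$ci_low, 0)

  r1 <- estimate_proportion(make_outcome_cohort(20, 20), sp)
  expect_equal(r1$point, 1)
  expect_equal(r1$ci_high, 1)

  # independent oracle: prop.test without continuity correction is Wilson
  r <- estimate_proportion(make_outcome_cohort(50, 100), sp)
  oracle <- stats::prop.test(50, 100, correct = FALSE)$conf.int
  expect_equal(r$point, 0.5)
  expect_equal(c(r$ci_low, r$ci_high), as.numeric(oracle), tolerance = 1e-10)
  expect_equal(round(c(r$ci_low, r$ci_high), 3), c(0.404, 0.596))
})

or_cohort <- function(a, b, c, d, strata = NULL) {
  df <- data.frame(
    exposed = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
    case = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)))
  specs <- list(variable_spec("exposed", "boolean"),
                variable_spec("case", "boolean", role = "outcome"))
  if (!is.null(strata)) {
    df$matched_set <- strata
    specs <- c(specs, list(variable_spec("matched_set", "categorical",
                                         role = "stratum",
                                         categories = unique(strata))))
  }
  cohort(df, cohort_schema(specs))
}

test_that("odds ratios: symmetry, closed form, and MH on duplicated strata", {
  sp <- estimand_spec("or", "odds_ratio", outcome = "case", exposure = "exposed")

  expect_equal(estimate_odds_ratio(or_cohort(10, 10, 10, 10), sp)$point, 0)
  r4 <- estimate_odds_ratio(or_cohort(20, 10, 10, 20), sp)
  expect_equal(r4$point, log(4))
  expect_equal(r4$diagnostics$or, 4)
  # Woolf CI closed form
  se <- sqrt(1/20 + 1/10 + 1/10 + 1/20)
  expect_equal(r4$ci_high - r4$point, stats::qnorm(0.975) * se)
  expect_lt(r4$diagnostics$fisher_p, 0.05)

  # MH common OR across two identical strata equals the single-stratum OR,
  # verified against the defining formula
  one <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  expect_equal(mh_oracle(list(one, one)), 4)
  xm <- or_cohort(40, 20, 20, 40,
                  strata = rep(rep(c("s1", "s2"), 60), length.out = 120))
  rm <- estimate_odds_ratio(xm, sp)
  expect_equal(rm$diagnostics$method, "mantel_haenszel_rbg")
  expect_equal(exp(rm$point), 4, tolerance = 1e-10)
})

test_that("a zero margin triggers the Haldane-Anscombe correction", {
  sp <- estimand_spec("or", "odds_ratio", outcome = "case", exposure = "exposed")
  r <- estimate_odds_ratio(or_cohort(10, 0, 5, 10), sp)
  expect_true(r$diagnostics$haldane_corrected)
  expect_true(is.finite(r$point) && is.finite(r$ci_high))
  expect_equal(r$diagnostics$or, (10.5 * 10.5) / (0.5 * 5.5))
})

matchable_cohort <- function(n_exposed, n_control, seed = 1) {
  set.seed(seed)
  n <- n_exposed + n_control
  cohort(data.frame(
    exposed = rep(c(TRUE, FALSE), c(n_exposed, n_control)),
    age = rnorm(n, 60, 8),
    lab = rnorm(n, 1, 0.2),
    case = sample(c(TRUE, FALSE), n, replace = TRUE)),
    cohort_schema(
      variable_spec("exposed", "boolean"),
      variable_spec("age", "continuous"),
      variable_spec("lab", "continuous"),
      variable_spec("case", "boolean", role = "outcome")))
}

test_that("propensity matching forms the requested matched sets", {
  sp <- estimand_spec("or", "odds_ratio", outcome = "case",
                      exposure = "exposed", covariates = c("age", "lab"),
                      matching = list(ratio = 4L))
  x <- matchable_cohort(5, 20, seed = 2)
  m <- propensity_match(x, sp, seed = 3)
  d <- attr(m, "match_diagnostics")
  expect_equal(d$matched_sets, 5L)
  expect_equal(nrow(m), 25L)  # 5 sets of 1 exposed + 4 controls
  expect_true(all(table(m$matched_set) == 5L))
  expect_equal(d$shortfall, 0L)

  # ratio 1 with ample controls: every exposed is matched
  sp1 <- estimand_spec("or", "odds_ratio", outcome = "case",
                       exposure = "exposed", covariates = c("age", "lab"),
                       matching = list(ratio = 1L))
  m1 <- propensity_match(matchable_cohort(10, 30, seed = 4), sp1, seed = 5)
  expect_equal(attr(m1, "match_diagnostics")$matched_sets, 10L)
})

test_that("control shortfall is recorded, and separation is flagged", {
  sp <- estimand_spec("or", "odds_ratio", outcome = "case",
                      exposure = "exposed", covariates = c("age", "lab"),
                      matching = list(ratio = 4L))
  x <- matchable_cohort(6, 10, seed = 6)  # needs 24 controls, has 10
  m <- propensity_match(x, sp, seed = 7)
  d <- attr(m, "match_diagnostics")
  expect_equal(d$shortfall, 24L - 10L)

  # a covariate separating the groups perfectly
  df <- as.data.frame(matchable_cohort(10, 10, seed = 8))
  df$age <- ifelse(df$exposed, 100, 20)
  xs <- cohort(df, get_schema(x))
  ms <- propensity_match(xs, sp, seed = 9)
  expect_true(attr(ms, "match_diagnostics")$separation)
})

test_that("Kaplan-Meier matches hand computation and the product-limit oracle", {
  sp <- estimand_spec("s", "km_survival", time = "t", event = "e")

  # no events: S(t) = 1 everywhere
  r <- estimate_km(toy_survival_cohort(c(5, 8, 10), c(FALSE, FALSE, FALSE)), sp)
  expect_equal(r$point, 1)

  # n=4, one event at t=2: S(2) = 3/4
  r2 <- estimate_km(toy_survival_cohort(c(2, 3, 4, 5),
                                        c(TRUE, FALSE, FALSE, FALSE)),
                    estimand_spec("s", "km_survival", time = "t", event = "e",
                                  horizon = 2))
  expect_equal(r2$point, 0.75)

  # n=10 with interleaved censoring against the brute-force oracle
  tt <- c(1, 2, 2.5, 3, 4, 4.5, 5, 6, 7, 8)
  ee <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  r3 <- estimate_km(toy_survival_cohort(tt, ee), sp)
  oracle <- km_oracle(tt, ee)
  got <- r3$curve[r3$curve$time %in% oracle$time, ]
  expect_equal(got$survival, oracle$survival, tolerance = 1e-12)
  # Greenwood log-log band brackets the curve
  expect_true(all(got$band_low <= got$survival + 1e-12))
  expect_true(all(got$band_high >= got$survival - 1e-12))
})

test_that("Cox single-covariate fit agrees with a partial-likelihood grid search", {
  set.seed(31)
  n <- 30
  xvec <- rep(c(TRUE, FALSE), each = n / 2)
  tt <- round(rexp(n, rate = ifelse(xvec, 0.4, 0.2)), 6)  # no ties w.p. 1
  ee <- tt < 6
  tt <- pmin(tt, 6)
  sp <- estimand_spec("hr", "cox_hr", time = "t", event = "e",
                      covariates = "x", term = "x")
  fit <- fit_cox(toy_survival_cohort(tt, ee, x = xvec), sp)
  beta_grid <- cox_grid_oracle(tt, ee, as.numeric(xvec))
  expect_equal(fit[["xTRUE"]]$point, beta_grid, tolerance = 1e-4)
})

test_that("duplicating every record leaves the Cox point estimate unchanged", {
  x <- simulate_fixture(fixture_preset("bun_adhf", n = 400, seed = 41))
  sp <- estimand_spec("hr", "cox_hr", time = "followup_days", event = "event",
                      covariates = "bun_category", term = "bun_category")
  single <- fit_cox(x, sp)
  doubled <- cohort(rbind(as.data.frame(x), as.data.frame(x)), get_schema(x))
  twice <- fit_cox(doubled, sp)
  # duplication introduces ties, so Efron handling perturbs the maximizer
  # by O(1/n); the point estimates agree to well below the CI width
  for (nm in names(single)) {
    expect_equal(twice[[nm]]$point, single[[nm]]$point, tolerance = 5e-3)
    expect_lt(twice[[nm]]$ci_high - twice[[nm]]$ci_low,
              single[[nm]]$ci_high - single[[nm]]$ci_low)
  }
})

test_that("stepwise logistic keeps a strong interaction and prunes pure noise", {
  # pure noise: selected model should carry at most one spurious term
  set.seed(51)
  n <- 2000
  df <- data.frame(a = rnorm(n), b = rnorm(n),
                   y = sample(c(TRUE, FALSE), n, replace = TRUE))
  x <- cohort(df, cohort_schema(
    variable_spec("a", "continuous"), variable_spec("b", "continuous"),
    variable_spec("y", "boolean", role = "outcome")))
  sp <- estimand_spec("r", "logistic_risk", outcome = "y",
                      covariates = c("a", "b"),
                      risk_profile = list(a = 0, b = 0))
  fit <- fit_logistic_stepwise(x, sp)
  n_terms <- length(attr(stats::terms(fit$model$formula), "term.labels"))
  expect_lte(n_terms, 1L)
  # every stepwise move strictly lowered AIC
  expect_true(all(diff(fit$model$anova$AIC) < 0))

  # strong drug x lab interaction is retained and estimated near the truth
  # dose effect switched off so the generative logit lies inside the
  # fitted scope and the interaction coefficient is the recovery target
  z <- simulate_fixture(fixture_preset("insulin_hypoglycemia", n = 20000,
                                       params = list(b_dose = 0), seed = 52))
  spz <- estimand_spec("risk", "logistic_risk", outcome = "hypoglycemia",
                       covariates = c("detemir", "albumin"),
                       risk_profile = list(detemir = TRUE, albumin = 2))
  fz <- fit_logistic_stepwise(z, spz)
  labels <- attr(stats::terms(fz$model$formula), "term.labels")
  expect_true("detemir:albumin" %in% labels)
  # the drug main effect and the interaction are nearly collinear (albumin
  # has little relative spread), so recovery is judged on the mean over
  # independent cohorts rather than a single draw
  truth <- fixture_defaults("insulin_hypoglycemia")$params$b_interaction
  coefs <- vapply(52:56, function(s) {
    zz <- simulate_fixture(fixture_preset("insulin_hypoglycemia", n = 20000,
                                          params = list(b_dose = 0), seed = s))
    unname(fit_logistic_stepwise(zz, spz)$model$coefficients[["detemirTRUE:albumin"]])
  }, numeric(1))
  expect_lt(abs(mean(coefs) - truth), 0.15)
})

test_that("predicted risks for the two drugs agree at the crossing albumin", {
  # logit difference between drugs is b_drug + b_int * albumin, which
  # vanishes at albumin = -b_drug / b_int
  p <- fixture_defaults("insulin_hypoglycemia")$params
  crossing <- -p$b_drug / p$b_interaction
  z <- simulate_fixture(fixture_preset("insulin_hypoglycemia", n = 20000,
                                       params = list(b_dose = 0), seed = 53))
  risk_at <- function(drug) {
    sp <- estimand_spec("r", "logistic_risk", outcome = "hypoglycemia",
                        covariates = c("detemir", "albumin"),
                        risk_profile = list(detemir = drug, albumin = crossing))
    fit_logistic_stepwise(z, sp)$estimate
  }
  ra <- risk_at(TRUE); rb <- risk_at(FALSE)
  expect_lt(abs(ra$point - rb$point), (ra$ci_high - ra$ci_low))
  expect_true(rb$point <= ra$ci_high && rb$point >= ra$ci_low)
})

test_that("estimators reject empty inputs and missing variables", {
  x <- six_record_cohort()
  expect_error(
    estimate_proportion(x, estimand_spec("p", "proportion", outcome = "nope")),
    class = "synthcohort_schema_error")
  empty <- cohort(data.frame(y = logical(0)),
                  cohort_schema(variable_spec("y", "boolean", role = "outcome")))
  expect_error(
    estimate_proportion(empty, estimand_spec("p", "proportion", outcome = "y")),
    class = "synthcohort_estimation_error")
})
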