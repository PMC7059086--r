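#' Fixture presets: seeded simulators of five study archetypes
#'
#' The validation pipeline was designed against five archetypal
#' observational hospital studies; because protected patient records cannot
#' ship with a package, these seeded simulators generate ground-truth
#' "real" cohorts with the same statistical structure, making the whole
#' pipeline exercisable end-to-end. The presets are shape choices that echo
#' the magnitudes typical of such studies, not reproductions of any
#' hospital's data:
#'
#' * `ppi_prescription` — subgroup proportions with binary outcomes
#'   (gastroprotective co-prescription rates across antithrombotic
#'   subgroups, with heavy subgroup-size imbalance).
#' * `pci_stemi` — proportional-hazards survival over 180 days with a
#'   door-to-balloon > 90 min exposure, boolean severity/comorbidity flags
#'   and thresholded-lab covariates, administrative censoring.
#' * `bun_adhf` — 3-year post-discharge survival by admission blood urea
#'   nitrogen category (<30 / 30-39 / >=40) with hazard ratios near 1.29
#'   and 1.67 versus the lowest category and ~60/44/37% survival.
#' * `imaging_aki` — a 2x2 exposure-outcome contingency (MRI vs CT
#'   contrast, acute kidney injury) with boolean confounders and heavy
#'   group imbalance (hundreds vs ten thousand).
#' * `insulin_hypoglycemia` — a logistic outcome with a drug x albumin
#'   interaction making the drug's hypoglycemia risk higher at low albumin.
#'
#' @param name One of the five preset names.
#' @param n Total cohort size, or a named vector of per-subgroup sizes
#'   where the preset is subgroup-structured; `NULL` uses the preset
#'   default.
#' @param params Named list overriding individual true parameters (see the
#'   preset defaults in `fixture_defaults()`).
#' @param seed Integer seed; `(preset, seed)` fully determines the cohort.
#' @return An object of class `fixture_preset`.
#' @export
fixture_preset <- function(name, n = NULL, params = list(), seed = 1L) {
  names_ok <- c("ppi_prescription", "pci_stemi", "bun_adhf",
                "imaging_aki", "insulin_hypoglycemia")
  name <- match.arg(name, names_ok)
  def <- fixture_defaults(name)
  if (!is.null(n)) def$n <- n
  for (k in names(params)) def$params[[k]] <- params[[k]]
  bad_p <- unlist(Filter(function(v) is.numeric(v) && length(v) > 0,
                         def$params[grepl("^p_|_p$|prob", names(def$params))]))
  if (length(bad_p) && any(bad_p < 0 | bad_p > 1))
    stop_parameter(sprintf("preset '%s': probabilities must lie in [0,1]", name))
  structure(list(name = name, n = def$n, params = def$params,
                 seed = as.integer(seed)), class = "fixture_preset")
}

#' Default parameters for each fixture preset
#' @param name Preset name.
#' @return A list with `n` and `params`.
#' @export
fixture_defaults <- function(name) {
  switch(name,
    ppi_prescription = list(
      # subgroup sizes with the heavy imbalance typical of prescription
      # cohorts; outcome = gastroprotective PPI co-prescribed
      n = c(oac_only = 6936, oac_aspirin = 3953, oac_at2 = 882, oac_dat = 417),
      params = list(
        p_outcome = c(oac_only = 0.45, oac_aspirin = 0.55,
                      oac_at2 = 0.60, oac_dat = 0.70),
        p_steroids = 0.15, p_internal = 0.70, p_age_gt65 = 0.6)),
    pci_stemi = list(
      n = 597,
      params = list(
        p_d2b_gt90 = 0.35, p_age_gt65 = 0.45, p_male = 0.75,
        p_severe_cardiac = 0.12, p_prior_ihd = 0.20,
        p_low_hb = 0.10, p_high_creatinine = 0.25, p_high_bun = 0.20,
        log_hr = c(d2b_gt90 = log(1.1), age_gt65 = log(2.0), male = log(0.9),
                   severe_cardiac = log(2.5), prior_ihd = log(1.4),
                   low_hb = log(1.5), high_creatinine = log(1.3),
                   high_bun = log(1.6)),
        weibull_shape = 1, baseline_scale = 2000, horizon = 180)),
    bun_adhf = list(
      n = 4590,
      params = list(
        p_bun = c(lt30 = 0.55, b30_39 = 0.25, ge40 = 0.20),
        log_hr_bun = c(b30_39 = log(1.29), ge40 = log(1.67)),
        p_many_comorbidities = 0.40, log_hr_comorbid = log(1.5),
        p_high_bnp = 0.50, log_hr_bnp = log(1.3),
        # baseline scale set so marginal 3-year survival in the reference
        # BUN group (averaged over the comorbidity mix) sits near 60%
        weibull_shape = 1, baseline_scale = 2960, horizon = 1095)),
    imaging_aki = list(
      n = c(mri = 718, ct = 12592),
      params = list(
        p_age_gt65 = c(mri = 0.40, ct = 0.55),
        p_diabetes = c(mri = 0.18, ct = 0.28),
        p_high_creatinine = c(mri = 0.12, ct = 0.22),
        # logit of AKI: baseline + exposure + confounders
        b0 = stats::qlogis(0.03), b_mri = log(0.8),
        b_age = log(1.8), b_diabetes = log(1.6), b_creatinine = log(2.2))),
    insulin_hypoglycemia = list(
      n = 4677,
      params = list(
        p_detemir = 0.178,
        albumin_mean = 3.4, albumin_sd = 0.55,
        dose_meanlog = 3.0, dose_sdlog = 0.5,
        # logit(hypoglycemia) = b0 + b_drug*drug + b_alb*albumin
        #                       + b_int*drug*albumin + b_dose*log(dose)
        b0 = 1.0, b_drug = 4.0, b_albumin = -0.8,
        b_interaction = -1.2, b_dose = 0.15)),
    stop_parameter(sprintf("unknown preset '%s'", name)))
}

#' Simulate a fixture cohort
#'
#' Dispatches to the family simulator matching the preset:
#' [simulate_categorical_outcome_cohort()] for `ppi_prescription` and
#' `imaging_aki`, [simulate_survival_cohort()] for `pci_stemi` and
#' `bun_adhf`, [simulate_binary_risk_cohort()] for `insulin_hypoglycemia`.
#'
#' @param preset A `fixture_preset`.
#' @return A `cohort`.
#' @export
simulate_fixture <- function(preset) {
  stopifnot(inherits(preset, "fixture_preset"))
  switch(preset$name,
    ppi_prescription = ,
    imaging_aki = simulate_categorical_outcome_cohort(preset),
    pci_stemi = ,
    bun_adhf = simulate_survival_cohort(preset),
    insulin_hypoglycemia = simulate_binary_risk_cohort(preset))
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Simulate a subgroup-proportions cohort
#'
#' Subgroup labels are fixed at the preset's per-subgroup sizes; the boolean
#' outcome of each record is Bernoulli at its subgroup's true probability.
#' The `imaging_aki` preset instead draws exposure-dependent boolean
#' confounders and an outcome whose logit combines exposure and confounder
#' effects.
#'
#' @param preset A `fixture_preset` named `ppi_prescription` or
#'   `imaging_aki`.
#' @return A `cohort`.
#' @export
simulate_categorical_outcome_cohort <- function(preset) {
  stopifnot(inherits(preset, "fixture_preset"))
  if (!preset$name %in% c("ppi_prescription", "imaging_aki"))
    stop_parameter(sprintf("preset '%s' is not a categorical-outcome fixture", preset$name))
  p <- preset$params
  with_seed(preset$seed, {
    if (preset$name == "ppi_prescription") {
      sizes <- preset$n
      grp <- rep(names(sizes), times = sizes)
      df <- data.frame(
        subgroup = grp,
        internal_dept = stats::runif(length(grp)) < p$p_internal,
        steroids = stats::runif(length(grp)) < p$p_steroids,
        age_gt65 = stats::runif(length(grp)) < p$p_age_gt65,
        ppi_prescribed = stats::runif(length(grp)) < p$p_outcome[grp],
        stringsAsFactors = FALSE)
      schema <- cohort_schema(
        variable_spec("subgroup", "categorical", role = "group",
                      categories = names(sizes)),
        variable_spec("internal_dept", "boolean"),
        variable_spec("steroids", "boolean"),
        variable_spec("age_gt65", "boolean"),
        variable_spec("ppi_prescribed", "boolean", role = "outcome"))
      cohort(df, schema)
    } else {
      sizes <- preset$n
      modality <- rep(c("mri", "ct"), times = c(sizes[["mri"]], sizes[["ct"]]))
      m <- length(modality)
      age <- stats::runif(m) < p$p_age_gt65[modality]
      dia <- stats::runif(m) < p$p_diabetes[modality]
      cre <- stats::runif(m) < p$p_high_creatinine[modality]
      eta <- p$b0 + p$b_mri * (modality == "mri") + p$b_age * age +
        p$b_diabetes * dia + p$b_creatinine * cre
      df <- data.frame(
        mri = modality == "mri",
        age_gt65 = age, diabetes = dia, high_creatinine = cre,
        aki = stats::runif(m) < stats::plogis(eta),
        stringsAsFactors = FALSE)
      schema <- cohort_schema(
        variable_spec("mri", "boolean", role = "group"),
        variable_spec("age_gt65", "boolean"),
        variable_spec("diabetes", "boolean"),
        variable_spec("high_creatinine", "boolean"),
        variable_spec("aki", "boolean", role = "outcome"))
      cohort(df, schema)
    }
  })
}

#' Simulate a proportional-hazards survival cohort
#'
#' Covariates are drawn per the preset; event times are Weibull with a
#' linear predictor given by the preset's log-hazards (shape 1 by default,
#' i.e. exponential); follow-up is administratively censored at the
#' preset's horizon. Emits `event_time` and `event_indicator` columns.
#'
#' @param preset A `fixture_preset` named `pci_stemi` or `bun_adhf`.
#' @return A `cohort`.
#' @export
simulate_survival_cohort <- function(preset) {
  stopifnot(inherits(preset, "fixture_preset"))
  if (!preset$name %in% c("pci_stemi", "bun_adhf"))
    stop_parameter(sprintf("preset '%s' is not a survival fixture", preset$name))
  p <- preset$params
  n <- sum(preset$n)
  with_seed(preset$seed, {
    if (preset$name == "pci_stemi") {
      flags <- c("d2b_gt90", "age_gt65", "male", "severe_cardiac",
                 "prior_ihd", "low_hb", "high_creatinine", "high_bun")
      df <- as.data.frame(lapply(setNames(flags, flags), function(v)
        stats::runif(n) < p[[paste0("p_", v)]]))
      eta <- as.matrix(df) %*% p$log_hr[flags]
      tt <- rweibull_ph(n, p$weibull_shape, p$baseline_scale, drop(eta))
      df$event <- tt <= p$horizon
      df$followup_days <- pmin(tt, p$horizon)
      specs <- c(lapply(flags, function(v) variable_spec(v, "boolean")),
                 list(variable_spec("event", "boolean", role = "event_indicator"),
                      variable_spec("followup_days", "continuous",
                                    role = "event_time", units = "days")))
      cohort(df, cohort_schema(specs))
    } else {
      bun_levels <- names(p$p_bun)
      bun <- sample(bun_levels, n, replace = TRUE, prob = p$p_bun)
      comorbid <- stats::runif(n) < p$p_many_comorbidities
      bnp <- stats::runif(n) < p$p_high_bnp
      eta <- ifelse(bun == "b30_39", p$log_hr_bun[["b30_39"]],
             ifelse(bun == "ge40", p$log_hr_bun[["ge40"]], 0)) +
        p$log_hr_comorbid * comorbid + p$log_hr_bnp * bnp
      tt <- rweibull_ph(n, p$weibull_shape, p$baseline_scale, eta)
      df <- data.frame(
        bun_category = bun,
        many_comorbidities = comorbid,
        high_bnp = bnp,
        event = tt <= p$horizon,
        followup_days = pmin(tt, p$horizon),
        stringsAsFactors = FALSE)
      schema <- cohort_schema(
        variable_spec("bun_category", "categorical", role = "group",
                      categories = bun_levels),
        variable_spec("many_comorbidities", "boolean"),
        variable_spec("high_bnp", "boolean"),
        variable_spec("event", "boolean", role = "event_indicator"),
        variable_spec("followup_days", "continuous", role = "event_time",
                      units = "days"))
      cohort(df, schema)
    }
  })
}

# Weibull event times under a proportional-hazards linear predictor:
# h(t) = shape/scale * (t/scale)^(shape-1) * exp(eta)
rweibull_ph <- function(n, shape, scale, eta) {
  u <- stats::runif(n)
  scale * (-log(u) * exp(-eta))^(1 / shape)
}

#' Simulate a logistic drug-lab interaction cohort
#'
#' Continuous albumin and insulin-dose covariates, a boolean drug indicator,
#' and a Bernoulli outcome whose logit includes a drug x albumin interaction
#' whose sign makes the drug's hypoglycemia risk higher at low albumin
#' (risk curves for the two drugs cross).
#'
#' @param preset A `fixture_preset` named `insulin_hypoglycemia`.
#' @return A `cohort`.
#' @export
simulate_binary_risk_cohort <- function(preset) {
  stopifnot(inherits(preset, "fixture_preset"))
  if (preset$name != "insulin_hypoglycemia")
    stop_parameter(sprintf("preset '%s' is not a binary-risk fixture", preset$name))
  p <- preset$params
  n <- sum(preset$n)
  with_seed(preset$seed, {
    drug <- stats::runif(n) < p$p_detemir
    albumin <- stats::rnorm(n, p$albumin_mean, p$albumin_sd)
    dose <- stats::rlnorm(n, p$dose_meanlog, p$dose_sdlog)
    eta <- p$b0 + p$b_drug * drug + p$b_albumin * albumin +
      p$b_interaction * drug * albumin + p$b_dose * log(dose)
    df <- data.frame(
      detemir = drug, albumin = albumin, insulin_dose = dose,
      hypoglycemia = stats::runif(n) < stats::plogis(eta),
      stringsAsFactors = FALSE)
    schema <- cohort_schema(
      variable_spec("detemir", "boolean", role = "group"),
      variable_spec("albumin", "continuous", units = "g/dL"),
      variable_spec("insulin_dose", "continuous", units = "units/day"),
      variable_spec("hypoglycemia", "boolean", role = "outcome"))
    cohort(df, schema)
  })
}
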