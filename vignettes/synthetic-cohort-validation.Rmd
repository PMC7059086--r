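---
title: "Synthetic clinical cohorts and how to tell whether you can trust them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic clinical cohorts and how to tell whether you can trust them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-level hospital data cannot be shared freely: privacy law and
institutional policy put them behind review-board approval, which delays or
blocks exploratory analysis. One practical escape is to hand the analyst a
*synthetic* cohort — a table of fictitious patients whose joint statistical
structure matches the real extract closely enough that proportions, odds
ratios, survival curves and regression coefficients computed on it predict
what the real analysis will show.

Two questions follow immediately. First, how do you generate such a table
without parametric assumptions about hospital data (which are skewed,
mixed-type, and full of structured missingness)? Second — and this is the
part too often skipped — how do you *quantify* how much an analysis on
synthetic data can be trusted? `synthcohort` implements both halves: a
censoring + copula synthesis engine, and a replicate-based validation
harness that measures bias, stability and confidence-interval containment
of any declared estimand.

## The generator

### Step 1: privacy censoring

Before any statistic is extracted, `censor_unique_cells()` scans the full
cross-classification of all categorical and boolean variables, counting
missing as its own level. Any cell with fewer than `k` records (default
`k = 5`, the usual small-cell suppression convention) could single out a
patient, so its identifying values are blanked. The algorithm is greedy
and deterministic: while an offending cell exists, the variable with the
most schema levels among the cell's non-missing variables is set to missing
for the cell's records, and the cross-classification is rebuilt. Blanking
high-cardinality variables first merges cells fastest, so the least
information is destroyed; ties break by schema order so reports are
reproducible. Continuous values are never touched at this stage — their
privacy protection comes from the fact that the sampler never emits a real
record (and never emits a value outside the observed support, see below).

A record whose categorical values are all missing cannot be censored
further; it remains as part of the all-missing cell whatever that cell's
size, which is the correct fixed point (it carries no categorical
information that could identify anyone).

### Step 2: a stratified, distribution-free model

`fit_synthesis_model()` summarises the (censored) cohort as:

* one **stratum** per observed joint level of the categorical variables
  (missingness patterns included), with its exact count;
* per stratum and continuous variable, the **sorted observed values** —
  an empirical quantile table — plus a missing fraction;
* per stratum, the correlation matrix of **normal scores of within-stratum
  ranks** of the continuous variables. With ranks mapped through
  `qnorm((rank - 0.5)/m)`, this is the Gaussian-copula correlation: it
  captures monotone dependence without assuming any marginal form.

Pairwise-complete estimation can produce an indefinite matrix, so negative
eigenvalues are clipped at `1e-8` and the diagonal is renormalised — the
standard deterministic repair.

### Step 3: sampling replicates

`sample_synthetic()` regenerates each stratum. Under the default
`count_mode = "exact"`, every stratum is drawn at exactly its real count,
which makes **every purely categorical statistic identical to the real
cohort's** on every replicate. That is a deliberate design choice: for
uncensored categorical estimands the synthetic answer should not merely
approximate the real one, it should *be* the real one, uncertainty included.
`count_mode = "multinomial"` instead redraws stratum sizes multinomially at
fixed total, which restores sampling variability in the categorical part;
it is the mode in which censoring-induced instability becomes visible (see
the validation laws below).

Continuous values are drawn by sampling a multivariate normal vector with
the stratum's copula correlation and pushing each coordinate through the
stratum's empirical quantile function — linear interpolation between order
statistics at plotting positions `(i - 0.5)/m`, clamped to the observed
minimum and maximum. Clamping means no synthetic patient can ever carry a
lab value more extreme than any real patient, a privacy-conservative
choice; its cost is mild shrinkage in the far tails. Missingness of each
continuous variable is an independent Bernoulli draw at the stratum's
observed missing fraction (the categorical missingness pattern is already
part of the stratum key, so only within-stratum continuous missingness
needs a model).

Strata smaller than `small_cell_min = 10` get no correlation matrix —
rank correlations on a handful of records are noise — and fall back to
independent draws from the within-stratum marginals with uniform jitter of
half the mean gap between adjacent order statistics, so tiny strata do not
return verbatim copies of real values.

Every draw is a pure function of `(model, seed)`: the same pair reproduces
a replicate bit-for-bit, and `replicate_seed(master, r)` gives each
replicate of a run an independent, individually re-derivable child seed.

### The QC report

`qc_report()` produces the three-part reliability summary that should
accompany any synthetic release: per-variable censoring rates, side-by-side
marginal summaries (real vs synthetic), and a matrix of pairwise
association deltas — Spearman for continuous pairs, rank point-biserial for
boolean–continuous pairs, Cramér's V among categoricals. Pairs of a
multi-level categorical with a continuous variable have no single standard
correlation coefficient and are reported as `NA` rather than inventing one.

## The validation harness

`run_validation()` is the package's core protocol. Given the real cohort
and a list of estimands it: censors, fits the model once, draws `K`
replicates, runs every estimator on the real data and on each replicate,
and reports per estimand:

* **bias** — mean of replicate points minus the real point;
* **stability** — the (min, max) range of replicate-minus-real differences;
* **containment** — the fraction of replicate points inside the real 95%
  confidence interval, plus, for survival estimands, the fraction of
  time-grid points at which the mean replicate curve stays inside the real
  Greenwood band.

Bias and range are computed on each estimand's natural scale — log scale
for odds and hazard ratios — where sampling distributions are closest to
symmetric. A replicate on which an estimator fails (a small synthetic draw
can lose all its events) is recorded and excluded, never fatal: long
unattended runs must complete. `K = 5` is a sensible interactive default;
bias studies want `K` in the hundreds to make the Monte-Carlo error of the
bias estimate small.

Three qualitative laws anchor the harness, and the test suite checks all
of them:

1. **Neutrality.** If the generator is replaced by the identity, every
   estimand must show bias exactly 0, range (0, 0), containment 1. This
   validates the harness itself, independent of the generator.
2. **Categorical exactness.** Under `count_mode = "exact"` with no
   censoring triggered, categorical estimands have zero bias and zero
   range for any `K` — by construction, not approximately.
3. **Censoring widens ranges.** A subgroup pushed below the privacy
   threshold shows a strictly wider replicate range than the same subgroup
   left uncensored. This law is checked under `count_mode = "multinomial"`:
   under exact counts the categorical part is replicate-invariant (law 2),
   so stochastic stratum sizes are the channel through which
   censoring-induced instability manifests.

## Estimators

The harness ships adapters for the five estimator families that cover most
observational hospital research, each delegating the fit to the standard
tool and fixing a conventional 95% interval:

| family | point estimate | interval |
|---|---|---|
| `proportion` | successes / n | Wilson score |
| `odds_ratio` (unmatched) | sample OR (+ Fisher exact p) | Woolf logit |
| `odds_ratio` (matched sets) | Mantel–Haenszel common OR | Robins–Breslow–Greenland |
| `km_survival` | product-limit S(horizon) | Greenwood, log–log |
| `cox_hr` | hazard ratio per coefficient, Efron ties | Wald |
| `logistic_risk` | predicted risk at a covariate profile | delta method |

Zero margins in 2×2 tables get the Haldane–Anscombe 0.5 correction,
flagged in diagnostics. `propensity_match()` implements greedy
nearest-neighbour 1:ratio matching on the logit propensity scale without
replacement, exposed records processed in a seeded random order; no caliper
by default (one can be supplied). Matching is the only seeded estimator —
everything else is deterministic given the data. Stepwise logistic
selection starts from the main-effects model and moves bidirectionally
through the scope of all main effects and pairwise interactions, minimising
AIC; the formula-based scope enforces marginality, so an interaction can
never outlive its main effects. All estimators use complete-case records
and record the analysed n in diagnostics; imputation is left to the
analyst, exactly as it would be on real data.

## The fixture simulators

Real hospital extracts cannot ship with a package, so `fixture_preset()`
provides seeded generators for five study archetypes: subgroup proportions
with heavy size imbalance (`ppi_prescription`), 180-day
proportional-hazards survival with boolean severity flags and a
door-to-balloon exposure (`pci_stemi`), 3-year survival by blood-urea-
nitrogen category with hazard ratios near 1.29 and 1.67 and ~60/44/37%
survival in the three categories (`bun_adhf`), a heavily imbalanced
exposure–outcome contingency with confounders (`imaging_aki`, hundreds vs
ten thousand), and a logistic outcome with a drug × albumin interaction
that makes the drug's hypoglycemia risk higher at low albumin
(`insulin_hypoglycemia`). Default sizes and effect magnitudes are chosen to
look like the studies such pipelines serve; they are shape choices, not
reproductions of any hospital's numbers. Survival baselines are Weibull
with shape 1 (exponential) — any proportional-hazards-compatible baseline
suffices for recovery testing, and the exponential keeps the inverse-CDF
sampler trivial.

What the fixtures deliberately do *not* emulate: longitudinal visit
structure, calendar effects, coding-system quirks, informative (rather
than administrative) censoring, and missingness that is anything but
stratum-conditionally random. Tests passing on these fixtures therefore
demonstrate that the machinery is correct under its stated model, not that
real EMR extracts satisfy that model.

## Numerical choices and problem sizes

Parameter-recovery studies run the Cox fixture at n = 5,000 over 200
simulations and the logistic fixture at n = 20,000 over 200 (coverage) and
50 (stepwise retention) simulations; fidelity checks use a 10,000-record
stratum with Spearman 0.8 and paired 3,000-record strata with Spearman
0.7/0.0; containment checks use the full-size fixtures (4,590–13,310
records) at K = 25. These sizes give Monte-Carlo error comfortably below
the property margins being asserted. In the recovery studies the dose
effect of the insulin fixture is switched off so the generative logit
coincides with the fitted scope — with it on, the recovery target would be
the coefficient of a misspecified projection rather than the preset
parameter. The drug main effect and the drug × albumin interaction are
strongly collinear at realistic albumin values (mean 3.4, SD 0.55 g/dL),
so single-draw coefficient comparisons are made against means over
independent cohorts.

Degenerate inputs are handled explicitly: a stratum with a single distinct
continuous value yields that constant; a stratum with all values missing
yields all-missing draws; empirical quantile inversion never extrapolates;
an empty subgroup raises an estimation error that the harness records as a
failed replicate.

## Known limitations

* Only monotone (rank) dependence is preserved within strata; a
  non-monotone relationship between two continuous variables survives only
  insofar as the categorical stratification captures it.
* Exact stratum counts leak the true cross-classification table of the
  censored cohort. That is intentional (it is what makes categorical
  results exact) but means `count_mode = "exact"` should be combined with
  a censoring threshold the data holder actually trusts.
* No formal privacy guarantee (k-anonymity certification, differential
  privacy) is claimed; the censoring rule is a small-cell suppression
  heuristic, and adversarial re-identification testing is out of scope.
* No longitudinal synthesis: repeated measurements must be flattened into
  fixed columns (e.g. admission and discharge values) before synthesis.
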