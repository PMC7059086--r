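# shared builders and independent oracles for the test suite

two_cat_schema <- function() {
  cohort_schema(
    variable_spec("sex", "categorical", categories = c("F", "M")),
    variable_spec("smoker", "boolean"))
}

# tiny fixed cohort over {sex, smoker} with one unique combination:
# (M, TRUE) appears once, all other cells have >= 2 records
six_record_cohort <- function() {
  cohort(data.frame(
    sex = c("F", "F", "F", "M", "M", "M"),
    smoker = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE), two_cat_schema())
}

# random mixed-kind cohort for property tests; shape varies with the seed
random_cohort <- function(seed, n = 60L) {
  set.seed(seed)
  df <- data.frame(
    grp = sample(c("a", "b", "c"), n, replace = TRUE),
    flag = sample(c(TRUE, FALSE), n, replace = TRUE),
    lab = round(stats::rlnorm(n, 3, 0.4), 2),
    stringsAsFactors = FALSE)
  miss <- sample(n, size = max(1L, n %/% 10))
  df$lab[miss] <- NA
  if (seed %% 2 == 0) df$grp[sample(n, 2L)] <- NA
  cohort(df, cohort_schema(
    variable_spec("grp", "categorical", categories = c("a", "b", "c")),
    variable_spec("flag", "boolean"),
    variable_spec("lab", "continuous")))
}

# one-stratum bivariate continuous cohort with a target Spearman correlation,
# generated through a Gaussian copula (Pearson r = 2*sin(pi*rho_s/6))
bivariate_cohort <- function(n, rho_s, seed, meanlog = 0, sdlog = 1) {
  set.seed(seed)
  r <- 2 * sin(pi * rho_s / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  df <- data.frame(x = stats::qlnorm(stats::pnorm(z1), meanlog, sdlog),
                   y = stats::qnorm(stats::pnorm(z2), 10, 2))
  cohort(df, cohort_schema(
    variable_spec("x", "continuous"),
    variable_spec("y", "continuous")))
}

# direct-scan safety oracle: smallest cell count among cross-classification
# cells that retain at least one non-missing categorical value
min_informative_cell <- function(x) {
  schema <- get_schema(x)
  vars <- names(schema)[vapply(schema, function(v)
    v$kind %in% c("categorical", "boolean"), logical(1))]
  df <- as.data.frame(x)
  key <- do.call(paste, c(lapply(vars, function(v) {
    col <- as.character(df[[v]])
    col[is.na(col)] <- "<NA>"
    col
  }), sep = "|"))
  informative <- rowSums(!is.na(df[, vars, drop = FALSE])) > 0
  tab <- table(key[informative])
  if (length(tab) == 0L) Inf else min(tab)
}

# brute-force product-limit oracle: S(t) over the observed event times
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, survival = out)
}

# brute-force Cox partial log-likelihood for a single covariate, no ties
cox_loglik <- function(beta, time, event, xvec) {
  vapply(beta, function(b) {
    ll <- 0
    for (i in which(event)) {
      risk <- time >= time[i]
      ll <- ll + b * xvec[i] - log(sum(exp(b * xvec[risk])))
    }
    ll
  }, numeric(1))
}

# two-stage grid maximizer of the partial likelihood (resolution 1e-5)
cox_grid_oracle <- function(time, event, xvec) {
  coarse <- seq(-3, 3, by = 1e-2)
  b0 <- coarse[which.max(cox_loglik(coarse, time, event, xvec))]
  fine <- seq(b0 - 2e-2, b0 + 2e-2, by = 1e-5)
  fine[which.max(cox_loglik(fine, time, event, xvec))]
}

# Mantel-Haenszel common OR oracle from the defining formula
mh_oracle <- function(tables) {
  num <- sum(vapply(tables, function(t) t[1, 1] * t[2, 2] / sum(t), numeric(1)))
  den <- sum(vapply(tables, function(t) t[1, 2] * t[2, 1] / sum(t), numeric(1)))
  num / den
}

# survival cohort small enough for hand-checking KM/Cox
toy_survival_cohort <- function(time, event, x = NULL) {
  df <- data.frame(t = time, e = event)
  specs <- list(
    variable_spec("t", "continuous", role = "event_time"),
    variable_spec("e", "boolean", role = "event_indicator"))
  if (!is.null(x)) {
    df$x <- x
    specs <- c(specs, list(variable_spec("x", "boolean")))
  }
  cohort(df, cohort_schema(specs))
}

# single-boolean cohort with a fixed success count
make_outcome_cohort <- function(successes, n) {
  cohort(data.frame(y = rep(c(TRUE, FALSE), c(successes, n - successes))),
         cohort_schema(variable_spec("y", "boolean", role = "outcome")))
}
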