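test_that("an all-categorical model stores the observed joint cells exactly", {
  x <- six_record_cohort()
  m <- fit_synthesis_model(x, small_cell_min = 2L)
  expect_equal(sum(vapply(m$strata, `[[`, integer(1), "count")), 6L)
  expect_equal(length(m$strata), 4L)  # (F,T),(F,F),(M,F),(M,T)
  expect_true(all(vapply(m$strata, function(s) length(s$marginals) == 0L,
                         logical(1))))
})

test_that("a single continuous variable in one stratum keeps its sorted values", {
  vals <- c(3.2, 1.1, 7.8, 5.5, 2.0)
  x <- cohort(data.frame(lab = vals),
              cohort_schema(variable_spec("lab", "continuous")))
  m <- fit_synthesis_model(x, small_cell_min = 2L)
  expect_length(m$strata, 1L)
  expect_equal(m$strata[[1]]$marginals$lab$values, sort(vals))
  expect_equal(dim(m$strata[[1]]$rank_correlation), c(1L, 1L))
  expect_equal(m$strata[[1]]$rank_correlation[1, 1], 1)
})

test_that("normal-scores correlation matches the Gaussian-copula relation", {
  # for a Gaussian copula with Spearman rho, the latent Pearson correlation
  # is 2*sin(pi*rho/6); the model estimate must land within +-0.03 of it
  x <- bivariate_cohort(n = 10000, rho_s = 0.8, seed = 401)
  m <- fit_synthesis_model(x)
  est <- m$strata[[1]]$rank_correlation["x", "y"]
  expect_lt(abs(est - 2 * sin(pi * 0.8 / 6)), 0.03)
})

test_that("PSD repair clips negative eigenvalues and keeps unit diagonal", {
  r <- matrix(c(1, 0.9, -0.9,
                0.9, 1, 0.9,
                -0.9, 0.9, 1), 3, 3)  # indefinite
  expect_lt(min(eigen(r, symmetric = TRUE)$values), 0)
  fixed <- synthcohort:::repair_psd(r)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), 0)
  expect_equal(diag(fixed), rep(1, 3))
  expect_true(all(abs(fixed) <= 1 + 1e-12))
})

test_that("exact count mode reproduces every categorical statistic", {
  x <- simulate_fixture(fixture_preset("ppi_prescription",
    n = c(oac_only = 120, oac_aspirin = 80, oac_at2 = 50, oac_dat = 40),
    seed = 77))
  m <- fit_synthesis_model(x, count_mode = "exact")
  syn <- sample_synthetic(m, seed = 5)
  expect_equal(nrow(syn), nrow(x))
  for (v in c("subgroup", "internal_dept", "steroids", "age_gt65",
              "ppi_prescribed"))
    expect_equal(table(syn[[v]], useNA = "always"),
                 table(x[[v]], useNA = "always"))
  # joint cross-classification, not just marginals
  expect_equal(table(syn$subgroup, syn$ppi_prescribed),
               table(x$subgroup, x$ppi_prescribed))
})

test_that("multinomial count mode keeps the total fixed but varies cells", {
  x <- simulate_fixture(fixture_preset("ppi_prescription",
    n = c(oac_only = 200, oac_aspirin = 100, oac_at2 = 60, oac_dat = 40),
    seed = 78))
  m <- fit_synthesis_model(x, count_mode = "multinomial")
  sizes <- vapply(1:10, function(s) nrow(sample_synthetic(m, s)), integer(1))
  expect_true(all(sizes == nrow(x)))
  p1 <- mean(sample_synthetic(m, 1)$ppi_prescribed)
  p2 <- mean(sample_synthetic(m, 2)$ppi_prescribed)
  expect_false(identical(p1, p2))
})

test_that("same seed reproduces bit-identically, different seeds differ", {
  x <- bivariate_cohort(n = 500, rho_s = 0.5, seed = 11)
  m <- fit_synthesis_model(x)
  a <- sample_synthetic(m, 99)
  b <- sample_synthetic(m, 99)
  c <- sample_synthetic(m, 100)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$x, c$x))
})

test_that("synthetic continuous values stay inside the real support", {
  x <- bivariate_cohort(n = 400, rho_s = 0.6, seed = 21)
  m <- fit_synthesis_model(x)
  syn <- sample_synthetic(m, 3)
  expect_gte(min(syn$x), min(x$x))
  expect_lte(max(syn$x), max(x$x))
})

test_that("marginal KS distance shrinks as the stratum grows", {
  ks <- function(a, b) suppressWarnings(stats::ks.test(a, b)$statistic)
  dist_at <- vapply(c(100, 1000, 10000), function(m_size) {
    x <- bivariate_cohort(n = m_size, rho_s = 0.5, seed = 1000 + m_size)
    m <- fit_synthesis_model(x)
    mean(vapply(1:3, function(s)
      ks(sample_synthetic(m, s)$x, x$x), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(dist_at) < 0))
  expect_lt(dist_at[3], 0.03)
})

test_that("missingness is regenerated at the stratum's missing fraction", {
  set.seed(8)
  df <- data.frame(lab = c(rnorm(700), rep(NA, 300)))
  x <- cohort(df, cohort_schema(variable_spec("lab", "continuous")))
  m <- fit_synthesis_model(x)
  fr <- vapply(1:20, function(s) mean(is.na(sample_synthetic(m, s)$lab)),
               numeric(1))
  expect_lt(abs(mean(fr) - 0.3), 0.02)
})

test_that("small strata fall back to jittered independent sampling", {
  set.seed(3)
  df <- data.frame(
    grp = rep(c("big", "tiny"), c(200, 4)),
    x = rnorm(204), y = rnorm(204))
  x <- cohort(df, cohort_schema(
    variable_spec("grp", "categorical", categories = c("big", "tiny")),
    variable_spec("x", "continuous"), variable_spec("y", "continuous")))
  m <- fit_synthesis_model(x, small_cell_min = 10L)
  flags <- vapply(m$strata, `[[`, logical(1), "independent")
  counts <- vapply(m$strata, `[[`, integer(1), "count")
  expect_equal(flags, counts < 10L)
  syn <- sample_synthetic(m, 7)
  tiny_real <- df$x[df$grp == "tiny"]
  tiny_syn <- syn$x[syn$grp == "tiny"]
  expect_length(tiny_syn, 4L)
  # jitter keeps values inside the support and off the verbatim originals
  # (support clamping may reproduce an endpoint, but never the whole set)
  expect_false(all(tiny_syn %in% tiny_real))
  expect_true(all(tiny_syn >= min(tiny_real) & tiny_syn <= max(tiny_real)))
})

test_that("qc_report on self-comparison is all-zero", {
  x <- random_cohort(31)
  q <- qc_report(x, x)
  expect_equal(q$max_abs_correlation_delta, 0)
  # multi-level categorical vs continuous pairs carry no measure (NA)
  expect_true(all(q$correlation_delta == 0, na.rm = TRUE))
})

test_that("qc_report detects a destroyed association", {
  x <- bivariate_cohort(n = 2000, rho_s = 0.7, seed = 51)
  shuffled <- as.data.frame(x)
  set.seed(52)
  shuffled$y <- sample(shuffled$y)
  y <- cohort(shuffled, get_schema(x))
  q <- qc_report(x, y)
  rho_real <- q$correlation_real["x", "y"]
  expect_lt(abs(q$max_abs_correlation_delta - abs(rho_real)), 0.1)
})

test_that("qc_report rejects mismatched schemas", {
  expect_error(qc_report(six_record_cohort(), random_cohort(1)),
               class = "synthcohort_schema_error")
})

test_that("correlations survive synthesis within a categorical subpopulation", {
  # two strata with different dependence; both must be recovered
  n <- 1500
  a <- bivariate_cohort(n, rho_s = 0.7, seed = 61)
  b <- bivariate_cohort(n, rho_s = 0.0, seed = 62)
  df <- rbind(cbind(grp = "a", as.data.frame(a)),
              cbind(grp = "b", as.data.frame(b)))
  x <- cohort(df, cohort_schema(
    variable_spec("grp", "categorical", categories = c("a", "b")),
    variable_spec("x", "continuous"), variable_spec("y", "continuous")))
  m <- fit_synthesis_model(x)
  rho_in <- function(syn, g) stats::cor(syn$x[syn$grp == g], syn$y[syn$grp == g],
                                        method = "spearman")
  est <- rowMeans(vapply(1:5, function(s) {
    syn <- sample_synthetic(m, s)
    c(rho_in(syn, "a"), rho_in(syn, "b"))
  }, numeric(2)))
  expect_lt(abs(est[1] - 0.7), 0.07)
  expect_lt(abs(est[2] - 0.0), 0.07)
})
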