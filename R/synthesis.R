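#' Fit a distribution-free synthesis model to a cohort
#'
#' Builds the stratified statistical summary from which synthetic replicates
#' are drawn. One stratum is created per observed joint level of all
#' categorical and boolean variables, with missing counted as its own level
#' (so the missingness pattern of the categorical part is itself part of the
#' stratum key). Within each stratum, each continuous variable is summarised
#' by its sorted non-missing values (an empirical quantile table) plus a
#' missing fraction, and the dependence between continuous variables is
#' captured as a correlation matrix of normal scores of within-stratum ranks
#' (a Gaussian-copula correlation), estimated pairwise-complete and repaired
#' to the nearest positive semidefinite matrix. No parametric form is assumed
#' for any marginal.
#'
#' Strata smaller than `small_cell_min` are flagged independent: correlation
#' matrices are too unstable there, so their continuous variables are later
#' sampled independently from the within-stratum marginals with a small
#' uniform jitter (half the mean gap between adjacent order statistics) to
#' avoid verbatim value copying.
#'
#' @param x A `cohort` (censoring, if wanted, is applied beforehand with
#'   [censor_unique_cells()]; it is not re-checked here).
#' @param small_cell_min Minimum stratum size for correlation estimation.
#'   Default 10.
#' @param count_mode `"exact"` (default): each replicate regenerates every
#'   stratum at exactly its real count, so all purely categorical statistics
#'   are identical to the real cohort's. `"multinomial"`: stratum sizes are
#'   redrawn multinomially at fixed total n.
#' @return An object of class `synthesis_model`.
#' @export
fit_synthesis_model <- function(x, small_cell_min = 10L,
                                count_mode = c("exact", "multinomial")) {
  stopifnot(inherits(x, "cohort"))
  count_mode <- match.arg(count_mode)
  if (nrow(x) == 0L) stop_parameter("cannot fit a synthesis model to an empty cohort")
  if (!is.numeric(small_cell_min) || small_cell_min < 1)
    stop_parameter("small_cell_min must be a positive integer")
  small_cell_min <- as.integer(small_cell_min)
  schema <- get_schema(x)
  cat_vars <- categorical_like_vars(schema)
  con_vars <- continuous_vars(schema)

  key <- cell_key(x, cat_vars)
  idx_by_cell <- split(seq_len(nrow(x)), key)

  strata <- lapply(seq_along(idx_by_cell), function(ci) {
    cell <- names(idx_by_cell)[ci]
    rows <- idx_by_cell[[ci]]
    m <- length(rows)
    cell_values <- if (length(cat_vars))
      lapply(setNames(cat_vars, cat_vars), function(v) {
        val <- x[[v]][rows[1L]]
        if (is.na(val)) NA else if (is.factor(val)) as.character(val) else val
      })
    else list()

    marginals <- lapply(setNames(con_vars, con_vars), function(v) {
      vals <- x[[v]][rows]
      obs <- sort(vals[!is.na(vals)])
      list(values = obs, missing_fraction = mean(is.na(vals)))
    })

    independent <- m < small_cell_min
    rc <- NULL
    if (!independent && length(con_vars) > 0L) {
      rc <- normal_scores_correlation(as.data.frame(x)[rows, con_vars, drop = FALSE])
      rc <- repair_psd(rc)
    } else if (length(con_vars) > 0L) {
      rc <- diag(length(con_vars))
      dimnames(rc) <- list(con_vars, con_vars)
    }

    list(cell_key = cell, cell_values = cell_values, count = m,
         marginals = marginals, rank_correlation = rc,
         independent = independent)
  })

  structure(list(
    schema = schema,
    strata = strata,
    n_total = nrow(x),
    count_mode = count_mode,
    small_cell_min = small_cell_min
  ), class = "synthesis_model")
}

#' @export
print.synthesis_model <- function(x, ...) {
  cat(sprintf(
    "synthesis model: n = %d, %d strata (%d independent), count_mode = %s\n",
    x$n_total, length(x$strata),
    sum(vapply(x$strata, `[[`, logical(1), "independent")), x$count_mode))
  invisible(x)
}

# normal scores of within-column ranks; pairwise-complete correlation
normal_scores_correlation <- function(df) {
  p <- ncol(df)
  vars <- names(df)
  z <- lapply(df, function(col) {
    out <- rep(NA_real_, length(col))
    ok <- !is.na(col)
    m <- sum(ok)
    if (m > 0L) out[ok] <- stats::qnorm((rank(col[ok], ties.method = "average") - 0.5) / m)
    out
  })
  z <- do.call(cbind, z)
  r <- diag(p)
  dimnames(r) <- list(vars, vars)
  if (p >= 2L) {
    for (i in 1:(p - 1L)) for (j in (i + 1L):p) {
      ok <- !is.na(z[, i]) & !is.na(z[, j])
      rij <- if (sum(ok) >= 3L && stats::sd(z[ok, i]) > 0 && stats::sd(z[ok, j]) > 0)
        stats::cor(z[ok, i], z[ok, j]) else 0
      r[i, j] <- r[j, i] <- rij
    }
  }
  r
}

# clip negative eigenvalues and renormalize to unit diagonal
repair_psd <- function(r, floor = 1e-8) {
  if (is.null(r) || nrow(r) < 2L) return(r)
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= 0) return(r)
  lam <- pmax(e$values, floor)
  out <- e$vectors %*% diag(lam, nrow = length(lam)) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(r)
  out
}

# empirical quantile function: linear interpolation between order statistics
# at plotting positions (i - 0.5)/m, clamped to the observed min/max so no
# synthetic value ever leaves the real support
empirical_quantile <- function(sorted_values, u) {
  m <- length(sorted_values)
  if (m == 0L) return(rep(NA_real_, length(u)))
  if (m == 1L) return(rep(sorted_values, length(u)))
  p <- (seq_len(m) - 0.5) / m
  stats::approx(p, sorted_values, xout = u, rule = 2, ties = "ordered")$y
}

#' Draw one synthetic replicate cohort from a synthesis model
#'
#' Per stratum, categorical values are fixed by the stratum key (under
#' `count_mode = "exact"` each stratum is regenerated at exactly its real
#' count); continuous values are drawn by sampling a multivariate normal
#' vector with the stratum's normal-scores correlation and mapping each
#' coordinate through the stratum's empirical quantile function.
#' Missingness per continuous variable is an independent Bernoulli draw at
#' the stratum's observed missing fraction. Same `(model, seed)` always
#' reproduces the same cohort bit-for-bit; different seeds give different
#' cohorts.
#'
#' @param model A `synthesis_model`.
#' @param seed Integer random seed.
#' @return A `cohort` with the model's schema and `n_total` records.
#' @export
sample_synthetic <- function(model, seed) {
  stopifnot(inherits(model, "synthesis_model"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop_parameter("seed must be a single integer")
  schema <- model$schema
  cat_vars <- categorical_like_vars(schema)
  con_vars <- continuous_vars(schema)
  nms <- schema_names(schema)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  counts <- vapply(model$strata, `[[`, integer(1), "count")
  if (model$count_mode == "multinomial") {
    counts <- as.integer(stats::rmultinom(1, model$n_total, counts / model$n_total))
  }

  pieces <- vector("list", length(model$strata))
  for (s in seq_along(model$strata)) {
    st <- model$strata[[s]]
    m <- counts[s]
    if (m == 0L) next
    rec <- vector("list", length(nms))
    names(rec) <- nms
    for (v in cat_vars) {
      val <- st$cell_values[[v]]
      rec[[v]] <- rep(if (is.null(val)) NA else val, m)
    }
    if (length(con_vars) > 0L) {
      u <- draw_copula_uniforms(st, con_vars, m)
      for (v in con_vars) {
        marg <- st$marginals[[v]]
        vals <- empirical_quantile(marg$values, u[, v])
        if (st$independent) vals <- jitter_within_support(vals, marg$values)
        if (marg$missing_fraction > 0) {
          miss <- stats::runif(m) < marg$missing_fraction
          vals[miss] <- NA_real_
        }
        rec[[v]] <- vals
      }
    }
    pieces[[s]] <- as.data.frame(rec, optional = TRUE, stringsAsFactors = FALSE)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  df <- do.call(rbind, pieces)
  names(df) <- nms
  cohort(df, schema)
}

# correlated uniforms for one stratum (independent strata get iid uniforms)
draw_copula_uniforms <- function(st, con_vars, m) {
  p <- length(con_vars)
  if (st$independent || p == 1L || is.null(st$rank_correlation)) {
    u <- matrix(stats::runif(m * p), nrow = m)
  } else {
    r <- repair_psd(st$rank_correlation)
    e <- eigen(r, symmetric = TRUE)
    a <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = p)
    z <- matrix(stats::rnorm(m * p), nrow = m) %*% t(a)
    u <- stats::pnorm(z)
  }
  colnames(u) <- con_vars
  u
}

# uniform jitter of half the mean gap between adjacent order statistics,
# clamped to the observed support (small independent strata only)
jitter_within_support <- function(vals, sorted_values) {
  m <- length(sorted_values)
  if (m < 2L) return(vals)
  h <- mean(diff(sorted_values)) / 2
  if (!is.finite(h) || h <= 0) return(vals)
  out <- vals + stats::runif(length(vals), -h, h)
  pmin(pmax(out, sorted_values[1L]), sorted_values[m])
}

#' Generate several synthetic replicates
#'
#' Convenience wrapper around [sample_synthetic()] with a deterministic
#' per-replicate seed schedule derived from the master seed (see
#' [replicate_seed()]).
#'
#' @param model A `synthesis_model`.
#' @param n_replicates Number of replicates.
#' @param seed Master seed.
#' @return A list of `cohort`s.
#' @export
sample_replicates <- function(model, n_replicates, seed) {
  lapply(seq_len(n_replicates), function(r)
    sample_synthetic(model, replicate_seed(seed, r)))
}

#' Deterministic per-replicate seed schedule
#'
#' Maps a master seed and replicate index to a child seed via a fixed
#' multiplicative hash modulo 2^31 - 1, so replicate r can be regenerated in
#' isolation and runs are parallelizable.
#'
#' @param seed Master seed.
#' @param r Replicate index (1-based).
#' @return A single integer seed.
#' @export
replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 2654435761) %% 2147483647)
}
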