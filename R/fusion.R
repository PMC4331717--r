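# Combining per-source calibrated p-values: Fisher's statistic under a
# scaled chi-squared dependence correction (moment matching through
# pairwise covariances of the -2 log p terms), and Storey q-values
# controlling the positive false discovery rate.

#' Fisher's combination statistic
#'
#' `X = sum_i -2 log p_i`. Inputs are clipped away from 0 and 1 so the
#' logs are finite.
#'
#' @param pvals numeric vector of p-values.
#' @return the non-negative statistic X.
#' @export
fisher_statistic <- function(pvals) {
  if (length(pvals) == 0) stop("no p-values to combine")
  sum(-2 * log(clip_p(pvals)))
}

#' Bias-corrected (shrunk) correlation estimate
#'
#' Applies the standard small-sample bias correction to an estimated
#' correlation: `rho_tilde = rho_hat * (1 + (1 - rho_hat^2) / (2 (n - 1)))`,
#' clipped back into \[-1, 1\].
#'
#' @param rho_hat estimated correlation in \[-1, 1\].
#' @param n_corr sample size behind the estimate (>= 2).
#' @return the corrected correlation.
#' @export
shrink_correlation <- function(rho_hat, n_corr) {
  if (any(abs(rho_hat) > 1)) stop("|rho_hat| must be <= 1")
  if (n_corr < 2) stop("n_corr must be >= 2")
  r <- rho_hat * (1 + (1 - rho_hat^2) / (2 * (n_corr - 1)))
  pmin(1, pmax(-1, r))
}

#' Covariance of two -2 log p terms under a normal dependence model
#'
#' Polynomial approximation
#' `cov(V_i, V_j) ~= a1 r + a2 r^2 + a3 r^3 + a4 r^4` with
#' `a1 = 3.263119`, `a2 = 0.709866`, `a3 = 0.026589` and
#' `a4 = -0.709866 / n`, where `r` is the corrected correlation of the
#' underlying probit-scale statistics and `n` the sample size behind it.
#' At `r = 1` and large `n` the value approaches 4, the variance of a
#' chi-squared variable with 2 degrees of freedom.
#'
#' @param rho_tilde corrected correlation in \[-1, 1\].
#' @param n_corr sample size behind the correlation estimate.
#' @return approximate covariance of the two V terms.
#' @export
cov_vi_vj <- function(rho_tilde, n_corr) {
  3.263119 * rho_tilde + 0.709866 * rho_tilde^2 +
    0.026589 * rho_tilde^3 - (0.709866 / n_corr) * rho_tilde^4
}

#' Between-source correlation of association scores
#'
#' Estimates the correlation structure of the per-source tests from a table
#' of calibrated p-values for a common background of disease-gene pairs.
#' Each p-value is mapped to its probit score `z = qnorm(1 - p)` (standard
#' normal under the null) and pairwise-complete Pearson correlations are
#' taken. Source pairs with fewer than `min_overlap` complete observations
#' fall back to independence (correlation 0) with a warning.
#'
#' @param score_table numeric matrix: rows are disease-gene pairs, columns
#'   are sources (named); `NA` marks a missing source for a pair.
#' @param min_overlap minimum pairwise-complete count per source pair.
#' @return object of class `source_correlation`: list with `rho` (k x k),
#'   `n_corr` (minimum pairwise-complete count), `sources`.
#' @export
estimate_source_correlation <- function(score_table, min_overlap = 30L) {
  if (is.null(colnames(score_table))) stop("score_table needs source names")
  z <- stats::qnorm(1 - clip_p(score_table))
  z[is.na(score_table)] <- NA
  rho <- suppressWarnings(stats::cor(z, use = "pairwise.complete.obs"))
  counts <- crossprod(!is.na(z))
  low <- counts < min_overlap & upper.tri(counts)
  if (any(low)) {
    warning(sprintf("%d source pair(s) with < %d complete observations; set to 0",
                    sum(low), min_overlap))
    rho[low | t(low)] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  off <- counts[upper.tri(counts)]
  n_corr <- if (length(off)) max(2L, min(off[off >= min_overlap], nrow(z))) else nrow(z)
  structure(list(rho = rho, n_corr = as.integer(n_corr),
                 sources = colnames(score_table)),
            class = "source_correlation")
}

#' Independence correlation structure over a set of sources
#'
#' @param sources character vector of source names.
#' @param n_corr nominal sample size.
#' @return a `source_correlation` with identity correlation matrix.
#' @export
independent_sources <- function(sources, n_corr = 1e9) {
  k <- length(sources)
  rho <- diag(1, k); dimnames(rho) <- list(sources, sources)
  structure(list(rho = rho, n_corr = n_corr, sources = sources),
            class = "source_correlation")
}

#' Scale and degrees of freedom of the corrected Fisher statistic
#'
#' Moment-matches `X = sum V_i` over the available sources to a scaled
#' chi-squared `r * chi^2_v`: `r_hat = (1 / 4k) * sum_ij cov(V_i, V_j)`
#' with diagonal terms `cov(V_i, V_i) = 4`, and `v_hat = 2k / r_hat`.
#' Off-diagonal covariances use the shrunk correlations and the covariance
#' polynomial. A pathological non-positive `r_hat` falls back to
#' independence (`r_hat = 1`) with a warning.
#'
#' @param corr a `source_correlation`.
#' @param available character vector naming the sources observed for the
#'   gene at hand (subset of `corr$sources`).
#' @return list `r_hat`, `v_hat`, `k`.
#' @export
scaled_chi2_params <- function(corr, available = corr$sources) {
  if (length(available) == 0) stop("no available sources")
  if (!all(available %in% corr$sources)) stop("unknown source in `available`")
  k <- length(available)
  rho <- corr$rho[available, available, drop = FALSE]
  cv <- matrix(4, k, k)
  if (k > 1) {
    off <- upper.tri(rho)
    rt <- shrink_correlation(rho[off], corr$n_corr)
    cv[off] <- cov_vi_vj(rt, corr$n_corr)
    cv[lower.tri(cv)] <- t(cv)[lower.tri(cv)]
  }
  r_hat <- sum(cv) / (4 * k)
  if (!is.finite(r_hat) || r_hat <= 0) {
    warning("non-positive scale estimate; falling back to independence")
    r_hat <- 1
  }
  list(r_hat = r_hat, v_hat = 2 * k / r_hat, k = k)
}

#' Combine per-source p-values with the dependence correction
#'
#' Missing sources (`NA`) are dropped and the number of combined tests
#' reduced accordingly. The combined p-value is the upper tail of
#' `chi^2_{v_hat}` at `X / r_hat`. With a single available source the
#' combined p-value equals that source's p-value; with zero between-source
#' correlation the procedure reduces to textbook Fisher (`chi^2_{2k}`).
#'
#' @param pvals named numeric vector, one (possibly `NA`) p-value per source.
#' @param corr a `source_correlation` covering the sources; `NULL` assumes
#'   independence.
#' @return list `k_used`, `X_stat`, `r_hat`, `v_hat`, `combined_p`; `NULL`
#'   when every source is missing.
#' @export
combine_pvalues <- function(pvals, corr = NULL) {
  if (is.null(names(pvals))) stop("pvals must be named by source")
  avail <- names(pvals)[!is.na(pvals)]
  if (length(avail) == 0) return(NULL)
  if (is.null(corr)) corr <- independent_sources(names(pvals))
  p <- clip_p(pvals[avail])
  X <- fisher_statistic(p)
  par <- scaled_chi2_params(corr, avail)
  cp <- stats::pchisq(X / par$r_hat, df = par$v_hat, lower.tail = FALSE)
  list(k_used = par$k, X_stat = X, r_hat = par$r_hat, v_hat = par$v_hat,
       combined_p = max(cp, P_CLIP_LO))
}

#' Storey q-values controlling the positive false discovery rate
#'
#' Estimates the null proportion at a fixed lambda,
#' `pi0 = #\{p > lambda\} / ((1 - lambda) m)` clipped into (0, 1\], and
#' computes the step-up quantities
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`. With `pi0 = 1` this is the
#' Benjamini-Hochberg adjusted p-value.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param lambda tuning point for the null-proportion estimate.
#' @param pi0 optional override of the estimated null proportion.
#' @return q-values in the input order, each in (0, 1\].
#' @export
qvalues <- function(pvals, lambda = 0.5, pi0 = NULL) {
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) {
    pi0 <- sum(pvals > lambda, na.rm = TRUE) / ((1 - lambda) * m)
    pi0 <- min(1, max(pi0, 1 / m))  # keep strictly positive
  }
  o <- order(pvals)
  q <- pi0 * m * pvals[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m); out[o] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Prioritize candidate genes for a query disease
#'
#' Runs the full chain for one query: per-source genotype regression scores
#' with empirical calibration, dependence-corrected combination across the
#' available sources, q-value conversion and ranking. Ranks are competition
#' ranks on (q-value, combined p, gene identifier), so ordering is
#' deterministic under ties.
#'
#' @param query_disease disease identifier present in `phenotype`.
#' @param candidates character vector of candidate gene identifiers.
#' @param phenotype disease `similarity_matrix`.
#' @param sources named list of transformed gene similarity matrices.
#' @param assoc an [association_map()].
#' @param nulls named list of [build_null_sample()] results, one per source
#'   (same names as `sources`); `NULL` skips calibration (raw p used).
#' @param corr optional `source_correlation`; `NULL` assumes independence.
#' @param leave_one_out drop the query's annotations before scoring
#'   (validation protocol).
#' @return data frame with one row per scoreable candidate: `gene`,
#'   `k_used`, `X_stat`, `r_hat`, `v_hat`, `combined_p`, `q_value`, `rank`,
#'   sorted by rank. Candidates absent from every source are dropped and
#'   counted in the `n_unscored` attribute.
#' @export
prioritize <- function(query_disease, candidates, phenotype, sources, assoc,
                       nulls = NULL, corr = NULL, leave_one_out = FALSE) {
  if (is.null(names(sources))) stop("`sources` must be a named list")
  pmat <- matrix(NA_real_, length(candidates), length(sources),
                 dimnames = list(candidates, names(sources)))
  for (s in names(sources)) {
    sc <- score_gene_set(query_disease, candidates, phenotype, sources[[s]],
                         assoc, null_sample = nulls[[s]],
                         leave_one_out = leave_one_out)
    pmat[, s] <- if (is.null(nulls)) sc$raw_p else sc$calibrated_p
  }
  rows <- lapply(candidates, function(g) {
    cmb <- combine_pvalues(stats::setNames(pmat[g, ], colnames(pmat)), corr)
    if (is.null(cmb)) return(NULL)
    data.frame(gene = g, k_used = cmb$k_used, X_stat = cmb$X_stat,
               r_hat = cmb$r_hat, v_hat = cmb$v_hat,
               combined_p = cmb$combined_p, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no candidate is covered by any source")
  res$q_value <- as.numeric(qvalues(res$combined_p))
  o <- order(res$q_value, res$combined_p, res$gene)
  res <- res[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))  # ties resolved deterministically by gene id
  rownames(res) <- NULL
  attr(res, "n_unscored") <- dropped
  res
}
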