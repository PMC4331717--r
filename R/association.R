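# Scoring the strength of association between a query disease and a
# candidate gene for one genomic data source: genotype-similarity sums,
# the one-sided regression slope t-test, and empirical p-value calibration.

#' Create an association map
#'
#' A named list mapping each disease identifier to the character vector of
#' its associated gene identifiers. Duplicates are collapsed and empty gene
#' sets rejected.
#'
#' @param diseases,genes character vectors of equal length (one row per
#'   disease-gene association).
#' @return named list of class `association_map`.
#' @export
association_map <- function(diseases, genes) {
  diseases <- as.character(diseases); genes <- as.character(genes)
  if (length(diseases) != length(genes)) stop("diseases and genes differ in length")
  if (length(diseases) == 0) stop("empty association table")
  if (any(!nzchar(diseases)) || any(!nzchar(genes))) stop("blank identifier")
  amap <- lapply(split(genes, diseases), function(g) sort(unique(g)))
  structure(amap, class = "association_map")
}

#' @export
print.association_map <- function(x, ...) {
  cat(sprintf("association_map: %d diseases, %d associations, %d genes\n",
              length(x), sum(lengths(x)), length(unique(unlist(x)))))
  invisible(x)
}

# Raw p-value clip bounds applied before logs and probit transforms.
P_CLIP_LO <- 1e-300
P_CLIP_HI <- 1 - 1e-16

clip_p <- function(p) pmin(pmax(p, P_CLIP_LO), P_CLIP_HI)

#' Genotype similarity vector for one candidate gene
#'
#' For a candidate gene g and reference diseases i = 1..n, computes
#' `x_i = sum over k in I_i of phi(g, k)`, where `I_i` is disease i's
#' annotated gene set. Annotated genes absent from the source matrix, and
#' `NA` similarity entries, are skipped (and counted in the `n_skipped`
#' attribute).
#'
#' @param query_gene candidate gene identifier; must be present in `phi`.
#' @param reference_diseases ordered character vector of disease identifiers.
#' @param assoc an [association_map()].
#' @param phi transformed gene `similarity_matrix`.
#' @return numeric vector of genotype similarities, one per reference disease.
#' @export
genotype_vector <- function(query_gene, reference_diseases, assoc, phi) {
  if (!(query_gene %in% rownames(phi)))
    stop(sprintf("gene '%s' absent from source '%s'", query_gene, attr(phi, "source")))
  row <- phi[query_gene, ]
  skipped <- 0L
  x <- vapply(reference_diseases, function(d) {
    genes <- assoc[[d]]
    vals <- row[genes[genes %in% names(row)]]
    skipped <<- skipped + (length(genes) - sum(!is.na(vals)))
    sum(vals, na.rm = TRUE)
  }, numeric(1))
  attr(x, "n_skipped") <- skipped
  x
}

#' Genotype similarity between two diseases' gene sets
#'
#' `x_de = sum over g in D, h in E of phi(g, h)`: the total pairwise
#' functional similarity of the two diseases' associated genes.
#'
#' @param D,E character vectors of gene identifiers (non-empty).
#' @param phi transformed gene `similarity_matrix`.
#' @return the double sum; `NA` entries are skipped. Errors if no pair of
#'   members is resolvable in `phi`.
#' @export
pair_genotype_similarity <- function(D, E, phi) {
  D <- D[D %in% rownames(phi)]; E <- E[E %in% rownames(phi)]
  if (length(D) == 0 || length(E) == 0)
    stop("no resolvable gene pair between the two sets")
  block <- phi[D, E, drop = FALSE]
  if (all(is.na(block))) stop("all cross pairs missing in the source matrix")
  sum(block, na.rm = TRUE)
}

#' One-sided slope test of phenotype on genotype similarity
#'
#' Fits `Y = alpha + beta * x + eps` by ordinary least squares and tests
#' `H0: beta = 0` against `H1: beta > 0` with
#' `T = beta_hat / sqrt(S^2 / sum((x - mean(x))^2))`, where
#' `S^2` is the residual sum of squares divided by `n - 2`. Under the null
#' and Gaussian errors `T` follows a Student t distribution with `n - 2`
#' degrees of freedom; the raw p-value is the upper tail `P(T >= t)`.
#'
#' @param x genotype similarity vector (the predictor).
#' @param y phenotype similarity vector (the response), same length as `x`.
#' @return list with `beta_hat`, `alpha_hat`, `t_stat`, `raw_p`, `df`.
#' @export
slope_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (n < 3) stop("slope test needs n >= 3")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("degenerate predictor: x has zero variance")
  beta <- sum((x - xbar) * (y - ybar)) / sxx
  alpha <- ybar - beta * xbar
  rss <- sum((y - alpha - beta * x)^2)
  s2 <- rss / (n - 2)
  t_stat <- if (s2 > 0) beta / sqrt(s2 / sxx) else sign(beta) * Inf
  raw_p <- clip_p(stats::pt(t_stat, df = n - 2, lower.tail = FALSE))
  list(beta_hat = beta, alpha_hat = alpha, t_stat = t_stat,
       raw_p = raw_p, df = n - 2)
}

# Vectorized slope tests: one Y, many candidate x vectors (rows of X).
# Returns a data frame with one row per candidate; degenerate predictors
# yield NA raw_p. Used by the null-sample builder and the LOOCV harness.
slope_test_rows <- function(X, y) {
  n <- length(y)
  xbar <- rowMeans(X)
  sxx <- rowSums(X^2) - n * xbar^2
  sxx[sxx < 0] <- 0
  ybar <- mean(y)
  sxy <- as.vector(X %*% y) - n * xbar * ybar
  syy <- sum((y - ybar)^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- pmax(syy - beta * sxy, 0)
  s2 <- rss / (n - 2)
  t_stat <- ifelse(s2 > 0, beta / sqrt(s2 / sxx), sign(beta) * Inf)
  raw_p <- clip_p(stats::pt(t_stat, df = n - 2, lower.tail = FALSE))
  raw_p[!is.finite(beta) & is.na(beta)] <- NA_real_
  data.frame(beta_hat = beta, t_stat = t_stat, raw_p = raw_p)
}

#' Calibrate a raw p-value against a simulated null sample
#'
#' Ranks a raw p-value within a sample of raw p-values obtained from
#' non-associated disease-gene pairs, with add-one smoothing:
#' `(#\{null <= p\} + 1) / (M + 1)`. The smoothing keeps calibrated
#' p-values strictly positive so that downstream log transforms are finite.
#'
#' @param raw_p raw p-value(s) in \[0, 1\] (vectorized).
#' @param null_raw_ps numeric vector of null raw p-values.
#' @return calibrated p-value(s) in (0, 1\].
#' @export
calibrate_p <- function(raw_p, null_raw_ps) {
  if (length(null_raw_ps) == 0) {
    warning("empty null sample: raw p-value passed through uncalibrated")
    return(raw_p)
  }
  if (any(null_raw_ps < 0 | null_raw_ps > 1, na.rm = TRUE))
    stop("null p-values must lie in [0, 1]")
  srt <- sort(null_raw_ps)
  (findInterval(raw_p, srt) + 1) / (length(srt) + 1)
}

#' Build a null sample of raw p-values from non-associated pairs
#'
#' Samples disease-gene pairs uniformly (without replacement) among pairs
#' *not* in the annotated associations, scores each with the same regression
#' protocol as [score_gene()], and returns their raw p-values. The sample is
#' the reference distribution for [calibrate_p()] and the background used to
#' estimate between-source correlations.
#'
#' @param assoc an [association_map()].
#' @param phenotype disease `similarity_matrix`.
#' @param phi gene `similarity_matrix` for one source.
#' @param m_pairs number of pairs to sample (all eligible pairs are used,
#'   with a warning, when fewer exist); `NULL` enumerates every eligible
#'   pair, which is practical on small instances only.
#' @param seed integer seed for the pair sampling.
#' @return data frame with columns `disease`, `gene`, `raw_p` (class
#'   `null_sample`); pairs whose regression is degenerate carry `NA`.
#' @export
build_null_sample <- function(assoc, phenotype, phi, m_pairs = 10000L,
                              seed = 1L) {
  exhaustive <- is.null(m_pairs)
  if (!exhaustive && m_pairs < 1) stop("m_pairs must be >= 1")
  diseases <- intersect(names(assoc), rownames(phenotype))
  genes <- rownames(phi)
  nd <- length(diseases); ng <- length(genes)
  if (nd < 3) stop("need at least 3 annotated diseases in the phenotype matrix")
  is_assoc <- matrix(FALSE, nd, ng, dimnames = list(diseases, genes))
  for (d in diseases) {
    g <- intersect(assoc[[d]], genes)
    if (length(g)) is_assoc[d, g] <- TRUE
  }
  eligible <- which(!is_assoc)
  if (exhaustive) {
    idx <- eligible
  } else if (length(eligible) < m_pairs) {
    warning(sprintf("only %d eligible non-associated pairs; using all",
                    length(eligible)))
    idx <- eligible
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    idx <- sample(eligible, m_pairs)
  }
  di <- diseases[(idx - 1L) %% nd + 1L]
  gi <- genes[(idx - 1L) %/% nd + 1L]
  out <- data.frame(disease = di, gene = gi, raw_p = NA_real_,
                    stringsAsFactors = FALSE)
  B <- gene_membership(assoc, diseases, genes)
  phi0 <- unclass(phi); phi0[is.na(phi0)] <- 0
  for (d in unique(di)) {
    rows <- which(di == d)
    refs <- reference_diseases(d, assoc, phenotype, phi)
    if (length(refs) < 3) next
    X <- phi0[gi[rows], , drop = FALSE] %*% B[, refs, drop = FALSE]
    y <- as.numeric(phenotype[d, refs])
    out$raw_p[rows] <- slope_test_rows(X, y)$raw_p
  }
  structure(out, class = c("null_sample", "data.frame"))
}

# Membership indicator: genes (rows of phi) x diseases; entry 1 when the
# gene is annotated to the disease.
gene_membership <- function(assoc, diseases, genes) {
  B <- matrix(0, length(genes), length(diseases),
              dimnames = list(genes, diseases))
  for (d in diseases) {
    g <- intersect(assoc[[d]], genes)
    if (length(g)) B[g, d] <- 1
  }
  B
}

# Reference diseases for a query: every disease other than the query that is
# annotated with at least one gene resolvable in the source matrix and is
# present in the phenotype matrix.
reference_diseases <- function(query_disease, assoc, phenotype, phi) {
  cand <- setdiff(intersect(names(assoc), rownames(phenotype)), query_disease)
  keep <- vapply(cand, function(d) any(assoc[[d]] %in% rownames(phi)), logical(1))
  cand[keep]
}

#' Score one candidate gene for one query disease and one source
#'
#' Implements the per-source association score: the candidate is treated as
#' if it were the only gene associated with the query disease; the response
#' is the query's phenotype similarity to every other annotated disease and
#' the predictor is the candidate's summed functional similarity to each of
#' those diseases' gene sets. With `leave_one_out = TRUE` (validation mode)
#' all annotated associations of the query disease are removed first, so the
#' query's genetic basis plays no role in its own score.
#'
#' @param query_disease disease identifier present in `phenotype`.
#' @param gene candidate gene identifier.
#' @param phenotype disease `similarity_matrix`.
#' @param phi gene `similarity_matrix` for one source.
#' @param assoc an [association_map()].
#' @param null_sample optional [build_null_sample()] result used for
#'   calibration; rows involving the query disease are excluded first.
#' @param leave_one_out drop the query's own annotations before scoring.
#' @return list (`source_score`): `gene`, `source`, `beta_hat`, `t_stat`,
#'   `raw_p`, `calibrated_p`, `n_used`; or `NULL` when the gene is absent
#'   from this source.
#' @export
score_gene <- function(query_disease, gene, phenotype, phi, assoc,
                       null_sample = NULL, leave_one_out = FALSE) {
  if (!(query_disease %in% rownames(phenotype)))
    stop(sprintf("query disease '%s' absent from phenotype matrix", query_disease))
  if (!(gene %in% rownames(phi))) return(NULL)  # source missing for this gene
  if (leave_one_out) assoc[[query_disease]] <- NULL
  refs <- reference_diseases(query_disease, assoc, phenotype, phi)
  if (length(refs) < 3) stop("fewer than 3 usable reference diseases")
  x <- genotype_vector(gene, refs, assoc, phi)
  y <- as.numeric(phenotype[query_disease, refs])
  fit <- slope_test(as.numeric(x), y)
  cal <- NA_real_
  if (!is.null(null_sample)) {
    nu <- null_sample$raw_p[null_sample$disease != query_disease]
    nu <- nu[!is.na(nu)]
    cal <- calibrate_p(fit$raw_p, nu)
  }
  structure(list(gene = gene, source = attr(phi, "source"),
                 beta_hat = fit$beta_hat, t_stat = fit$t_stat,
                 raw_p = fit$raw_p, calibrated_p = cal,
                 n_used = length(refs)),
            class = "source_score")
}

# Vectorized counterpart of score_gene for a set of candidate genes; used by
# the LOOCV harness and the CLI. Genes absent from the source get NA rows.
score_gene_set <- function(query_disease, genes, phenotype, phi, assoc,
                           null_sample = NULL, leave_one_out = FALSE) {
  if (leave_one_out) assoc[[query_disease]] <- NULL
  refs <- reference_diseases(query_disease, assoc, phenotype, phi)
  if (length(refs) < 3) stop("fewer than 3 usable reference diseases")
  out <- data.frame(gene = genes, beta_hat = NA_real_, t_stat = NA_real_,
                    raw_p = NA_real_, calibrated_p = NA_real_,
                    n_used = length(refs), stringsAsFactors = FALSE)
  present <- genes %in% rownames(phi)
  if (!any(present)) return(out)
  B <- gene_membership(assoc, refs, rownames(phi))
  phi0 <- unclass(phi); phi0[is.na(phi0)] <- 0
  X <- phi0[genes[present], , drop = FALSE] %*% B
  y <- as.numeric(phenotype[query_disease, refs])
  fit <- slope_test_rows(X, y)
  out$beta_hat[present] <- fit$beta_hat
  out$t_stat[present] <- fit$t_stat
  out$raw_p[present] <- fit$raw_p
  if (!is.null(null_sample)) {
    nu <- null_sample$raw_p[null_sample$disease != query_disease]
    nu <- nu[!is.na(nu)]
    ok <- present & !is.na(out$raw_p)
    out$calibrated_p[ok] <- calibrate_p(out$raw_p[ok], nu)
  }
  out
}

# Seed handling: set the RNG to a known state and restore the caller's state
# afterwards, so seeded helpers do not perturb an enclosing simulation.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
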