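# Validation machinery: leave-one-out cross-validation against
# linkage-interval or random controls, rank ratio / MRR / rank-ROC AUC /
# top-k summaries, the binned phenotype-genotype correlation analysis, and
# the hypergeometric enrichment test.

#' Linkage-interval control genes
#'
#' Emulates prioritization within a linkage interval: the `m` genes on the
#' same chromosome as the test gene whose representative coordinates are
#' closest to it. Ties in distance are broken by the smaller coordinate and
#' then lexicographic identifier, so the set is platform-independent.
#'
#' @param test_gene gene identifier.
#' @param locations data frame with columns `gene`, `chrom`, `pos`.
#' @param m number of controls (all same-chromosome genes are returned, with
#'   a warning, when fewer exist).
#' @return character vector of control gene identifiers.
#' @export
linkage_controls <- function(test_gene, locations, m = 99L) {
  loc <- locations[match(test_gene, locations$gene), ]
  if (is.na(loc$gene)) stop(sprintf("no location for gene '%s'", test_gene))
  same <- locations[locations$chrom == loc$chrom &
                      locations$gene != test_gene, , drop = FALSE]
  if (nrow(same) < m)
    warning(sprintf("only %d genes on chromosome %s; using all",
                    nrow(same), loc$chrom))
  o <- order(abs(same$pos - loc$pos), same$pos, same$gene)
  same$gene[o][seq_len(min(m, nrow(same)))]
}

#' Random control genes from the whole genome
#'
#' @param test_gene gene identifier (never sampled).
#' @param genome character vector of all gene identifiers.
#' @param m number of controls.
#' @param seed optional integer seed (sampling otherwise uses the current
#'   RNG state).
#' @param exclude additional genes to exclude (e.g. genes annotated to the
#'   query disease).
#' @return character vector of `m` control genes.
#' @export
random_controls <- function(test_gene, genome, m = 99L, seed = NULL,
                            exclude = character(0)) {
  pool <- setdiff(genome, c(test_gene, exclude))
  if (length(pool) < m) stop("genome too small for the requested control count")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  sample(pool, m)
}

#' Mean rank ratio of a set of validation runs
#'
#' @param runs data frame with a `rank_ratio` column (as produced by
#'   [loocv()]).
#' @return the arithmetic mean rank ratio (a fraction in (0, 1\]).
#' @export
mean_rank_ratio <- function(runs) {
  if (nrow(runs) == 0) stop("no validation runs")
  mean(runs$rank_ratio)
}

#' Rank ROC curve and AUC
#'
#' Sweeps a threshold over the rank ratio. At threshold `t` the sensitivity
#' is the fraction of test genes with rank ratio `<= t` and the specificity
#' the fraction of control ranks with rank ratio `> t`; the curve plots
#' sensitivity against 1 - specificity and the AUC is its trapezoidal area.
#' Control rank ratios are the positions not taken by the test gene in each
#' run.
#'
#' @param runs data frame with columns `rank` and `list_size`.
#' @return list with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rank_roc_auc <- function(runs) {
  if (nrow(runs) == 0) stop("no validation runs")
  test_rr <- runs$rank / runs$list_size
  ctrl_rr <- unlist(lapply(seq_len(nrow(runs)), function(i) {
    setdiff(seq_len(runs$list_size[i]), runs$rank[i]) / runs$list_size[i]
  }))
  thr <- sort(unique(c(0, test_rr, ctrl_rr, 1)))
  tpr <- vapply(thr, function(t) mean(test_rr <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(ctrl_rr <= t), numeric(1))
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Expected number of test genes in the top k under random guessing
#'
#' With lists of `list_size` genes and a uniformly random ranking, each run
#' lands in the top `k` with probability `k / list_size`.
#'
#' @param n_runs number of validation runs.
#' @param list_size genes ranked per run (test + controls).
#' @param k cutoff.
#' @return expected count `n_runs * k / list_size`.
#' @export
expected_random_topk <- function(n_runs, list_size, k) {
  if (k < 1 || k > list_size) stop("k must lie in [1, list_size]")
  n_runs * k / list_size
}

#' Leave-one-out cross-validation of the full prioritization pipeline
#'
#' For every annotated disease-gene association, the disease becomes the
#' query and the gene the test gene; a control set is drawn (nearest
#' same-chromosome genes or a random genome sample), all annotations of the
#' query disease are masked, and the test gene is ranked among test +
#' controls by combined p-value (ties broken by gene identifier). Controls
#' never include genes annotated to the query disease.
#'
#' @param assoc an [association_map()].
#' @param phenotype disease `similarity_matrix`.
#' @param sources named list of transformed gene similarity matrices.
#' @param locations gene location table (required for
#'   `control_mode = "linkage"`).
#' @param control_mode `"random"` or `"linkage"`.
#' @param m controls per run.
#' @param seed root seed for control sampling and null-sample construction.
#' @param null_size null-sample size per source for calibration.
#' @param corr optional `source_correlation`; estimated from the null
#'   samples when `NULL`.
#' @param top_k cutoffs for the top-k counts.
#' @return list of class `validation_summary`: `runs` (per-run data frame),
#'   `mrr`, `auc`, `top_k` (named counts), `n_runs`, `n_excluded`.
#' @export
loocv <- function(assoc, phenotype, sources, locations = NULL,
                  control_mode = c("random", "linkage"), m = 99L,
                  seed = 1L, null_size = 2000L, corr = NULL,
                  top_k = c(1L, 5L, 10L, 20L)) {
  control_mode <- match.arg(control_mode)
  if (control_mode == "linkage" && is.null(locations))
    stop("linkage controls need a gene location table")
  genome <- sort(unique(unlist(lapply(sources, rownames))))
  nulls <- lapply(sources, function(phi)
    build_null_sample(assoc, phenotype, phi, m_pairs = null_size, seed = seed))
  names(nulls) <- names(sources)
  if (is.null(corr)) corr <- correlation_from_nulls(nulls)
  old <- local_seed(seed + 1L)
  on.exit(restore_seed(old), add = TRUE)
  runs <- list(); excluded <- 0L
  for (d in names(assoc)) {
    if (!(d %in% rownames(phenotype))) { excluded <- excluded + length(assoc[[d]]); next }
    for (g in assoc[[d]]) {
      if (!any(vapply(sources, function(s) g %in% rownames(s), logical(1)))) {
        excluded <- excluded + 1L; next
      }
      controls <- if (control_mode == "linkage") {
        cs <- linkage_controls(g, locations, m)
        setdiff(cs, assoc[[d]])
      } else {
        random_controls(g, genome, m, exclude = assoc[[d]])
      }
      res <- prioritize(d, c(g, controls), phenotype, sources, assoc,
                        nulls = nulls, corr = corr, leave_one_out = TRUE)
      pos <- match(g, res$gene)
      if (is.na(pos)) { excluded <- excluded + 1L; next }
      runs[[length(runs) + 1L]] <- data.frame(
        disease = d, gene = g, rank = pos, list_size = nrow(res),
        rank_ratio = pos / nrow(res), stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs)) stop("no scoreable validation runs")
  tk <- vapply(top_k, function(k) sum(runs$rank <= k), integer(1))
  names(tk) <- paste0("top", top_k)
  structure(list(runs = runs, mrr = mean_rank_ratio(runs),
                 auc = rank_roc_auc(runs)$auc, top_k = tk,
                 n_runs = nrow(runs), n_excluded = excluded,
                 corr = corr),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("LOOCV: %d runs (%d excluded)\n  MRR = %.2f%%  AUC = %.2f%%\n",
              x$n_runs, x$n_excluded, 100 * x$mrr, 100 * x$auc))
  cat("  ", paste(sprintf("%s=%d", names(x$top_k), x$top_k), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

# Build the between-source correlation from per-source null samples that
# share the same sampled pairs (same seed): calibrate each source's raw
# p-values against itself (leave-one-out style would change little) and
# correlate the probit scores.
correlation_from_nulls <- function(nulls) {
  key <- paste(nulls[[1]]$disease, nulls[[1]]$gene)
  tab <- sapply(names(nulls), function(s) {
    ns <- nulls[[s]]
    stopifnot(identical(paste(ns$disease, ns$gene), key))
    ok <- !is.na(ns$raw_p)
    out <- rep(NA_real_, nrow(ns))
    out[ok] <- calibrate_p(ns$raw_p[ok], ns$raw_p[ok])
    out
  })
  estimate_source_correlation(tab)
}

#' Binned phenotype-versus-genotype correlation
#'
#' For every unordered pair of annotated diseases, the phenotype similarity
#' is placed into equal-width bins on \[0, 1\] (last bin closed) and the
#' genotype similarity `x_de` (total pairwise similarity of the two
#' diseases' gene sets) is averaged within each bin. The Pearson correlation
#' over the per-bin means quantifies how tightly phenotypic overlap tracks
#' genotypic overlap for one genomic data source.
#'
#' @param phenotype disease `similarity_matrix`.
#' @param assoc an [association_map()].
#' @param phi gene `similarity_matrix` for one source.
#' @param bins number of equal-width bins.
#' @return list of class `binned_correlation`: `table` (per-bin data frame),
#'   `pearson_r`, `r_pvalue`, `n_pairs`.
#' @export
bin_correlation <- function(phenotype, assoc, phi, bins = 10L) {
  diseases <- intersect(names(assoc), rownames(phenotype))
  diseases <- diseases[vapply(diseases, function(d)
    any(assoc[[d]] %in% rownames(phi)), logical(1))]
  nd <- length(diseases)
  if (nd < 2) stop("need at least 2 annotated diseases resolvable in the source")
  A <- gene_membership(assoc, diseases, rownames(phi))
  phi0 <- unclass(phi); phi0[is.na(phi0)] <- 0
  G <- crossprod(A, phi0 %*% A)  # x_de for all disease pairs
  up <- upper.tri(G)
  geno <- G[up]
  pheno <- phenotype[diseases, diseases][up]
  edges <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(pheno, edges, rightmost.closed = TRUE), 1L), bins)
  tab <- data.frame(
    bin_lo = edges[seq_len(bins)], bin_hi = edges[-1],
    n = as.integer(tabulate(idx, bins)),
    mean_pheno = vapply(seq_len(bins), function(b)
      if (any(idx == b)) mean(pheno[idx == b]) else NA_real_, numeric(1)),
    mean_geno = vapply(seq_len(bins), function(b)
      if (any(idx == b)) mean(geno[idx == b]) else NA_real_, numeric(1)))
  ok <- !is.na(tab$mean_pheno)
  if (sum(ok) < bins) warning(sprintf("%d empty bin(s) dropped", bins - sum(ok)))
  if (sum(ok) < 3) stop("too few populated bins for a correlation")
  ct <- stats::cor.test(tab$mean_pheno[ok], tab$mean_geno[ok])
  structure(list(table = tab, pearson_r = unname(ct$estimate),
                 r_pvalue = ct$p.value, n_pairs = length(pheno)),
            class = "binned_correlation")
}

#' One-sided hypergeometric enrichment test
#'
#' Upper-tail probability `P(X >= x)` for a hypergeometric draw: out of `N`
#' candidates of which `K` are functional, `n` are selected (e.g. the top-n
#' ranked genes) and `x` of those are functional. This is the one-sided
#' Fisher's exact test of a 2x2 table against enrichment.
#'
#' @param N total candidates.
#' @param K functional candidates.
#' @param n selected candidates.
#' @param x functional among selected.
#' @return the enrichment p-value.
#' @export
hypergeom_enrichment <- function(N, K, n, x) {
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > min(n, K))
    stop("inconsistent counts for the hypergeometric test")
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}
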