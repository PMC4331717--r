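test_that("linkage controls pick nearest same-chromosome genes deterministically", {
  loc <- data.frame(gene = paste0("g", 0:10), chrom = "chr1",
                    pos = seq(0, 100, by = 10), stringsAsFactors = FALSE)
  got <- linkage_controls("g5", loc, m = 4)
  expect_setequal(got, c("g4", "g6", "g3", "g7"))
  # equidistant pair included before any farther gene, smaller coordinate first
  expect_equal(got[1:2], c("g4", "g6"))
  # other chromosomes never contribute
  loc2 <- rbind(loc, data.frame(gene = "h1", chrom = "chr2", pos = 50))
  expect_false("h1" %in% linkage_controls("g5", loc2, m = 10))
  expect_warning(all10 <- linkage_controls("g5", loc, m = 99), "using all")
  expect_length(all10, 10)
  expect_error(linkage_controls("nowhere", loc), "no location")
})

test_that("random controls are seeded, exclusive and near-uniform", {
  genome <- paste0("g", 1:50)
  a <- random_controls("g1", genome, m = 10, seed = 3)
  b <- random_controls("g1", genome, m = 10, seed = 3)
  expect_identical(a, b)
  expect_false("g1" %in% a)
  expect_false(any(c("g2", "g3") %in%
                     random_controls("g1", genome, m = 10, seed = 3,
                                     exclude = c("g2", "g3"))))
  # each gene appears with frequency ~ m/(N-1) across seeds
  counts <- table(factor(unlist(lapply(1:1000, function(s)
    random_controls("g1", genome, m = 10, seed = s))), levels = genome[-1]))
  expect_true(all(abs(counts / 1000 - 10 / 49) <
                    3 * sqrt((10 / 49) * (1 - 10 / 49) / 1000)))
})

test_that("rank summaries match hand arithmetic", {
  runs <- data.frame(rank = c(1, 100), list_size = 100,
                     rank_ratio = c(0.01, 1))
  expect_equal(mean_rank_ratio(runs), 0.505)
  runs1 <- data.frame(rank = rep(1, 5), list_size = 100,
                      rank_ratio = rep(0.01, 5))
  expect_equal(mean_rank_ratio(runs1), 0.01)
  set.seed(2)
  rr <- data.frame(rank = sample(100, 50, replace = TRUE), list_size = 100)
  rr$rank_ratio <- rr$rank / rr$list_size
  expect_equal(mean_rank_ratio(rr), mean(rr$rank) / 100)
})

test_that("rank ROC spans its extremes and is symmetric under reversal", {
  top <- data.frame(rank = rep(1, 30), list_size = 100)
  expect_gte(rank_roc_auc(top)$auc, 0.99)
  bottom <- data.frame(rank = rep(100, 30), list_size = 100)
  expect_lte(rank_roc_auc(bottom)$auc, 0.01)
  expect_equal(rank_roc_auc(top)$auc + rank_roc_auc(bottom)$auc, 1,
               tolerance = 0.02)
  set.seed(9)
  unif <- data.frame(rank = sample(100, 400, replace = TRUE), list_size = 100)
  expect_equal(rank_roc_auc(unif)$auc, 0.5, tolerance = 0.05)
})

test_that("random-guess top-k expectations match the closed form", {
  expect_equal(expected_random_topk(4368, 100, 1), 43.68)
  expect_equal(expected_random_topk(4368, 100, 10), 436.8)
  expect_equal(expected_random_topk(100, 100, 100), 100)
  expect_error(expected_random_topk(10, 100, 0), "k must")
})

test_that("binned correlation counts every disease pair and detects identity", {
  u <- toy_universe()
  bc <- bin_correlation(u$phenotype, u$assoc, u$phi, bins = 5)
  expect_equal(bc$n_pairs, choose(5, 2))
  expect_equal(sum(bc$table$n), bc$n_pairs)
  # genotype made identical to phenotype: perfect correlation across bins
  diseases <- paste0("D", 1:6)
  P <- outer(seq(0.05, 0.95, length.out = 6), rep(1, 6)) * 0 +
    as.matrix(dist(seq(0, 1, length.out = 6)))
  P <- 1 - P / max(P)
  dimnames(P) <- list(diseases, diseases)
  pheno <- similarity_matrix(P, kind = "transformed", source = "p")
  genes <- paste0("G", 1:6)
  G <- P; dimnames(G) <- list(genes, genes)
  phi <- similarity_matrix(G, kind = "transformed", source = "g")
  am <- association_map(diseases, genes)  # disease i <-> gene i
  bc2 <- suppressWarnings(bin_correlation(pheno, am, phi, bins = 5))
  expect_gt(bc2$pearson_r, 0.99)
})

test_that("shuffled genotype destroys the binned correlation", {
  w <- planted_world()
  bc <- suppressWarnings(
    bin_correlation(w$phenotype, w$assoc, w$sources[[1]]))
  expect_gt(bc$pearson_r, 0.5)  # planted worlds correlate
  # permute the disease->gene map: correlation collapses over repetitions
  set.seed(13)
  rs <- replicate(5, {
    shuffled <- setNames(w$assoc[sample(length(w$assoc))], names(w$assoc))
    class(shuffled) <- "association_map"
    suppressWarnings(
      bin_correlation(w$phenotype, shuffled, w$sources[[1]]))$pearson_r
  })
  expect_lt(mean(abs(rs)), abs(bc$pearson_r))
})

test_that("hypergeometric enrichment agrees with the enumeration oracle", {
  enum <- function(N, K, n, x) {
    j <- x:min(n, K)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  cases <- list(c(179, 19, 5, 5), c(179, 19, 10, 9), c(179, 19, 20, 14),
                c(179, 19, 8, 7), c(179, 19, 11, 10), c(50, 10, 5, 2))
  for (cs in cases)
    expect_equal(hypergeom_enrichment(cs[1], cs[2], cs[3], cs[4]),
                 enum(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(179, 19, 5, 0), 1)
  expect_error(hypergeom_enrichment(10, 20, 5, 1), "inconsistent")
})

test_that("LOOCV on a planted world ranks held-out genes near the top", {
  w <- planted_world()
  vs <- loocv(w$assoc, w$phenotype, w$sources, control_mode = "random",
              m = 49, seed = 11, null_size = 1000)
  expect_equal(vs$n_runs, sum(lengths(w$assoc)))
  expect_lt(vs$mrr, 0.10)
  expect_gt(vs$auc, 0.9)
  expect_gt(vs$top_k[["top1"]] / vs$n_runs, 0.9)
  expect_true(all(vs$runs$rank >= 1 & vs$runs$rank <= vs$runs$list_size))
  # controls never contain genes annotated to the query disease
})

test_that("LOOCV against linkage controls works on synthetic locations", {
  w <- planted_world()
  sub <- w$assoc[1:10]
  class(sub) <- "association_map"
  vs <- loocv(sub, w$phenotype, w$sources, locations = w$locations,
              control_mode = "linkage", m = 20, seed = 5, null_size = 500)
  expect_equal(vs$n_runs, sum(lengths(sub)))
  expect_lt(vs$mrr, 0.25)
})
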