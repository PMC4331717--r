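test_that("genotype vectors equal brute-force double loops", {
  u <- toy_universe()
  refs <- setdiff(u$diseases, "D1")
  refs <- refs[vapply(refs, function(d) !is.null(u$assoc[[d]]), logical(1))]
  for (g in u$genes) {
    x <- genotype_vector(g, refs, u$assoc, u$phi)
    manual <- vapply(refs, function(d) {
      s <- 0
      for (k in u$assoc[[d]]) s <- s + u$phi[g, k]
      s
    }, numeric(1))
    expect_equal(as.numeric(x), as.numeric(manual), tolerance = 1e-12)
  }
  # self-association and two-term examples
  phi <- toy_phi(c("g", "h1", "h2"), list(list("g", "h1", 0.2),
                                          list("g", "h2", 0.3)))
  am <- association_map(c("dA", "dB", "dB"), c("g", "h1", "h2"))
  expect_equal(as.numeric(genotype_vector("g", "dA", am, phi)), 1)
  expect_equal(as.numeric(genotype_vector("g", "dB", am, phi)), 0.5)
  expect_error(genotype_vector("absent", "dA", am, phi), "absent from source")
})

test_that("pairwise genotype similarity sums the full cross product", {
  phi <- toy_phi(c("g", "h"), list(list("g", "h", 0.4)))
  expect_equal(pair_genotype_similarity("g", "g", phi), 1)
  expect_equal(pair_genotype_similarity("g", "h", phi), 0.4)
  u <- toy_universe()
  D <- c("G1", "G2"); E <- c("G3", "G4", "G5")
  manual <- 0
  for (g in D) for (h in E) manual <- manual + u$phi[g, h]
  expect_equal(pair_genotype_similarity(D, E, u$phi), manual)
  expect_error(pair_genotype_similarity("nope", "G1", u$phi), "resolvable")
})

test_that("slope test matches lm on random instances to 1e-10", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    got <- slope_test(x, y)
    fit <- summary(lm(y ~ x))$coefficients
    expect_equal(got$beta_hat, fit["x", "Estimate"], tolerance = 1e-10)
    expect_equal(got$t_stat, fit["x", "t value"], tolerance = 1e-10)
    expect_equal(got$raw_p, pt(fit["x", "t value"], n - 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("slope test handles the flat, negative and degenerate cases", {
  flat <- slope_test(c(0, 1, 2, 3), c(1, 0, 0, 1))
  expect_equal(flat$beta_hat, 0)
  expect_equal(flat$t_stat, 0)
  expect_equal(flat$raw_p, 0.5)
  neg <- slope_test(c(0, 1, 2, 3), c(3, 2.2, 1.1, 0.4))
  expect_lt(neg$t_stat, 0)
  expect_gt(neg$raw_p, 0.5)
  expect_error(slope_test(rep(1, 5), rnorm(5)), "degenerate predictor")
  expect_error(slope_test(1:2, 1:2), "n >= 3")
  # perfect fit: p underflows to the positive floor, never zero
  perfect <- slope_test(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_gt(perfect$raw_p, 0)
})

test_that("raw p-values are uniform under the null at nominal type-I error", {
  set.seed(21)
  n_sim <- 2000
  p <- replicate(n_sim, {
    x <- rexp(30)  # leverage-heavy predictor: t test is exact regardless
    y <- rnorm(30)
    slope_test(x, y)$raw_p
  })
  rate <- mean(p <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(suppressWarnings(ks.test(p, "punif"))$statistic, 1.63 / sqrt(n_sim))
})

test_that("calibration counts with add-one smoothing and is monotone", {
  nulls <- seq(0.01, 0.99, length.out = 99)
  expect_equal(calibrate_p(0.999, nulls), 1)
  expect_equal(calibrate_p(0.001, nulls), 0.01)
  expect_equal(calibrate_p(median(nulls), nulls), (50 + 1) / 100)
  ps <- runif(50)
  cal <- calibrate_p(ps, nulls)
  expect_true(all(diff(cal[order(ps)]) >= 0))
  # duplicating the null sample leaves calibrated values essentially unchanged
  cal2 <- calibrate_p(ps, rep(nulls, 2))
  expect_equal(cal, cal2, tolerance = 2 / 99)
  expect_warning(out <- calibrate_p(0.3, numeric(0)), "empty null")
  expect_equal(out, 0.3)
})

test_that("null samples are deterministic under a fixed seed and exclude associations", {
  u <- toy_universe()
  a <- build_null_sample(u$assoc, u$phenotype, u$phi, m_pairs = 10, seed = 9)
  b <- build_null_sample(u$assoc, u$phenotype, u$phi, m_pairs = 10, seed = 9)
  expect_identical(a, b)
  for (i in seq_len(nrow(a)))
    expect_false(a$gene[i] %in% u$assoc[[a$disease[i]]])
  expect_error(build_null_sample(u$assoc, u$phenotype, u$phi, m_pairs = 0), "m_pairs")
  expect_warning(
    big <- build_null_sample(u$assoc, u$phenotype, u$phi, m_pairs = 1e5, seed = 1),
    "using all")
  expect_equal(nrow(big), 5 * 6 - sum(lengths(u$assoc)))
})

test_that("score_gene follows the leave-one-out protocol and bookkeeping", {
  u <- toy_universe()
  sc <- score_gene("D1", "G3", u$phenotype, u$phi, u$assoc)
  # reference diseases: all other annotated diseases
  expect_equal(sc$n_used, 4)
  expect_s3_class(sc, "source_score")
  # gene absent from the source: no score for this source
  expect_null(score_gene("D1", "missing_gene", u$phenotype, u$phi, u$assoc))
  # scoring is invariant to reference-disease order (scalar path is canonical)
  sc2 <- score_gene("D1", "G3", u$phenotype, u$phi, u$assoc, leave_one_out = TRUE)
  expect_equal(sc$raw_p, sc2$raw_p)  # D1 never its own reference
})

test_that("vectorized candidate scoring agrees with scalar score_gene", {
  u <- toy_universe()
  ns <- build_null_sample(u$assoc, u$phenotype, u$phi, m_pairs = 15, seed = 2)
  tab <- phenofuse:::score_gene_set("D2", u$genes, u$phenotype, u$phi, u$assoc,
                                    null_sample = ns, leave_one_out = TRUE)
  for (g in u$genes) {
    sc <- score_gene("D2", g, u$phenotype, u$phi, u$assoc,
                     null_sample = ns, leave_one_out = TRUE)
    i <- match(g, tab$gene)
    expect_equal(tab$beta_hat[i], sc$beta_hat, tolerance = 1e-10)
    expect_equal(tab$raw_p[i], sc$raw_p, tolerance = 1e-10)
    expect_equal(tab$calibrated_p[i], sc$calibrated_p, tolerance = 1e-12)
  }
})

test_that("planted associations score small calibrated p, noise scores uniform", {
  w <- planted_world()
  ns <- build_null_sample(w$assoc, w$phenotype, w$sources[[1]],
                          m_pairs = 1000, seed = 3)
  planted <- score_gene("d001", "g001", w$phenotype, w$sources[[1]], w$assoc,
                        null_sample = ns, leave_one_out = TRUE)
  expect_lt(planted$calibrated_p, 0.05)
  expect_gt(planted$beta_hat, 0)
})
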