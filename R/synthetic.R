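# Synthetic disease/gene universes with planted associations and
# source-specific, cross-correlated similarity structure. The generator
# embodies the working assumption of the method: genes associated with
# phenotypically similar diseases share functional properties across
# genomic data sources.

#' Configuration of a synthetic world
#'
#' Genes are organized into functional modules of `module_size` genes;
#' `assoc_rate` diseases attach to each module and each such disease is
#' associated with every gene of its module. Phenotype similarity of a
#' disease pair is a baseline plus `effect_b` when the diseases share a
#' module, plus Gaussian noise. Raw gene similarity under each source is a
#' baseline plus a within-module boost scaled by that source's reliability,
#' plus pair-level noise split into a component shared across sources
#' (weight `cross_source_rho`) and an independent component; raw scores are
#' clipped to \[0, 1\] and passed through [exp_transform()].
#'
#' @param n_genes total genes; genes beyond `n_modules * module_size` are
#'   unassigned background genes.
#' @param n_modules number of functional modules.
#' @param module_size genes per module.
#' @param assoc_rate diseases attached to each module (total diseases =
#'   `n_modules * assoc_rate`).
#' @param effect_b phenotype-similarity boost for module-sharing disease
#'   pairs (0 = null world).
#' @param noise_sd standard deviation of phenotype-similarity noise.
#' @param base_pheno baseline phenotype similarity.
#' @param source_reliabilities named vector in \[0, 1\]: strength of the
#'   within-module similarity boost per source (0 = pure noise source).
#' @param cross_source_rho share of gene-pair noise variance common to all
#'   sources, in \[0, 1).
#' @param base_gene baseline raw gene similarity.
#' @param gene_noise_sd standard deviation of raw gene-similarity noise.
#' @param module_boost raw-similarity boost for same-module gene pairs (at
#'   reliability 1).
#' @param n_chrom chromosomes over which gene locations are scattered.
#' @param seed root seed; all randomness derives from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200L, n_modules = 30L,
                             module_size = 3L, assoc_rate = 2L,
                             effect_b = 0.3, noise_sd = 0.05,
                             base_pheno = 0.2,
                             source_reliabilities = c(expr = 1, func = 1, ppin = 1),
                             cross_source_rho = 0.3,
                             base_gene = 0.3, gene_noise_sd = 0.1,
                             module_boost = 0.6,
                             n_chrom = 5L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              assoc_rate = as.integer(assoc_rate),
              n_diseases = as.integer(n_modules) * as.integer(assoc_rate),
              effect_b = effect_b, noise_sd = noise_sd,
              base_pheno = base_pheno,
              source_reliabilities = source_reliabilities,
              cross_source_rho = cross_source_rho,
              base_gene = base_gene, gene_noise_sd = gene_noise_sd,
              module_boost = module_boost,
              n_chrom = as.integer(n_chrom), seed = as.integer(seed))
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop("infeasible config: modules require more genes than available")
  if (cfg$n_modules < 1 || cfg$module_size < 1 || cfg$assoc_rate < 1)
    stop("sizes must be >= 1")
  if (cfg$noise_sd <= 0 || cfg$gene_noise_sd <= 0) stop("noise SDs must be > 0")
  if (cfg$cross_source_rho < 0 || cfg$cross_source_rho >= 1)
    stop("cross_source_rho must lie in [0, 1)")
  if (any(cfg$source_reliabilities < 0 | cfg$source_reliabilities > 1))
    stop("source reliabilities must lie in [0, 1]")
  if (is.null(names(cfg$source_reliabilities)))
    stop("source_reliabilities must be named")
  structure(cfg, class = "synthetic_config")
}

# Component seeds are derived from the root seed with fixed offsets so each
# block of randomness is reproducible in isolation.
component_seed <- function(seed, offset) (seed * 97L + offset) %% 2147483647L

#' Generate a synthetic world
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_world`: `assoc` (planted truth),
#'   `phenotype` (disease `similarity_matrix`), `sources` (named list of
#'   transformed gene similarity matrices), `locations` (gene location data
#'   frame), `modules` (gene module assignment, `NA` for background genes),
#'   `disease_modules`, `config`.
#' @export
generate_world <- function(config) {
  cfg <- config
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  diseases <- sprintf("d%03d", seq_len(cfg$n_diseases))
  gene_module <- rep(NA_integer_, cfg$n_genes)
  gene_module[seq_len(cfg$n_modules * cfg$module_size)] <-
    rep(seq_len(cfg$n_modules), each = cfg$module_size)
  disease_module <- rep(seq_len(cfg$n_modules), each = cfg$assoc_rate)

  # planted associations: each disease annotated with its module's genes
  amap <- association_map(
    diseases = rep(diseases, each = cfg$module_size),
    genes = unlist(lapply(disease_module, function(m) genes[which(gene_module == m)])))

  # phenotype similarity
  old <- local_seed(component_seed(cfg$seed, 1L))
  on.exit(restore_seed(old), add = TRUE)
  nd <- cfg$n_diseases
  same <- outer(disease_module, disease_module, "==")
  P <- matrix(cfg$base_pheno, nd, nd) + cfg$effect_b * same
  noise <- matrix(stats::rnorm(nd * nd, sd = cfg$noise_sd), nd, nd)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  P <- pmin(pmax(P + noise, 0), 1)
  diag(P) <- 1
  dimnames(P) <- list(diseases, diseases)
  phenotype <- similarity_matrix(P, kind = "transformed", source = "phenotype")

  # gene similarity per source: shared + independent pair noise
  ng <- cfg$n_genes
  set.seed(component_seed(cfg$seed, 2L))
  shared <- matrix(stats::rnorm(ng * ng, sd = cfg$gene_noise_sd), ng, ng)
  shared[lower.tri(shared)] <- t(shared)[lower.tri(shared)]
  same_g <- outer(gene_module, gene_module, function(a, b)
    !is.na(a) & !is.na(b) & a == b)
  sources <- list()
  for (i in seq_along(cfg$source_reliabilities)) {
    s <- names(cfg$source_reliabilities)[i]
    rel <- cfg$source_reliabilities[[i]]
    set.seed(component_seed(cfg$seed, 10L + i))
    indep <- matrix(stats::rnorm(ng * ng, sd = cfg$gene_noise_sd), ng, ng)
    indep[lower.tri(indep)] <- t(indep)[lower.tri(indep)]
    W <- matrix(cfg$base_gene, ng, ng) + cfg$module_boost * rel * same_g +
      sqrt(cfg$cross_source_rho) * shared +
      sqrt(1 - cfg$cross_source_rho) * indep
    W <- pmin(pmax(W, 0), 1)
    diag(W) <- 1
    dimnames(W) <- list(genes, genes)
    raw <- similarity_matrix(W, kind = "raw", source = s)
    sources[[s]] <- exp_transform(raw)
  }

  # gene locations: uniform over synthetic chromosomes
  set.seed(component_seed(cfg$seed, 3L))
  locations <- data.frame(
    gene = genes,
    chrom = sprintf("chr%d", sample.int(cfg$n_chrom, ng, replace = TRUE)),
    pos = sample.int(1e8L, ng, replace = TRUE),
    stringsAsFactors = FALSE)

  structure(list(assoc = amap, phenotype = phenotype, sources = sources,
                 locations = locations,
                 modules = stats::setNames(gene_module, genes),
                 disease_modules = stats::setNames(disease_module, diseases),
                 config = cfg),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic_world: %d diseases, %d genes, %d modules, ",
                     "%d sources, effect_b=%g\n"),
              x$config$n_diseases, x$config$n_genes, x$config$n_modules,
              length(x$sources), x$config$effect_b))
  invisible(x)
}

#' Null p-value grid from a synthetic world
#'
#' Raw p-values of the per-source association score for sampled
#' non-associated disease-gene pairs; in a world without planted effect
#' these are uniform on (0, 1).
#'
#' @param world a [generate_world()] result.
#' @param n_pairs number of pairs to sample.
#' @param seed integer seed.
#' @param source source name (defaults to the first source).
#' @return numeric vector of raw p-values.
#' @export
null_pvalue_grid <- function(world, n_pairs, seed = 1L, source = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (is.null(source)) source <- names(world$sources)[1]
  ns <- build_null_sample(world$assoc, world$phenotype,
                          world$sources[[source]], m_pairs = n_pairs,
                          seed = seed)
  ns$raw_p[!is.na(ns$raw_p)]
}
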