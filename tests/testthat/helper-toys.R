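# Small fixtures built in code, shared across test files.

# A labeled transformed similarity matrix from explicit entries.
toy_phi <- function(labels, entries, source = "toy") {
  n <- length(labels)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  for (e in entries) m[e[[1]], e[[2]]] <- m[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  similarity_matrix(m, kind = "transformed", source = source)
}

# A deterministic 5-disease / 6-gene toy: phenotype + one source + assoc.
toy_universe <- function(seed = 42) {
  set.seed(seed)
  diseases <- paste0("D", 1:5)
  genes <- paste0("G", 1:6)
  P <- matrix(runif(25, 0.1, 0.9), 5, 5, dimnames = list(diseases, diseases))
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  diag(P) <- 1
  S <- matrix(runif(36, 0.05, 0.95), 6, 6, dimnames = list(genes, genes))
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  diag(S) <- 1
  assoc <- association_map(
    diseases = c("D1", "D2", "D2", "D3", "D4", "D4", "D4", "D5"),
    genes    = c("G1", "G2", "G3", "G4", "G1", "G5", "G6", "G2"))
  list(phenotype = similarity_matrix(P, kind = "transformed", source = "pheno"),
       phi = similarity_matrix(S, kind = "transformed", source = "src1"),
       assoc = assoc, diseases = diseases, genes = genes)
}

# The default planted world used by power-style tests.
planted_world <- function(seed = 7) generate_world(synthetic_config(seed = seed))

# Null world: no phenotype effect, pure-noise sources.
null_world <- function(seed = 5) {
  generate_world(synthetic_config(
    effect_b = 0, source_reliabilities = c(expr = 0, func = 0, ppin = 0),
    seed = seed))
}
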