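# Gene-gene (and disease-disease) similarity construction: raw pairwise
# operators on profile vectors and networks, and the exponential
# transformation that maps raw scores to final similarity scores.

#' Construct a labeled similarity matrix
#'
#' A `similarity_matrix` is the universal currency of the method: a symmetric,
#' labeled square matrix of pairwise scores in \[0, 1\]. Entries that are
#' undefined (e.g. a zero-norm profile, or a disconnected network pair whose
#' distance carries no information) are stored as `NA` and excluded from
#' downstream dispersion estimates and genotype sums.
#'
#' @param values square numeric matrix with identical row and column names.
#' @param kind `"raw"` for untransformed scores (omega) or `"transformed"`
#'   for final scores (phi).
#' @param source short name of the data source the matrix was derived from.
#' @param tol relative tolerance for the symmetry check.
#' @return an object of class `similarity_matrix` (a numeric matrix with
#'   attributes `kind` and `source`).
#' @export
similarity_matrix <- function(values, kind = c("raw", "transformed"),
                              source = "unnamed", tol = 1e-10) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square")
  labels <- rownames(values)
  if (is.null(labels) || is.null(colnames(values)))
    stop("similarity matrix must carry row and column labels")
  if (anyDuplicated(labels))
    stop("duplicate labels in similarity matrix")
  if (!identical(labels, colnames(values)))
    stop("row and column labels disagree")
  finite <- values[!is.na(values)]
  if (length(finite) && (min(finite) < -tol || max(finite) > 1 + tol))
    stop("similarity entries must lie in [0, 1]")
  scale <- max(1, max(abs(finite), na.rm = TRUE))
  d <- abs(values - t(values))
  if (any(d[!is.na(d)] > tol * scale))
    stop("matrix is asymmetric beyond tolerance")
  values <- (values + t(values)) / 2  # exact symmetry
  values[values < 0] <- 0
  values[values > 1] <- 1
  structure(values, class = c("similarity_matrix", "matrix"),
            kind = kind, source = source)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s] source=%s: %d x %d, %d missing entries\n",
              attr(x, "kind"), attr(x, "source"), nrow(x), ncol(x),
              sum(is.na(x))))
  invisible(x)
}

#' Cosine similarity of two non-negative profile vectors
#'
#' The raw similarity operator for annotation-style profiles: concept
#' frequency or information-content vectors, binary pathway/domain membership
#' vectors, and binding-site count vectors. Because the inputs are
#' non-negative the cosine lies in \[0, 1\].
#'
#' @param a,b numeric vectors of equal length with non-negative entries.
#' @return the cosine of the angle between `a` and `b`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must share dimensions")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite profile entry")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("undefined similarity: zero-norm profile vector")
  min(1, sum(a * b) / (na * nb))
}

#' Absolute Pearson correlation of two profile vectors
#'
#' Raw similarity for co-expression style profiles, where strong negative
#' correlation is as informative as strong positive correlation.
#'
#' @param a,b numeric vectors of equal length, at least 3 entries each.
#' @return `|cor(a, b)|`.
#' @export
abs_pearson <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must share dimensions")
  if (length(a) < 3) stop("abs_pearson needs vectors of length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined similarity: zero-variance profile vector")
  min(1, abs(stats::cor(a, b)))
}

#' Build a raw similarity matrix from a collection of profile vectors
#'
#' Applies a pairwise similarity measure to every pair of profiles. Pairs
#' for which the measure is undefined (zero norm or zero variance) become
#' `NA` entries rather than asserting dissimilarity the data cannot support.
#'
#' @param profiles numeric matrix with one row per entity (row names are the
#'   entity identifiers) and one column per dimension, or a named list of
#'   equal-length numeric vectors.
#' @param measure `"cosine"` or `"abs_pearson"`.
#' @param source name recorded on the resulting matrix.
#' @return a raw `similarity_matrix`.
#' @export
build_similarity_matrix <- function(profiles,
                                    measure = c("cosine", "abs_pearson"),
                                    source = "profile") {
  measure <- match.arg(measure)
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (!is.matrix(profiles)) stop("`profiles` must be a matrix or list of vectors")
  if (is.null(rownames(profiles))) stop("profiles must carry entity identifiers")
  if (nrow(profiles) < 2) stop("need at least two profiles")
  n <- nrow(profiles)
  if (measure == "cosine") {
    nrm <- sqrt(rowSums(profiles^2))
    bad <- nrm == 0
    m <- tcrossprod(profiles) / outer(nrm, nrm)
  } else {
    sds <- apply(profiles, 1, stats::sd)
    bad <- sds == 0
    m <- abs(suppressWarnings(stats::cor(t(profiles))))
  }
  m[bad, ] <- NA_real_
  m[, bad] <- NA_real_
  diag(m)[!bad] <- 1
  m[m > 1] <- 1
  m[m < 0] <- 0
  dimnames(m) <- list(rownames(profiles), rownames(profiles))
  similarity_matrix(m, kind = "raw", source = source)
}

#' Build an undirected network from alignment e-values
#'
#' Connects two genes with an undirected edge when their alignment e-value
#' is strictly below the threshold (default 1e-4). Self-pairs and duplicate
#' edges are collapsed.
#'
#' @param pairs data frame or 3-column structure: gene, gene, e-value.
#' @param threshold strict upper bound on the e-value for an edge.
#' @param nodes optional character vector of node identifiers to declare even
#'   when they gain no edge (isolated genes remain in the network).
#' @return an [igraph::graph] object.
#' @export
sequence_network_from_evalues <- function(pairs, threshold = 1e-4,
                                          nodes = NULL) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0) {
    if (ncol(pairs) < 3) stop("expected columns: gene, gene, e-value")
    ev <- as.numeric(pairs[[3]])
    if (any(!is.finite(ev)) || any(ev < 0)) stop("e-values must be finite and >= 0")
    keep <- ev < threshold & as.character(pairs[[1]]) != as.character(pairs[[2]])
    el <- unique(t(apply(cbind(as.character(pairs[[1]][keep]),
                               as.character(pairs[[2]][keep])), 1, sort)))
  } else {
    el <- matrix(character(), ncol = 2)
  }
  all_nodes <- unique(c(nodes,
                        as.character(pairs[[1]])[seq_len(nrow(pairs))],
                        as.character(pairs[[2]])[seq_len(nrow(pairs))]))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  igraph::simplify(g)
}

#' Raw similarity from shortest-path distances in a network
#'
#' For every pair of nodes with a finite shortest-path distance `d`,
#' `omega = 1 - d / d_max`, where `d_max` is the largest finite distance
#' observed. The diagonal is 1 (distance zero). Pairs in different connected
#' components have no defined distance; they are assigned `omega = 0`
#' (maximal dissimilarity) and counted in the `disconnected` attribute.
#'
#' @param net an [igraph::graph] (undirected) with named vertices.
#' @param source name recorded on the resulting matrix.
#' @return a raw `similarity_matrix` over the network's nodes.
#' @export
network_raw_similarity <- function(net, source = "network") {
  if (igraph::vcount(net) == 0) stop("network is empty")
  d <- igraph::distances(net)
  finite <- is.finite(d)
  dmax <- max(d[finite])
  if (dmax == 0) {  # no edges at all: only self-distances are finite
    omega <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
    diag(omega) <- 1
  } else {
    omega <- 1 - d / dmax
  }
  n_disc <- sum(!finite) / 2
  omega[!finite] <- 0
  out <- similarity_matrix(omega, kind = "raw", source = source)
  attr(out, "disconnected") <- n_disc
  out
}

#' Exponential transformation of raw similarity scores
#'
#' Maps raw scores `omega` to final scores `phi = exp(-((1 - omega)/sigma)^2)`.
#' The transformation keeps the top of the scale fixed (`omega = 1` maps to
#' `phi = 1`) while compressing noisy low scores towards zero: `omega = 0`
#' becomes `exp(-sigma^-2)`, which is tiny when the dispersion `sigma` is
#' small. By default `sigma` is the population standard deviation of the
#' observed strictly-off-diagonal raw scores (self-pairs are not pairs and
#' are excluded, as are missing entries).
#'
#' @param raw a raw `similarity_matrix`.
#' @param sigma positive dispersion; estimated from `raw` when `NULL`.
#' @return a transformed `similarity_matrix`; `NA` entries stay `NA`.
#' @export
exp_transform <- function(raw, sigma = NULL) {
  if (!inherits(raw, "similarity_matrix") || attr(raw, "kind") != "raw")
    stop("`raw` must be a raw similarity_matrix")
  if (is.null(sigma)) {
    up <- raw[upper.tri(raw)]
    up <- up[!is.na(up)]
    if (length(up) < 2) stop("too few observed pairs to estimate sigma")
    mu <- mean(up)
    sigma <- sqrt(mean((up - mu)^2))  # population SD
  }
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate dispersion: sigma must be > 0")
  phi <- exp(-((1 - unclass(raw)) / sigma)^2)
  out <- similarity_matrix(phi, kind = "transformed", source = attr(raw, "source"))
  attr(out, "sigma") <- sigma
  out
}
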