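# Readers and writers for the on-disk formats: labeled similarity matrices,
# association tables, gene locations (all TSV) and JSON summaries.

#' Read a labeled similarity matrix from TSV
#'
#' Expects a header row of labels and a first column of labels; the two must
#' agree. Symmetry and the \[0, 1\] range are validated on load.
#'
#' @param path file path.
#' @param kind,source forwarded to [similarity_matrix()].
#' @return a `similarity_matrix`.
#' @export
read_similarity_tsv <- function(path, kind = "transformed", source = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("%s: expected labels plus at least one column", path))
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (is.null(source))
    source <- sub("\\.[^.]*$", "", basename(path))
  similarity_matrix(m, kind = kind, source = source)
}

#' Write a similarity matrix to TSV
#'
#' Values are written with 17 significant digits so that a read-back
#' reproduces the matrix exactly.
#'
#' @param mat a `similarity_matrix`.
#' @param path file path.
#' @export
write_similarity_tsv <- function(mat, path) {
  vals <- matrix(formatC(unclass(mat), digits = 17, format = "g"),
                 nrow(mat), dimnames = dimnames(mat))
  df <- data.frame(id = rownames(mat), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease-gene association table from TSV
#'
#' Two columns (disease id, gene id), with or without a header; duplicate
#' rows are collapsed.
#'
#' @param path file path.
#' @param header whether the first line is a header.
#' @return an [association_map()].
#' @export
read_association_tsv <- function(path, header = TRUE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("%s: empty association table", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop(sprintf("%s: malformed row at line %d (need 2 tab-separated columns)",
                 path, bad[1] + as.integer(header)))
  association_map(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
}

#' Write an association map to TSV
#' @param assoc an [association_map()].
#' @param path file path.
#' @export
write_association_tsv <- function(assoc, path) {
  df <- data.frame(disease = rep(names(assoc), lengths(assoc)),
                   gene = unlist(assoc, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene locations from a BED-like TSV
#'
#' Three columns: chromosome, position, gene id.
#'
#' @param path file path.
#' @param header whether the first line is a header.
#' @return data frame with columns `gene`, `chrom`, `pos`.
#' @export
read_locations_tsv <- function(path, header = TRUE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop(sprintf("%s: expected chromosome, position, gene", path))
  out <- data.frame(gene = as.character(df[[3]]), chrom = as.character(df[[1]]),
                    pos = as.numeric(df[[2]]), stringsAsFactors = FALSE)
  if (any(is.na(out$pos)) || any(out$pos < 0))
    stop(sprintf("%s: positions must be non-negative numbers", path))
  if (anyDuplicated(out$gene)) stop(sprintf("%s: duplicate gene record", path))
  out
}

#' Write a synthetic world to a directory
#'
#' Emits the world in the package's TSV formats plus a JSON manifest of the
#' generating configuration.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return the directory path.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_similarity_tsv(world$phenotype, file.path(dir, "phenotype.tsv"))
  for (s in names(world$sources))
    write_similarity_tsv(world$sources[[s]], file.path(dir, paste0("source_", s, ".tsv")))
  write_association_tsv(world$assoc, file.path(dir, "associations.tsv"))
  loc <- world$locations[, c("chrom", "pos", "gene")]
  utils::write.table(loc, file.path(dir, "locations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- world$config
  cfg$source_reliabilities <- as.list(cfg$source_reliabilities)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic world (or any compatible data directory)
#'
#' @param dir directory produced by [write_world()] or laid out the same
#'   way: `phenotype.tsv`, `source_*.tsv`, `associations.tsv`, optional
#'   `locations.tsv`.
#' @return list with `phenotype`, `sources`, `assoc`, `locations`.
#' @export
read_world <- function(dir) {
  phenotype <- read_similarity_tsv(file.path(dir, "phenotype.tsv"),
                                   source = "phenotype")
  sfiles <- list.files(dir, pattern = "^source_.*\\.tsv$", full.names = TRUE)
  if (length(sfiles) == 0) stop("no source_*.tsv matrices found")
  sources <- lapply(sfiles, read_similarity_tsv)
  names(sources) <- sub("^source_(.*)\\.tsv$", "\\1", basename(sfiles))
  for (s in names(sources)) attr(sources[[s]], "source") <- s
  assoc <- read_association_tsv(file.path(dir, "associations.tsv"))
  locations <- NULL
  locp <- file.path(dir, "locations.tsv")
  if (file.exists(locp)) locations <- read_locations_tsv(locp)
  list(phenotype = phenotype, sources = sources, assoc = assoc,
       locations = locations)
}

# Provenance record written next to every CLI output.
write_provenance <- function(path, config, inputs = character(0)) {
  rec <- list(
    tool = "phenofuse",
    version = as.character(utils::packageVersion("phenofuse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
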