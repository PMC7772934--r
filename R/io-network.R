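#' Weighted protein-protein interaction network container
#'
#' Undirected graph over protein IDs with confidence-score edge weights in
#' `[0, 1]`, plus the gene-to-protein mapping used to query it from gene
#' space.  Internally stores a per-protein named weight vector of
#' neighbours for fast neighbourhood-overlap similarity.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`, `score`.
#' @param gene2protein Named character vector mapping gene ID to protein ID.
#' @return An object of class `ppin` with elements `graph` (igraph),
#'   `neighbors` (named list of named weight vectors) and `gene2protein`.
#' @export
ppin <- function(edges, gene2protein = character()) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges)) {
    if (any(edges$score < 0)) stop("negative PPI confidence score")
    self <- edges$protein_a == edges$protein_b
    if (any(self)) {
      warning(sum(self), " self-loop row(s) skipped")
      edges <- edges[!self, , drop = FALSE]
    }
  }
  if (nrow(edges) && any(edges$score > 1)) {
    rng <- range(edges$score)
    edges$score <- if (diff(rng) == 0) rep(1, nrow(edges)) else
      (edges$score - rng[1L]) / diff(rng)
  }
  # canonical order + duplicate edges keep the max score
  if (nrow(edges)) {
    a <- pmin(edges$protein_a, edges$protein_b)
    b <- pmax(edges$protein_a, edges$protein_b)
    key <- paste(a, b, sep = "\r")
    score <- tapply(edges$score, key, max)
    ab <- strsplit(names(score), "\r", fixed = TRUE)
    edges <- data.frame(protein_a = vapply(ab, `[[`, "", 1L),
                        protein_b = vapply(ab, `[[`, "", 2L),
                        score = as.numeric(score),
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE,
    vertices = NULL)
  if (nrow(edges)) igraph::E(g)$weight <- edges$score
  neighbors <- list()
  for (i in seq_len(nrow(edges))) {
    pa <- edges$protein_a[i]; pb <- edges$protein_b[i]; w <- edges$score[i]
    neighbors[[pa]][pb] <- w
    neighbors[[pb]][pa] <- w
  }
  structure(list(graph = g, edges = edges, neighbors = neighbors,
                 gene2protein = gene2protein),
            class = "ppin")
}

#' @export
print.ppin <- function(x, ...) {
  cat(sprintf("ppin: %d proteins, %d edges, %d mapped genes\n",
              length(x$neighbors), nrow(x$edges), length(x$gene2protein)))
  invisible(x)
}

#' Read a weighted PPI edge list
#'
#' TSV with columns `protein_a`, `protein_b`, `score` (header optional).
#' Scores above 1 trigger min-max rescaling of the whole file to `[0, 1]`;
#' duplicate edges keep the maximum score; self-loops are skipped with a
#' warning and negative scores are an error.
#'
#' @param path Path to the edge list.
#' @param gene2protein Optional named character vector (see
#'   [read_gene2protein()]).
#' @return A [ppin()].
#' @export
read_ppin <- function(path, gene2protein = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^protein_a\t", lines[1L]))
    lines <- lines[-1L]
  if (!length(lines))
    return(ppin(data.frame(protein_a = character(),
                           protein_b = character(),
                           score = numeric()), gene2protein))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  score <- suppressWarnings(
    as.numeric(vapply(parts, `[[`, character(1L), 3L)))
  if (anyNA(score)) stop("non-numeric PPI score")
  if (any(score < 0)) stop("negative PPI confidence score")
  ppin(data.frame(protein_a = vapply(parts, `[[`, character(1L), 1L),
                  protein_b = vapply(parts, `[[`, character(1L), 2L),
                  score = score, stringsAsFactors = FALSE),
       gene2protein)
}

#' Write a PPI edge list as TSV
#' @param net A [ppin()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ppin <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-to-protein ID mapping
#'
#' Two-column TSV `gene_id<TAB>protein_id`; if a gene maps to several
#' protein isoforms, the first occurrence is kept.
#'
#' @param path Path to the mapping file.
#' @return Named character vector, names are gene IDs.
#' @export
read_gene2protein <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("gene_id", "protein_id"),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  setNames(df$protein_id, df$gene_id)
}

#' Write a gene-to-protein mapping as TSV
#' @param map Named character vector (names = gene IDs).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene2protein <- function(map, path) {
  write.table(data.frame(names(map), unname(map)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bit-score matrix container
#'
#' Raw pairwise BLAST bit scores over the proteins mapped from a gene
#' index.  The raw matrix may be asymmetric (BLAST is not symmetric);
#' symmetrization, log-scaling and min-max normalization happen in
#' [seq_sim_matrix()].  Genes whose protein has no BLAST row at all are
#' flagged unmapped, which later triggers the sequence-similarity
#' fallback.
#'
#' @param raw Square numeric matrix of raw bit scores (protein IDs as
#'   dimnames), zero where no hit was reported.
#' @param gene2protein Named character vector mapping gene ID to protein ID.
#' @param gene_ids Gene index the matrix serves.
#' @return An object of class `bitscore_matrix` with elements `raw`,
#'   `proteins`, `gene2protein`, `gene_ids` and logical `mapped` per gene.
#' @export
bitscore_matrix <- function(raw, gene2protein, gene_ids) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  if (any(raw < 0)) stop("negative bit score")
  proteins <- rownames(raw)
  has_rows <- rowSums(raw > 0) + colSums(raw > 0) > 0
  prot <- gene2protein[gene_ids]
  mapped <- !is.na(prot) & prot %in% proteins
  mapped[mapped] <- has_rows[prot[mapped]]
  names(mapped) <- gene_ids
  structure(list(raw = raw, proteins = proteins,
                 gene2protein = gene2protein,
                 gene_ids = gene_ids, mapped = mapped),
            class = "bitscore_matrix")
}

#' Read BLAST tabular output (outfmt 6) into a bit-score matrix
#'
#' Standard 12-column BLAST tabular rows; column 1 is the query protein,
#' column 2 the subject, column 12 the bit score.  Multiple HSPs for one
#' ordered pair keep the maximum bit score.  Rows whose proteins are not
#' targets of the gene-to-protein mapping are skipped with a warning.
#'
#' @param path Path to the BLAST tabular file.
#' @param gene2protein Named character vector mapping gene ID to protein ID.
#' @param gene_ids Gene index the matrix should serve (defaults to the
#'   mapping's genes).
#' @return A [bitscore_matrix()].
#' @export
read_blast_tab <- function(path, gene2protein,
                           gene_ids = names(gene2protein)) {
  proteins <- unique(unname(gene2protein[gene_ids]))
  proteins <- proteins[!is.na(proteins)]
  raw <- matrix(0, length(proteins), length(proteins),
                dimnames = list(proteins, proteins))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  skipped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) stop("BLAST tabular row with fewer than 12 columns")
    q <- f[1L]; s <- f[2L]; bits <- as.numeric(f[12L])
    if (!(q %in% proteins) || !(s %in% proteins)) {
      skipped <- skipped + 1L
      next
    }
    raw[q, s] <- max(raw[q, s], bits)
  }
  if (skipped)
    warning(skipped, " BLAST row(s) with unmappable protein ID skipped")
  bitscore_matrix(raw, gene2protein, gene_ids)
}

#' Write a bit-score matrix as BLAST tabular text
#'
#' Emits one outfmt-6 style row per non-zero ordered pair (self rows
#' included), with placeholder alignment statistics and the bit score in
#' column 12.
#'
#' @param bits A [bitscore_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_blast_tab <- function(bits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- bits$proteins
  for (i in seq_along(p)) for (j in seq_along(p)) {
    b <- bits$raw[i, j]
    if (b > 0)
      writeLines(paste(p[i], p[j], "100.0", "100", "0", "0", "1", "100",
                       "1", "100", "1e-50", formatC(b, format = "g", digits = 10),
                       sep = "\t"), con)
  }
  invisible(path)
}
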