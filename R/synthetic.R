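#' Specification for the synthetic multi-view benchmark generator
#'
#' Describes planted structure for all six pipeline inputs: co-expressed
#' gene clusters, two sample classes separated by a minority of relevant
#' genes, a toy ontology with one branch per gene cluster (branches are
#' separately rooted, cycling through the three namespaces), annotation
#' coherence, cluster-biased PPI edge density and cluster-biased BLAST
#' bit scores.
#'
#' @param n Number of genes.
#' @param d Number of samples.
#' @param C Number of planted gene clusters.
#' @param d1,d2 Sample class sizes (`d1 + d2 == d`).
#' @param n_rel Number of relevant (class-separating) genes, spread
#'   evenly over the clusters.
#' @param delta Additional class-mean separation of relevant genes
#'   (log-expression units), applied in the direction of their module's
#'   class effect.
#' @param sigma Per-gene Gaussian noise SD around the module profile.
#' @param tau SD of the per-module class effect (module-level
#'   differential expression; makes the two classes the dominant
#'   sample-level structure, as in real two-class expression data).
#' @param eta SD of the per-sample module variation within a class.
#' @param rho Annotation coherence: probability an annotation draw comes
#'   from the gene's own ontology branch.
#' @param terms_per_branch Terms per ontology branch (root + 2 children +
#'   grandchildren).
#' @param ann_per_gene Annotation draws per gene.
#' @param ppin_within,ppin_between Within/between-cluster PPI edge
#'   probabilities.
#' @param bits_within,bits_between Ranges (length-2) of directed BLAST
#'   bit scores for within/between-cluster protein pairs.
#' @param blast_unmapped_frac Fraction of genes absent from the BLAST
#'   output (exercises the sequence-similarity fallback).
#' @param seed Optional RNG seed applied by [generate_synthetic()].
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 200L, d = 40L, C = 5L,
                           d1 = d %/% 2L, d2 = d - d1,
                           n_rel = 10L, delta = 2.0, sigma = 0.5,
                           tau = 1.0, eta = 0.5,
                           rho = 0.9, terms_per_branch = 6L,
                           ann_per_gene = 2L,
                           ppin_within = 0.3, ppin_between = 0.02,
                           bits_within = c(150, 250),
                           bits_between = c(20, 60),
                           blast_unmapped_frac = 0,
                           seed = NULL) {
  stopifnot(n >= C, d1 + d2 == d, n_rel <= n, rho >= 0, rho <= 1,
            sigma > 0, C >= 2L, terms_per_branch >= 3L)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Toy ontology: C separately rooted branches, namespaces cycling through
# BP/MF/CC; each branch is root -> 2 children -> grandchildren.
synthetic_go <- function(C, terms_per_branch) {
  namespaces <- c("biological_process", "molecular_function",
                  "cellular_component")
  terms <- character(); parents <- list(); ns <- character()
  branch_terms <- vector("list", C)
  for (b in seq_len(C)) {
    ids <- sprintf("GO:%02d%05d", b, seq_len(terms_per_branch))
    root <- ids[1L]
    parents[[root]] <- character()
    for (k in 2L:terms_per_branch) {
      parents[[ids[k]]] <- if (k <= 3L) root else
        ids[2L + ((k - 4L) %% 2L)]  # grandchildren under the 2 children
    }
    terms <- c(terms, ids)
    ns <- c(ns, rep(namespaces[(b - 1L) %% 3L + 1L], terms_per_branch))
    branch_terms[[b]] <- ids
  }
  list(graph = go_graph(terms, parents, setNames(ns, terms)),
       branch_terms = branch_terms)
}

#' Generate a synthetic multi-view benchmark bundle
#'
#' Draws all six inputs with the planted structure of a
#' [synthetic_spec()]: expression = module profile (class-dependent
#' module mean plus within-class per-sample variation) + per-gene
#' Gaussian noise, with relevant genes separated by an additional
#' `delta` between the class means along their module's class
#' direction (values are on log scale, so preprocessing standardizes
#' with `log_base = NA`); ontology and annotations with own-branch
#' coherence `rho`; a PPI network and a directed bit-score matrix that
#' are denser/stronger within clusters than between.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_bundle`: `expr`, `go` (IC computed),
#'   `ann`, `net`, `bits`, `truth` (gene_cluster, relevant,
#'   sample_class) and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n; d <- spec$d; C <- spec$C

  gene_ids <- sprintf("g%03d", seq_len(n))
  sample_ids <- sprintf("s%02d", seq_len(d))
  sample_class <- rep(c(1L, 2L), c(spec$d1, spec$d2))
  gene_cluster <- sort(rep_len(seq_len(C), n))

  # relevant genes: spread evenly, the first per-cluster genes
  per <- tabulate(rep_len(seq_len(C), spec$n_rel), C)
  relevant <- unlist(lapply(seq_len(C), function(c) {
    members <- which(gene_cluster == c)
    members[seq_len(per[c])]
  }))

  # module profile = class-dependent module mean + within-class
  # per-sample module variation; genes add independent noise
  a <- rnorm(C, 0, spec$tau)                   # module class effect
  z <- ifelse(sample_class == 1L, 0.5, -0.5)   # class half-coding
  base <- outer(a, z) + matrix(rnorm(C * d, sd = spec$eta), C, d)
  values <- base[gene_cluster, , drop = FALSE] +
    matrix(rnorm(n * d, sd = spec$sigma), n, d)
  # relevant genes: extra separation delta along their module direction
  dir <- ifelse(a[gene_cluster[relevant]] >= 0, 1, -1)
  values[relevant, ] <- values[relevant, , drop = FALSE] +
    outer(dir * spec$delta, z)
  dimnames(values) <- list(gene_ids, sample_ids)
  expr <- expr_matrix(values, sample_class)

  go <- synthetic_go(C, spec$terms_per_branch)
  ann <- lapply(seq_len(n), function(i) {
    own <- gene_cluster[i]
    draws <- vapply(seq_len(spec$ann_per_gene), function(k) {
      b <- if (runif(1L) < spec$rho) own else {
        others <- setdiff(seq_len(C), own)
        others[rand_int(length(others))]
      }
      pool <- go$branch_terms[[b]][-1L]  # non-root terms
      pool[rand_int(length(pool))]
    }, character(1L))
    unique(draws)
  })
  names(ann) <- gene_ids
  go_ic <- compute_ic(go$graph, ann)

  proteins <- sprintf("P%03d", seq_len(n))
  gene2protein <- setNames(proteins, gene_ids)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  same <- gene_cluster[pairs[, 1L]] == gene_cluster[pairs[, 2L]]
  p_edge <- ifelse(same, spec$ppin_within, spec$ppin_between)
  has <- runif(nrow(pairs)) < p_edge
  w <- ifelse(same[has], runif(sum(has), 0.6, 1),
              runif(sum(has), 0.05, 0.3))
  edges <- data.frame(protein_a = proteins[pairs[has, 1L]],
                      protein_b = proteins[pairs[has, 2L]],
                      score = w, stringsAsFactors = FALSE)
  net <- ppin(edges, gene2protein)

  raw <- matrix(0, n, n, dimnames = list(proteins, proteins))
  lo <- ifelse(same, spec$bits_within[1L], spec$bits_between[1L])
  hi <- ifelse(same, spec$bits_within[2L], spec$bits_between[2L])
  raw[pairs] <- runif(nrow(pairs), lo, hi)
  raw[pairs[, c(2L, 1L)]] <- runif(nrow(pairs), lo, hi)
  diag(raw) <- runif(n, 300, 500)
  if (spec$blast_unmapped_frac > 0) {
    drop <- sample.int(n, round(spec$blast_unmapped_frac * n))
    raw[drop, ] <- 0
    raw[, drop] <- 0
  }
  bits <- bitscore_matrix(raw, gene2protein, gene_ids)

  structure(list(expr = expr, go = go_ic, ann = ann, net = net,
                 bits = bits,
                 truth = list(gene_cluster = setNames(gene_cluster,
                                                      gene_ids),
                              relevant = gene_ids[relevant],
                              sample_class = sample_class),
                 spec = spec),
            class = "synthetic_bundle")
}

#' The standard desk-scale benchmark bundle
#'
#' Fixed published setting used by the acceptance suite: `n = 200`
#' genes in `C = 5` clusters, `d = 40` samples (20 + 20), `n_rel = 10`
#' relevant genes (2 per cluster), `delta = 2`, `sigma = 0.5`,
#' `rho = 0.9`, seed 17.
#'
#' @return A `synthetic_bundle`.
#' @export
standard_benchmark <- function() {
  generate_synthetic(synthetic_spec(seed = 17L))
}

#' Write a synthetic bundle to disk in the standard input formats
#'
#' Emits `expression.tsv`, `go.obo`, `annotations.tsv`, `ppin.tsv`,
#' `gene2protein.tsv`, `blast.tsv` and two truth tables
#' (`truth_gene_clusters.tsv`, `truth_sample_classes.tsv`).
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(bundle$expr, p("expression.tsv"))
  write_obo(bundle$go, p("go.obo"))
  write_annotations(bundle$ann, p("annotations.tsv"))
  write_ppin(bundle$net, p("ppin.tsv"))
  write_gene2protein(bundle$net$gene2protein, p("gene2protein.tsv"))
  write_blast_tab(bundle$bits, p("blast.tsv"))
  write.table(data.frame(gene_id = names(bundle$truth$gene_cluster),
                         cluster = unname(bundle$truth$gene_cluster),
                         relevant = names(bundle$truth$gene_cluster) %in%
                           bundle$truth$relevant),
              p("truth_gene_clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = bundle$expr$sample_ids,
                         class = bundle$truth$sample_class),
              p("truth_sample_classes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Write a GO graph as OBO 1.2 text
#'
#' @param go A [go_graph()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_obo <- function(go, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in go$terms) {
    p <- go$parents[[t]]
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("namespace: ", go$namespace[[t]]),
                 if (length(p)) paste0("is_a: ", p)), con)
  }
  invisible(path)
}
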