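#' Correlation distance between two vectors
#'
#' `1 - |phi(x, y)|` with `phi = cov(x, y) / sqrt(var(x) var(y))`.  A
#' constant vector has zero variance and, by the zero-covariance
#' convention, distance 1 to everything.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return A scalar in `[0, 1]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("vectors must have equal length >= 2")
  vx <- pop_var(x); vy <- pop_var(y)
  if (vx < 1e-24 || vy < 1e-24) return(1)
  phi <- mean((x - mean(x)) * (y - mean(y))) / sqrt(vx * vy)
  max(0, 1 - abs(phi))
}

validate_view <- function(D, tol = 1e-9) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > tol) stop("view matrix not symmetric")
  if (any(abs(diag(D)) > tol)) stop("view diagonal not zero")
  if (min(D) < -tol || max(D) > 1 + tol) stop("view entries outside [0, 1]")
  invisible(D)
}

#' Build the expression-correlation view (view 1)
#'
#' Pairwise correlation distance between gene expression vectors, computed
#' on the (preprocessed) expression matrix restricted to the genes taking
#' part in selection.
#'
#' @param expr An [expr_matrix()], typically after
#'   [preprocess_expression()] and restriction to GO-mapped genes.
#' @return A symmetric n x n dissimilarity matrix with gene dimnames,
#'   zero diagonal, entries in `[0, 1]`.
#' @export
build_view1 <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  if (nrow(v) < 2L) stop("need at least two genes")
  sds <- apply(v, 1L, pop_sd)
  D <- matrix(1, nrow(v), nrow(v), dimnames = list(rownames(v), rownames(v)))
  ok <- sds > 1e-12
  if (any(ok)) {
    # population and sample covariances cancel in the correlation ratio
    C <- suppressWarnings(cor(t(v[ok, , drop = FALSE])))
    D[ok, ok] <- 1 - abs(C)
  }
  D[D < 0] <- 0
  diag(D) <- 0
  (D + t(D)) / 2
}

# --- GO multi-factored similarity -------------------------------------

# Lowest common ancestor = shared ancestor of maximal IC; NULL if none.
lca_term <- function(t1, t2, go) {
  common <- intersect(go$ancestors[[t1]], go$ancestors[[t2]])
  if (!length(common)) return(NULL)
  common[which.max(go$ic[common])]
}

# Shortest chain of terms from `from` up to ancestor `to` (both included),
# following child -> parent edges.
up_path <- function(from, to, go) {
  # BFS on parent edges
  prev <- list(); queue <- from; seen <- from
  if (from == to) return(from)
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (p in go$parents[[cur]]) {
      if (p %in% seen) next
      prev[[p]] <- cur; seen <- c(seen, p)
      if (p == to) {
        path <- to
        while (path[1L] != from) path <- c(prev[[path[1L]]], path)
        return(path)
      }
      queue <- c(queue, p)
    }
  }
  to  # unreachable in a valid DAG when `to` is an ancestor
}

#' Multi-factored semantic similarity between two GO terms
#'
#' Sum of Lin similarity, Shen path-based similarity and normalized
#' structural depth similarity, squashed through `arctan(Y) / (pi/2)` so
#' the value stays in `[0, 1)`.  Terms from different namespaces (or with
#' no common ancestor) have similarity 0 by convention.
#'
#' The three components are:
#' `sim_Lin = 2 IC(LCA) / (IC(t1) + IC(t2))` (0 when both ICs are 0);
#' `sim_Shen = 1 - arctan(sum over the t1-LCA-t2 path of 1/IC) / (pi/2)`
#' (zero-IC terms skipped);
#' `sim_depth = depth(LCA) / max(depth(t1), depth(t2))` (0 at the root).
#' The LCA is the common ancestor of maximal IC.
#'
#' @param t1,t2 Term IDs.
#' @param go A [go_graph()] with IC computed.
#' @return A scalar in `[0, 1)`.
#' @export
multi_sim_terms <- function(t1, t2, go) {
  if (anyNA(go$ic[c(t1, t2)])) stop("IC not computed; call compute_ic()")
  if (go$namespace[t1] != go$namespace[t2]) return(0)
  lca <- lca_term(t1, t2, go)
  if (is.null(lca)) return(0)
  ic1 <- go$ic[[t1]]; ic2 <- go$ic[[t2]]; icl <- go$ic[[lca]]
  sim_lin <- if (ic1 + ic2 > 0) 2 * icl / (ic1 + ic2) else 0
  path <- unique(c(up_path(t1, lca, go), up_path(t2, lca, go)))
  ics <- go$ic[path]
  ics <- ics[ics > 0]
  sim_shen <- 1 - atan(sum(1 / ics)) / (pi / 2)
  dmax <- max(go$depth[[t1]], go$depth[[t2]])
  sim_depth <- if (dmax > 0) go$depth[[lca]] / dmax else 0
  y <- sim_lin + sim_shen + sim_depth
  atan(y) / (pi / 2)
}

# Normalized term overlap between two annotation sets.
sim_nto <- function(a1, a2) {
  length(intersect(a1, a2)) / min(length(a1), length(a2))
}

#' Multi-factored semantic similarity between two genes
#'
#' Mean of [multi_sim_terms()] over all term pairs of the two genes'
#' annotation sets, averaged with the normalized term overlap:
#' `(mean_term_sim + sim_NTO) / 2`.  Both genes must be annotated;
#' unannotated genes are filtered out before selection.
#'
#' @param g1,g2 Gene IDs.
#' @param ann Annotation map (named list gene -> term IDs).
#' @param go A [go_graph()] with IC computed.
#' @return A scalar in `[0, 1]`.
#' @export
multi_sim_genes <- function(g1, g2, ann, go) {
  a1 <- ann[[g1]]; a2 <- ann[[g2]]
  if (is.null(a1) || is.null(a2))
    stop("unannotated gene; only GO-mapped genes take part in selection")
  s <- 0
  for (t1 in a1) for (t2 in a2) s <- s + multi_sim_terms(t1, t2, go)
  (s / (length(a1) * length(a2)) + sim_nto(a1, a2)) / 2
}

#' Weighted-neighbourhood functional similarity in a PPI network
#'
#' Weighted Jaccard-style overlap of the two proteins' interaction
#' neighbourhoods: shared neighbours contribute `min(w_ik, w_jk)` to the
#' numerator, while the denominator adds the private-neighbour weights of
#' both proteins and `max(w_ik, w_jk)` over shared neighbours.  Genes not
#' mapped into the network, or pairs with an empty denominator, score 0.
#'
#' @param g1,g2 Gene IDs.
#' @param net A [ppin()].
#' @return A scalar in `[0, 1]`.
#' @export
ppi_sim <- function(g1, g2, net) {
  p1 <- net$gene2protein[g1]; p2 <- net$gene2protein[g2]
  if (is.na(p1) || is.na(p2)) return(0)
  w1 <- net$neighbors[[p1]]; w2 <- net$neighbors[[p2]]
  if (is.null(w1) || is.null(w2)) return(0)
  common <- intersect(names(w1), names(w2))
  num <- sum(pmin(w1[common], w2[common]))
  den <- sum(w1[setdiff(names(w1), common)]) +
    sum(pmax(w1[common], w2[common])) +
    sum(w2[setdiff(names(w2), common)])
  if (den == 0) return(0)
  num / den
}

#' Sequence similarity matrix from BLAST bit scores
#'
#' For each protein pair, the two directed bit scores are averaged, passed
#' through `log10(avg + pseudocount)` and the resulting values are
#' min-max normalized to `[0, 1]` over all mapped pairs.  The default
#' pseudo-count of 1 keeps the log defined for pairs with no reciprocal
#' hit (average 0 maps to 0 before normalization); the normalization
#' absorbs the shift.  Gene pairs involving a BLAST-unmapped gene are NA
#' here and handled by the fallback rule in [intdis()]/[build_view2()].
#'
#' @param bits A [bitscore_matrix()].
#' @param pseudocount Value added inside the log (default 1).
#' @return A symmetric gene-indexed matrix in `[0, 1]` with NA rows and
#'   columns for unmapped genes.
#' @export
seq_sim_matrix <- function(bits, pseudocount = 1) {
  stopifnot(inherits(bits, "bitscore_matrix"))
  genes <- bits$gene_ids
  n <- length(genes)
  S <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  mp <- genes[bits$mapped]
  if (length(mp) < 2L) return(S)
  prot <- bits$gene2protein[mp]
  avg <- (bits$raw[prot, prot, drop = FALSE] +
            t(bits$raw[prot, prot, drop = FALSE])) / 2
  pre <- log10(avg + pseudocount)
  rng <- range(pre)
  norm <- if (diff(rng) == 0) matrix(1, nrow(pre), ncol(pre)) else
    (pre - rng[1L]) / diff(rng)
  S[mp, mp] <- norm
  S
}

#' Integrated dissimilarity between two genes
#'
#' `1 - (Multi-SIM + PPI-SIM + Seq-SIM) / 3`.  When the sequence
#' similarity is unavailable (either gene absent from the BLAST output),
#' it is replaced by the average of the other two components before the
#' dissimilarity is formed.
#'
#' @param multi_sim,ppi_sim GO and PPI similarity components in `[0, 1]`.
#' @param seq_sim Sequence similarity component in `[0, 1]`, or `NA` to
#'   trigger the fallback.
#' @return A scalar in `[0, 1]`.
#' @export
intdis <- function(multi_sim, ppi_sim, seq_sim = NA_real_) {
  if (is.na(seq_sim)) seq_sim <- (multi_sim + ppi_sim) / 2
  comps <- c(multi_sim, ppi_sim, seq_sim)
  if (any(comps < -1e-9) || any(comps > 1 + 1e-9))
    stop("similarity component outside [0, 1]")
  min(1, max(0, 1 - mean(comps)))
}

#' Build the integrated functional view (view 2)
#'
#' Pairwise integrated dissimilarity over a gene index: GO multi-factored
#' similarity, PPI neighbourhood similarity and BLAST sequence similarity
#' are combined per [intdis()].  The GO component is vectorized through a
#' term-by-term similarity matrix; annotation sets may span namespaces,
#' with cross-namespace term pairs contributing 0.
#'
#' @param ann Annotation map (named list gene -> term IDs).
#' @param go A [go_graph()] with IC computed.
#' @param net A [ppin()].
#' @param bits A [bitscore_matrix()], or NULL to use the fallback for all
#'   pairs.
#' @param gene_ids Gene index; every gene must be annotated.
#' @return A symmetric dissimilarity matrix with gene dimnames.
#' @export
build_view2 <- function(ann, go, net, bits, gene_ids) {
  missing_ann <- setdiff(gene_ids, names(ann))
  if (length(missing_ann))
    stop("unannotated gene(s) in index: ",
         paste(head(missing_ann, 5L), collapse = ", "))
  n <- length(gene_ids)
  if (n < 2L) stop("need at least two genes")

  # term-level similarity matrix over the terms actually used
  used <- sort(unique(unlist(ann[gene_ids], use.names = FALSE)))
  Ts <- matrix(0, length(used), length(used), dimnames = list(used, used))
  for (i in seq_along(used)) for (j in i:length(used)) {
    s <- multi_sim_terms(used[i], used[j], go)
    Ts[i, j] <- s; Ts[j, i] <- s
  }
  # gene x term indicator; double sum of Eq-style term pairs as G Ts G^T
  G <- matrix(0, n, length(used), dimnames = list(gene_ids, used))
  for (g in gene_ids) G[g, ann[[g]]] <- 1
  m <- rowSums(G)
  mean_term <- (G %*% Ts %*% t(G)) / outer(m, m)
  nto <- (G %*% t(G)) / outer(m, m, pmin)
  multi <- (mean_term + nto) / 2

  ppi <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  for (i in seq_len(n)) for (j in i:n) {
    s <- ppi_sim(gene_ids[i], gene_ids[j], net)
    ppi[i, j] <- s; ppi[j, i] <- s
  }

  seqs <- if (is.null(bits)) {
    matrix(NA_real_, n, n, dimnames = list(gene_ids, gene_ids))
  } else {
    seq_sim_matrix(bits)[gene_ids, gene_ids, drop = FALSE]
  }
  fb <- is.na(seqs)
  seqs[fb] <- ((multi + ppi) / 2)[fb]

  D <- 1 - (multi + ppi + seqs) / 3
  D[D < 0] <- 0; D[D > 1] <- 1
  diag(D) <- 0
  (D + t(D)) / 2
}
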