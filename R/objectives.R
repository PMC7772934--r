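#' Signal-to-noise ratio of a gene across two sample classes
#'
#' `|MN(CL1) - MN(CL2)| / (SD(CL1) + SD(CL2))` with population (1/N)
#' standard deviations; the denominator is guarded by `1e-12` for
#' degenerate genes.
#'
#' @param values Numeric vector of one gene's expression across samples.
#' @param labels Integer vector in `{1, 2}`, one per sample; both classes
#'   need at least two samples.
#' @return A non-negative scalar.
#' @export
snr <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  v1 <- values[labels == 1L]; v2 <- values[labels == 2L]
  if (length(v1) < 2L || length(v2) < 2L)
    stop("each class needs at least two samples")
  abs(mean(v1) - mean(v2)) / (pop_sd(v1) + pop_sd(v2) + 1e-12)
}

# Per-gene SNR vector, computed once per dataset and reused by every
# objective evaluation.
snr_all_genes <- function(expr, labels) {
  apply(expr$values, 1L, snr, labels = labels)
}

#' Average SNR of the consensus centers
#'
#' @param sol An `mv_solution` with consensus built.
#' @param snr_values Per-gene SNR vector aligned with the gene index.
#' @return Mean SNR over the consensus centers.
#' @export
avg_snr_of_centers <- function(sol, snr_values) {
  if (!length(sol$centers_cons)) stop("consensus not built")
  mean(snr_values[sol$centers_cons])
}

#' Average pairwise correlation distance among consensus centers
#'
#' Mean of the view-1 dissimilarity over all unordered pairs of consensus
#' centers.
#'
#' @param sol An `mv_solution` with consensus built.
#' @param D1 The view-1 (correlation distance) matrix.
#' @return A scalar in `[0, 1]`.
#' @export
avg_corr_dist_of_centers <- function(sol, D1) {
  ctr <- sol$centers_cons
  if (!length(ctr)) stop("consensus not built")
  if (length(ctr) < 2L) return(0)
  sub <- D1[ctr, ctr, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Agreement index between two partitions
#'
#' Co-assignment agreement over all `n^2` ordered gene pairs (diagonal
#' included; self-pairs always agree): with `A^v[i, j] = 1` iff genes i
#' and j share a cluster in partition v, `n_a` counts positions where the
#' two agreement matrices coincide, `n_d = n^2 - n_a`, and
#' `AI = (n_a + 1) / (n_d + 1)`.
#'
#' @param labels1,labels2 Integer label vectors over the same n genes.
#' @return A positive scalar.
#' @export
agreement_index <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop("partitions must cover the same genes")
  A1 <- outer(labels1, labels1, "==")
  A2 <- outer(labels2, labels2, "==")
  n_a <- sum(A1 == A2)
  n_d <- length(labels1)^2 - n_a
  (n_a + 1) / (n_d + 1)
}

#' Evaluate the three objectives of a multi-view solution
#'
#' Returns the maximization triple: average SNR of consensus centers,
#' average pairwise view-1 correlation distance among consensus centers,
#' and the agreement index between the two view partitions.
#'
#' @param sol An `mv_solution` with consensus built.
#' @param snr_values Per-gene SNR vector.
#' @param D1 The view-1 matrix.
#' @param objectives Character subset of `c("snr", "corrdist", "ai")`
#'   selecting which objectives to compute (all by default).
#' @return Named numeric vector with the selected objectives.
#' @export
evaluate_objectives <- function(sol, snr_values, D1,
                                objectives = c("snr", "corrdist", "ai")) {
  objectives <- match.arg(objectives, several.ok = TRUE)
  out <- c(
    snr = if ("snr" %in% objectives)
      avg_snr_of_centers(sol, snr_values) else NULL,
    corrdist = if ("corrdist" %in% objectives)
      avg_corr_dist_of_centers(sol, D1) else NULL,
    ai = if ("ai" %in% objectives)
      agreement_index(sol$labels1, sol$labels2) else NULL)
  out
}
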