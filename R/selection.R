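#' Majority-voting ensemble of the Pareto-front consensus partitions
#'
#' Builds the gene-pair co-association counts over the consensus
#' partitions of all archive members.  Pairs co-clustered in strictly
#' more than half of the solutions are linked; connected components of
#' the link graph (of size >= 2) become the ensemble clusters, each
#' centered on its medoid under the averaged views, and the remaining
#' genes join the center of minimum `(DView1 + DView2)/2` dissimilarity.
#' If the link graph is all singletons, the archive member of maximum
#' Silhouette (under the averaged views) is returned instead.
#'
#' @param archive Archive list from [anneal()]; each `sol` must be an
#'   `mv_solution` with consensus built.
#' @param D1,D2 The two view dissimilarity matrices.
#' @return List with `labels` (final partition), `centers` (candidate
#'   gene indices), `K`, `co_assoc` (count matrix), `fallback` (logical).
#' @export
ensemble_majority <- function(archive, D1, D2) {
  if (!length(archive)) stop("empty archive")
  n <- archive[[1L]]$sol$n
  Davg <- (D1 + D2) / 2
  co <- matrix(0L, n, n)
  for (e in archive) {
    l <- e$sol$labels_cons
    if (is.null(l)) stop("archive member without consensus partition")
    co <- co + outer(l, l, "==")
  }
  nsol <- length(archive)
  link <- co > nsol / 2
  diag(link) <- FALSE

  g <- igraph::graph_from_adjacency_matrix(link, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  real <- which(sizes >= 2L)
  if (!length(real)) {
    # degenerate link graph: fall back to the best-Silhouette member
    sil <- vapply(archive, function(e)
      internal_indices(e$sol$labels_cons, Davg)["silhouette"],
      numeric(1L))
    best <- archive[[which.max(sil)]]$sol
    return(list(labels = best$labels_cons, centers = best$centers_cons,
                K = best$K, co_assoc = co, fallback = TRUE))
  }

  labels <- rep(NA_integer_, n)
  for (k in seq_along(real))
    labels[comp$membership == real[k]] <- k
  centers <- vapply(seq_along(real), function(k) {
    members <- which(labels == k)
    if (length(members) == 1L) return(members)
    members[which.min(rowSums(Davg[members, members, drop = FALSE]))]
  }, integer(1L))
  un <- which(is.na(labels))
  if (length(un)) {
    dc <- Davg[un, centers, drop = FALSE]
    labels[un] <- max.col(-dc, ties.method = "first")
  }
  list(labels = as.integer(labels), centers = centers,
       K = length(real), co_assoc = co, fallback = FALSE)
}

#' Validate the clusters of a partition by silhouette width
#'
#' The default stand-in for per-cluster biological validation: a cluster
#' is valid when its mean silhouette width (under the supplied
#' dissimilarity) is positive, i.e. its members sit closer to their own
#' cluster than to any other.  Used by the selection pipeline to decide
#' whether an ensembled solution is acceptable or whether to fall back
#' to the best Pareto-front member.
#'
#' @param labels Integer label vector in `1..K`.
#' @param D Square dissimilarity matrix.
#' @param min_mean_sil Minimum per-cluster mean silhouette width
#'   (default 0).
#' @return Logical: TRUE when every cluster passes.
#' @export
clusters_valid <- function(labels, D, min_mean_sil = 0) {
  K <- max(labels)
  if (K < 2L) return(FALSE)
  n <- length(labels)
  sizes <- tabulate(labels, K)
  cl_sum <- matrix(0, n, K)
  for (k in seq_len(K))
    cl_sum[, k] <- rowSums(D[, labels == k, drop = FALSE])
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- labels[i]
    if (sizes[k] == 1L) next
    a <- cl_sum[i, k] / (sizes[k] - 1L)
    b <- min(cl_sum[i, -k] / sizes[-k])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  all(tapply(s, labels, mean) > min_mean_sil)
}

#' Extract candidate genes from an ensemble partition
#'
#' The ensemble cluster centers are the candidate genes; the reduced
#' expression matrix holds exactly their rows of the original matrix.
#'
#' @param ens Result of [ensemble_majority()].
#' @param expr The [expr_matrix()] whose row order matches the gene index
#'   the views were built on.
#' @return The reduced [expr_matrix()] (`n_c` rows).
#' @export
extract_candidates <- function(ens, expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  expr_matrix(expr$values[ens$centers, , drop = FALSE],
              expr$class_labels)
}

#' Intersect candidate sets across independent runs
#'
#' Genes appearing in every one of the `t` candidate sets are the
#' markers.  The saturation trace records the intersection after each
#' additional run, which is non-increasing in size; an empty final
#' intersection is a valid outcome and is reported with a warning.
#'
#' @param candidate_sets List of `t >= 2` character vectors of gene IDs.
#' @return List of class `marker_report` with `markers`, `set_sizes`,
#'   `saturation` (list of cumulative intersections) and `t`.
#' @export
markers_across_runs <- function(candidate_sets) {
  t <- length(candidate_sets)
  if (t < 2L) stop("need candidate sets from at least two runs")
  saturation <- Reduce(intersect, candidate_sets, accumulate = TRUE)[-1L]
  markers <- saturation[[length(saturation)]]
  if (!length(markers)) warning("empty marker intersection across runs")
  structure(list(markers = markers,
                 set_sizes = lengths(candidate_sets),
                 saturation = saturation, t = t),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("marker_report: %d marker(s) common to %d runs (set sizes: %s)\n",
              length(x$markers), x$t,
              paste(x$set_sizes, collapse = ", ")))
  if (length(x$markers))
    cat(" ", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' Regulation mode of a gene between two sample classes
#'
#' `"Up"` when the mean expression in the disease-designated class
#' exceeds the other class mean, `"Down"` otherwise; an exact tie is
#' reported as `"Up"` with a warning.
#'
#' @param values Numeric vector of one gene's expression.
#' @param labels Integer class labels in `{1, 2}`.
#' @param disease_class Which class represents the disease group
#'   (default 1).
#' @return `"Up"` or `"Down"`.
#' @export
regulation_mode <- function(values, labels, disease_class = 1L) {
  m_d <- mean(values[labels == disease_class])
  m_o <- mean(values[labels != disease_class])
  if (m_d == m_o) {
    warning("exactly equal class means; reporting Up")
    return("Up")
  }
  if (m_d > m_o) "Up" else "Down"
}

#' Internal cluster validity indices from a dissimilarity matrix
#'
#' Silhouette (singletons contribute 0), Davies-Bouldin with medoid
#' scatter (`S_k` = mean dissimilarity of members to the cluster medoid,
#' separation = medoid-medoid dissimilarity) and the Dunn index (minimum
#' between-cluster distance over maximum cluster diameter; a zero
#' diameter yields `Inf`).
#'
#' @param labels Integer label vector in `1..K`.
#' @param D Square dissimilarity matrix.
#' @return Named numeric vector `silhouette`, `db`, `dunn`.
#' @export
internal_indices <- function(labels, D) {
  K <- max(labels)
  if (K < 2L) stop("need at least two clusters")
  n <- length(labels)
  sizes <- tabulate(labels, K)
  if (any(sizes == 0L)) stop("empty cluster")

  # silhouette
  s <- numeric(n)
  cl_mean <- matrix(0, n, K)
  for (k in seq_len(K))
    cl_mean[, k] <- rowSums(D[, labels == k, drop = FALSE])
  for (i in seq_len(n)) {
    k <- labels[i]
    if (sizes[k] == 1L) { s[i] <- 0; next }
    a <- cl_mean[i, k] / (sizes[k] - 1L)
    b <- min(cl_mean[i, -k] / sizes[-k])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }

  # Davies-Bouldin (medoid formulation)
  medoids <- update_medoids(labels, D, K)
  S <- vapply(seq_len(K), function(k)
    mean(D[labels == k, medoids[k]]), numeric(1L))
  R <- vapply(seq_len(K), function(k) {
    vals <- vapply(setdiff(seq_len(K), k), function(l) {
      m <- D[medoids[k], medoids[l]]
      if (m == 0) Inf else (S[k] + S[l]) / m
    }, numeric(1L))
    max(vals)
  }, numeric(1L))

  # Dunn
  intra <- max(vapply(seq_len(K), function(k) {
    members <- which(labels == k)
    if (length(members) < 2L) 0 else
      max(D[members, members])
  }, numeric(1L)))
  inter <- min(vapply(seq_len(K - 1L), function(k) {
    min(vapply((k + 1L):K, function(l)
      min(D[labels == k, labels == l, drop = FALSE]), numeric(1L)))
  }, numeric(1L)))
  dunn <- if (intra == 0) Inf else inter / intra

  c(silhouette = mean(s), db = mean(R), dunn = dunn)
}

#' External classification indices for two-class partitions
#'
#' Clusters are mapped to the true classes by the accuracy-maximizing
#' permutation, then sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' F-score (harmonic mean of precision and sensitivity) and
#' classification accuracy `(TP+TN)/total` are computed with class 1 as
#' the positive class.
#'
#' @param predicted Integer predicted labels in `{1, 2}`.
#' @param truth Integer true labels in `{1, 2}`; both classes must occur.
#' @return Named numeric vector `sensitivity`, `specificity`, `f_score`,
#'   `ca`.
#' @export
external_indices <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (length(unique(truth)) < 2L) stop("one-class truth vector")
  acc <- function(p) mean(p == truth)
  swapped <- 3L - predicted
  if (acc(swapped) > acc(predicted)) predicted <- swapped
  tp <- sum(predicted == 1L & truth == 1L)
  fn <- sum(predicted == 2L & truth == 1L)
  tn <- sum(predicted == 2L & truth == 2L)
  fp <- sum(predicted == 1L & truth == 2L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  c(sensitivity = sens, specificity = spec, f_score = f,
    ca = (tp + tn) / length(truth))
}

#' Export a marker heatmap and its underlying matrix
#'
#' Writes the markers-by-samples expression matrix as TSV (samples
#' grouped by class, rows in marker-report order) and renders a
#' red-black-green heatmap (high expression red, low green) to an image
#' file next to it.
#'
#' @param markers Character vector of marker gene IDs.
#' @param expr An [expr_matrix()] containing the markers.
#' @param labels Integer sample class labels in `{1, 2}`.
#' @param path Output TSV path; the image uses the same stem with a
#'   `.pdf` (or `.png`) extension.
#' @param image_format `"pdf"` (default, always available) or `"png"`.
#' @return Invisible list with the `tsv` and `image` paths.
#' @export
heatmap_export <- function(markers, expr, labels, path,
                           image_format = c("pdf", "png")) {
  stopifnot(length(markers) >= 1L, all(markers %in% expr$gene_ids))
  image_format <- match.arg(image_format)
  ord <- order(labels)
  mat <- expr$values[markers, ord, drop = FALSE]
  out <- cbind(data.frame(gene_id = rownames(mat)), as.data.frame(mat))
  write_tsv_meta(out, path)

  img <- sub("\\.[^.]*$", paste0(".", image_format), path)
  pal <- grDevices::colorRampPalette(c("green", "black", "red"))(64L)
  if (image_format == "pdf") grDevices::pdf(img, width = 7, height = 5)
  else grDevices::png(img, width = 700, height = 500)
  op <- graphics::par(mar = c(4, 6, 2, 1))
  graphics::image(t(mat)[, rev(seq_len(nrow(mat))), drop = FALSE],
                  col = pal, axes = FALSE,
                  xlab = "samples (grouped by class)", ylab = "")
  graphics::axis(2L, at = seq(1, 0, length.out = nrow(mat)),
                 labels = rownames(mat), las = 2, cex.axis = 0.7)
  graphics::par(op)
  grDevices::dev.off()
  invisible(list(tsv = path, image = img))
}
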