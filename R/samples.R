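#' Correlation-distance matrix between samples
#'
#' Pairwise signed correlation distance `(1 - cor)/2` between sample
#' expression profiles (columns).  Unlike the gene view, the sample
#' stage keeps the correlation sign: two anti-correlated samples are
#' maximally different for class discovery, whereas the absolute
#' correlation distance would treat them as identical.
#'
#' @param expr An [expr_matrix()].
#' @return A d x d symmetric dissimilarity matrix in `[0, 1]` with
#'   sample dimnames.
#' @export
sample_dissimilarity <- function(expr) {
  v <- expr$values
  d <- ncol(v)
  if (d < 2L) stop("need at least two samples")
  sds <- apply(v, 2L, pop_sd)
  D <- matrix(1, d, d, dimnames = list(colnames(v), colnames(v)))
  ok <- sds > 1e-12
  if (any(ok)) {
    C <- suppressWarnings(cor(v[, ok, drop = FALSE]))
    D[ok, ok] <- (1 - C) / 2
  }
  D[D < 0] <- 0; D[D > 1] <- 1
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Default annealing schedule for the sample-clustering stage
#'
#' The sample stage searches K-medoid partitions of a few dozen
#' samples, a far smaller space than the gene stage, so it uses a
#' shorter geometric schedule (31 stages of 20 generations, 20 initial
#' solutions) with the same acceptance rules.
#'
#' @return An [anneal_config()].
#' @export
sample_anneal_config <- function() {
  anneal_config(t_max = 100, t_min = 0.1, alpha = 0.8,
                total_iter = 20L, sl = 40L, hl = 20L, p = 20L)
}

# Single-view medoid solution over a dissimilarity matrix: centers +
# nearest-center labels, with one k-medoids convergence pass at init.
sv_solution <- function(centers, D, medoid_update = FALSE) {
  labels <- assign_noncenters(centers, D)
  if (medoid_update) {
    centers <- update_medoids(labels, D, length(centers))
    labels <- assign_noncenters(centers, D)
  }
  list(centers = as.integer(centers), labels = labels)
}

#' Cluster samples by single-view multi-objective annealing
#'
#' Medoid clustering of the sample columns under correlation distance
#' between sample profiles, optimized by the same archived
#' multi-objective annealer as the gene stage with two internal
#' objectives: maximize the Silhouette index and minimize the
#' Davies-Bouldin index.  `K` is fixed (the perturbation operator swaps
#' one randomly chosen center for a random non-center sample).  The
#' archive solution of maximum Silhouette is returned.
#'
#' @param expr An [expr_matrix()].
#' @param K Number of sample clusters (default 2, the two-class setting).
#' @param cfg An [anneal_config()]; the default is a shorter schedule
#'   than the gene stage (see [sample_anneal_config()]) because the
#'   K-medoid search space over tens of samples is small.
#' @return List with `labels`, `centers`, `silhouette`, `db` and the
#'   final `archive`.
#' @export
cluster_samples <- function(expr, K = 2L, cfg = sample_anneal_config()) {
  D <- sample_dissimilarity(expr)
  d <- ncol(D)
  if (d < 2L * K) stop("need at least 2K samples")

  eval_fun <- function(sol) {
    idx <- internal_indices(sol$labels, D)
    db <- unname(idx["db"])
    # coincident medoids make DB infinite; clamp so objective vectors
    # (and domination amounts) stay finite
    if (!is.finite(db)) db <- 1e6
    c(silhouette = unname(idx["silhouette"]), neg_db = -db)
  }
  init_fun <- function() sv_solution(sample.int(d, K), D,
                                     medoid_update = TRUE)
  perturb_fun <- function(sol) {
    ctr <- sol$centers
    j <- rand_int(K)
    pool <- setdiff(seq_len(d), ctr)
    ctr[j] <- pool[rand_int(length(pool))]
    sv_solution(ctr, D)
  }
  res <- anneal(init_fun, perturb_fun, eval_fun, cfg)
  sil <- vapply(res$archive, function(e) e$obj[["silhouette"]],
                numeric(1L))
  best <- res$archive[[which.max(sil)]]
  list(labels = best$sol$labels, centers = best$sol$centers,
       silhouette = best$obj[["silhouette"]],
       db = -best$obj[["neg_db"]], archive = res$archive)
}

#' Pre-cluster samples into two groups for SNR labels
#'
#' The unsupervised stand-in for class labels: samples are clustered into
#' exactly two groups by [cluster_samples()] on correlation distance over
#' all genes.  The grouping is computed once per dataset and cached on
#' the expression object by the pipeline drivers.  User-supplied labels
#' (the `class_labels` field) take precedence when `use_known = TRUE`.
#'
#' @param expr An [expr_matrix()].
#' @param cfg An [anneal_config()] for the sample-clustering run.
#' @param use_known If TRUE and `expr$class_labels` is set, return those
#'   labels instead of pre-clustering.
#' @return Integer vector of labels in `{1, 2}`, both classes non-empty.
#' @export
preclass_samples <- function(expr, cfg = sample_anneal_config(),
                             use_known = FALSE) {
  if (use_known && !is.null(expr$class_labels))
    return(expr$class_labels)
  res <- cluster_samples(expr, K = 2L, cfg = cfg)
  labels <- res$labels
  if (length(unique(labels)) < 2L)
    stop("degenerate one-group pre-clustering outcome")
  labels
}
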