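#' Multi-view clustering solution
#'
#' A solution encodes, for a shared cluster count `K`, three medoid center
#' vectors (view 1, view 2 and their consensus) as positional gene
#' indices, plus the three induced partitions as integer label vectors.
#' Binary membership matrices are derived views of the labels (see
#' [membership_matrix()]).
#'
#' @name mv_solution
#' @keywords internal
NULL

new_mv_solution <- function(n, K, centers1, centers2,
                            labels1 = NULL, labels2 = NULL,
                            centers_cons = NULL, labels_cons = NULL) {
  structure(list(n = n, K = K,
                 centers1 = as.integer(centers1),
                 centers2 = as.integer(centers2),
                 centers_cons = if (is.null(centers_cons)) integer() else
                   as.integer(centers_cons),
                 labels1 = labels1, labels2 = labels2,
                 labels_cons = labels_cons),
            class = "mv_solution")
}

#' @export
print.mv_solution <- function(x, ...) {
  cat(sprintf("mv_solution: n=%d, K=%d, consensus %s\n", x$n, x$K,
              if (length(x$centers_cons)) "built" else "pending"))
  invisible(x)
}

#' Membership matrix of a partition
#'
#' @param labels Integer label vector in `1..K`.
#' @param K Number of clusters.
#' @return A K x n binary matrix with one-hot columns.
#' @export
membership_matrix <- function(labels, K) {
  n <- length(labels)
  mm <- matrix(0L, K, n)
  mm[cbind(labels, seq_len(n))] <- 1L
  mm
}

# Internal invariant check used by tests and defensive callers.
validate_solution <- function(sol) {
  stopifnot(inherits(sol, "mv_solution"))
  kmax <- floor(sqrt(sol$n))
  if (sol$K < 2L || sol$K > kmax) stop("K outside [2, floor(sqrt(n))]")
  for (ctr in list(sol$centers1, sol$centers2)) {
    if (length(ctr) != sol$K) stop("center vector length != K")
    if (anyDuplicated(ctr)) stop("duplicate centers within a view")
    if (any(ctr < 1L | ctr > sol$n)) stop("center index out of range")
  }
  for (nm in c("labels1", "labels2", "labels_cons")) {
    lab <- sol[[nm]]
    if (is.null(lab)) next
    if (length(lab) != sol$n) stop(nm, " has wrong length")
    if (any(lab < 1L | lab > sol$K)) stop(nm, " outside 1..K")
  }
  if (!is.null(sol$labels1) &&
      any(sol$labels1[sol$centers1] != seq_len(sol$K)))
    stop("view-1 centers not members of their own clusters")
  if (!is.null(sol$labels2) &&
      any(sol$labels2[sol$centers2] != seq_len(sol$K)))
    stop("view-2 centers not members of their own clusters")
  if (length(sol$centers_cons) &&
      any(sol$labels_cons[sol$centers_cons] != seq_len(sol$K)))
    stop("consensus centers not members of their own clusters")
  invisible(sol)
}

#' Draw an initial cluster count
#'
#' `K = (r mod (floor(sqrt(n)) - 1)) + 2` with `r` a uniform random
#' integer, so `K` is uniform on `[2, floor(sqrt(n))]`.
#'
#' @param n Number of genes (>= 4 so the range is non-empty).
#' @return An integer cluster count.
#' @export
init_cluster_count <- function(n) {
  if (n < 4L) stop("need n >= 4 for a valid cluster-count range")
  kmax <- floor(sqrt(n))
  (rand_int(kmax - 1L) - 1L) + 2L
}

#' Assign non-center genes to their nearest center
#'
#' Minimum-dissimilarity assignment under one view; exact ties go to the
#' lowest cluster index, and each center belongs to its own cluster.
#'
#' @param centers Integer vector of distinct center gene indices.
#' @param D Square dissimilarity matrix of the view.
#' @return Integer label vector in `1..length(centers)`.
#' @export
assign_noncenters <- function(centers, D) {
  if (anyDuplicated(centers)) stop("centers must be distinct")
  dc <- D[, centers, drop = FALSE]
  labels <- max.col(-dc, ties.method = "first")
  labels[centers] <- seq_along(centers)
  as.integer(labels)
}

#' Replace centers by cluster medoids
#'
#' Per cluster, returns the member with minimum average dissimilarity to
#' its co-members; singletons keep their sole member and ties go to the
#' lowest gene index.
#'
#' @param labels Integer label vector in `1..K`.
#' @param D Square dissimilarity matrix.
#' @param K Number of clusters (defaults to `max(labels)`).
#' @return Integer vector of K medoid gene indices.
#' @export
update_medoids <- function(labels, D, K = max(labels)) {
  vapply(seq_len(K), function(k) {
    members <- which(labels == k)
    if (!length(members)) stop("empty cluster ", k)
    if (length(members) == 1L) return(members)
    sums <- rowSums(D[members, members, drop = FALSE])
    members[which.min(sums)]
  }, integer(1L))
}

# Assign every gene to its nearest center under D, ties to the lowest
# cluster index, centers pinned to their own cluster.
assign_full <- function(centers, D) {
  assign_noncenters(centers, D)
}

#' Build the consensus partition of a multi-view solution
#'
#' Three steps: (1) view-1 clusters, in index order, each greedily take
#' the not-yet-matched view-2 cluster of maximal overlap (ties to the
#' lowest view-2 index); the intersection seeds a consensus cluster, or
#' the view-1 cluster's medoid when the intersection is empty so `K` is
#' preserved.  (2) Each seed's center is the member with minimum average
#' pairwise dissimilarity to co-members under the average of the two
#' views.  (3) Every unallocated gene joins the consensus center of
#' minimum `(DView1 + DView2)/2` dissimilarity.
#'
#' @param sol An `mv_solution` with both view partitions populated.
#' @param D1,D2 The two view dissimilarity matrices.
#' @param Davg Optional precomputed `(D1 + D2) / 2`, to avoid repeated
#'   allocation in tight optimizer loops.
#' @return The solution with `centers_cons` and `labels_cons` filled.
#' @export
build_consensus <- function(sol, D1, D2, Davg = NULL) {
  K <- sol$K; n <- sol$n
  l1 <- sol$labels1; l2 <- sol$labels2
  if (is.null(l1) || is.null(l2)) stop("view partitions not populated")
  if (is.null(Davg)) Davg <- (D1 + D2) / 2

  matched2 <- integer(0)
  seeds <- vector("list", K)
  for (i in seq_len(K)) {
    mem1 <- which(l1 == i)
    avail <- setdiff(seq_len(K), matched2)
    overlap <- vapply(avail, function(j) sum(l2[mem1] == j), integer(1L))
    j <- avail[which.max(overlap)]   # first max = lowest view-2 index
    matched2 <- c(matched2, j)
    seed <- mem1[l2[mem1] == j]
    if (!length(seed)) {
      # empty intersection: reseed from the view-1 cluster's medoid
      seed <- update_medoids(l1, D1, K)[i]
    }
    seeds[[i]] <- seed
  }

  centers <- vapply(seq_len(K), function(i) {
    s <- seeds[[i]]
    if (length(s) == 1L) return(s)
    s[which.min(rowSums(Davg[s, s, drop = FALSE]))]
  }, integer(1L))

  labels <- rep(NA_integer_, n)
  for (i in seq_len(K)) labels[seeds[[i]]] <- i
  un <- which(is.na(labels))
  if (length(un)) {
    dc <- Davg[un, centers, drop = FALSE]
    labels[un] <- max.col(-dc, ties.method = "first")
  }
  labels[centers] <- seq_len(K)

  sol$centers_cons <- centers
  sol$labels_cons <- as.integer(labels)
  sol
}

#' Initialize a random multi-view solution
#'
#' Draws one shared cluster count `K` (see [init_cluster_count()]) and two
#' independent sets of `K` distinct random centers, assigns non-centers in
#' each view, replaces centers by cluster medoids, reassigns, and builds
#' the consensus.
#'
#' @param D1,D2 The two view dissimilarity matrices.
#' @param Davg Optional precomputed `(D1 + D2) / 2`.
#' @return A complete `mv_solution`.
#' @export
init_solution <- function(D1, D2, Davg = NULL) {
  n <- nrow(D1)
  K <- init_cluster_count(n)
  centers1 <- sample.int(n, K)
  centers2 <- sample.int(n, K)
  finalize_solution(n, K, centers1, centers2, D1, D2,
                    medoid_update = TRUE, Davg = Davg)
}

# Common tail: assignment (optionally with a medoid-update pass) and
# consensus construction from given center vectors.
finalize_solution <- function(n, K, centers1, centers2, D1, D2,
                              medoid_update = FALSE, Davg = NULL) {
  l1 <- assign_noncenters(centers1, D1)
  l2 <- assign_noncenters(centers2, D2)
  if (medoid_update) {
    centers1 <- update_medoids(l1, D1, K)
    centers2 <- update_medoids(l2, D2, K)
    l1 <- assign_noncenters(centers1, D1)
    l2 <- assign_noncenters(centers2, D2)
  }
  sol <- new_mv_solution(n, K, centers1, centers2, l1, l2)
  build_consensus(sol, D1, D2, Davg)
}

# Nearest non-center gene to a given center under D; ties to the lowest
# gene index.
nearest_noncenter <- function(center, centers, D) {
  pool <- setdiff(seq_len(nrow(D)), centers)
  pool[which.min(D[center, pool])]
}

#' Perturb a multi-view solution
#'
#' Three operator kinds: `update` replaces a randomly chosen center in
#' each view by its minimum-dissimilarity non-center gene (or all centers
#' when `update_all = TRUE`); `insert` appends one random non-center gene
#' as a new center in each view (requires `K + 1 <= floor(sqrt(n))`);
#' `delete` removes one random center in each view (requires `K >= 3`).
#' When `kind` is NULL one of the three is drawn uniformly; an illegal
#' draw is resampled among the legal operators.  Memberships of both
#' views are recomputed and the consensus rebuilt afterwards.
#'
#' @param sol An `mv_solution`.
#' @param D1,D2 The two view dissimilarity matrices.
#' @param kind One of `"update"`, `"insert"`, `"delete"`, or NULL to draw
#'   at random.
#' @param update_all Replace every center during `update` instead of one.
#' @param Davg Optional precomputed `(D1 + D2) / 2`.
#' @return A new, fully rebuilt `mv_solution`.
#' @export
perturb <- function(sol, D1, D2, kind = NULL, update_all = FALSE,
                    Davg = NULL) {
  n <- sol$n; K <- sol$K
  kmax <- floor(sqrt(n))
  legal <- c("update",
             if (K + 1L <= kmax) "insert",
             if (K >= 3L) "delete")
  if (is.null(kind))
    kind <- c("update", "insert", "delete")[rand_int(3L)]
  if (!(kind %in% legal)) kind <- legal[rand_int(length(legal))]

  c1 <- sol$centers1; c2 <- sol$centers2
  if (kind == "update") {
    for (v in 1:2) {
      ctr <- if (v == 1L) c1 else c2
      D <- if (v == 1L) D1 else D2
      idx <- if (update_all) seq_len(K) else rand_int(K)
      for (j in idx) ctr[j] <- nearest_noncenter(ctr[j], ctr, D)
      if (v == 1L) c1 <- ctr else c2 <- ctr
    }
    Knew <- K
  } else if (kind == "insert") {
    pool1 <- setdiff(seq_len(n), c1)
    pool2 <- setdiff(seq_len(n), c2)
    c1 <- c(c1, pool1[rand_int(length(pool1))])
    c2 <- c(c2, pool2[rand_int(length(pool2))])
    Knew <- K + 1L
  } else {
    c1 <- c1[-rand_int(K)]
    c2 <- c2[-rand_int(K)]
    Knew <- K - 1L
  }
  finalize_solution(n, Knew, c1, c2, D1, D2, Davg = Davg)
}
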