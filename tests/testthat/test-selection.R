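# helper: wrap a labels vector as an archive entry with consensus filled
as_entry <- function(labels, D) {
  K <- max(labels)
  centers <- update_medoids(labels, D, K)
  sol <- mvmarker:::new_mv_solution(length(labels), K, centers, centers,
                                    labels, labels, centers, labels)
  list(sol = sol, obj = c(0, 0, 0))
}

test_that("an archive of identical partitions ensembles to itself", {
  set.seed(81)
  D <- block_view(c(4, 4))
  lab <- rep(1:2, each = 4L)
  arch <- replicate(3, as_entry(lab, D), simplify = FALSE)
  ens <- ensemble_majority(arch, D, D)
  expect_equal(ens$K, 2L)
  expect_true(all(outer(ens$labels, ens$labels, "==") ==
                    outer(lab, lab, "==")))
})

test_that("a pair co-clustered in 2 of 3 solutions is linked", {
  set.seed(82)
  D <- random_view(6)
  l1 <- c(1L, 1L, 2L, 2L, 1L, 2L)
  l2 <- c(1L, 1L, 2L, 2L, 2L, 1L)
  l3 <- c(1L, 2L, 1L, 2L, 1L, 2L)
  arch <- lapply(list(l1, l2, l3), as_entry, D = D)
  ens <- ensemble_majority(arch, D, D)
  # genes 1 and 2 share a cluster in l1 and l2 (2/3 > 1/2)
  expect_equal(ens$labels[1L], ens$labels[2L])
  expect_equal(ens$co_assoc[1L, 2L], 2L)
})

test_that("ensemble components equal the brute-force majority closure", {
  set.seed(83)
  for (trial in 1:20) {
    n <- 10L
    D <- random_view(n)
    arch <- lapply(1:5, function(i)
      as_entry(random_partition(n, sample(2:3, 1L)), D))
    ens <- ensemble_majority(arch, D, D)
    co <- Reduce(`+`, lapply(arch, function(e)
      outer(e$sol$labels_cons, e$sol$labels_cons, "==") * 1L))
    link <- co > length(arch) / 2
    diag(link) <- FALSE
    # transitive closure by repeated boolean multiplication
    reach <- link | diag(n) > 0
    repeat {
      nxt <- (reach %*% reach) > 0
      if (all(nxt == reach)) break
      reach <- nxt
    }
    if (ens$fallback) next  # all-singleton graphs fall back
    comp_sizes <- rowSums(reach)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp_sizes[i] >= 2L && comp_sizes[j] >= 2L) {
        # genes in one closure component share an ensemble cluster
        if (reach[i, j])
          expect_equal(ens$labels[i], ens$labels[j])
      }
    }
  }
})

test_that("candidate extraction slices the original expression rows", {
  set.seed(84)
  ex <- toy_expr(matrix(rnorm(60), 10, 6))
  ens <- list(centers = c(2L, 7L, 9L), K = 3L)
  red <- extract_candidates(ens, ex)
  expect_equal(dim(red)[1L], 3L)
  expect_true(all(red$gene_ids %in% ex$gene_ids))
  expect_identical(red$values, ex$values[c(2L, 7L, 9L), ])
  expect_lt(dim(red)[1L], dim(ex)[1L])
})

test_that("markers are the run-order-invariant intersection", {
  sets <- list(c("a", "b", "c"), c("a", "b"), c("a", "b", "d"))
  rep1 <- markers_across_runs(sets)
  expect_setequal(rep1$markers, c("a", "b"))
  rep2 <- markers_across_runs(rev(sets))
  expect_setequal(rep1$markers, rep2$markers)
  expect_error(markers_across_runs(sets[1L]), "two runs")
  # saturation trace sizes are non-increasing
  expect_true(all(diff(lengths(rep1$saturation)) <= 0))
  expect_warning(markers_across_runs(list("x", "y")), "empty marker")
})

test_that("regulation mode compares class means", {
  lab <- c(1L, 1L, 2L, 2L)
  expect_equal(regulation_mode(c(5, 5, 1, 1), lab), "Up")
  expect_equal(regulation_mode(c(1, 1, 5, 5), lab), "Down")
  expect_warning(m <- regulation_mode(c(3, 3, 3, 3), lab), "equal")
  expect_equal(m, "Up")
  # configurable disease class flips the call
  expect_equal(regulation_mode(c(5, 5, 1, 1), lab, disease_class = 2L),
               "Down")
})

test_that("silhouette matches the 1-D hand computation", {
  x <- c(0, 0.1, 10, 10.1)
  D <- as.matrix(dist(x))
  lab <- c(1L, 1L, 2L, 2L)
  idx <- internal_indices(lab, D)
  # point 1: a = 0.1, b = (10 + 10.1)/2 = 10.05 -> (10.05-0.1)/10.05;
  # inner points have b = 9.95, and the four widths average to 0.99
  s1 <- (10.05 - 0.1) / 10.05
  s2 <- (9.95 - 0.1) / 9.95
  expect_equal(round(s1, 3), 0.990)
  expect_equal(bf_silhouette(lab, D), idx[["silhouette"]])
  expect_equal(idx[["silhouette"]], mean(c(s1, s2, s2, s1)),
               tolerance = 1e-12)
  expect_gt(idx[["dunn"]], 1)
})

test_that("internal indices equal brute-force references", {
  set.seed(85)
  for (trial in 1:30) {
    D <- random_view(10)
    lab <- random_partition(10, sample(2:3, 1L))
    idx <- internal_indices(lab, D)
    expect_equal(idx[["silhouette"]], bf_silhouette(lab, D),
                 tolerance = 1e-12)
    expect_equal(idx[["dunn"]], bf_dunn(lab, D), tolerance = 1e-12)
    # medoid Davies-Bouldin reference
    K <- max(lab)
    med <- bf_medoids(lab, D)
    S <- vapply(1:K, function(k) mean(D[lab == k, med[k]]), numeric(1))
    R <- vapply(1:K, function(k)
      max(vapply(setdiff(1:K, k), function(l)
        (S[k] + S[l]) / D[med[k], med[l]], numeric(1))), numeric(1))
    expect_equal(idx[["db"]], mean(R), tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster package on Euclidean data", {
  skip_if_not_installed("cluster")
  set.seed(86)
  x <- matrix(rnorm(30), 15, 2)
  D <- as.matrix(dist(x))
  lab <- random_partition(15, 3L)
  ref <- mean(cluster::silhouette(lab, dist(x))[, "sil_width"])
  expect_equal(internal_indices(lab, D)[["silhouette"]], ref,
               tolerance = 1e-12)
})

test_that("degenerate identical clusters give an infinite Dunn index", {
  D <- matrix(0, 4, 4)
  D[1:2, 3:4] <- 1; D[3:4, 1:2] <- 1
  idx <- internal_indices(c(1L, 1L, 2L, 2L), D)
  expect_equal(idx[["dunn"]], Inf)
})

test_that("external indices follow the confusion-matrix arithmetic", {
  # TP 9, FN 1, TN 8, FP 2
  truth <- rep(c(1L, 2L), c(10L, 10L))
  pred <- c(rep(1L, 9L), 2L, rep(2L, 8L), 1L, 1L)
  idx <- external_indices(pred, truth)
  expect_equal(unname(idx["sensitivity"]), 0.9)
  expect_equal(unname(idx["specificity"]), 0.8)
  expect_equal(unname(idx["f_score"]),
               2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9))
  expect_equal(round(unname(idx["f_score"]), 3), 0.857)
  expect_equal(unname(idx["ca"]), 0.85)
  # perfect and label-swapped perfect predictions both score 1
  expect_true(all(external_indices(truth, truth) == 1))
  expect_true(all(external_indices(3L - truth, truth) == 1))
  expect_error(external_indices(pred, rep(1L, 20L)), "one-class")
})

test_that("cluster validity requires positive per-cluster silhouette", {
  D <- block_view(c(5, 5), within = 0.05, between = 0.9)
  good <- rep(1:2, each = 5L)
  expect_true(clusters_valid(good, D))
  bad <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)  # mixes the blocks
  expect_false(clusters_valid(bad, D))
})

test_that("heatmap export writes the marker matrix as TSV", {
  set.seed(87)
  ex <- toy_expr(matrix(rnorm(30), 3, 10))
  lab <- rep(c(2L, 1L), each = 5L)
  markers <- ex$gene_ids[c(3L, 1L)]
  tsv <- withr::local_tempfile(fileext = ".tsv")
  out <- heatmap_export(markers, ex, lab, tsv)
  expect_true(file.exists(out$tsv))
  expect_true(file.exists(out$image))
  got <- read.table(tsv, sep = "\t", header = TRUE, skip = 1L)
  expect_equal(got$gene_id, markers)     # rows in marker order
  expect_equal(ncol(got), 11L)
  # samples grouped by class: class-1 columns first
  expect_equal(names(got)[2:6], ex$sample_ids[lab == 1L])
})
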