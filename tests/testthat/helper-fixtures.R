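# Shared fixture builders: everything is generated in code at test time.

# Small expression matrix with named genes/samples.
toy_expr <- function(values, class_labels = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expr_matrix(values, class_labels)
}

# Five-term toy ontology: root, two children, two grandchildren.
toy_go <- function() {
  terms <- c("GO:0000001", "GO:0000002", "GO:0000003",
             "GO:0000004", "GO:0000005")
  parents <- list("GO:0000001" = character(),
                  "GO:0000002" = "GO:0000001",
                  "GO:0000003" = "GO:0000001",
                  "GO:0000004" = "GO:0000002",
                  "GO:0000005" = "GO:0000003")
  go_graph(terms, parents,
           setNames(rep("biological_process", 5L), terms))
}

# Annotation map over the toy ontology covering all five terms.
toy_ann <- function() {
  list(gA = c("GO:0000004"),
       gB = c("GO:0000005"),
       gC = c("GO:0000002", "GO:0000003"),
       gD = c("GO:0000004", "GO:0000005"),
       gE = c("GO:0000001"))
}

# Random symmetric dissimilarity matrix with zero diagonal in [0, 1].
random_view <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(sprintf("g%02d", seq_len(n)),
                      sprintf("g%02d", seq_len(n)))
  m
}

# Block-structured view: small within-block, large between-block
# dissimilarity plus jitter.
block_view <- function(block_sizes, within = 0.1, between = 0.8,
                       jitter = 0.02) {
  lab <- rep(seq_along(block_sizes), block_sizes)
  n <- length(lab)
  m <- ifelse(outer(lab, lab, "=="), within, between) +
    matrix(runif(n * n, 0, jitter), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Brute-force references ------------------------------------------------

# Exhaustive nearest-center assignment.
bf_assign <- function(centers, D) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    if (i %in% centers) return(match(i, centers))
    which.min(D[i, centers])
  }, integer(1L))
}

# Exhaustive medoid scan.
bf_medoids <- function(labels, D) {
  vapply(seq_len(max(labels)), function(k) {
    members <- which(labels == k)
    means <- vapply(members, function(g)
      mean(D[g, setdiff(members, g)]), numeric(1L))
    if (length(members) == 1L) return(members)
    members[which.min(means)]
  }, integer(1L))
}

# Exhaustive pairwise correlation-distance matrix.
bf_view1 <- function(values) {
  n <- nrow(values)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) m[i, j] <- correlation_distance(values[i, ], values[j, ])
  m
}

# Exhaustive silhouette from a dissimilarity matrix.
bf_silhouette <- function(labels, D) {
  n <- length(labels)
  mean(vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k)
      mean(D[i, labels == k]), numeric(1L)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1L)))
}

# Exhaustive Dunn index.
bf_dunn <- function(labels, D) {
  ks <- unique(labels)
  intra <- max(vapply(ks, function(k) {
    m <- which(labels == k)
    if (length(m) < 2L) 0 else max(D[m, m])
  }, numeric(1L)))
  inter <- min(apply(expand.grid(ks, ks), 1L, function(p) {
    if (p[1L] >= p[2L]) return(Inf)
    min(D[labels == p[1L], labels == p[2L]])
  }))
  if (intra == 0) Inf else inter / intra
}

# Random valid partition with every label used.
random_partition <- function(n, K) {
  repeat {
    lab <- sample.int(K, n, replace = TRUE)
    if (length(unique(lab)) == K) return(lab)
  }
}
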