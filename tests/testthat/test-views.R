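test_that("correlation distance matches hand-computed values", {
  x <- c(1, 2, 3)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, -x), 0)     # absolute correlation
  expect_equal(correlation_distance(x, c(1, 3, 2)), 0.5)  # phi = 0.5
  expect_equal(correlation_distance(x, c(5, 5, 5)), 1)    # constant
  expect_error(correlation_distance(x, c(1, 2)), "equal length")
})

test_that("view 1 equals the entry-by-entry brute-force loop", {
  set.seed(21)
  ex <- toy_expr(matrix(rnorm(50), 5, 10))
  D <- build_view1(ex)
  expect_equal(unname(D), bf_view1(ex$values), tolerance = 1e-12)
  expect_equal(D, t(D), tolerance = 1e-12)
  expect_true(all(diag(D) == 0))
  # identical gene rows are at distance 0
  ex2 <- toy_expr(rbind(a = 1:6, b = 1:6, c = rnorm(6)))
  expect_equal(build_view1(ex2)["a", "b"], 0)
})

test_that("term similarity respects the arctan normalization bounds", {
  go <- compute_ic(toy_go(), toy_ann())
  # same term with positive IC: Y > 0 so sim in (0, 1)
  s_self <- multi_sim_terms("GO:0000004", "GO:0000004", go)
  expect_gt(s_self, 0); expect_lt(s_self, 1)
  # closed form: Y = 1 maps to arctan(1)/(pi/2) = 0.5
  expect_equal(atan(1) / (pi / 2), 0.5)
  # root against itself: Lin 0 (IC 0), Shen 1 (no positive-IC path),
  # depth 0 -> Y = 1 -> 0.5
  expect_equal(multi_sim_terms("GO:0000001", "GO:0000001", go), 0.5)
  # monotone increasing in Y: deeper shared ancestry scores higher
  s_sib <- multi_sim_terms("GO:0000004", "GO:0000005", go)
  expect_gt(s_self, s_sib)
})

test_that("cross-namespace terms have similarity zero", {
  terms <- c("A", "B")
  go <- go_graph(terms, list(A = character(), B = character()),
                 c(A = "biological_process", B = "molecular_function"))
  go$ic <- c(A = 1, B = 1)
  expect_equal(multi_sim_terms("A", "B", go), 0)
})

test_that("gene-level similarity equals the exhaustive double sum", {
  go <- compute_ic(toy_go(), toy_ann())
  ann <- toy_ann()
  # 2x2 term case: gC = {2,3}, gD = {4,5}
  s <- 0
  for (t1 in ann$gC) for (t2 in ann$gD)
    s <- s + multi_sim_terms(t1, t2, go)
  nto <- length(intersect(ann$gC, ann$gD)) /
    min(length(ann$gC), length(ann$gD))
  expect_equal(multi_sim_genes("gC", "gD", ann, go), (s / 4 + nto) / 2)
  # m = n = 1 identical annotation: (s_self + 1) / 2
  s_self <- multi_sim_terms("GO:0000004", "GO:0000004", go)
  expect_equal(multi_sim_genes("gA", "gA", ann, go), (s_self + 1) / 2)
  expect_error(multi_sim_genes("gA", "gZ", ann, go), "unannotated")
})

test_that("PPI similarity matches the weighted-overlap formula", {
  edges <- data.frame(protein_a = c("pi", "pj", "pj"),
                      protein_b = c("pk", "pk", "pm"),
                      score = c(0.5, 1.0, 0.5))
  net <- ppin(edges, c(gi = "pi", gj = "pj", gk = "pk", gm = "pm"))
  # N_i = {k: 0.5}; N_j = {k: 1.0, m: 0.5} -> 0.5 / (1.0 + 0.5)
  expect_equal(ppi_sim("gi", "gj", net), 0.5 / 1.5)
  # identical neighborhoods and weights -> 1; self -> 1
  net2 <- ppin(data.frame(protein_a = c("pa", "pb"),
                          protein_b = c("pc", "pc"),
                          score = c(0.7, 0.7)),
               c(ga = "pa", gb = "pb"))
  expect_equal(ppi_sim("ga", "gb", net2), 1)
  expect_equal(ppi_sim("ga", "ga", net2), 1)
  # disjoint neighborhoods -> 0
  net3 <- ppin(data.frame(protein_a = c("pa", "pb"),
                          protein_b = c("pc", "pd"),
                          score = c(0.7, 0.7)),
               c(ga = "pa", gb = "pb"))
  expect_equal(ppi_sim("ga", "gb", net3), 0)
})

test_that("sequence similarity log-averages and min-max normalizes", {
  g2p <- c(g1 = "p1", g2 = "p2", g3 = "p3")
  raw <- matrix(0, 3, 3, dimnames = list(unname(g2p), unname(g2p)))
  # averages chosen so pre-normalization log10 values are {2, 4, 6}
  raw["p1", "p2"] <- raw["p2", "p1"] <- 100      # log10 = 2
  raw["p1", "p3"] <- raw["p3", "p1"] <- 1e4      # log10 = 4
  raw["p2", "p3"] <- raw["p3", "p2"] <- 1e6      # log10 = 6
  diag(raw) <- 1e6
  bits <- bitscore_matrix(raw, g2p, names(g2p))
  # without the pseudo-count the literal log-average form holds
  S0 <- seq_sim_matrix(bits, pseudocount = 0)
  expect_equal(S0["g1", "g2"], 0)    # min of {2,4,6}
  expect_equal(S0["g1", "g3"], 0.5)
  expect_equal(S0["g2", "g3"], 1)    # the maximizing pair gets 1
  # default pseudo-count keeps zero averages defined and shifts little
  S1 <- seq_sim_matrix(bits)
  expect_true(all(S1 >= 0 & S1 <= 1))
  expect_equal(S1["g2", "g3"], 1)
  expect_equal(S1, t(S1))
})

test_that("integrated dissimilarity combines components and falls back", {
  expect_equal(intdis(1, 1, 1), 0)
  expect_equal(intdis(0, 0, 0), 1)
  expect_equal(intdis(0.6, 0.3, 0.9), 0.4)
  # missing sequence similarity replaced by the mean of the other two
  expect_equal(intdis(0.6, 0.2, NA), 1 - mean(c(0.6, 0.2, 0.4)))
  expect_error(intdis(1.2, 0, 0), "outside")
})

test_that("view 2 equals a naive per-pair reference on a 5-gene fixture", {
  set.seed(33)
  genes <- c("gA", "gB", "gC", "gD")
  go <- compute_ic(toy_go(), toy_ann())
  ann <- toy_ann()[genes]
  edges <- data.frame(protein_a = c("pA", "pB", "pC"),
                      protein_b = c("pB", "pC", "pD"),
                      score = c(0.9, 0.8, 0.7))
  g2p <- c(gA = "pA", gB = "pB", gC = "pC", gD = "pD")
  net <- ppin(edges, g2p)
  raw <- matrix(runif(16, 10, 200), 4, 4,
                dimnames = list(unname(g2p), unname(g2p)))
  bits <- bitscore_matrix(raw, g2p, genes)
  D2 <- build_view2(ann, go, net, bits, genes)

  S <- seq_sim_matrix(bits)
  ref <- matrix(0, 4, 4, dimnames = list(genes, genes))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ref[i, j] <- intdis(multi_sim_genes(genes[i], genes[j], ann, go),
                        ppi_sim(genes[i], genes[j], net),
                        S[genes[i], genes[j]])
  }
  expect_equal(unname(D2), unname(ref), tolerance = 1e-12)
  expect_equal(D2, t(D2), tolerance = 1e-12)
  expect_true(all(diag(D2) == 0))
  expect_true(all(D2 >= 0 & D2 <= 1))
  # permuting the gene index permutes the matrix consistently
  perm <- c("gC", "gA", "gD", "gB")
  D2p <- build_view2(ann, go, net,
                     bitscore_matrix(raw, g2p, perm), perm)
  expect_equal(D2p[genes, genes], D2, tolerance = 1e-12)
})

test_that("without BLAST input every pair uses the fallback rule", {
  go <- compute_ic(toy_go(), toy_ann())
  ann <- toy_ann()[c("gA", "gB", "gC")]
  net <- ppin(data.frame(protein_a = character(),
                         protein_b = character(), score = numeric()),
              c(gA = "pA", gB = "pB", gC = "pC"))
  D2 <- build_view2(ann, go, net, NULL, names(ann))
  m <- multi_sim_genes("gA", "gB", ann, go)
  # PPI component 0, sequence falls back to (m + 0)/2
  expect_equal(D2["gA", "gB"], 1 - (m + 0 + m / 2) / 3)
})
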