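test_that("Pareto dominance follows the componentwise definition", {
  expect_true(dominates(c(1, 1, 1), c(1, 1, 0.5)))
  expect_false(dominates(c(1, 0, 1), c(0, 1, 1)))
  expect_false(dominates(c(0, 1, 1), c(1, 0, 1)))
  expect_false(dominates(c(1, 1), c(1, 1)))  # equality is not dominance
  set.seed(71)
  for (i in 1:100) {
    a <- runif(3); b <- runif(3)
    ref <- all(a >= b) && any(a > b)
    expect_identical(dominates(a, b), ref)
  }
})

test_that("amount of domination multiplies normalized gaps", {
  a <- c(1.0, 0.5, 0.2); b <- c(0.5, 0.5, 0.1)
  expect_equal(delta_dom(a, b, c(1, 1, 1)), 0.05)  # equal obj excluded
  # scaling a differing objective and its range together changes nothing
  a2 <- a; b2 <- b; a2[1] <- a[1] * 10; b2[1] <- b[1] * 10
  expect_equal(delta_dom(a2, b2, c(10, 1, 1)), 0.05)
  expect_equal(delta_dom(a, a, c(1, 1, 1)), 1)  # empty product
})

test_that("archive insertion preserves mutual non-domination", {
  arch <- list()
  r <- archive_add(arch, "s1", c(1, 0, 0))
  r <- archive_add(r$archive, "s2", c(0, 1, 0))
  # dominated candidate leaves the archive unchanged
  r2 <- archive_add(r$archive, "bad", c(0.5, 0, 0))
  expect_false(r2$added)
  expect_equal(length(r2$archive), 2L)
  # dominating candidate purges everything it dominates
  r3 <- archive_add(r$archive, "top", c(1, 1, 1))
  expect_true(r3$added)
  expect_equal(length(r3$archive), 1L)
  expect_equal(r3$archive[[1L]]$sol, "top")
  # random-insert property: archive always pairwise non-dominated
  set.seed(72)
  arch <- list()
  ok <- TRUE
  for (i in 1:200) {
    r <- archive_add(arch, i, runif(3), sl = 100L, hl = 50L)
    arch <- r$archive
    objs <- mvmarker:::archive_objs(arch)
    for (a in seq_len(nrow(objs))) for (b in seq_len(nrow(objs)))
      if (a != b && dominates(objs[a, ], objs[b, ])) ok <- FALSE
  }
  expect_true(ok)
})

test_that("soft-limit overflow prunes to the hard limit", {
  # mutually non-dominated points on a 2-D anti-diagonal
  arch <- list()
  x <- seq(0, 1, length.out = 120L)
  sizes <- integer(120L)
  for (i in seq_along(x)) {
    r <- archive_add(arch, i, c(x[i], 1 - x[i]), sl = 100L, hl = 50L)
    arch <- r$archive
    sizes[i] <- length(arch)
  }
  expect_true(all(sizes <= 100L))          # never beyond the soft limit
  expect_equal(sizes[101L], 50L)           # crossing SL prunes to HL
  expect_equal(length(arch), 50L + 19L)    # growth resumes after pruning
})

test_that("the cooling schedule stage count matches the closed form", {
  cfg <- anneal_config()
  stages <- 0L; tmp <- cfg$t_max
  while (tmp > cfg$t_min) { stages <- stages + 1L; tmp <- tmp * cfg$alpha }
  expect_equal(stages,
               ceiling(log(cfg$t_min / cfg$t_max) / log(cfg$alpha)))
  expect_equal(stages, 132L)
})

test_that("annealing is deterministic and keeps a valid archive", {
  set.seed(73)
  D1 <- block_view(c(5, 5, 5)); D2 <- block_view(c(5, 5, 5))
  ex <- toy_expr(matrix(rnorm(15 * 8), 15, 8))
  lab <- rep(c(1L, 2L), each = 4L)
  sv <- apply(ex$values, 1L, snr, labels = lab)
  cfg <- anneal_config(t_max = 5, t_min = 0.5, alpha = 0.6,
                       total_iter = 8L, p = 6L, sl = 20L, hl = 10L)
  mk <- function() {
    init <- function() init_solution(D1, D2)
    pert <- function(s) perturb(s, D1, D2)
    ev <- function(s) evaluate_objectives(s, sv, D1)
    anneal(init, pert, ev, cfg)
  }
  set.seed(9); r1 <- mk()
  set.seed(9); r2 <- mk()
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$trace, r2$trace)
  # non-domination after every generation, checked via the test hook
  set.seed(10)
  checks <- 0L; nondom <- TRUE
  hook <- function(arch) {
    objs <- mvmarker:::archive_objs(arch)
    if (nrow(objs) >= 2L) {
      pick <- utils::combn(nrow(objs), 2L)
      for (c in seq_len(ncol(pick)))
        if (dominates(objs[pick[1, c], ], objs[pick[2, c], ]) ||
            dominates(objs[pick[2, c], ], objs[pick[1, c], ]))
          nondom <<- FALSE
    }
    checks <<- checks + 1L
  }
  init <- function() init_solution(D1, D2)
  pert <- function(s) perturb(s, D1, D2)
  ev <- function(s) evaluate_objectives(s, sv, D1)
  r3 <- anneal(init, pert, ev,
               anneal_config(t_max = 2, t_min = 0.5, alpha = 0.5,
                             total_iter = 5L, p = 4L), trace_hook = hook)
  expect_equal(checks, 10L)  # 2 stages x 5 generations
  expect_true(nondom)
  # temperatures strictly decreasing
  expect_true(all(diff(r1$trace$tmp) < 0))
})

test_that("hill-climb mode never accepts a dominated move", {
  set.seed(74)
  D1 <- block_view(c(6, 6)); D2 <- block_view(c(6, 6))
  sv <- runif(12)
  cfg <- anneal_config(t_max = 2, t_min = 0.5, alpha = 0.5,
                       total_iter = 10L, p = 4L, hill_climb = TRUE)
  prev_best <- NULL
  hook <- function(arch) {
    best <- max(vapply(arch, function(e) sum(e$obj), numeric(1L)))
    if (!is.null(prev_best)) expect_gte(best, prev_best - 1e-12)
    prev_best <<- best
  }
  init <- function() init_solution(D1, D2)
  pert <- function(s) perturb(s, D1, D2)
  ev <- function(s) evaluate_objectives(s, sv, D1)
  invisible(anneal(init, pert, ev, cfg, trace_hook = hook))
})

test_that("annealing recovers planted blocks on a separable toy problem", {
  set.seed(75)
  D1 <- block_view(c(4, 4, 4), within = 0.05, between = 0.9)
  D2 <- block_view(c(4, 4, 4), within = 0.05, between = 0.9)
  truth <- rep(1:3, each = 4L)
  sv <- runif(12)
  cfg <- anneal_config(t_max = 20, t_min = 0.1, alpha = 0.7,
                       total_iter = 20L, p = 10L, sl = 30L, hl = 15L)
  init <- function() init_solution(D1, D2)
  pert <- function(s) perturb(s, D1, D2)
  ev <- function(s) evaluate_objectives(s, sv, D1)
  r <- anneal(init, pert, ev, cfg)
  agree <- vapply(r$archive, function(e) {
    l <- e$sol$labels_cons
    e$sol$K == 3L && all(outer(l, l, "==") == outer(truth, truth, "=="))
  }, logical(1L))
  expect_true(any(agree))
})
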