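#' Annealing configuration
#'
#' Parameters of the archived multi-objective simulated annealing run.
#' Defaults are the standard setting used throughout: `t_max = 100`,
#' `t_min = 1e-4`, cooling rate `alpha = 0.9`, `total_iter = 100`
#' generations per temperature, soft archive limit `sl = 100`, hard limit
#' `hl = 50`, and `p = 50` initial solutions.
#'
#' @param t_max,t_min Initial and final temperatures (`t_max > t_min > 0`).
#' @param alpha Geometric cooling rate in (0, 1).
#' @param total_iter Generations per temperature stage (>= 1).
#' @param sl,hl Soft and hard archive size limits (`sl >= hl >= 1`).
#' @param p Number of initial solutions (>= 2).
#' @param hill_climb If TRUE, all probabilistic acceptances are disabled
#'   and the run degenerates to a Pareto hill-climber (regression mode).
#' @return A list of class `anneal_config`.
#' @export
anneal_config <- function(t_max = 100, t_min = 1e-4, alpha = 0.9,
                          total_iter = 100L, sl = 100L, hl = 50L,
                          p = 50L, hill_climb = FALSE) {
  stopifnot(t_max > t_min, t_min > 0, alpha > 0, alpha < 1,
            total_iter >= 1L, sl >= hl, hl >= 1L, p >= 2L)
  structure(list(t_max = t_max, t_min = t_min, alpha = alpha,
                 total_iter = as.integer(total_iter),
                 sl = as.integer(sl), hl = as.integer(hl),
                 p = as.integer(p), hill_climb = isTRUE(hill_climb)),
            class = "anneal_config")
}

#' Pareto dominance between two objective vectors
#'
#' All objectives are maximized: `a` dominates `b` iff `a >= b`
#' componentwise with at least one strict inequality.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == length(b))
  all(a >= b) && any(a > b)
}

#' Amount of domination between two objective vectors
#'
#' Product over the objectives where the two vectors differ of
#' `|f_i(a) - f_i(b)| / R_i`, with `R_i` the range of objective i over
#' the archive plus the two points under comparison.  Objectives with
#' zero range contribute a factor of 1.
#'
#' @param a,b Numeric objective vectors.
#' @param ranges Per-objective ranges `R_i`.
#' @return A non-negative scalar (empty product = 1).
#' @export
delta_dom <- function(a, b, ranges) {
  stopifnot(length(a) == length(b), length(ranges) == length(a))
  differ <- a != b & ranges > 0 & is.finite(ranges)
  if (!any(differ)) return(1)
  prod(abs(a[differ] - b[differ]) / ranges[differ])
}

# Objective matrix of an archive (rows = members).
archive_objs <- function(archive) {
  if (!length(archive)) return(matrix(numeric(), 0L, 0L))
  do.call(rbind, lapply(archive, `[[`, "obj"))
}

# Single-linkage pruning of an archive down to `hl` members: cluster in
# min-max-normalized objective space and keep, per cluster, the member
# closest to its cluster centroid.
prune_archive <- function(archive, hl) {
  if (length(archive) <= hl) return(archive)
  objs <- archive_objs(archive)
  rng <- apply(objs, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  norm <- sweep(sweep(objs, 2L, rng[1L, ]), 2L, span, "/")
  hc <- hclust(dist(norm), method = "single")
  cl <- cutree(hc, k = hl)
  keep <- vapply(seq_len(hl), function(k) {
    idx <- which(cl == k)
    if (length(idx) == 1L) return(idx)
    centroid <- colMeans(norm[idx, , drop = FALSE])
    d2 <- rowSums(sweep(norm[idx, , drop = FALSE], 2L, centroid)^2)
    idx[which.min(d2)]
  }, integer(1L))
  archive[keep]
}

#' Insert a candidate into a non-dominated archive
#'
#' If the candidate is dominated by any member the archive is unchanged;
#' otherwise the candidate enters and every member it dominates is
#' removed.  If the size then exceeds the soft limit, single-linkage
#' clustering in normalized objective space reduces it to the hard limit.
#'
#' @param archive List of entries, each `list(sol = ..., obj = ...)`.
#' @param sol Candidate solution (any object).
#' @param obj Candidate objective vector.
#' @param sl,hl Soft and hard size limits.
#' @return List with elements `archive` (updated list) and `added`
#'   (logical).
#' @export
archive_add <- function(archive, sol, obj, sl = 100L, hl = 50L) {
  for (e in archive)
    if (dominates(e$obj, obj))
      return(list(archive = archive, added = FALSE))
  keep <- !vapply(archive, function(e) dominates(obj, e$obj), logical(1L))
  archive <- c(archive[keep], list(list(sol = sol, obj = obj)))
  if (length(archive) > sl) archive <- prune_archive(archive, hl)
  list(archive = archive, added = TRUE)
}

# Acceptance probability for a move worsened by delta_avg at temperature
# tmp; decreasing in delta_avg * tmp.
accept_prob <- function(delta_avg, tmp) {
  1 / (1 + exp(delta_avg * tmp))
}

#' Archived multi-objective simulated annealing
#'
#' Generic AMOSA driver over problem-specific closures.  `p` initial
#' solutions are generated and perturbed once each; a perturbed solution
#' replaces its original only if it dominates it.  The mutually
#' non-dominated survivors seed the archive.  A current point drawn at
#' random from the archive is then evolved: at each of the
#' `total_iter` generations per temperature stage it is perturbed, and
#' the new point is accepted according to the three AMOSA domination
#' cases (probabilistic acceptance when the new point is dominated, with
#' probability decreasing in the range-normalized amount of domination
#' times the temperature; archive insertion when it is non-dominated).
#' Cooling is geometric until `t_min`.
#'
#' @param init_fun Zero-argument closure returning a fresh random
#'   solution.
#' @param perturb_fun One-argument closure perturbing a solution.
#' @param eval_fun One-argument closure returning the objective vector
#'   (all maximized) of a solution.
#' @param cfg An [anneal_config()].
#' @param trace_hook Optional function called after every generation with
#'   the current archive (used by invariant tests).
#' @return List with `archive` (the final Pareto set: entries with `sol`
#'   and `obj`) and `trace` (one row per temperature stage: temperature,
#'   archive size, best value of each objective).
#' @export
anneal <- function(init_fun, perturb_fun, eval_fun, cfg = anneal_config(),
                   trace_hook = NULL) {
  # Step 1-2: initial solutions; Step 5: one perturbation round, keep the
  # dominating variant, then dominance-filter into the archive.
  pop <- lapply(seq_len(cfg$p), function(i) {
    sol <- init_fun()
    list(sol = sol, obj = eval_fun(sol))
  })
  pop <- lapply(pop, function(e) {
    alt <- perturb_fun(e$sol)
    alt_obj <- eval_fun(alt)
    if (dominates(alt_obj, e$obj)) list(sol = alt, obj = alt_obj) else e
  })
  archive <- list()
  for (e in pop) {
    res <- archive_add(archive, e$sol, e$obj, cfg$sl, cfg$hl)
    archive <- res$archive
  }

  cur <- archive[[rand_int(length(archive))]]
  trace <- list()
  tmp <- cfg$t_max
  while (tmp > cfg$t_min) {
    for (iter in seq_len(cfg$total_iter)) {
      new_sol <- perturb_fun(cur$sol)
      new_obj <- eval_fun(new_sol)
      objs <- rbind(archive_objs(archive), cur$obj, new_obj)
      ranges <- apply(objs, 2L, function(x) diff(range(x)))
      dom_by <- vapply(archive, function(e) dominates(e$obj, new_obj),
                       logical(1L))

      if (dominates(cur$obj, new_obj)) {
        # case 1: new point dominated by the current point
        dd <- vapply(archive[dom_by], function(e)
          delta_dom(e$obj, new_obj, ranges), numeric(1L))
        delta_avg <- (sum(dd) + delta_dom(cur$obj, new_obj, ranges)) /
          (length(dd) + 1L)
        if (!cfg$hill_climb && runif(1L) < accept_prob(delta_avg, tmp))
          cur <- list(sol = new_sol, obj = new_obj)
      } else if (dominates(new_obj, cur$obj)) {
        # case 3: new point dominates the current point
        if (any(dom_by)) {
          dd <- vapply(archive[dom_by], function(e)
            delta_dom(e$obj, new_obj, ranges), numeric(1L))
          jmin <- which(dom_by)[which.min(dd)]
          if (!cfg$hill_climb && runif(1L) < 1 / (1 + exp(-min(dd)))) {
            cur <- archive[[jmin]]
          } else {
            cur <- list(sol = new_sol, obj = new_obj)
          }
        } else {
          cur <- list(sol = new_sol, obj = new_obj)
          res <- archive_add(archive, new_sol, new_obj, cfg$sl, cfg$hl)
          archive <- res$archive
        }
      } else {
        # case 2: new and current points mutually non-dominating
        if (any(dom_by)) {
          dd <- vapply(archive[dom_by], function(e)
            delta_dom(e$obj, new_obj, ranges), numeric(1L))
          if (!cfg$hill_climb && runif(1L) < accept_prob(mean(dd), tmp))
            cur <- list(sol = new_sol, obj = new_obj)
        } else {
          cur <- list(sol = new_sol, obj = new_obj)
          res <- archive_add(archive, new_sol, new_obj, cfg$sl, cfg$hl)
          archive <- res$archive
        }
      }
      if (!is.null(trace_hook)) trace_hook(archive)
    }
    best <- apply(archive_objs(archive), 2L, max)
    trace[[length(trace) + 1L]] <-
      c(tmp = tmp, size = length(archive), best)
    tmp <- tmp * cfg$alpha
  }
  trace <- as.data.frame(do.call(rbind, trace))
  list(archive = archive, trace = trace)
}
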