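#' Build both gene dissimilarity views
#'
#' Restricts the expression matrix to GO-annotated genes (only mapped
#' genes take part in selection, which keeps the two views on one shared
#' gene index), preprocesses it, and computes the correlation-distance
#' view and the integrated functional view.
#'
#' @param expr An [expr_matrix()] of raw or log-scale values.
#' @param go A [go_graph()] with IC computed (or to be computed from
#'   `ann`).
#' @param ann Annotation map.
#' @param net A [ppin()].
#' @param bits A [bitscore_matrix()] or NULL.
#' @param log_base Passed to [preprocess_expression()]; use `NA` when the
#'   values are already on log scale.
#' @return List with `D1`, `D2`, `gene_ids` (the shared index) and
#'   `expr` (the preprocessed, restricted matrix).
#' @export
build_views <- function(expr, go, ann, net, bits = NULL, log_base = NA) {
  if (anyNA(go$ic)) go <- compute_ic(go, ann)
  gene_ids <- intersect(expr$gene_ids, names(ann))
  if (length(gene_ids) < 9L)
    stop("fewer than 9 GO-mapped genes; cannot cluster")
  ex <- expr_matrix(expr$values[gene_ids, , drop = FALSE],
                    expr$class_labels)
  ex <- preprocess_expression(ex, log_base = log_base)
  D1 <- build_view1(ex)
  D2 <- build_view2(ann, go, net, bits, gene_ids)
  validate_view(D1); validate_view(D2)
  list(D1 = D1, D2 = D2, gene_ids = gene_ids, expr = ex)
}

#' One gene-selection run: anneal, ensemble, validate, candidates
#'
#' Runs the multi-view multi-objective annealer over the two views,
#' ensembles the Pareto-front consensus partitions by majority voting,
#' validates the result cluster-by-cluster, and extracts the final
#' cluster centers as candidate genes.
#'
#' Validation is Silhouette-based solution selection: the final
#' partition is the one of maximum Silhouette index (under the averaged
#' views) among the ensembled solution and the archive's consensus
#' solutions, with the ensemble preferred on ties.  A per-cluster
#' validity predicate (by default [clusters_valid()], positive mean
#' silhouette) first excludes degenerate candidates from consideration;
#' if nothing passes it, the maximum-Silhouette solution is taken
#' regardless, with a warning.
#'
#' @param views Result of [build_views()].
#' @param labels Integer sample class labels in `{1, 2}` (normally from
#'   [preclass_samples()]).
#' @param cfg An [anneal_config()].
#' @param objectives Subset of `c("snr", "corrdist", "ai")` to optimize.
#' @param update_all Passed to [perturb()].
#' @param validity_fun Per-solution validity predicate
#'   `function(labels, D) -> logical`; NULL disables validation.
#' @return List with `candidates` (gene IDs), `ensemble`, `validation`
#'   (`"ensemble"`, `"re-ensemble"` or `"best-silhouette"`), `archive`,
#'   `trace` and `snr_values`.
#' @export
run_gene_selection <- function(views, labels, cfg = anneal_config(),
                               objectives = c("snr", "corrdist", "ai"),
                               update_all = FALSE,
                               validity_fun = clusters_valid) {
  D1 <- views$D1; D2 <- views$D2
  Davg <- (D1 + D2) / 2
  snr_values <- snr_all_genes(views$expr, labels)

  eval_fun <- function(sol)
    evaluate_objectives(sol, snr_values, D1, objectives)
  init_fun <- function() init_solution(D1, D2, Davg)
  perturb_fun <- function(sol)
    perturb(sol, D1, D2, update_all = update_all, Davg = Davg)

  res <- anneal(init_fun, perturb_fun, eval_fun, cfg)
  sel <- finalize_selection(res$archive, D1, D2, Davg, validity_fun)
  list(candidates = views$gene_ids[sel$ensemble$centers],
       ensemble = sel$ensemble, validation = sel$validation,
       archive = res$archive, trace = res$trace,
       snr_values = snr_values)
}

# Ensemble + Silhouette-based solution selection, shared by the
# pipeline and tests.
finalize_selection <- function(archive, D1, D2, Davg, validity_fun) {
  ens <- ensemble_majority(archive, D1, D2)
  cand <- c(list(list(labels = ens$labels, what = "ensemble", ens = ens)),
            lapply(archive, function(e)
              list(labels = e$sol$labels_cons, what = "best-silhouette",
                   ens = list(labels = e$sol$labels_cons,
                              centers = e$sol$centers_cons,
                              K = e$sol$K, co_assoc = NULL,
                              fallback = TRUE))))
  ok <- if (is.null(validity_fun)) rep(TRUE, length(cand)) else
    vapply(cand, function(c) validity_fun(c$labels, Davg), logical(1L))
  if (!any(ok)) {
    warning("no solution passes cluster validation; ",
            "selecting the maximum-Silhouette solution regardless")
    ok <- rep(TRUE, length(cand))
  }
  pool <- cand[ok]
  sil <- vapply(pool, function(c)
    internal_indices(c$labels, Davg)["silhouette"], numeric(1L))
  # which.max keeps the first (ensemble) entry on exact ties
  pick <- pool[[which.max(sil)]]
  list(ensemble = pick$ens, validation = pick$what)
}

#' Full marker-selection pipeline over multiple independent runs
#'
#' Pre-clusters the samples once into two groups (unless labels are
#' supplied), executes `t` independent seeded gene-selection runs, and
#' reports the genes common to all candidate sets as markers, with their
#' regulation modes.
#'
#' @param views Result of [build_views()].
#' @param t Number of independent runs (>= 2).
#' @param seed Run-level seed; per-stage seeds are derived from it (see
#'   [derive_seed()]).
#' @param cfg An [anneal_config()].
#' @param labels Optional user-supplied sample labels in `{1, 2}`;
#'   bypasses pre-clustering.
#' @param preclass_cfg Annealing configuration for the sample
#'   pre-clustering stage.
#' @param objectives Objective subset, see [run_gene_selection()].
#' @return List with the `marker_report`, per-run `candidate_sets` and
#'   `runs`, the SNR `labels` used, and a `regulation` data frame.
#' @export
select_markers <- function(views, t = 3L, seed = 1L,
                           cfg = anneal_config(),
                           labels = NULL,
                           preclass_cfg = sample_anneal_config(),
                           objectives = c("snr", "corrdist", "ai")) {
  if (t < 2L) stop("need t >= 2 runs for marker intersection")
  if (is.null(labels)) {
    # label pre-clustering is seeded independently of the optimizer runs
    set.seed(derive_seed(seed, 0L))
    labels <- preclass_samples(views$expr, preclass_cfg)
  }
  runs <- vector("list", t)
  for (r in seq_len(t)) {
    set.seed(derive_seed(seed, r))
    runs[[r]] <- run_gene_selection(views, labels, cfg, objectives)
  }
  candidate_sets <- lapply(runs, `[[`, "candidates")
  report <- markers_across_runs(candidate_sets)
  regulation <- if (length(report$markers)) {
    data.frame(
      gene_id = report$markers,
      mode = vapply(report$markers, function(g)
        regulation_mode(views$expr$values[g, ], labels),
        character(1L)),
      mean_cl1 = vapply(report$markers, function(g)
        mean(views$expr$values[g, labels == 1L]), numeric(1L)),
      mean_cl2 = vapply(report$markers, function(g)
        mean(views$expr$values[g, labels == 2L]), numeric(1L)),
      row.names = NULL)
  } else {
    data.frame(gene_id = character(), mode = character(),
               mean_cl1 = numeric(), mean_cl2 = numeric())
  }
  list(report = report, candidate_sets = candidate_sets, runs = runs,
       labels = labels, regulation = regulation)
}

#' Classify samples on an original or reduced gene space
#'
#' Clusters the samples of the given expression matrix into two groups
#' with [cluster_samples()] and, when true class labels are attached,
#' scores the grouping with the external indices.
#'
#' @param expr An [expr_matrix()] (full or reduced).
#' @param cfg An [anneal_config()].
#' @param seed Optional seed set before clustering.
#' @return List with `labels`, `silhouette`, `db` and, when truth is
#'   available, `indices` (sensitivity, specificity, f_score, ca).
#' @export
classify_samples <- function(expr, cfg = sample_anneal_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- cluster_samples(expr, K = 2L, cfg = cfg)
  out <- list(labels = res$labels, silhouette = res$silhouette,
              db = res$db)
  if (!is.null(expr$class_labels))
    out$indices <- external_indices(res$labels, expr$class_labels)
  out
}
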