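---
title: "Multi-view multi-objective gene marker selection: model and methods"
author: "mvmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view multi-objective gene marker selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvmarker)
```

## The problem

Two-class expression studies (tumour versus normal, subtype A versus
subtype B) routinely need a small panel of *marker genes*: genes that
are relevant to the class distinction, non-redundant among themselves,
and biologically coherent.  Purely statistical filters (t-statistics,
signal-to-noise ranking) pick relevant genes but ignore redundancy and
biology; purely functional groupings ignore the class signal.
`mvmarker` implements an unsupervised pipeline that clusters genes
under **two complementary dissimilarity views at once** and extracts
cluster centers as candidates:

* **View 1 — expression correlation.**  For genes with expression
  vectors $a, b$ over samples, the dissimilarity is the correlation
  distance $1-|\varphi(a,b)|$ with
  $\varphi = \mathrm{cov}(a,b)/\sqrt{\mathrm{var}(a)\mathrm{var}(b)}$.
  The sign is deliberately dropped: strongly anti-correlated genes
  belong to the same co-regulation module.

* **View 2 — integrated functional dissimilarity.**  Each gene pair is
  scored by three similarities in $[0,1]$ that are averaged and
  subtracted from 1:

  1. *GO semantic similarity.*  A term-level similarity
     $\arctan(Y)/(\pi/2)$, where
     $Y = \mathrm{sim}_{\mathrm{Lin}} + \mathrm{sim}_{\mathrm{Shen}} +
     \mathrm{sim}_{\mathrm{depth}}$ combines Lin's
     information-content ratio $2\,IC(\mathrm{LCA})/(IC(t_1)+IC(t_2))$,
     Shen's path-based similarity
     $1-\arctan\!\big(\sum_{t\in \mathrm{path}} 1/IC(t)\big)/(\pi/2)$,
     and the normalized depth of the lowest common ancestor
     $\mathrm{depth}(\mathrm{LCA})/\max(\mathrm{depth}(t_1),
     \mathrm{depth}(t_2))$.  The LCA is the common ancestor of maximal
     IC; IC is $-\log$ of a term's annotation frequency (natural log),
     with never-used terms assigned the rarest used term's IC.  Gene
     similarity averages the term matrix over all annotation pairs and
     is itself averaged with the normalized term overlap
     $|A_1\cap A_2|/\min(|A_1|,|A_2|)$.  Terms of different
     namespaces, or without a common ancestor, contribute 0; the
     double sum runs over the pooled annotations of all three
     namespaces and includes identical-term pairs.
  2. *PPI neighbourhood similarity.*  A weighted-overlap score on the
     confidence-weighted interaction network: shared neighbours
     contribute $\min(w_{ik},w_{jk})$; the denominator adds private
     neighbour weights and $\max(w_{ik},w_{jk})$; unmapped genes or an
     empty denominator give 0.
  3. *Sequence similarity.*  Directed BLAST bit scores are averaged
     per pair, passed through $\log_{10}(\cdot + 1)$, and min–max
     normalized over all mapped pairs.  The $+1$ pseudo-count keeps
     pairs with no reciprocal hit defined (they map to the minimum);
     the normalization absorbs the shift.  For genes absent from the
     BLAST output, the sequence component is replaced by the average
     of the other two components before combining.

Only GO-annotated genes take part, so both views share one gene index.

## The multi-view solution and its optimizer

A solution encodes `K` medoid centers per view (`2 <= K <=
floor(sqrt(n))`), with non-centers assigned to their
minimum-dissimilarity center (ties to the lowest cluster index) and
centers then replaced by cluster medoids.  A **consensus partition**
merges the views in three steps: view-1 clusters greedily match the
unmatched view-2 cluster of maximal overlap (ties to the lowest
index); each intersection seeds a consensus cluster whose center is
the seed medoid under the *averaged* views (an empty intersection is
reseeded from the view-1 cluster medoid, preserving `K`); leftover
genes join the nearest consensus center under the averaged views.

Three objectives, all maximized, score a solution:

1. **average SNR** of the consensus centers,
   $|\mu_1-\mu_2|/(\sigma_1+\sigma_2)$ per gene with population SDs
   (relevance);
2. **average pairwise correlation distance** among consensus centers,
   read from view 1 (non-redundancy);
3. **agreement index** between the two view partitions:
   with co-membership matrices $A^{(1)}, A^{(2)}$ (diagonal 1),
   $AI = (n_a+1)/(n_d+1)$ where $n_a$ counts agreeing ordered pairs
   over all $n^2$ and $n_d = n^2-n_a$ (cross-view consistency).
   For two views the pairwise AI is returned directly; the multi-view
   aggregate (which double-counts ordered view pairs) is monotone
   equivalent at $m=2$ and only relevant for $m>2$.

SNR needs two sample groups; since the pipeline is unsupervised, the
samples are pre-clustered once per dataset into two groups by the same
machinery (see below), and those labels are cached for all runs.

The optimizer is **archived multi-objective simulated annealing**: a
bounded archive holds mutually non-dominated solutions (soft limit
100; crossing it triggers single-linkage pruning in min–max-normalized
objective space down to 50, keeping per cluster the member nearest its
centroid).  Candidate moves come from three perturbation operators
chosen uniformly at random (illegal draws are resampled among the
legal ones): *update* replaces one randomly chosen center per view by
its nearest non-center gene (a flag restores the replace-all-centers
variant), *insert* appends a random non-center (if $K$ permits),
*delete* removes a random center (if $K \ge 3$).  Acceptance follows
the three classic domination cases, with probability
$1/(1+\exp(\Delta\mathrm{dom}\cdot T))$ of accepting a dominated move,
where the amount of domination is the product of range-normalized
objective gaps over the differing objectives (ranges taken over the
archive plus the two points).  The current point is drawn from the
archive once and evolves through the acceptance cases.  Cooling is
geometric: $T_{\max} = 100$, $T_{\min} = 10^{-4}$, $\alpha = 0.9$, 100
generations per stage (132 stages), 50 initial solutions.  These
gene-stage defaults follow the standard published setting; a
sensitivity study in the original formulation found them stable.

## From Pareto front to markers

The front's consensus partitions are **ensembled by majority voting**:
gene pairs co-clustered in strictly more than half of the solutions
are linked, connected components (size at least 2) become clusters
(the pairwise relation is not transitive, so components are the
minimal closure), centers are medoids under the averaged views, and
unlinked genes join the nearest center.  Because the front spans many
values of `K`, the co-association majority can be dominated by
coarse partitions; the final solution is therefore chosen by
**Silhouette-based selection** — the maximum-Silhouette partition
(under the averaged views) among the ensemble and the individual
Pareto members, the ensemble winning ties.  This replaces the
external-enrichment validation a full biological workflow would run
at this point; a per-cluster validity predicate (default: every
cluster has positive mean silhouette width) is exposed as a hook and
excludes degenerate candidates first.

The final partition's centers are the **candidate genes** (`n_c` = the
number of clusters, strictly fewer than `n`).  The whole optimization
is repeated `t` times with independent derived seeds; genes present in
every candidate set are reported as **markers**, with a saturation
trace of the cumulative intersection.  Each marker is called *Up* or
*Down* by comparing class means (ties are reported Up with a warning;
the disease class designation is configurable), and a red–black–green
markers-by-samples heatmap plus its underlying TSV can be exported.

## Sample clustering and evaluation

Sample pre-clustering and the downstream classification both run the
same annealer in single-view mode over the samples: medoid partitions
under the **signed** correlation distance $(1-\varphi)/2$ between
sample profiles, with two internal objectives (maximize Silhouette,
minimize Davies–Bouldin) and fixed $K=2$; the max-Silhouette archive
member is returned.  The sign matters here: anti-correlated samples
are maximally different for class discovery, while for genes
anti-correlation means co-regulation — hence the two stages use
different distances on purpose.  Because the $K=2$ medoid space over
tens of samples is tiny, the sample stage uses a shorter schedule (31
stages of 20 generations, 20 initial solutions) with identical
acceptance rules.

Internal validity is computed from the dissimilarity matrix:
Silhouette (singletons contribute 0), Davies–Bouldin in its medoid
form ($S_k$ = mean member–medoid dissimilarity, separation =
medoid–medoid distance), and Dunn (minimum between-cluster distance
over maximum diameter; zero diameter yields `Inf`).  External
two-class validity maps clusters to classes by the
accuracy-maximizing permutation and reports sensitivity, specificity,
F-score and classification accuracy with class 1 positive.

## What the synthetic generator emulates

`generate_synthetic()` plants one coherent structure through all six
inputs so the complete pipeline is testable offline:

* **Expression** (log-scale; standardize with `log_base = NA`):
  each of `C` gene clusters is a co-expression module with profile
  $a_c z_s + e_c(s)$, where $z_s = \pm 1/2$ codes the sample class,
  $a_c \sim N(0, \tau^2)$ is a module-level class effect and
  $e_c(s) \sim N(0, \eta^2)$ is within-class sample variation; genes
  add $N(0, \sigma^2)$ noise.  The `n_rel` relevant genes (spread
  evenly over clusters) receive an extra class separation $\delta$
  along their module's direction, so their expected SNR is
  $(|a_c| + \delta)/(2\sqrt{\eta^2+\sigma^2})$, about
  $\delta/(2\sigma)$ at the defaults, versus
  $|a_c|/(2\sqrt{\eta^2+\sigma^2})$ for the rest.  Module-level
  differential expression ($\tau = 1$) makes the two classes the
  dominant sample-level correlation structure, as in real two-class
  data; with $\tau$ near zero no unsupervised method could recover
  the classes and the SNR objective would be meaningless.
* **Ontology and annotations**: `C` separately-rooted branches
  (namespaces cycling through BP/MF/CC), each root + 2 children +
  grandchildren; every gene draws `ann_per_gene` terms from its own
  branch with probability $\rho$, otherwise from a random other
  branch.  Separate roots mean fully coherent annotations
  ($\rho = 1$) give exactly zero cross-cluster GO similarity.
* **PPI network and bit scores**: edge probability and weight, and
  directed bit scores, are high within clusters and low between;
  the bit-score matrix is asymmetric by construction and a
  configurable fraction of genes can be left out of the BLAST output
  to exercise the fallback rule.

The standard benchmark (`standard_benchmark()`) fixes $n = 200$,
$d = 40$ (20 + 20), $C = 5$, $n_{rel} = 10$ (2 per cluster),
$\delta = 2$, $\sigma = 0.5$, $\rho = 0.9$, seed 17.  The acceptance
checks run the full pipeline on it: three selection runs under the
full gene-stage schedule, then reduced- versus full-space sample
classification over ten seeded repetitions.

What passing these tests does **not** show: the generator draws
Gaussian log-expression with exactly one module per gene — it does not
mimic real microarray intensity distributions, overlapping pathways,
real GO topology or annotation depth, or batch effects.  Recovery on
the benchmark demonstrates internal correctness of the machinery, not
performance on real cohorts.

One structural property of the method is worth stating plainly: the
candidate set has exactly one gene per final cluster, and centers are
dissimilarity medoids.  When the planted clusters are recovered
perfectly, `n_c` equals `C`, so the candidates are module
*prototypes* — which carry the module-level class signal and classify
samples well — rather than the individually strongest class-separating
genes.  The SNR objective biases which partitions survive, but cannot
make more than `n_c` relevant genes candidates.

## Numerical choices and degenerate inputs

* One variance convention everywhere: population (1/N) SDs, for
  standardization, SNR and correlation.
* Constant vectors have correlation distance 1 (zero-covariance
  convention); the SNR denominator carries an $\epsilon = 10^{-12}$
  guard.
* Assignment and medoid ties break to the lowest cluster/gene index,
  making every stage deterministic given the RNG stream.
* `rand()`-style draws are realized as uniform integers from R's
  seeded generator; one run-level seed expands into per-stage seeds
  via `derive_seed()` (a fixed affine counter scheme modulo
  $2^{31}-1$), so any stage can be reproduced in isolation.
* Empty clusters cannot arise: centers are always members of their
  own clusters, and consensus seeds are re-seeded from view-1 medoids
  when an intersection is empty.
* The log base of the expression preprocessing defaults to 2 and is
  configurable; standardization is per sample, with a per-gene flag.
* OBO parsing keeps `is_a` and `part_of` only, the standard practice
  for semantic similarity; depth is the longest path to the namespace
  root.
* Initial solutions that never enter the archive are discarded after
  the initial dominance filtering round.

## Known limitations

* Dense $n \times n$ views bound the practical gene count to a few
  thousand per run on desktop memory.
* The GO-enrichment validation and competitor-method comparisons of a
  full biological study are out of scope; the Silhouette-based
  selection stands in for the former.
* With `t` large, the marker intersection can legitimately become
  empty; the report then carries a warning and the saturation trace
  shows where it collapsed.
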