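---
title: "Predicting reporter activity from TFBS enrichment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reporter activity from TFBS enrichment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`mpramars` predicts the transcriptional activity of DNA constructs
measured by massively parallel reporter assays (MPRA) or luciferase
reporter assays, using only the construct sequence and a library of
transcription-factor binding-site (TFBS) position weight matrices
(PWMs).  This vignette explains the model, its assumptions, the tunable
parameters, the synthetic-data generators that the test suite relies
on, and the numerical choices made where the design was genuinely open.

## The model in one page

The pipeline has four stages.

1. **Preprocessing.**  MPRA activity is the log2 ratio of mRNA to DNA
   barcode counts: per barcode
   $\log_2\frac{mRNA + q}{DNA + q}$ (pseudocount $q$, default 1),
   aggregated as the median across barcodes within a replicate and the
   mean across replicates.  Constructs whose between-replicate standard
   deviation exceeds the 95% quantile of all replicate SDs are removed
   as irregular.

2. **Encoding.**  Every sequence $j$ becomes a vector of TFBS
   enrichment scores, one per matrix $i$:
   $$E_{ij} = \sum_k \mathrm{score}(\text{hit } k \text{ of matrix } i
   \text{ in sequence } j),$$
   where hits are windows (both strands) whose normalized similarity
   score passes the matrix cutoff.  The similarity score is the
   information-weighted matrix similarity
   $$s(w) = \frac{\sum_i I_i f_i(w_i) - \min}{\max - \min},
   \qquad I_i = \sum_b f_{ib}\ln(4 f_{ib}),$$
   which is 1 for the consensus window and 0 for the anti-consensus.
   Assays run under several conditions (cell types, stimulations) add
   one 0/1 indicator column per condition label.

3. **Clustering.**  A binary regression tree (SSE splitting) groups
   constructs into clusters, with the minimum terminal cluster size set
   from the redundancy of the feature matrix:
   $$\mathit{vp} = \frac{2^{-p_1}\cdot 10^7}{n^2},\qquad
     \mathit{minbucket} = \mathit{vp}\cdot n,$$
   where $p_1$ is the proportion of variance on the first principal
   component of the (standardized) enrichment columns and $n$ the number
   of rows.  Redundant feature sets (large $p_1$) permit smaller
   clusters; small libraries push $\mathit{minbucket}$ past $n$, so no
   clustering is performed and one response function is fitted to all
   data.  The grown tree is pruned by cost-complexity pruning with
   10-fold cross-validation.

4. **Response functions.**  Inside each cluster, multivariate adaptive
   regression splines (MARS) fit
   $$\hat y_j = c + \sum c''\, h(E_{i''j})
     + \sum c'\, h(E_{i'j})\, h(E_{i''j}),$$
   with hinge functions $h(x) = \max(0, x - c)$ or $\max(0, c - x)$ at
   knots chosen from observed values.  The forward pass adds reflected
   hinge pairs by largest exact RSS decrease; the backward pass selects
   the subset minimizing the generalized cross-validation score
   $$\mathrm{GCV} = \frac{RSS/n}{(1 - M_{\mathrm{eff}}/n)^2},\qquad
     M_{\mathrm{eff}} = M + \mathrm{penalty}\cdot\frac{M-1}{2}.$$

Evaluation follows the 100-fold cross-validation convention: the whole
pipeline (sizing, tree, pruning, per-cluster MARS) is refitted on every
training fold, held-out predictions are pooled, and both the closed-test
(training fit) and open-test (cross-validated) Pearson correlations are
reported.

## A worked example

```{r}
library(mpramars)

spec <- mpra_scenario(n_sequences = 800, seed = 7)
sim <- simulate_mpra(spec)

activities <- activity_from_counts(sim$counts)
kept <- filter_irregular(activities)$kept
design <- build_design_matrix(sim$enrichments, kept)

sizing_params(pc1_proportion(design), nrow(design$x))
```

At 800 constructs the sizing formula keeps the tree at a single root
(the small-library regime); at the reference size of 5000 it yields two
to three clusters.  Fitting and evaluating:

```{r}
fit <- mpra_fit(design, list(tree_cv_folds = 5, max_terms = 21))
fit$tree
head(tfbs_tree_report(fit))
selected_tfbs_frequencies(fit)
```

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pseudocount` (counts) | 1 | added to both counts before the log ratio |
| `sd_quantile` | 0.95 | replicate-SD quantile above which constructs are dropped |
| `target_fnr` | 0.05 | tolerated false negative rate when calibrating matrix cutoffs |
| `cp` | 0.01 | minimum SSE reduction of a split, as a fraction of the root SSE |
| `tree_cv_folds` | 10 | folds for cost-complexity pruning |
| `max_terms` | 61 | cap on MARS basis functions (including the intercept) |
| `max_degree` | 2 | 1 = additive, 2 = allow two-hinge products |
| `penalty` | 3 (2 if additive) | GCV charge per knot |
| `thresh` | 1e-4 | forward stop: RSS decrease under this fraction of the total SS |
| `knot_max` | 500 | per-column cap on candidate knots (deterministic stride) |

Matrix cutoffs deserve a note.  Database-distributed "minimum false
negative" profiles are proprietary, so the package calibrates each
matrix by Monte Carlo: sample 10,000 sites from the matrix's own
frequency model, score them, and take the `target_fnr` quantile.  At
least $1 - \mathrm{FNR}$ of true sites then pass the cutoff.  Cutoffs
supplied in the motif file (a `CC cutoff=` line) take precedence.

## The synthetic reference scenario

Real MPRA libraries and licensed matrix collections cannot ship with
the package, so correctness is demonstrated on seeded generators whose
structure matches the model's assumptions:

* 12 random PWMs of width 10, one dominant base per position at
  frequency 0.9, cutoffs calibrated at FNR 0.05;
* 5000 constructs of 200 bp, uniform background, consensus sites
  planted at Poisson rates (1.5 for the cluster-defining motif, 1.2 for
  the four effect motifs, 0.5 for the rest).  Sites occupy a
  motif-width slot grid with a random per-sequence phase, which makes
  non-overlap cheap to guarantee; planted copies are recorded in a
  ledger;
* activity = cluster baseline (0 or 3; the two clusters split the
  library at the median enrichment of the first motif, so they are
  balanced whatever background hit level the seed's motif set
  produces) + per-cluster hinge terms + Gaussian noise (SD 0.3);
* counts: 10 barcodes x 3 replicates, DNA depth Poisson(200), mRNA
  Poisson(200 * 2^activity); 5% of constructs get per-replicate
  activity offsets (SD 1.5) to emulate irregular replicates.

Unit tests run a scaled-down version of this scenario (300-900
constructs, 6 motifs of width 8) to stay fast; the acceptance tests run
the full reference scenario on seeds 1-5 with 100-fold cross-validation.

What passing these tests shows — and what it does not.  The generators
produce data *from the model family*: hinge-shaped effects of
enrichment scores, independent Gaussian noise, Poisson counts.  Success
demonstrates that the estimation machinery recovers planted structure
(open-test $r \ge 0.9$, the cluster motif at the tree root, knots
within 0.05) under realistic sizes and noise.  It does not demonstrate
that real regulatory sequences follow hinge-shaped enrichment
responses, that matrix libraries are complete, or that replicate noise
is Gaussian; on real data the achievable correlations are lower and
dataset-dependent.  Notable departures from real data: planted sites
are exact consensus (no affinity gradation), background is uniform
(no GC structure), and sites never overlap.

## Numerical choices and open design points

* **PCA for redundancy** runs on standardized (unit-variance)
  enrichment columns.  Redundancy is a correlation notion, and
  standardization makes $p_1$ invariant to per-matrix scale; condition
  indicator columns are excluded.
* **Split search**: candidate thresholds are midpoints of consecutive
  distinct values; rows with value `< threshold` go left, ties go
  right; equal-gain ties resolve to the lowest column index, then the
  lowest threshold.  A split must clear `cp` times the root SSE.
* **Pruning** selects the complexity with the minimum cross-validated
  error (not the 1-SE rule); error ties prefer the smaller tree.  Fold
  assignment is a seeded permutation, so results are reproducible.
* **MARS forward pass** computes, for every (parent, column, knot)
  triple, the exact joint RSS decrease of the reflected hinge pair via
  prefix/suffix-sum identities (cost O(n * model size) per parent and
  column, independent of the number of knots), in a small C++ kernel.
  Knots are the distinct observed values, stride-subsampled to
  `knot_max` per column.
* **Least squares** uses a ridge stabilizer of 1e-8 times the largest
  Gram diagonal.  Hinge bases are often near-collinear (reflected pairs
  plus their products); the stabilizer keeps coefficients finite at a
  bias far below any reported tolerance.
* **Backward pass**: for models with at most 12 terms the GCV-optimal
  subset is found by exhaustive search (so the selection is exact, and
  testable against an independent enumeration); larger models use the
  classical greedy deletion path, keeping the best model seen.  Greedy
  deletion alone can miss the optimum when hinge bases are correlated,
  which is why the exact branch exists.
* **Degenerate inputs**: constant responses yield intercept-only
  models; a degenerate (single-window) matrix calibrates to cutoff
  $1 - 10^{-9}$; ambiguous bases contribute a position's mean
  frequency; an all-constant feature matrix is an error for
  `pc1_proportion` (redundancy undefined).
* **Misfit reports** compare mean enrichments of the 5% most over- and
  under-estimated constructs against the 10% best fitted, with a
  pseudo-mean of 0.01 guarding empty columns; the two tails are
  reported separately.  Because the reference set is defined by
  absolute residuals, the report is origin-invariant only when the
  model is refitted after shifting activities (the intercept absorbs
  the shift).
* **Cross-validation granularity**: folds partition design rows.  With
  multi-condition data, rows of one construct under different
  conditions can land in different folds, mirroring the row-level
  convention; grouping rows by construct would be the leakage-safe
  alternative and is deliberately not the default.

## Problem sizes used by the shipped checks

The acceptance suite runs the reference scenario (5000 constructs) for
seeds 1-5 with 100-fold cross-validation, 20 seeds of the tree-split
recovery check (no count generation), 20 seeds of MARS knot recovery at
n = 2000, and brute-force oracle comparisons at n <= 200.  These sizes
were chosen so the whole suite demonstrates recovery at realistic scale
while remaining convenient to run on a laptop.

## Known limitations

* Enrichment scores are the only sequence features; position,
  orientation, spacing and GC content are deliberately ignored, so
  effects that depend on them (e.g. enhanceosome-style overlapping
  sites) are invisible to the model.
* The per-cluster MARS surfaces are piecewise linear in enrichment;
  saturating or non-monotone responses are approximated by extra knots.
* Matrix-scanning false positives inflate enrichment baselines; the
  minFN cutoff philosophy trades sensitivity for exactly this cost.
* The tree's sizing formula contains the constant $10^7$ on the scale
  of published library sizes (hundreds to tens of thousands of rows);
  far outside that range the formula's behaviour is untested.
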