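---
title: "Whole-brain functional network group analysis with readnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain functional network group analysis with readnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readnet)
```

## The analysis

readnet implements a graph-theoretical analysis of task-fMRI functional
connectivity for two-group comparisons, of the kind used to contrast reading
groups performing phonological and orthographic judgement tasks. The chain
is:

1. **ROI BOLD signal.** Each subject-session is a 90 x T matrix: the mean
   BOLD time course of each region of the AAL-90 parcellation over the
   analysed volumes of one block-design run.
2. **Connectivity.** Edges are Pearson correlations between all ROI pairs,
   Fisher transformed (z = atanh r) to stabilise variance
   (`roiCorrelationMatrix`).
3. **Binary graphs.** At each sparsity s in {5%, 10%, ..., 50%}, the
   strongest positive `floor(s * 4005)` correlations become the edges of an
   undirected, unweighted graph (`thresholdBySparsity`, `sparsityLadder`).
   Negative correlations are never edges, since their physiological
   interpretation is ambiguous.
4. **Topology metrics.** Per graph: clustering coefficient Cp, characteristic
   path length Lp, global and local efficiency, and - normalised against
   degree-preserving rewired null graphs - gamma, lambda and their ratio
   sigma (small-worldness). Nodal degree and Brandes betweenness centrality
   are computed at the sparsest threshold.
5. **Group statistics.** Pooled-variance two-sample t-tests per metric,
   session and sparsity (and per node for centralities), with Bonferroni
   correction.

A synthetic cohort generator (`simulateCohort`) reproduces the statistical
structure this analysis assumes, so the full pipeline is testable without
access to any scanner data.

## The synthetic cohort

The generator emulates a study with two groups of 16 children, each scanned
in two block-design sessions (phonological and orthographic tasks, modelled
as identical timing with different labels): TR = 2 s, four experimental
blocks of a 2-s instruction plus eight 3-s trials (26 s), interleaved with
12-s fixation blocks. We place fixation before and after every experimental
block (F E F E F E F E F) - the standard layout, and it puts the dummy scans
inside the opening fixation - giving a 164-s run, 82 volumes, of which the
first 3 (dummy scans) are discarded by the generator itself, leaving 79.

Per subject-session the signal is

* **correlated noise** drawn from a multivariate normal whose correlation
  matrix has 6 contiguous modules of 15 ROIs, r = 0.35 within modules and
  r = 0.10 between (unit variances). These are mid-range values for
  task-state cortical networks: strong enough that thresholded graphs have
  community structure, weak enough that 79 volumes leave realistic sampling
  noise on each edge;
* **task activation**: the HRF-convolved task boxcar, amplitude 1, added to
  one ROI per module (round-robin), so the GLM stage has something to
  detect; which ROIs carry it is immaterial to the network claims;
* **white noise** with sd 0.5, standing in for scanner/physiological noise
  that is uncorrelated across ROIs.

The group effect is a +0.15 offset on the *within-module* correlations of
the poor group's orthographic session only. This injects the qualitative
pattern under study - a topological group difference (higher clustering,
longer paths at fixed sparsity) present in one task and absent in the
other - while leaving the phonological session exchangeable between groups.
Behavioural scores are drawn from the printed group summaries (reading
115.75 +/- 13.57 vs 35.63 +/- 13.59; Raven 68.44 +/- 15.78 vs 75 +/- 16.73).

If a perturbed correlation target loses positive semi-definiteness it is
repaired by clipping eigenvalues at 1e-8 and rescaling to unit diagonal,
with a warning; with the default parameters no repair is needed.

Per-run seeds are derived deterministically from the spec seed and the
(group, session, subject) coordinates by an integer mixing recurrence
(modulo 2^31 - 1), so a cohort is a pure function of its spec while runs
are mutually decorrelated.

What the generator does **not** emulate: spatial structure and voxel-level
preprocessing, head motion, physiological rhythms, haemodynamic variability
across regions, session-order effects, and any empirical region-specific
connectivity profile. Tests passing on these cohorts therefore validate the
*statistical machinery* - calibration, selectivity, determinism - not claims
about real readers' brains.

## The ROI-level GLM

`buildDesignMatrix` assembles task and instruction boxcars convolved with
the canonical double-gamma HRF (response delay 6 s, undershoot delay 16 s,
dispersions 1, response:undershoot ratio 6, 32-s support, peak-normalised;
the conventional defaults), 16x oversampled before sampling at acquisition
times. The instruction period gets its own regressor so the 2-s cue does not
bias the task boxcar. High-pass filtering uses a discrete-cosine basis with
K = floor(2D / 128 s) columns for analysed duration D; at D = 158 s that is
K = 2. Estimation is ordinary least squares without autocorrelation
modelling - at 79 volumes and block-level inference an AR model buys little
and the reference analysis does not mention prewhitening. A mean-across-ROIs
global-signal regressor is optional: on by default in the activation stage,
never used for network construction.

One numerical caveat documented here because the tests rely on it: a K = 2
DCT filter on a 158-s run has a soft transition band. Drifts with periods
well above the cut-off (>= 200 s) are >= 90% removed and fluctuations at
<= 64 s pass nearly untouched, but a sinusoid at, say, 140 s is only
partially (~70-85%) attenuated. The property tests therefore probe the
filter away from the transition band.

`contrastT` flags ROIs with zero residual variance (exact interpolation)
with an infinite t rather than failing; `groupActivationTTest` runs the
second-level pooled t-test per ROI.

## Graph conventions and numerics

* **Sparsity semantics.** A binary graph cannot hold a fractional edge:
  the edge count is `floor(s * N(N-1)/2)` (200 at 5%, 2002 at 50% for
  N = 90) and the achieved sparsity is always recorded, including when too
  few positive correlations exist. Ties at the cut-off break by (row,
  column) index, which makes ladders nested and runs reproducible.
* **Disconnected graphs.** At 5% sparsity isolation is common. Lp is the
  mean over *reachable* pairs, with the reachable fraction and the
  isolated-node count reported on every record row, so the convention is
  visible in the output rather than silently poisoning means. Efficiency
  metrics need no convention (1/infinity = 0). Note the tension inherited
  from the reference analysis: nodal tests run at 5% sparsity described as
  the threshold where "most nodes are connected", yet 5% is where isolation
  is most likely - we run 5% as specified and surface the isolation counts.
* **Degree < 2 nodes** have clustering and local efficiency 0, keeping means
  over all N nodes well defined.
* **Null models.** gamma, lambda, sigma normalise against Maslov-Sneppen
  degree-preserving rewiring: 10x|E| attempted double-edge swaps rejecting
  self-loops and multi-edges, 100 nulls by default (configurable; a complete
  graph admits no swap and is its own null). Null Lp uses the same
  reachable-pairs convention.
* **Betweenness** is Brandes' algorithm, unnormalised (group t-tests are
  scale invariant), each unordered pair counted once.
* Shortest paths are computed by levelwise boolean matrix products - exact
  BFS, vectorised for the 90-node scale.

## Group inference

Pooled-variance Student t with df = n_a + n_b - 2 is used throughout (the
reported df = 30 at 16 + 16 subjects implies the pooled form), sign
convention group A minus group B, recorded in every table header. The
Bonferroni family is the number of sparsity levels per metric per session
(10 by default) for global metrics and the number of nodes per measure (90)
for nodal tests; both corrected and uncorrected flags are always emitted,
since reported nodal effects in this literature are typically uncorrected.
Rows where a metric is undefined for some subject (Lp on a fully
disconnected graph) are dropped with a warning and the family shrinks.
When the pipeline is asked whether a metric "differs between groups in one
session only", the Bonferroni-corrected flag is the criterion: with ten
correlated tests per session, the uncorrected flag alone would generate a
spurious session hit in a fifth of null sessions by construction.

## Problem sizes used by the checks

The packaged checks run the full study geometry - 16 subjects per group, 90
ROIs, 79 analysed volumes, both sessions. Calibration of the null pipeline
uses 200 simulated cohorts at sparsity 0.10 on the four unnormalised global
metrics (1,600 t statistics for the Kolmogorov-Smirnov comparison against
t(30)); the session-selectivity check uses 100 cohorts with the default
+0.15 effect and the Cp ladder. The acceptance script reports the same
quantities from 100 and 50 cohorts respectively. Normalised metrics are
exercised on reference graphs (lattices, random graphs, complete graphs)
rather than inside these loops, because 100 rewired nulls per network
multiply the cost a hundredfold without changing what the calibration
measures: under the null the normalised metrics are t-tested the same way.

## Known limitations

* The generator's stationarity (one correlation matrix per run) ignores
  task-block-dependent connectivity; the `taskBlocksOnly` toggle changes
  which volumes enter the correlation, not the generating process.
* Motion regressors exist only as user-supplied surrogate nuisance columns;
  no claim is made about their realism.
* Weighted, directed, partial-correlation and community-detection analyses
  are out of scope.
* Small-worldness sigma is computed but has no external anchor value;
  treat its absolute level on synthetic cohorts as generator-dependent.

## A minimal run

```{r, eval = FALSE}
cfg <- pipelineConfig(spec = cohortSpec(seed = 7), nNull = 0, seed = 7L)
res <- runPipeline(cfg, "run_out")
head(res$globalComparisons)
subset(res$globalComparisons, significant_bonferroni)
```

`run_out/` then holds the resolved configuration, per-subject Fisher-z
matrices, the metric and centrality tables, and the comparison tables with
their provenance headers.
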