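---
title: "Methods: pathway-based integration of coupled omics time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-based integration of coupled omics time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathconsensus)
```

# The problem

Growth-factor stimulation triggers a layered cellular response: kinases are
phosphorylated within minutes, transcription factors (TFs) are activated,
immediate-early genes are induced within an hour, delayed and secondary
response genes follow, and newly translated proteins appear with a further
lag. Parallel time-course measurements on different layers
(phosphoproteome, transcriptome, proteome) each see only a slice of this
cascade, and each platform carries its own false positives.

`pathconsensus` integrates such coupled time courses through prior pathway
knowledge instead of comparing the layers directly. The key idea is a
*consensus* construction: a molecule is trusted only when two independent
routes through the knowledge base - one starting from significant
phosphoproteins and walking downstream, one starting from significant
transcripts and walking upstream - both reach it on the same cellular
layer at the same time point.

# Per-time-point layer analyses

**Downstream** (`run_downstream()`): phosphoproteins significant at time
`t` select every pathway whose gene set contains one of them; the TFs of
those pathways are their members that appear in the TF-to-target map; the
potential target genes are the union of those TFs' targets. Membership is
plain set intersection - no enrichment test - because the phosphoprotein
panels this analysis starts from are small and hand-picked, and a
hypergeometric test on a five-protein query is not informative.

**Upstream** (`run_upstream()`): transcripts significant at `t` select the
TFs with at least one significant target; pathways containing at least
`min_tfs` of those TFs (default 1) are hit; potential upstream proteomic
regulators are found by walking each hit pathway's directed topology
*against* the edge direction from its member TFs, up to `order = 10` steps.
Traversal is per pathway with results unioned, not on a merged supergraph:
pathway boundaries encode curated context, and merging topologies would
let signals jump between unrelated cascades through shared hub proteins.
Seed TFs are excluded from their own regulator set (the TF layer and the
protein layer are reported separately), and edge sign is ignored for
reachability - sign is annotation for interpretation, not a traversal
constraint.

**Consensus** (`intersect_layers()`): per layer and time point,

* proteins: significant phosphoproteins that are also upstream regulators,
* TFs: found by both analyses,
* genes: downstream target genes that are also significant transcripts.

# Static consensus graphs

Consensus proteins and TFs are mapped to a confidence-scored
protein-protein interaction (PPI) network and connected with a
Steiner-tree approximation (`steiner_tree()`): the metric-closure
2-approximation (all-pairs shortest paths between terminals, minimum
spanning tree of that closure, path expansion, spanning tree again, then
pruning of non-terminal leaves). Its weight is at most `2(1 - 1/k)` times
the optimal Steiner tree for `k` terminals; the test suite checks this
bound against exhaustive optima on hundreds of small random graphs.
Non-terminal connector nodes - *Steiner nodes* - are reported in their own
layer: they are candidate regulators that neither platform measured.

Numerical choices:

* Edge length is `1 - score`, so high-confidence interactions are short.
  An unweighted mode (`weighted = FALSE`) treats all edges equally.
* Shortest-path ties are broken toward the lexicographically smallest node
  sequence and spanning-tree ties by sorted edge key, making the graph a
  deterministic function of its inputs.
* Terminals in different PPI components yield a forest, not an error -
  real consensus sets are frequently disconnected.

The graph is completed with directed TF-to-target edges between consensus
TFs and consensus genes (only between consensus molecules: the target
universe of a TF is large, and non-consensus targets have no evidence at
this time point) and with a *feedback* edge from a gene-layer node to the
protein-layer node of the same symbol whenever both are present. Feedback
runs gene to protein: the transcript feeds the protein pool. Consensus
molecules without edges stay in the graph as isolated nodes, so the
boolean *static consensus profile* matrix (`consensus_profiles()`) always
reflects consensus membership over time.

# Dynamic consensus network

All consensus molecules (any time point) contribute their full measured
time course. Because the measurement grid is sparse and irregular, each
series is first densified (`densify()`) with a cubic smoothing spline
whose penalty is chosen by generalized cross-validation, evaluated on an
equally spaced grid of `n_grid = 50` points - enough to make lag-one
regression meaningful on a 7-point design without manufacturing detail
the data cannot support. This presumes signaling changes gradually between
samples; oscillations faster than the sampling interval are invisible by
construction. Each densified series is standardized to zero mean and unit
variance so that regression coefficients are comparable across molecules
and platforms (an `interpolate` mode passes exactly through the measured
points, for diagnostics and tests). Proteins and transcripts enter one
observed vector; layer tags are kept for reporting only.

The network model (`fit_dbn()`) is the linear feedback state-space model

$$x_t = A x_{t-1} + B y_{t-1} + w_t, \qquad w_t \sim N(0, I)$$
$$y_t = C x_t + D y_{t-1} + v_t, \qquad v_t \sim N(0, \lambda^{-1} I)$$

where `y` is the observed vector and `x` a K-dimensional hidden state
absorbing unmeasured drivers. The observed-feedback matrix `D` *is* the
network: `D[j, i]` is the influence of molecule `i` on molecule `j` one
step later. Each row of `A`, `B`, `C`, `D` carries a zero-mean Gaussian
prior whose precision is a hyperparameter updated by empirical Bayes at
every EM iteration, alongside the shared observation precision; hidden
states are integrated out with Kalman forward-backward recursions. EM
stops when the maximum relative change of all hyperparameters falls below
`tol = 1e-3` (default cap 100 iterations; a non-converged fit is returned
with a warning rather than discarded). All precision hyperparameters start
at 1, the model matrices are drawn from `N(0, 0.1^2)` under the run seed,
and one seeded start is used - results are bit-reproducible given (data,
K, seed). With `K = 0` the model reduces to a Bayesian vector
autoregression `y_t = D y_{t-1} + v_t`.

The hidden dimension is selected (`select_hidden_dim()`) from the singular
values of a block-Hankel matrix of sample autocovariances: the smallest K
whose cumulative singular-value mass reaches 0.90, capped at 5. An
all-zero Hankel matrix gives K = 0.

**Edges and calibration.** Each potential edge gets a z-score: posterior
mean over posterior standard deviation of the corresponding `D` entry.
`threshold_edges()` keeps edges with `|z|` above the two-sided standard
normal quantile for a chance-edge probability `alpha = 0.15`, signed by
the coefficient (activation/inhibition; self-loops allowed). Two
calibration facts are worth knowing, and the test suite pins both down:

* On an exact white-noise null fed directly to the fitter, the empirical-
  Bayes precisions grow without bound (the data genuinely contain no
  edges), z-scores become under-dispersed, and far *fewer* than
  `alpha` of the edges are flagged. This conservatism is a feature of
  shrinkage, not a defect.
* On the dynamic stage as actually run - independent noise at the seven
  measured time points, spline-densified, then fit - the smooth series
  retain real lag-one predictability, shrinkage stays moderate, and the
  flagged fraction sits near the nominal `alpha`. This is the regime the
  default threshold is used in.

# Time-profile clustering

Co-regulation patterns are found by fuzzy c-means (`fuzzy_cmeans()`) on
the standardized logFC profiles of every molecule appearing in at least
one consensus graph, proteins and transcripts as separate rows.
Standardization makes shape, not magnitude, drive the clusters - a weak
and a strong response with the same kinetics should cluster together.
Memberships are soft (`m = 2` by default; `m` near 1 approaches hard
clustering), the objective is non-increasing over iterations, and the
best of 10 seeded restarts by final objective is kept. A profile at zero
distance from a centroid is hard-assigned to it, which also resolves the
degenerate duplicate-row case.

**Choosing the cluster count** (`select_cluster_count()`): the minimum
pairwise centroid distance is tracked as `c` grows. While `c` is at or
below the number of distinct co-regulation patterns, centroids occupy
distinct patterns and stay separated; the first `c` that exceeds it forces
two centroids into one pattern and the minimum separation collapses. The
rule returns the largest `c` whose minimum separation still exceeds
`drop_frac = 0.3` times the separation at the smallest candidate. A
relative-decrease (curve-slope) criterion was considered and rejected:
plateau values of the minimum-distance curve fluctuate by up to a factor
of two across fuzzy c-means restarts, so slope-based elbows are unstable,
while the collapse detected by the absolute criterion is nearly an order
of magnitude and separates cleanly. Because clustering inputs are
standardized, "positive" and "negative" regulation of a cluster is judged
on the raw logFC profiles of its max-membership members, not on the
(zero-mean) centroids.

# Time-course integration

For each measured phosphoprotein, `integrate_time_courses()` collects its
downstream consensus transcripts (consensus genes that are targets of TFs
of hit pathways containing that phosphoprotein, unioned over time points)
and maps them to the proteome: transcripts whose protein product is
significantly differentially abundant at at least one time point become
matched transcript/protein pairs with both logFC series attached; the
rest are reported as unmatched. A Pearson correlation between the two
series summarizes correlating versus anti-correlating behavior - it is
descriptive only, since translational and post-translational lags make
the instantaneous correlation a blunt instrument on sparse grids.

# Significance conventions

Phosphoprotein and protein layers call a molecule significant when its
fold change reaches 1.5 in either direction (`call_significant_fc()`;
`|logFC| >= log2(1.5)`). The rule is two-sided because downstream analyses
treat down-regulation as informative. Transcript significance is expected
to arrive precomputed (`sig_` columns from a differential-expression
pipeline); when absent, the fold-change rule is applied as a fallback with
a warning. Missing values are not supported anywhere: the spline and
state-space stages need complete series, and imputation policy is outside
this package's scope.

# The synthetic-data generator

`make_knowledge_base()` / `make_coupled_timecourses()` build a fully
specified test world: a pathway carrying a planted cascade
(upstream regulator X0 -> kinase K0 -> TF0, as topology and as
high-confidence PPI edges), background pathways and TFs drawn at random,
and coupled time courses on the default 7-point grid
(0, 1, 4, 8, 13, 18, 24 h). The planted kinase follows a rapid-rise /
slow-decay phosphorylation curve crossing the 1.5-fold threshold from 1 h
on; planted targets rise with an exponential saturation curve (amplitude
1.5 log2 units, about a 2.8-fold change - a moderate, realistic response)
after their onset, immediate at 1 h and delayed at 8 h, emulating the
wave-like immediate/delayed/secondary response tiers; planted proteins
follow their transcripts shifted by a 4 h lag. All other molecules are
i.i.d. Gaussian noise on logFC (sd 0.2 by default). Piecewise-smooth
curves keep spline densification well-posed.

`make_coregulation_profiles()` draws labeled profiles from the four
sign-by-onset archetypes (up/down crossed with immediate/delayed), using
the same response family and amplitude as the planted cascade, plus noise.

What the generator does *not* emulate - and what passing tests therefore
do not establish about real data: platform-specific noise (MS intensity
dependence, probe effects), missing values, correlated noise across
molecules, phosphosite-level resolution (the package works at gene-symbol
level throughout), redundant pathway annotations across source databases,
and scale-free PPI topology. The fixtures demonstrate correctness of the
machinery, not robustness to real-data pathologies.

# Pipeline and reproducibility

`run_pipeline()` (and the `pathconsensus` CLI under `inst/cli/`) executes
the stages in order from one configuration - defaults: `min_tfs = 1`,
`order = 10`, `fold_threshold = 1.5`, `min_score = 0.4`, `n_grid = 50`,
`K = "auto"`, `alpha = 0.15`, `c = 4`, `m = 2` - and writes TSV/GraphML/
SIF/JSON artifacts plus a manifest with input hashes, parameters, version
and seed. All randomness derives from the one configured seed; reruns are
byte-identical, and composing the exported stage functions manually
reproduces `run_pipeline()` exactly.

Problem sizes used by the test suite were chosen to make each check
decisive at desk scale: 20 replicate null datasets of 10 molecules for
threshold calibration, 200 random graphs of up to 12 nodes against
exhaustive Steiner optima, 20 seeds of a 5-molecule, 200-step vector
autoregression for edge ranking, and 100 archetype profiles for cluster
recovery.

# Known limitations

* Linear first-order dynamics only; oscillatory or switch-like signaling
  on sub-sampling-interval time scales is not identifiable here.
* The consensus construction inherits the knowledge base's blind spots: a
  true regulator absent from pathways, TF maps or the PPI cannot appear.
* Pathway sets from several source databases are kept as-is, so partially
  redundant pathways are counted separately in hit lists.
* Symbol harmonization is syntactic (trim, upper-case, optional alias
  table); no ortholog or identifier-history resolution.
* The z-score threshold controls a per-edge chance probability, not a
  network-wide error rate; dense networks at `alpha = 0.15` should be
  read as candidate sets.
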