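---
title: "Methods: stability-driven community discovery and classification in signed co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-driven community discovery and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`coexcomm` discovers groups of co-expressed genes that discriminate tumor
from non-tumor samples in bulk expression data (the motivating setting is
hepatocellular carcinoma microarray cohorts), and quantifies how much each
gene contributes to that discrimination. The pipeline has three phases:

1. **Community detection.** A signed, fully weighted co-expression network
   is built (nodes are genes, edge weights are Pearson correlations across
   samples) and partitioned with a hierarchical Leiden procedure. At every
   level a candidate partition is retained only if it is *stable*,
   *non-trivial* and *non-fragmented* (below).
2. **Learning.** Each final community is filtered by a shadow-feature
   (Boruta-style) wrapper on a dedicated 40% sample split, and the selected
   genes feed a random forest evaluated by stratified 5-fold
   cross-validation repeated many times on the remaining 60%. Communities
   whose mean CV accuracy exceeds a retention cutoff (default 90%) are
   carried forward and can be re-scored on an external cohort.
3. **Explanation.** The per-community classifiers are explained with
   Shapley values: an exact subset-enumeration implementation for small
   communities and a permutation-sampling estimator for the general case.

Every stage is deterministic given one master seed, and a synthetic-data
generator with planted ground truth makes each stage testable without any
external download.

# The signed network and its quality function

Gene-gene edge weights are correlations, so the network carries both
positive and negative edges. Standard Newman–Girvan modularity is
undefined for negative weights; we optimize the layer-weighted signed
modularity of Gómez, Jensen & Arenas:

$$Q \;=\; \frac{2m^+\,Q^+ \;-\; 2m^-\,Q^-}{2m^+ + 2m^-},$$

where $Q^{\pm}$ is the $\gamma$-resolution modularity of the
positive-weight (respectively absolute-negative-weight) layer with its own
configuration-model null, and $2m^{\pm}$ are the layer weight totals. This
rewards positive weight inside communities and negative weight between
them, and it reduces exactly to plain modularity when the network has no
negative edges.

We deliberately did **not** use the unweighted difference $Q^+ - Q^-$.
When the negative layer is nearly empty — which is exactly the situation
in a network of independent modules, where negative correlations are pure
sampling noise — the unweighted form lets the negative layer's null term
act as a merge bonus of order $\gamma\,\Delta\sum_c (K^-_c/2m^-)^2$,
independent of how little weight that layer actually carries. On planted
benchmarks this makes the global optimum merge genuinely separate modules
(we verified numerically that the merged partition scores higher than the
planted one, cross-checking both layers against igraph's modularity). The
layer-weighted form has no such pathology and satisfies the same sanity
anchors: the two-clique toy scores 0.5, the trivial partition scores 0,
and flipping every edge sign negates $Q$.

The optimizer itself (in C++) follows the Leiden cycle: greedy local moves
over a random visit order, a refinement phase in which singleton nodes
merge into refined communities within their parent community with
probability proportional to $\exp(\Delta Q/\beta)$, then aggregation, all
iterated from a random initial assignment until the quality stops
improving. On a complete weighted graph every pair of nodes is adjacent,
so the connectivity guarantees of the refinement phase are trivially
satisfied; the randomness parameter $\beta$ and the resolution $\gamma$
are the two tuned parameters. Runs are reproducible: all randomness flows
from one Mersenne–Twister stream seeded per run.

# Stability selection

The Leiden heuristic is stochastic, so a partition is trusted only if the
algorithm keeps finding it. For each $(\gamma,\beta)$ configuration on a
grid (defaults $\gamma \in \{0.5, 0.75, 1, 1.25, 1.5\}$,
$\beta \in \{0.01, 0.05, 0.1\}$) we perform $L$ seeded runs (default 100)
and compute

* the **majority partition** — the most frequent partition up to label
  permutation, with frequency ties broken by higher signed quality and
  then by lexicographically smallest canonical labeling, so the procedure
  is fully deterministic; and
* the **mean pairwise NMI** over all $L(L-1)/2$ run pairs, with
  $\mathrm{NMI}(a,b) = 2I(a;b)/(H(a)+H(b))$ in natural logs (the
  normalization used by igraph's `compare(..., method = "nmi")`; when both
  partitions are trivial the value is defined as 1).

A configuration is **accepted** iff the majority partition is
stable ($\langle \mathrm{NMI}\rangle \ge 0.80$), non-trivial (at least two
communities) and non-fragmented (no community smaller than 5% of the
current subnetwork; the comparison is strict, so a community of exactly 5%
survives). Among accepted configurations the one with the highest
$\langle\mathrm{NMI}\rangle$ wins (ties: smaller $\gamma$, then smaller
$\beta$). The 5% rule is applied to the *current* subnetwork during
recursion — the local reading; a root-relative reading would make deep
nodes nearly unconstrained.

Detection recurses depth-first: communities of at least 100 genes are
re-partitioned on their induced subnetwork (edge weights inherited, not
recomputed — the procedure partitions one fixed network); communities of
4–99 genes become leaves; communities under 4 genes are discarded but
serialized with the reserved leaf id 0 so gene accounting is conserved. A
node of 100+ genes where no configuration is accepted is recorded as
unresolvable rather than force-split or silently dropped.

# Feature selection and classification

Within each leaf community the gene count can still exceed what a
classifier comfortably handles at microarray sample sizes, so each
community is filtered by a re-implementation of the Boruta shadow-feature
wrapper: at every iteration each candidate feature competes against fresh
per-column permutations of the candidates ("shadows"); a feature scores a
hit when its out-of-bag permutation importance exceeds the best shadow's;
binomial tests of the hit count against $\mathrm{Bin}(n, 1/2)$ at a
Bonferroni-corrected $\alpha$ (default 0.05) confirm persistent winners
and eject persistent losers. Features still tentative at the iteration cap
are excluded from classification by default (conservative), with a flag to
include them.

To prevent leakage, feature selection runs on a dedicated stratified 40%
sample split drawn once per experiment; classification uses only the
remaining 60%. The classifier is a random forest of $M = 300$ CART trees
with all features eligible at every split ($s = |S|$, i.e. bagged trees) —
both values deliberately mirror the reference configuration, with
$\sqrt{|S|}$ available behind a flag. Performance is estimated by
stratified 5-fold cross-validation repeated (default 100 times; the test
suite and the bundled acceptance runs use 10 repeats to keep desk-scale
runtimes, a problem-size choice stated here once); each repeat pools its
held-out predictions into one set of metrics, and results are reported as
mean ± SD over repeats. Pooling per repeat rather than per fold stabilizes
AUC on small folds.

Metrics: accuracy, AUC (rank/pair-counting definition with half credit for
ties), F1 for the tumor class (0 when there are no true positives), and
the standard non-negative natural-log cross-entropy loss with
probabilities clipped to $[10^{-15}, 1-10^{-15}]$. External validation
matches genes by identifier, imputes genes missing from the external
cohort at their training means (with a logged count), and reports single
point estimates.

# Shapley explanation

For a community classifier $f$ and sample $x$, the attribution of feature
$j$ is the Shapley value over feature subsets with the factorial weights
$|F|!\,(|S|-|F|-1)!/|S|!$. The value of a subset $F$ is the
*interventional expectation*: the model's mean prediction over a fixed
background sample set with the features in $F$ pinned to $x$'s values.
Retraining the model on every subset would be the literal game-theoretic
reading but is computationally prohibitive and is not what any practical
explainer does; the interventional surrogate is the accepted choice and is
used consistently by both implementations, so they estimate the same
quantity. `exact_shap()` enumerates all subsets (capped at 15 features);
`approx_shap()` Monte-Carlo-samples feature orderings and credits each
feature with its marginal change, which telescopes so the local-accuracy
identity $\mathrm{base} + \sum_j \phi_j = f(x)$ holds exactly at any
number of permutations. Attributions are in probability space (tree-vote
fractions), so values lie in $[-1, 1]$. Explanations are computed for
held-out (selection-split) samples with the classification-split model,
preserving the pipeline's leakage discipline. Summaries rank features by
mean $|\phi|$ and report a direction — the sign of the correlation between
feature value and attribution — so "high expression pushes toward tumor"
is read directly off the summary.

# The synthetic-data generator

The generator emulates the structure of the motivating two-cohort liver
microarray study without reproducing any of its measurements. Defaults
mirror the study's sample counts (152 tumor, 91 adjacent, 14
metastasis-adjacent samples) on a five-module layout (60/50/40/30/20
genes) plus 100 noise genes.

Each module $m$ has one latent factor per sample,
$z_s \sim N(\mu_{\mathrm{class}}, 1)$; gene $g$ in $m$ is
$b_g + \lambda z_s + \varepsilon$, with $\lambda = \sqrt{\rho}$,
$\varepsilon \sim N(0, \sqrt{1-\rho})$, so the model-implied within-module
correlation is exactly $\rho$ (default 0.8) and the analytic value can be
tested against the sample correlation. Class effects shift the *factor*
(all genes co-shift, matching the premise of a discriminative community),
noise genes are i.i.d., and per-gene baselines $b_g \sim N(7, 0.5)$ give a
log2-microarray-like scale. Nested designs add a weak super-module factor:
$x = a u + b z_{\mathrm{child}} + \varepsilon$ with $a^2 = \rho_{\rm
super}$, $b^2 = \rho - \rho_{\rm super}$, planting an exactly two-level
hierarchy.

Two properties of the generator deserve emphasis:

* **In-sample factor decorrelation.** Module factors are jointly
  orthogonalized (and exactly standardized) in-sample before class shifts
  are applied. Without this, the sample correlation between two "independent"
  factors drifts by $O(1/\sqrt{n})$ — about ±0.065 at $n = 240$ — which
  plants coherent spurious correlation blocks between modules, and merging
  such modules can become *genuinely* optimal for any modularity-type
  objective. The planted truth would then not be identifiable, through no
  fault of the detector. With decorrelation, between-module correlation
  equals its model-implied value exactly, and any cross-module structure
  that remains is either residual gene noise or honestly induced by shared
  class membership.
* **A Bayes ceiling on classification.** Because the class signal lives
  only in the factor means, the best achievable accuracy on a single
  discriminative module is $\Phi(\mathrm{effect}/2)$ regardless of how
  many genes the module has (genes average out $\varepsilon$ but cannot
  reduce factor overlap). An effect of 2 SD caps accuracy at
  $\Phi(1) \approx 84\%$; the default effect size is 3 SD, whose ceiling
  $\Phi(1.5) \approx 93\%$ sits above the 90% retention cutoff the
  pipeline demonstrates. Measured CV accuracies on planted data sit 0–2
  points below these ceilings, which is the expected estimation loss.

What the generator does **not** emulate: probe-level noise, batch
effects, platform mapping, heavy-tailed expression, or correlated noise
genes (an optional weak global factor exists to stress-test
fragmentation). Passing tests on this generator therefore demonstrate the
pipeline's correctness and calibration on block-factor data, not
performance on any particular real cohort.

# Preprocessing and the unsupervised check

The pipeline starts from a normalized (or synthetic) matrix; probe-level
background correction is out of scope. `log2_transform()` and
`quantile_normalize()` (via limma, average-of-span tie convention) are
provided; quantile normalization forces every sample to the identical
sorted value multiset and is idempotent.

One caveat worth knowing: when a large fraction of genes truly shifts in
one direction in one class, quantile normalization redistributes that
shift into the remaining genes with opposite sign. On synthetic data with
many discriminative genes this can make *noise* genes form a coherent,
class-correlated community. This is a well-known property of
quantile normalization, not an artifact of this implementation; the
ground-truth comparisons in the tests therefore run on the unnormalized
synthetic matrix, while the end-to-end pipeline exercises the normalized
path.

The unsupervised check mirrors the exploratory step of the motivating
study: WSS for $k = 1..k_{\max}$ and mean silhouette for $k \ge 2$ over
samples, $k$-means (best-of-25 Lloyd restarts) at the silhouette-optimal
$k$, and a class-by-cluster contingency table reporting what percentage of
a designated class union (normal + peritumoral) lands in its joint
majority cluster. On merge-check data generated with zero peritumoral
shift, k-means cannot and should not separate the two non-tumor classes,
and the co-assignment percentage is the quantitative witness. The
clustering runs on all genes by default (the minimal reading when the
feature space is unstated); a top-variance-gene option exists. Empirical
co-assignment runs one to two points below the idealized
$\Phi(\sqrt{k}\,d/2)$ bound because centroids are estimated from noisy
high-dimensional data.

# Numerical choices and edge cases

* Per-run seeds derive from `(master_seed, gamma, beta, run_index)` by an
  integer mixing function, so runs are independent and reproducible, and
  all derived seeds stay below $2^{31}$.
* Quality comparisons in the optimizer use an absolute epsilon of
  $10^{-12}$; majority-vote quality ties use the same epsilon.
* Partitions are canonicalized by first-appearance relabeling; equality up
  to label permutation is equality of canonical forms.
* Degenerate inputs error early and loudly: constant genes are dropped
  (warning) before correlation, all-constant matrices, single-sample
  quantile normalization, single-class labels and sub-minimum root
  networks are errors naming the offending object.
* Probabilities are clipped before the log loss; AUC uses midranks, so
  tied scores receive half credit, matching the pair-counting oracle to
  machine precision.
* The expression writer prints doubles with `%.17g`, so matrix round-trips
  through TSV are bit-exact.

# Known limitations

* The signed Leiden implementation targets dense networks (co-expression
  matrices); it makes no attempt at sparse-graph data structures and is
  not intended for networks beyond a few thousand nodes.
* Stability selection reports a single winning configuration per node; it
  does not attempt multi-resolution consensus across configurations.
* Boruta's importance source is the forest's OOB permutation importance;
  alternative importance measures (impurity) are available but not
  calibrated here.
* The SHAP estimator assumes feature independence in the background
  (interventional semantics); strongly correlated features share credit
  accordingly, which is the standard behavior, not a defect, but should be
  kept in mind when reading per-gene attributions inside a correlated
  community.
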