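---
title: "Balance-weighted phylogenetic diversity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balance-weighted phylogenetic diversity: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwpd)
```

## The model

The data are a rooted, edge-weighted phylogenetic tree whose leaves are
OTUs (or taxa), and a contingency table of non-negative integer counts —
how many reads of each leaf were observed in each sample. Root placement is
a bookkeeping device: pick any root, call the side of an edge containing
the root *proximal* and the other side *distal*, and let $D_s(i)$ be the
fraction of sample $s$'s $n$ reads at leaves distal to edge $i$, with
$\ell_i$ the edge length and $d_i = n D_s(i)$ the distal read count.

Classical unrooted phylogenetic diversity is the total length of edges with
reads on both sides,
$$\mathrm{PD_u}(s) = \sum_i \ell_i\, g(D_s(i)),$$
where $g$ is 1 on the open unit interval and 0 at its endpoints. Since
$g$ is the pointwise limit as $\theta \to 0$ of
$$g_\theta(x) = \left[\,2\min(x, 1-x)\,\right]^{\theta},$$
PD embeds in a one-parameter family,
$$\mathrm{BWPD}_\theta(s) = \sum_i \ell_i\, g_\theta(D_s(i)),$$
which at $\theta = 1$ weights each edge by the *balance* of read mass
across it, $2\min(x,1-x) = 1 - |x - (1-x)|$. Intermediate $\theta$ is a
partially-abundance-weighted compromise; the exposed default grid is
$\theta \in \{0, 0.25, 0.5, 1\}$. The rooted analogue drops the symmetry:
$\mathrm{RBWPD}_\theta(s) = \sum_i \ell_i D_s(i)^\theta$.

Because $g_\theta$ and $d(n-d)$ are symmetric under the distal/proximal
flip $x \leftrightarrow 1-x$, the unrooted measures —
$\mathrm{PD_u}$, every $\mathrm{BWPD}_\theta$, and phylogenetic quadratic
entropy — are invariant under rerooting at any node (`reroot()`); the
rooted measures ($\mathrm{RBWPD}_\theta$, phylogenetic entropy, Hill
$^qD(T)$) are not, and the package requires the caller to fix the root
deliberately rather than guessing one.

The remaining phylogenetic measures follow the standard generalizations:
quadratic entropy $\mathrm{PQE} = n^{-2}\sum_i \ell_i d_i (n - d_i)$
(the phylogenetic Gini–Simpson), phylogenetic entropy
$-\sum_i \ell_i p_i \ln p_i$ (Shannon), and the order-$q$ Hill form
$^q\bar D(T) = \big[\sum_{a_i>0} (\ell_i/\bar T)\, a_i^q\big]^{1/(1-q)}$
with $\bar T = \sum_i \ell_i a_i$, taking the $q\to1$ limit
$\exp(-\sum (\ell_i/\bar T) a_i \ln a_i)$ at $q = 1$. On a star tree with
unit branch lengths each reduces exactly to its discrete counterpart,
which the test suite asserts.

## Conventions and numerical choices

* **$0^\theta := 0$** in $g_\theta$ and $\mathrm{RBWPD}_\theta$ for every
  $\theta \ge 0$ (including $0^0$), so $\theta = 0$ reproduces PD exactly —
  the pointwise-limit convention.
* **Natural logarithms** for all entropies (configurable base), matching
  the defaults of the common R implementations.
* **Counts, not proportions, are canonical.** Rarefaction and
  $E[\mathrm{PQE}_k]$ require integers; proportions are derived internally.
* **Hill form:** `hill_qdt()` returns the mean-diversity
  ("effective number of species") form $^q\bar D(T)$; whether tools in the
  wild report that or the product $\bar T \cdot {}^q\bar D(T)$ varies, so
  the scaled product is exposed via `scaled = TRUE` and the default is
  documented here.
* **Edges belong to their child node**; the root carries no edge. This
  makes every sum over edges unambiguous, including for multifurcating
  trees, which are processed as-is (no measure here needs a binary tree).
* **Missing Newick branch lengths become 0 with a warning** rather than an
  error: zero-length edges contribute nothing to any measure.
* **Strict tree/table alignment is the default**; a label mismatch is
  almost always an upstream bug, so silent intersection is opt-in
  (`mode = "intersect"`).
* **Tree representation.** Trees are stored in parent-vector form
  (`ptree`) rather than as `ape` `"phylo"` objects, because two legitimate
  degenerate inputs — a single-leaf tree and a tree rerooted at a leaf —
  are not representable as valid `phylo` objects. Newick *parsing* is still
  delegated to `ape::read.tree`.
* **q = 1 handling:** `hill_qdt` switches to the entropy limit within
  `1e-10` of $q = 1$; continuity is tested numerically at $q = 1 \pm 10^{-4}$.

## Rarefaction

Rarefaction means sampling $k$ reads *without replacement* (multivariate
hypergeometric over leaves) — the model under which the closed form
$$E[\mathrm{PQE}_k] = \frac{k-1}{k\,n\,(n-1)} \sum_i \ell_i d_i (n - d_i)
  = \mathrm{PQE}\cdot\frac{(k-1)\,n}{k\,(n-1)}$$
holds, which the suite verifies against exhaustive enumeration of all
$\binom{n}{k}$ read subsets at small $n$ and against Monte Carlo at
$n = 1000$. The factor $(k-1)n/(k(n-1))$ is increasing in $k$ and reaches
1 at $k = n$: rarefaction can only *decrease* expected quadratic entropy,
and barely does so for large $k$. No comparably simple form is apparent
for $\mathrm{BWPD}_\theta$ or phylogenetic entropy (non-integer moments of
the hypergeometric intervene), so only Monte Carlo means are offered for
those.

The batch protocol (`diversity_matrix(..., rarefy = list(k = "min",
R = 100, seed))`) mirrors standard practice: rarefy every sample to the
depth of the shallowest one and average each statistic over 100 draws.
Replicate seeds are derived deterministically from the top-level seed, so
runs are reproducible and replicate order is irrelevant; all measures for
one sample share the same draws, so measure comparisons are paired. One
caveat found while validating: seeds derived from small arithmetic
progressions produce draws correlated enough to bias a 3-standard-error
Monte-Carlo test at $n = 1000$, so the *calibration tests* use one
continuous RNG stream; the derived-seed scheme is retained for the batch
API, where determinism matters and bias of that size is immaterial.

`sensitivity_experiment()` quantifies how much each measure moves under a
single rarefaction, summarised per measure as the mean absolute relative
deviation over samples, $\mathrm{MARD} = \overline{|v_k - v|/v}$ (samples
with $v = 0$ excluded and counted). The underlying figure-style experiment
shows a scatter without naming a statistic; MARD is this package's choice,
made once and tested: on the default synthetic fixture MARD is strictly
decreasing in $\theta$ over $\{0, 0.25, 0.5, 1\}$ — abundance weighting
buys robustness to sampling depth.

## The synthetic two-state generator

No external dataset ships with the package; `simulate_two_state()` is a
first-class module that emulates the structure of dysbiosis studies in
which one community state is dominated and the other even. State `L`
draws leaf proportions from a Dirichlet with one *dominant* leaf (weight
`alpha_dom = 10`, background `alpha_bg = 0.1`; the dominant leaf is
redrawn per sample, mimicking different dominant taxa across subjects,
with a fixed-dominant mode behind a flag); state `H` uses a symmetric
Dirichlet(1). Counts are multinomial at a per-sample depth drawn uniformly
from [500, 2500] — unequal depths of the order seen in small amplicon
surveys, chosen once so the rarefy-to-minimum machinery is exercised
realistically. Defaults are 64 leaves and 50 samples per state. Metadata
adds a state-dependent Gaussian `score` (means 2 and 7, sd 1.5, clipped to
[0, 10]) emulating a 0–10 clinical severity scale, and an *independent*
two-level `stratum` ("siteA"/"siteB") — deliberately a null
stratification, useful for type-I-error checks; the spec-level metadata
schema required a stratum column but left its meaning open, and a null
factor is the one choice that cannot smuggle signal into the comparative
module.

What a green test on this generator does **not** establish: performance on
real communities. The generator has no read-level noise, no chimeras, no
placement uncertainty (read mass sits exactly at leaves — the model is
exact for OTU-table workflows but not for placement-based ones, where mass
can sit on interior edges), and its two states are far better separated
than most real contrasts. Green means the machinery is correct and the
qualitative orderings hold in a world stated in advance, not that any
particular accuracy will transfer.

## The comparative framework

`compare_measures()` evaluates each measure as a *sole predictor* of the
metadata: leave-one-out logistic accuracy at probability cutoff 0.5 for a
binary state, squared Pearson correlation for a continuous score, Welch's
t-test (two groups; pooled by flag) or fixed-effects ANOVA (more strata;
additive two-factor form when a second factor is supplied, first factor
reported) for stratifications. P-values are deliberately *uncorrected* —
they are used as descriptors of within- versus between-stratum
heterogeneity, not as evidence. Measures are then ranked within each
metric (average ranks on ties; accuracy and $R^2$ high-is-better,
p-values low-is-better) and ordered by mean rank. Measure similarity is
summarised by Pearson correlation and complete-linkage clustering at
distance $1 - r$, exported as a Newick dendrogram.

A limitation worth knowing: leave-one-out misclassification accuracy at a
0.5 cutoff is *pessimistically biased*, and with exactly balanced classes
and an uninformative predictor it degenerates — removing one sample makes
the other class the training majority, so a near-intercept-only classifier
misclassifies every held-out sample and accuracy approaches 0 rather than
0.5. This is a property of the estimator (the reference implementation
`boot::cv.glm` returns identical values fold for fold, which the suite
asserts), not of this implementation. Under the package's balanced null
fixture, accuracy should therefore be read as "at or below chance", and
the test suite asserts exactly that one-sided property.

## Known limitations

* Leaf-count read model only; interior-edge (placement) mass is out of
  scope.
* Alpha diversity only — no UniFrac-style beta diversity.
* Closed-form rarefaction expectations exist here only for quadratic
  entropy.
* The comparative module assumes complete metadata for the samples it is
  given; it does not impute.
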