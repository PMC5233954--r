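---
title: "Methods: altered pathway identification from co-expression rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: altered pathway identification from co-expression rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathrewire)
```

## The problem

Pathway-level analyses of case/control expression data usually ask whether a
gene set is differentially *expressed*. `pathrewire` asks a different
question: whether the *co-expression wiring* of a gene set changes between
conditions, and whether that change is driven by transcription factors (TFs)
whose targets respond. A pathway can be strongly rewired while almost none of
its genes pass a differential-expression cutoff, which is exactly the
situation where expression-centric tools stay silent.

The pipeline has four stages: (1) build a single *rewired network* whose
edges are gene pairs with significantly changed Pearson correlation;
(2) overlay a known TF-to-target network to flag *regulatory rewired edges*
whose target is differentially expressed; (3) score and rank pathway gene
sets; (4) optionally propagate disease seed genes over the rewired network
and prioritize individual genes.

## Rewiring detection

For each gene pair the per-group Pearson correlations $r^{case}, r^{ctrl}$
are Fisher-transformed, $z = \operatorname{atanh}(r)$, and compared with the
classic two-sample correlation difference statistic

$$\mathrm{rewire} = \frac{z^{case} - z^{ctrl}}
  {\sqrt{1/(n_{case}-3) + 1/(n_{ctrl}-3)}},$$

which is approximately standard normal when the pair's correlation is
unchanged. The statistics of the full tested edge set are then standardized
($Z_i = (x_i - \mu)/\sigma$, population $\sigma$; a sample-sd mode is
available via `sd_mode`), converted to two-tailed normal p-values, and
BH-adjusted across all tested pairs. Edges with adjusted $p \le \alpha$
(default 0.05) form the rewired network, and each retained edge carries the
score $\delta = 1 - p_{adj} \in (0.95, 1]$ — the simplest monotone transform
of significance that can be summed in the pathway scores below.

Assumptions worth stating: values are treated as log-scale intensities;
correlations are plain Pearson (no soft thresholding, no partial
correlations); missing values are rejected at read time rather than handled
pairwise; genes with zero variance in either group are removed first, and the
intersection of surviving genes defines the analysis universe.

Two tunables matter in practice:

* `r_min` (default 0.2): gene pairs with $\max(|r^{case}|, |r^{ctrl}|) <
  r_{min}$ are dropped before testing, restricting the test to pairs that are
  connected in at least one condition. Setting 0 disables the floor. Note a
  side effect: the floor selects pairs with large estimated correlations, so
  under the null the selected statistics have an inflated spread, and the
  score standardization becomes more conservative. On data sets with very few
  genes (small universes) this can noticeably reduce power; the null
  *calibration* of the raw p-values (without the floor) is unaffected and is
  checked in the test suite.
* `sd_mode`: the standardization divisor. The population form is the
  default; with thousands of tested pairs the two are indistinguishable.

Differential expression is computed per gene as the difference of group
means (logFC, case minus control) with a Welch two-sample t-test and BH
adjustment. Moderated (empirical-Bayes) statistics are deliberately not
reimplemented: only the logFC and a significance flag feed the downstream
scores, and at the sample sizes this pipeline targets (tens per group) the
Welch test is an adequate surrogate.

## Regulatory overlay

An undirected rewired edge $\{a, b\}$ is *regulatory* when $(a \to b)$ or
$(b \to a)$ is in the user-supplied TF-to-target network and the target is
significantly DE (`de_alpha`, default 0.05). Both directions may hold for
mutual TF pairs and both annotations are kept. `de_mode` chooses between
accepting DE in either direction (`"any"`, default) or up-regulated targets
only (`"up"`): TF-driven responses are often described as up-regulation of
targets, but rewired regulation of down-regulated programs (e.g. metabolic
genes in tumors) is just as interpretable, so the permissive reading is the
default. Whether the TF itself should be non-DE is not enforced; users who
want the "TF constant, targets move" signature can filter on the TF's
`de_adj_p` in the gene table.

## Pathway scores

For a pathway with $T$ genes mapped into the universe, $M = T(T-1)/2$
possible intra-pathway pairs, and $m$ retained intra-pathway rewired edges
with scores $\delta_i$:

* rewiring density $R = \sum_{i=1}^m \delta_i / M \in [0, 1]$;
* differential regulation $D_r = \frac{1}{t}\sum_{j=1}^t |f_j|$, the mean
  absolute logFC over the $t$ distinct DE targets carrying at least one
  regulatory rewired edge (a target regulated by several TFs counts once).
  The per-target regulatory edge counts $n_j$ are reported, and an
  edge-count-weighted variant $\sum n_j |f_j| / \sum n_j$ is available
  (`weighted_dr`), but the default follows the plain average. Absolute
  values are used because signed fold changes of co-regulated up and down
  programs would cancel;
* the raw alteration score $R + D_r$ is z-normalized (population sd) over
  $d$, the set of pathways with at least one rewired edge — intra-pathway
  ($m \ge 1$) or regulatory ($t \ge 1$) — giving the alteration score $D_y$.
  Pathways outside $d$ carry no $D_y$. When $|d| = 1$ or the raw scores are
  constant, $D_y = 0$ for all members.

Membership in $d$ includes the $t \ge 1$ pathways on purpose: a pathway whose
wiring to its regulators changes is altered even if no intra-pathway pair
passes the edge FDR, and excluding those pathways would blind the score to
purely regulatory rewiring (it would also make the simulation benchmark below
insensitive to its main parameter). Since $D_y$ is a monotone transform of
the raw score, the ranking within $d$ never depends on this choice.

Classification is gated: *altered* requires over-representation of rewired
genes in the pathway (one-sided Fisher's exact test against the universe,
BH-adjusted $p \le$ `enrich_alpha`) and $m \ge 1$; *differentially
regulated* additionally requires $D_r >$ `dr_threshold` (default 0.05).
Altered pathways are ranked by $D_y$.

Permutation significance re-runs the full pipeline on label-shuffled pooled
samples (group sizes preserved) and reports the add-one empirical p-value
$(1 + \#\{raw_{perm} \ge raw_{obs}\})/(B + 1)$, BH-adjusted across pathways.
The *raw* score is permuted rather than $D_y$ so one pathway's null does not
depend on which other pathways were co-shuffled.

## Disease-gene propagation

Random walk with restart on the $\delta$-weighted rewired network:
$p^{t+1} = (1-r)\,W p^t + r\,p^0$ with $W$ the column-normalized adjacency,
$p^0$ uniform over the mapped seed genes, and restart $r = 0.75$ (the
customary default of network propagation packages; configurable). Iteration
stops when the L1 change drops below `tol` ($10^{-10}$); the fixed point
equals the direct linear solve, which the test suite checks to $10^{-8}$.
The per-pathway disease score sums the endpoint affinities of every
intra-pathway rewired edge and divides by $m$ (so pathways are not penalized
for untested pairs); an $M$-divisor mode is provided. Components without
seeds legitimately receive near-zero mass.

## Gene prioritization

Four node centralities are computed on the rewired network: degree
(unweighted count), local clustering coefficient (unweighted, 0 for degree
< 2), and closeness and PageRank (damping 0.85) on the $\delta$-weighted
graph, with closeness using distance $1/\delta$ so stronger rewiring means
shorter distance (an unweighted mode is available). Each centrality is
z-standardized across network nodes and the composite centrality $cs$ is
their mean; raw degree would otherwise dominate the other three. The local
rewiring score of a gene is the z-standardized sum of $\delta$ over its
incident edges — a reconstruction chosen for being the simplest
node-level aggregate of edge rewiring strength on the same z-like scale as
$cs$.

## Simulation benchmark

The benchmark plants known truth into a scale-free network and asks whether
$D_y$ finds it. Per replicate:

1. a 2000-node Barabasi-Albert graph (attachment $m = 3$) gets edge weights
   Uniform(0.2, 1), read as true correlation strengths;
2. 10 *DR pathways* of 100 genes (mutually disjoint) and 90 *null* gene sets
   of 50-100 genes are sampled, with the null sets drawn from a pool
   disjoint from the DR genes; 300 nodes are reserved outside all gene sets
   as regulatory partners. (With 100 gene sets of these sizes fully disjoint
   assignment would need ~7,800 of the 2,000 nodes, so the null sets may
   overlap one another; they never overlap the DR sets, which is what the
   truth labels require.);
3. in the case copy, each DR pathway has one intra-pathway edge weight
   replaced by Uniform(0, 1) (the edge is added first if the pathway has
   none), and a proportion $\gamma$ of its genes each get one edge to a
   reserved partner rewired the same way; the partners are recorded as TFs
   of those genes and the targets stamped significantly DE
   ($|logFC| \sim$ Uniform(0.5, 2)); null-set intra edges are never touched;
4. observed per-group correlations are sampled from the Fisher model,
   $\operatorname{atanh}(\hat r) \sim N(\operatorname{atanh}(r), 1/(n-3))$
   with a nominal $n = 50$ per group, and the identical detection code path
   (statistic, standardization, BH, $\delta$) runs on the interaction list;
5. all 100 gene sets are scored and the Mann-Whitney auROC of $D_y$ against
   the 10-vs-90 truth is recorded (unscored pathways rank jointly last).

Step 4 is the one place the design goes beyond reading the weights directly
as correlations. A noiseless comparison of two weight graphs has no sampling
distribution: unchanged edges give a statistic of exactly zero, the spread of
the score set is then set entirely by the injected signals, and detection
becomes *easier* as fewer signals are planted — the benchmark's accuracy
would fall as $\gamma$ rises, inverting the property it is supposed to
measure, and null gene sets could never produce a false positive. Sampling
the observed correlations from the very noise model the rewiring statistic
assumes restores a genuine null (nominal false-positive behaviour on
unchanged edges) and makes detection power grow with the planted signal, so
accuracy increases monotonically with $\gamma$. The nominal $n$ is
configurable (`n_sim`), and the noiseless variant is kept behind
`noise = FALSE` for inspection.

Problem sizes: the packaged tests and the acceptance script run 20
replicates per $\gamma$ scenario (the benchmark is stable at that depth;
standard errors of the mean auROC are about 0.015-0.02 at the least
favourable $\gamma$), and the full five-scenario benchmark at 20 replicates
completes in well under a minute.

## What the synthetic data does and does not emulate

The expression generator (`generate_expression_pair`,
`make_planted_study`) produces equicorrelated Gaussian modules with a
specified within-module correlation per condition, mean shifts for planted
TF targets, and independent noise genes. It emulates the features the
pipeline actually consumes — correlation structure that differs between
conditions, DE targets tied to a TF, decoy gene sets — and deliberately not:
heavy-tailed intensity distributions, probe-level artifacts, batch effects,
sample-size imbalance, or overlapping real pathway annotations. Passing
tests therefore demonstrate correctness of the statistical machinery and
recoverability of planted signal, not performance on any particular
microarray platform. The default planted module uses $r^{ctrl} = 0.9$
collapsing to $r^{case} = 0$ with $n = 50$ per group and a 5-target
regulon: a tight module whose collapse is comfortably inside the detection
power of the edge test at that sample size, so end-to-end tests measure the
pipeline rather than the luck of a borderline effect.

## Numerical choices and degenerate inputs

* Correlations at $\pm 1$ (possible in toy data) are clamped to
  $\pm(1 - 10^{-7})$ before the Fisher transform, with a warning.
* Group sizes below 4 are a hard error: the statistic's variance term
  $1/(n-3)$ must be positive and finite.
* A score set with zero spread (e.g. identical matrices) standardizes to all
  zeros with a warning rather than NaN.
* All z-standardizations used for reporting ($D_y$, $cs$, local rewiring)
  treat a numerically constant vector (spread below $10^{-9}$ relative to
  magnitude) as constant and return zeros; otherwise floating-point jitter
  on symmetric graphs would be inflated into spurious $\pm 1$ scores.
* Gene pairs are stored once under lexicographic ID order; self-pairs are
  never formed. The analytic pipeline is deterministic; seeds affect only
  permutations and simulations.
* An isolated node cannot occur in a rewired network, but the RWR
  implementation still redirects any mass on a zero column to the restart
  distribution so hand-built toy graphs stay stochastic.

## Known limitations

* The edge score $\delta = 1 - p_{adj}$ compresses all strongly significant
  edges toward 1; it orders pathways by how many of their pairs pass the
  FDR, not by effect size of the correlation change.
* With `r_min > 0` the FDR is controlled over the *selected* pairs, and the
  selection also widens the standardized null; on very small universes this
  costs real power (disable the floor there).
* Enrichment uses gene-level overlap and ignores topology inside the
  pathway beyond the $m/M$ density.
* Activation/inhibition signs of regulatory edges are not modelled, and
  novel TF-target edges are not predicted; the overlay is only as good as
  the supplied network.
* The permutation test re-estimates the full pipeline per shuffle, which is
  exact but expensive on large matrices; choose `B` accordingly.
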