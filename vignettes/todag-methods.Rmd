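---
title: "Inferring timed oncogenetic DAGs: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring timed oncogenetic DAGs: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(todag)
```

## The model and its assumptions

`todag` infers a directed acyclic dependency model of somatic-mutation
accumulation from a binary samples-by-events table. The core assumptions
are:

* **Irreversibility.** Genetic alterations do not revert, so dependencies
  form a DAG rather than a general graph.
* **Frequency encodes order.** If event $j$ tends to occur only where $i$
  has occurred, $j$ is rarer than $i$ in a cross-section; edges are
  therefore oriented from the more frequent to the less frequent event.
* **Non-memoryless accumulation.** The probability of an event along a path
  is the probability that it occurs given *all* its predecessors on that
  path, not just the immediate one. Only the waiting times are modeled as
  memoryless (exponential) draws.

Given exact sample frequencies $p_i$ and pairwise joints $p_{i \cap j}$,
each dependent, strictly-ordered pair receives one candidate edge with
weight $w = p_{tgt|src} / (p_{src} + p_{tgt})$ and conditional probability
$p_{tgt|src}$; path probabilities are updated to
$p_{k \cap (k-1) \cap \cdots \cap (k-n_k)}$ over every root-to-node path;
waiting times are drawn as $\Delta t \sim \mathrm{Exp}(\lambda)$ with
$\lambda$ the stored conditional probability; and edges are labelled fast /
moderate / slow by the first and third quartiles of the waiting-time
distribution (or user-supplied absolute thresholds, with the printed
boundary convention: fast strictly below $t_1$, slow strictly above $t_2$,
moderate inclusive on both ends).

A structural consequence worth stating plainly: orienting by strict
frequency inequality makes acyclicity automatic, and pairs with *exactly*
equal frequencies cannot be oriented at all. Equality is decided on integer
occurrence counts — never on floating-point values — so ties are exact
events, not numerical accidents. Tied pairs are reported separately
(`graphTies()`) and excluded from the DAG by default.

## Choices made where the design was genuinely open

Several printed formulations of this model family are degenerate when taken
literally, and the package had to commit to one behaviour; each alternative
remains available as a configuration option so the degenerate forms can be
inspected.

* **Orientation rule.** The weight-comparison rule ("direct $i \to j$ when
  $w(v_i,v_j) > w(v_j,v_i)$") and the frequency rule ("from the most to the
  least frequently mutated gene") are algebraically opposite under the
  weight formula above, since $w(i,j) > w(j,i) \iff p_i < p_j$. The
  frequency rule is implemented: it is the one consistent with every worked
  example this model is known by (ubiquitous events become null-in-degree
  sources), and it guarantees acyclicity.
* **Step-3 filter.** The literal removal condition
  $p_{j|i} < p_i + p_j + (p_{max} - p_{min})$ discards *every* edge whenever
  $p_i + p_j \ge 1$ (a conditional probability cannot exceed 1) and empties
  the graph on the model's own worked examples. The default `filterMode =
  "basic"` therefore retains all candidates — pairs with null joint
  probability and exact ties were already excluded — while `"ci_sum"`
  (literal) and `"ci_product"` (independence baseline) are provided for
  exploration.
* **Confidence interval.** The literal polynomial $(p_c - p)^2 - z_\gamma$
  has half-width $\sqrt{z_\gamma} > 1$ for usual $\gamma$, i.e. the interval
  is always $[0, 1]$. The default `ciVariant = "wilson"` restores the
  sampling-variance term $z^2 p(1-p)/n$ the construction motivates, giving
  the Wilson score interval with $z$ the two-sided normal quantile of order
  $(1+\gamma)/2$; `"literal"` is kept for comparison. Default
  $\gamma = 0.95$.
* **Path pruning.** The literal prune condition compares a probability
  (≤ 1) against a sum of conditionals along the path (easily > 1), which
  deletes exactly the chain structures the model is meant to find. Default
  `pathPrune = "off"`; the literal rule sums over the path's edges only
  (the root has no predecessor term) and removes an edge only when every
  enumerated path through it fails.
* **Waiting-time rate.** $\lambda$ is the probability of the *target* given
  the *source* (the conditional stored at step 3); the subscript-reversed
  reading would use the rarer event as the conditioning side and contradict
  the stored quantity.
* **Multiple paths to an edge.** When several root-to-node paths share a
  terminal edge, the edge stores the maximum path joint (the most supported
  path) — the least destructive choice for downstream thresholding.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 0.95 | confidence level of the step-3 interval (dimensionless) |
| `ciVariant` | `wilson` | interval construction (see above) |
| `filterMode` | `basic` | edge-removal rule at step 3 |
| `pathPrune` | `off` | literal path-removal rule at step 4 |
| `tiePolicy` | `drop` | exact-tie handling (ties never enter the DAG; `keep_undirected` keeps them for reporting) |
| `minWeight` | 0 | report-time weight threshold |
| `pathCap` | 10^4 | enumerated root-to-node paths per node before pairwise fallback |
| timing `mode` | `quantile` | quartile thresholds from the graph's own waiting times; `absolute` uses `t1`, `t2` in the same arbitrary units (5 and 20 are conventional for real-data figures) |

Waiting times are in arbitrary units throughout; no calendar-time
calibration is attempted.

## Numerical choices

* Probabilities are stored as integer counts over `nSamples`; equality and
  ordering comparisons (tie detection, orientation) are integer
  comparisons.
* Quartiles use linear interpolation between order statistics
  (`stats::quantile` type 7), recorded in the graph's `timing` slot.
* Waiting times are inverse-transform draws $-\ln(u)/\lambda$ from a seeded
  uniform stream; a fixed seed reproduces the full edge table bit for bit.
* Path enumeration is depth-first with a per-node cap (`pathCap`) and a
  global work bound of $2 \times 10^5$ path extensions per call; edges the
  enumeration could not reach keep the pairwise joint, with a warning. On
  dense graphs (hundreds of events) the capped fallback is expected and
  only affects the `path_joint` annotation, never topology or weights.
* HITS runs to an L2 change below $10^{-8}$ or 1000 iterations, and scores
  are normalized to maximum 1.

## What the synthetic generators emulate

* `randomBinaryMatrix()` — structure-free null data at an imposed mutation
  frequency. With `exact = TRUE` (default) every column carries exactly
  `round(f · nSamples)` ones: the marginal frequencies are pinned, but all
  events then tie exactly and the inferred DAG is empty by design — exact
  mode exercises tie handling and marginal control. With `exact = FALSE`
  entries are i.i.d. Bernoulli($f$), column frequencies fluctuate as they
  would under weighted random sampling of entries, and directed-edge
  behaviour appears: edge counts grow quadratically with the number of
  events, saturate sigmoidally with the number of samples, the mean
  exponential rate rises with the imposed frequency, and assortativity and
  transitivity follow the documented frequency trends. The package's
  property tests use Bernoulli mode for exactly this reason.
* `triangularMatrix()` / `stepwiseFill()` — fully nested designs with a
  known progression order, stepped toward saturation; the penultimate step
  is the canonical worked example (19 independent sources, one sink).
* `disjointDataset()` / `sharedEventDataset()` — cohorts of sub-types
  sharing no events (block-diagonal; inference must return disconnected
  sub-networks) and the same design plus early events present in every
  sample of every block (inference must return a null-in-degree hub
  bridging the blocks).
* `generateAPG()` / `assignProbabilities()` / `sampleCooccurrence()` — the
  gold-standard benchmark: a random rooted DAG in which every node is
  reachable from the root, node probabilities assigned by multiplicative
  decay (child = most probable parent × a factor drawn from U(0.5, 0.9);
  root 0.9), and a sampled table in which each child's positive samples are
  nested inside the intersection of its parents'. Counts are clipped so
  every realized child frequency stays strictly below each parent's — a
  tied or inverted frequency would contradict the per-edge direction
  constraints the gold standard encodes. Because probabilities only respect
  the *maximal* parent, a multi-parent node can still outrank a minor
  parent nominally; such edges are genuinely hard and keep benchmark AUROC
  below 1. The default sampling depth is 100 samples per gold standard.

What passing tests on these generators do **not** show: real tumor cohorts
have correlated, non-nested event structures, subclonal mixtures,
panel-dependent missingness and frequency spectra far from any of these
designs. The benchmarks bound behaviour on clean, fully specified
structures only.

## Problem sizes used by the test-suite

The suite favours many small, fully checkable instances: brute-force oracle
comparisons up to 8 events, property loops on 25–80-event Bernoulli
matrices over a handful of seeds, $10^4$-draw distributional checks
(Kolmogorov–Smirnov at $\alpha = 0.01$), and benchmark runs of 10
replicates at 10/30, 100/300 and 1000/3000 nodes/edges with 100 samples
each. These sizes were chosen so each law is tested where its expected
effect is far larger than seed noise.

## Known limitations

* **Equal-frequency events are invisible.** The orientation rule cannot
  order exactly tied events; designs where many events share a frequency
  (including exact-mode random matrices) yield sparse or empty DAGs.
* **Indirect dependencies are reported.** Ancestors connect to descendants
  directly whenever their joint probability is positive; the model does not
  attempt transitive reduction, so dense cohorts produce dense graphs.
* **Benchmark collapse at extreme scale.** With the fixed 100-sample
  depth, a 1000-node gold standard assigns most nodes probabilities of a
  few percent; parent-support intersections shrink to a handful of samples
  or to nothing, most descendant columns are empty, and the majority of
  gold edges cannot be expressed in the data at all — the acceptance suite
  computes mean AUROC ≈ 0.55 there, far below the mid-size configurations.
  Recovering large gold standards would require sampling depth growing
  with network size.
* **Waiting times are annotations, not estimates.** They are draws from the
  rate implied by the conditional probability, intended for relative
  fast/slow comparison; absolute timing of mutations is out of scope.
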