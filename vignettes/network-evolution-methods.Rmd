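---
title: "Methods: functional network topology and betweenness-guided evolution"
author: "BrainNetEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional network topology and betweenness-guided evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainNetEvo)
```

## The model

BrainNetEvo implements a computational experiment on functional brain
networks. Region-wise time series (90 regions by default) are correlated
pairwise (Pearson), the correlation matrix is binarized at every
threshold of the grid 0.50–0.60 in steps of 0.01, and each binary network
is summarised by a topology profile: global efficiency, average
clustering coefficient, edge count, transitivity, and the number of
long-distance edges (endpoint separation strictly greater than 75 mm).
Networks of the healthy-like group are then evolved for 100 synchronous
steps under stochastic rewiring rules in which node betweenness and
inter-node Euclidean distance are the control factors, and the evolved
networks are scored by a per-feature linear SVM trained on the
healthy-like vs AD-like groups. The driving hypothesis is that pruning
long, high-traffic connections turns a healthy-like network into one
whose topology is classified with the AD-like group.

## The evolution rule

For the current network with betweenness vector $K$ and distance matrix
$D$, every unordered pair $(i,j)$ carries a raw connection affinity
$w^{c}_{ij} = (K_i + K_j) / D_{ij}^2$ and a raw disconnection strain
$w^{d}_{ij} = (K_i + K_j) \cdot D_{ij}^2$: wiring is favoured between
important, nearby nodes; unwiring between important, distant nodes. Both
are mapped to $[0,1]$ and compared with the cut-off 0.5; an eligible pair
then flips only when its entry in a fresh symmetric Uniform(0,1) matrix
$R$ is at most 0.03, so eligible pairs flip with exactly probability 0.03
per step. All decisions in a step use the state at step entry
(synchronous update, no order dependence), and $K$, the weights and $R$
are recomputed every step.

Three aspects of this rule are genuinely open design choices, fixed here
as follows:

* **Normalisation reference.** Connection weights are normalised by the
  maximum raw affinity over *all* pairs — a new link must rival the
  strongest affinity realised anywhere in the network. Disconnection
  weights are normalised by the maximum strain over the *connected*
  pairs — removal competes only among existing links. We compared this
  with normalising both families by the all-pairs maximum and with
  normalising each family by its own candidate set. With the all-pairs
  reference for both, the rewiring is almost inert (a handful of flips in
  100 steps, because the maximum usually sits on a pair the rule cannot
  act on); with candidate-set references for both, the addition rule
  feeds back on itself around newly created high-betweenness hubs and
  the network grows. Only the asymmetric reference produces the
  behaviour the model is meant to show: sustained pruning of long,
  high-betweenness edges with few additions.
* **Betweenness convention.** Unnormalised Brandes betweenness with
  fractional shortest-path credit, each unordered source–target pair
  counted once, endpoints excluded. The downstream normalisation makes
  the absolute scale irrelevant; the fractional convention is the
  standard one and is what the test oracles verify.
* **Per-step renormalisation.** Weights are renormalised every step from
  the current network rather than once at the start, so the cut-off 0.5
  always refers to the current weight landscape.

Evolution is per subject and per threshold: each healthy-like subject's
binary network at each of the 11 thresholds evolves independently, with
per-network RNG substreams derived from one master seed.

## Metric conventions

* Thresholding is inclusive ($r \ge \tau$) on the signed correlation; no
  absolute value, no negative-edge handling.
* The threshold grid is built by integer index
  ($\tau_k = 0.50 + k\,0.01$) to avoid floating-point accumulation.
* Disconnected pairs contribute 0 to global efficiency ($1/\infty = 0$).
* Nodes of degree below 2 contribute 0 to the average clustering
  coefficient but stay in the denominator, keeping the average
  comparable across thresholds and groups.
* Transitivity is $3 \times$ triangles over connected triples, 0 when no
  triples exist.
* The long-distance cut-off is strict (> 75 mm).
* Shortest paths and betweenness are computed in compiled code (BFS and
  Brandes' algorithm); the test suite checks them, and all derived
  metrics, for exact agreement against independent brute-force oracles
  (Floyd–Warshall, exhaustive neighbour scans, path-counting by the
  $\sigma_{sv}\sigma_{vt}$ identity) on hundreds of random graphs.

## The synthetic cohort generator

No imaging data ship with the package; a seeded generator produces a
cohort of 11 healthy-like and 10 AD-like subjects (240 timepoints per
region, i.e. 8 minutes at a 2 s sampling interval) with planted
group-level network structure, so every downstream stage is testable.

**Planted networks.** Each group network is a union of disjoint
functional modules (cliques of about 14 regions) plus single-link
pendant regions, with exactly the configured number of edges (healthy
380, AD-like 330 by default). Module membership is sampled with a
distance penalty controlled by a retention parameter: the healthy group
uses retention 1 (modules spread over the whole volume, many edges
longer than 75 mm), the AD-like group retention 0.1 (spatially
contracted modules, few long edges). The AD-like group also carries a
larger pendant share (0.07 vs 0.04), lowering its clustering and
transitivity. Per-subject variation resamples edges by swapping the
roles of nodes from different modules — a permutation similarity, so the
edge count and the adjacency spectrum are preserved exactly.

**Why cliques and pendants.** The subject covariance places the target
correlation 0.6 on planted edges and is repaired to positive
definiteness by diagonal loading (smallest eigenvalue at least 0.05)
followed by renormalisation to unit diagonal. The repair rescales every
off-diagonal entry by $1/(1+c)$, so the planted correlation survives
only if the loading $c$ is small, which requires the planted adjacency's
smallest eigenvalue to stay above about $-1.7$. That feasibility class is
narrow: unions of cliques have $\lambda_{\min} = -1$, adding single-link
pendants on distinct hosts gives $-1.618$, and essentially everything
else — Erdős–Rényi-like graphs, satellite nodes with two or more hosts,
thinned cliques, vertex- or edge-joined modules — falls below the bound
and would collapse the planted correlation (for a random graph of
realistic density the realised edge correlation caps near
$1/|\lambda_{\min}| \approx 0.14$). The generator therefore plants the
largest structure family that the covariance recipe itself permits.

**Background correlation.** All non-connected pairs share a background
correlation of 0.42, emulating residual global signal. At 240 timepoints
sampling noise promotes a modest, threshold-dependent number of
background pairs past the 0.50–0.60 cut-offs; these weak extra edges
connect the modules the way real functional networks are connected and
are the natural first targets of the disconnection rule, while at long
recordings (the regime used for recovery checks) they essentially never
cross the thresholds. The shared background component is
variance-standardised per subject — the generator's analogue of
global-signal normalisation: without it, the realised background level
fluctuates with the sample variance of a single common factor and the
per-subject count of threshold-crossing background pairs swings by
hundreds of edges, swamping the group contrasts at the lower thresholds.
The AD-like group's background is scaled by 0.985, a mild expression of
globally reduced synchrony.

**Calibration.** The group sizes, signal length, grid and the
correlation level are fixed study conditions; the density gap, module
sizes, retention, pendant shares and background level were calibrated
once, before the test suite was frozen, so that the group curves
separate across the grid while remaining within reach of the evolution
dynamics, and were not revisited afterwards.

**What the generator does not emulate.** Haemodynamics, temporal
autocorrelation, band-pass filtering, motion artefacts, spatially
heterogeneous noise, negative correlations, and any image-space
preprocessing. Passing tests on this cohort show that the pipeline's
stages behave as specified on data with known ground truth; they do not
show that real resting-state data would yield the same effect sizes.

## Classification protocol

Each of the four features (global efficiency, clustering coefficient,
edge count, transitivity) is classified separately at each threshold: a
linear-kernel SVM with regularisation constant 1 is trained on the 21
z-scored subject values (scaling statistics stored from the training
set), and each evolved network's value is labelled with the trained rule;
a value exactly on the boundary goes to the AD class. Accuracy is the
fraction of evolved networks assigned to the AD class, tabulated as 11
threshold rows plus an average row, in percent. The 1-D decision rule is
cross-checked in the tests against an exhaustive maximum-margin search.

## Numerical and reproducibility choices

* One master seed drives everything; atlas, cohort, and each
  subject-by-threshold evolution get deterministic derived substreams,
  so identical configurations give byte-identical result files (checked
  through the output manifest's checksums).
* Degenerate inputs fail loudly and early: zero-variance regions are
  rejected by index, coincident atlas regions at construction, missing
  groups or zero-variance features before the SVM, non-numeric cells
  with line and column on file input.
* The covariance repair raises an error rather than silently clipping if
  factorisation fails after loading.

## Known limitations

* The algebraic form of the connection/disconnection weights is a
  reconstruction from their qualitative description (proportionality to
  summed betweenness, inverse/direct proportionality to squared
  distance, a 0.5 cut-off on a normalised scale); other transforms
  matching the same description exist.
* Under the fixed rule constants (cut-off 0.5, gate 0.03, 100 steps) the
  rewiring prunes long-range and high-traffic edges reliably, but the
  net movement is modest: on the default cohort the evolved group mean
  typically crosses the halfway point towards the AD-like group for the
  efficiency- and count-like parameters at most thresholds, while the
  clustering-like parameters move less than halfway at some thresholds,
  and the per-step change has not fully settled by step 100 for every
  subject. The acceptance suite states these properties in their strict
  form and reports them honestly rather than loosening them.
* Group-level orderings at individual thresholds are stochastic in the
  tails; with 55 threshold-by-feature cells a few cells can invert at an
  unlucky seed, most often global efficiency or transitivity at the
  extreme thresholds.

## Problem sizes used by the tests

Unit tests run on graphs of up to 15 nodes against brute-force oracles
(hundreds of random cases), small cohorts (2–6 subjects, 30–90 regions,
30–240 timepoints), and short evolutions (5–30 steps). The acceptance
suite runs the full default experiment once (21 subjects, 90 regions,
240 timepoints, 11 thresholds, 121 evolutions of 100 steps — about a
minute of compute) plus a 10,000-replicate flip-rate check and a
6-subject, 5000-timepoint recovery check.

## A worked example

```{r example, eval = FALSE}
library(BrainNetEvo)
res <- runExperiment(experimentConfig(seed = 1))
res$groupMeans[res$groupMeans$threshold == 0.55, ]
round(res$accuracy, 1)
```
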