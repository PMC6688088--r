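---
title: "Combinatorial expansion of nested gating frequencies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial expansion of nested gating frequencies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combogate)
```

## The model

A panel of $M$ markers, each gated positive or negative against an
FMO-guided threshold, partitions events into $2^M$ fully-defined
phenotypes. Allowing each marker additionally to be *not considered*
defines a cell population for every word in $\{+,-,\ast\}^M$ except
the all-$\ast$ word, i.e. $3^M - 1$ informative populations.
Stratified by the number $m$ of considered markers this is
$\sum_{m=1}^{M} \binom{M}{m} 2^m = 3^M - 1$.

The input is what nested quadrant gating exports: for every node of a
level-structured gating tree, the node's frequency as a *percent of
its parent*. A two-marker level splits each parent into four
quadrants, a one-marker level into two halves. The frequency of a
fully-defined phenotype relative to the starting population (the
*root*) is the chain product along its path,
$$\%_{\text{root}}(\ell) \;=\; 100 \prod_{\text{levels } k}
  \frac{\%_{\text{parent}}(\ell_k)}{100},$$
and the frequency of any population with not-considered markers is the
sum of the chain products of all leaves that agree with it on every
considered marker. Because the chain product distributes over sums,
this marginal-sum formulation is identical to recursively splitting
each undefined marker into its positive and negative halves.

`compute_all()` evaluates all $3^M-1$ values per sample by computing
the $2^M$ leaf table once and then marginalizing it with a tensor
contraction: each marker axis $\{+,-\}$ is expanded to
$\{\ast = + + -,\; +,\; -\}$ in one pass, costing $O(M\,3^M)$ rather
than $O(3^M 2^M)$ of per-population summation. The naive recursion is
retained in the test suite as an independent oracle; a second, fully
independent route — direct counting of simulated single-cell events —
is described below.

## Conventions

* **Canonical population order.** Enumeration follows mixed-radix
  base-3 counting with marker 1 as the most significant digit and
  digit order $\ast < + < -$, the all-$\ast$ word skipped. The order is
  deterministic, so repeated runs write byte-identical output columns.
  The reference implementations of this expansion do not document
  their internal order; this one is a design choice, not a
  reconstruction.
* **Names.** A population is named by concatenating `<marker><sign>`
  for its considered markers in panel order (`CD3+CD4-`), ASCII signs
  only, for file-format portability.
* **Quadrant labels.** Node paths use `Q1..Q4` per two-marker level
  with the mainstream gating-software convention `Q1 = x−y+`,
  `Q2 = x+y+`, `Q3 = x+y−`, `Q4 = x−y−` (x = first marker of the
  level), and `P`/`N` for one-marker levels. Exports using any other
  header layout are mapped with a two-column schema table
  (`column`, `path`) passed to `read_gating_table()`.
* **Odd marker counts.** Levels of one marker are allowed; nothing in
  the mathematics requires pairs. Panels above 12 markers trigger a
  soft warning (3^12 ≈ 531k columns) but no hard limit.

## Tunable parameters and degenerate inputs

* **Sibling-sum tolerance.** Children of every node must sum to 100%
  of their parent. Exported tables are rounded, so deviations up to
  0.5 percentage points are accepted silently, up to 2 with a warning,
  and beyond 2 are an error. Inputs are *not* renormalized: any drift
  propagates to the output and is caught by the conservation check
  (fully-defined phenotypes summing to 100) rather than being silently
  corrected.
* **Empty gates.** A 0% node's descendants contribute 0 to every
  population regardless of their recorded values; descendants missing
  from the input under a 0% parent are imputed as 0 with a warning,
  because gating software exports empty gates inconsistently.
* **Output precision.** Population matrices are written with 6 fixed
  decimal places — beyond gating-software export precision, and enough
  to make write–parse–write round trips byte-identical, which the
  tests assert.
* **CSV dialects.** `point` (comma separator, `.` decimals) and
  `comma` (semicolon separator, `,` decimals) are supported both ways.
  Detection uses separator/decimal evidence from the first rows and
  refuses to guess when there is none; an explicit `dialect` argument
  always wins. Parsing sets the decimal mark explicitly, so results do
  not depend on the host locale.

## The synthetic cohort generator

`simulate_sample()` draws events multinomially over the $2^M$
phenotypes; `gate_events()` pushes them through the nested tree
exactly as manual gating would, and `simulate_cohort()` builds labeled
groups by drawing each sample's phenotype composition from a Dirichlet
distribution around its group centroid ($\alpha = c \cdot
\text{centroid}$, so the concentration $c$ is an interpretable
dispersion knob: large $c$ means samples hug the centroid). Group
centroids come from log-linear tilts of a common random base
composition, with a `separation` magnitude.

Events carry binary marker states, not fluorescence intensities: the
expansion consumes post-threshold gating results, so simulating
intensities, compensation, or gate placement would add nothing the
method reads. That bounds what passing tests show about real data:
correctness of the arithmetic from gated percentages onward is fully
verified, but threshold placement error, marker continua (dim/bright
populations), acquisition batch effects, and rounding in third-party
exports are outside the simulation — only the last is modelled, via
the sibling-sum tolerance.

Cohort defaults emulate a small clinical immunophenotyping study: two
groups × 10 samples, 10,000 events per sample, concentration 500
(within-group CVs of a few percent for major populations), separation
1. The verification routine uses 100 random event sets of 500 events
across panels of 2, 3, 4 and 6 markers; the two-group clustering
property is checked across 20 seeds at 2,000 events × 5+5 samples.
These sizes make the whole suite run in seconds while leaving the
binomial noise clearly visible to the assertions.

## Verification by direct counting

For simulated events, every computed population value can be compared
with the fraction of events that actually match the population's sign
pattern (`direct_fraction()`). Both routes are exact ratios of integer
event counts, so they must agree to floating-point rounding;
`verify_computation()` (and the `verify` CLI subcommand) asserts
agreement within a relative tolerance of $10^{-9}$ (with an absolute
floor of the same magnitude for near-zero frequencies) over randomized
event sets, alongside the count identities. A fault-injection mode
swaps two sibling leaf values — preserving the sibling sums so the
input still validates — and must make the verification fail, naming an
affected population.

## Downstream analysis

The classification pipeline is `autoscale()` →
`hcluster(metric = "pearson", linkage = "average")`, i.e. per-population
z-scores (sample SD, $n-1$), distance $1 - r$ between sample profiles,
average linkage. The correlation distance is the field's common choice
for this matrix; the linkage is not dictated by it, and *average* is
adopted here as the default of the web tools routinely used for such
matrices — a documented assumption, with `euclidean` distance and
`complete`/`ward` linkages available for comparison. Design choices
made where the design was genuinely open:

* **Constant profiles.** A constant vector has no defined correlation;
  its distance is set to 1 ($r := 0$) with a warning instead of
  propagating `NaN`. Zero-variance populations are zeroed and flagged
  by `autoscale()` rather than dropped, keeping column geometry stable.
* **PCA.** `pop_pca()` centers (a no-op after autoscaling), does not
  rescale, and fixes component signs by making each component's
  largest-magnitude loading positive, so scores are reproducible
  across BLAS implementations up to that convention.
* **Separation score.** A dendrogram cut at $k$ clusters is scored by
  majority label: each cluster takes its most frequent true label and
  every member with a different label counts as misclassified. Ties in
  the majority are broken toward the first label encountered.
* **No population filter by default.** All $3^M-1$ columns enter the
  clustering; an optional minimum-frequency filter can be applied by
  the user before `autoscale()` (near-empty populations autoscale to
  near-noise columns, which correlation distance tolerates well in the
  simulated cohorts).
* **Out of scope.** Bootstrap cluster confidence, survival modelling,
  multiple-testing machinery for per-population contrasts, and
  feature-selection/ML layers are deliberately not included; the
  package ends at the population matrix and its ordination/clustering.

## Known limitations

Percent-of-parent inputs are rounded by the exporting software, so
computed populations inherit that rounding multiplicatively down the
tree (worst case roughly the sum of per-level rounding errors). The
expansion is exact arithmetic on the gating results it is given: bias
in threshold placement, spillover, or acquisition drift passes through
untouched — and, because the method is unbiased across all
populations, often becomes visible as systematic structure in the
clustering. For panels much beyond 10–12 markers the population matrix
itself remains computable, but distance-based clustering on half a
million columns is rarely sensible without prior feature selection.

```{r example}
panel <- flow_panel(c("M1", "M2", "M3", "M4"))
cohort <- simulate_cohort(panel, seed = 1)
pops <- expand_populations(cohort, panel)
clust <- hcluster(autoscale(pops))
separation_score(clust, setNames(cohort$group, cohort$Sample), k = 2)
```
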