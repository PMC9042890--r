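---
title: "Two-dimensional enrichment on signed interaction maps: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional enrichment on signed interaction maps: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twodea)
```

## The problem

Curated disease maps and similar molecular interaction maps (MIMs) encode, at
single-interaction resolution, how genes, proteins, metabolites and clinical
phenotypes regulate one another. Classical set-based enrichment ignores both
the direction of measured changes and the sign structure of this network.
`twodea` implements a two-dimensional alternative: every measured element
carries a signed log2 fold change (one dimension), and the network contributes
a signed, distance-discounted *influence score* of that element on the entity
of interest (the second dimension). Enrichment statistics are then functions
of the paired `(influence, fold change)` values.

Two directions of inference are supported:

* **downstream** — treat the differentially changed elements (DCEs) as causes
  and ask which phenotypes they collectively push up or down;
* **upstream** — treat the DCEs as consequences and rank candidate regulators
  ("targets") by how specifically their regulon explains the changes.

## The graph model

A map is a set of typed elements and a set of interaction triples
`(source, sign, target)` with `sign` either `+1` (activation, induction,
synthesis) or `-1` (inhibition, repression, consumption), annotated with an
interaction class: `transcriptional`, `catalytic` or `generic`. The class is
load-bearing: transcriptional in-edges of a gene define its TF set,
catalytic in-edges of a metabolite define its enzyme set, and submap
membership defines the regulator neighbourhood of a phenotype. Maps without a
class column load with every edge `generic` (and a warning), which leaves the
transcriptional and catalytic contexts empty — the explicit column is
required for those analyses to be meaningful.

The *type* of a path is the product of its edge signs. A shortest path is
*consistent* when no equal-length path of the opposite type exists; the
implementation finds these with a breadth-first search over `(node, sign)`
states, so each node has an independent minimal depth per cumulative sign.
Inconsistent pairs are treated as sign-neutral: wherever a formula multiplies
by a shortest-path type, an inconsistent pair contributes zero. This is the
only sign-symmetric option; dropping such pairs silently would bias sums
toward whichever sign happened to be enumerated first.

Self-loops are rejected at load (they would make zero-length path cases
ambiguous in the influence recursions), and duplicate triples collapse with
set semantics — `(s, +1, t)` and `(s, -1, t)` may coexist as genuinely
different regulation modes.

## Influence scores

All three contexts share one recursion shape: a *base set* of direct
regulators with hand-assigned scores, plus an aggregation step that lets any
element at most two edges above a base-set member inherit a discounted,
sign-adjusted share:

\[
I_{u,v} \;=\; \sum_{\substack{k \in \mathrm{Base}(v) \\ L(u,k) \le 2}}
I_{k,v}\; \frac{T(u,k)}{2^{\,L(u,k)}}
\]

where `L` and `T` are the length and type of the consistent shortest path
from `u` to `k`. The two-edge horizon together with the `2^L` discount means
the smallest inherited weight is 1/4; deeper ancestry is considered
irrelevant noise. Specifics per context:

* **transcriptional** (gene targets): base set = TFs of `v`; base score = the
  edge sign (+1 induction, -1 suppression). Aggregates are hard-clamped to
  `[-1, 1]`.
* **catalytic** (metabolite targets): identical with enzymes as the base set
  (+1 synthesis, -1 consumption). Consuming enzymes belong to the base set —
  inhibiting the consumer of a metabolite raises its level, and the sign
  algebra reproduces that.
* **phenotype**: base set = elements sharing a submap with `v`. The base
  score is the shortest-path type times a topological share
  `N_{P_u}/N_P + N_{V_u}/N_V` (fraction of counted submap paths into `v`
  passing through `u`, plus fraction of path-connected elements lying on
  `u`'s paths). Aggregated entries are magnitude-capped at the largest base
  magnitude, and the finished column is divided by its maximum absolute
  value, so every non-degenerate phenotype column attains magnitude 1.

Choices worth stating explicitly, because the formulas alone do not fix them:

* *Counted paths.* "Number of paths to `v`" is infinite on cyclic submaps.
  We count **simple** paths within the submap-induced subgraph, capped at
  `max_path_len = 8` edges (an exposed parameter). Parallel edges collapse
  for counting purposes — a path is a vertex sequence.
* *Base-case precedence.* The piecewise definitions are exclusive: a direct
  TF of `v` takes its edge sign even if it also reaches other TFs
  indirectly.
* *Parallel opposite edges* from `u` to `v` net out by sign summation; a net
  of zero stores nothing (logged).
* *Clamp versus scale.* The bound on class-context scores is enforced by
  hard-clamping the aggregate; the phenotype context instead caps aggregates
  at the largest base magnitude and then rescales the whole column, with the
  normalising maximum taken **after** the full column (base plus aggregated
  entries) is assembled.
* *Shortest-path types for phenotype base cases* come from the full graph;
  the submap subgraph only defines the counting universe.
* Self-influence `I(v, v)` is never computed.

Influence tables are sparse (zero means absent), deterministic, and persist
to TSV/JSON with 17 significant digits so that save/load round-trips are
bit-exact.

## Downstream statistics

For a phenotype `v`, a sample's DCE set with fold changes `FC_u` and
influence column `I_u = I(u, v)` yields

* **Level** `= sum(I_u * FC_u)` — a linear, unclamped proxy for the change in
  the phenotype's activity. Levels are not comparable across phenotypes, so
  they are reported normalized per phenotype by the maximum absolute level
  across samples.
* **Saturation** `= sum(|I_u|, DCEs) / sum(|I_u|, all regulators)` — how much
  of the phenotype's regulatory mass the data actually covers.
* **Enrichment score**
  `ES = sum(|I FC| * I FC) / (k + sum(I^2 FC^2))`. Geometrically, project
  every point of the influence–fold-change plane onto the diagonals — x
  coordinate `FC * |I|`, y coordinate `|FC| * I` — append two baseline
  points `(±sqrt(k/2), 0)`, and take the slope of the least-squares
  regression through the origin. With the default `k = 2` the baseline
  points are exactly `(1, 0)` and `(-1, 0)`. `|ES| <= 1` always; the bound
  is approached as the baseline mass vanishes.

The baseline has two roles: it makes a handful of strong points insufficient
for a large score (set-size dependence), and it linearises the statistic near
zero so a Gaussian null fit is sensible. An adaptive mode
(`k_mode = "adaptive"`) sets `k = 2 * max(FC)^2` of the evaluated set,
placing the baseline points at `(±max|FC|, 0)`; because the permutation
scheme preserves the fold-change multiset, the observed and permuted sets
share the same maximum and hence the same adaptive `k`.

## Upstream statistics

For a candidate target `v` with influence row `I_u = I(v, u)` over data
elements `u`:

* **Sensitivity** `= sum(I_u FC_u) / sum(|FC_u|)` over DCEs — `+1` exactly
  when `v` pushes every DCE in its measured direction at full strength
  (a positive target), `-1` for the exact mirror (a negative target).
* **Specificity** `= mean(1 - |I_u|)` over non-DCEs — `1` when `v` touches
  nothing outside the data. The non-DCE universe defaults to map elements of
  the same biological type as the data (a transcriptomics run is judged
  against genes, not metabolites); `specificity_universe = "all"` widens it.
* **Upstream ES**: the enrichment score with the fixed baseline replaced by
  the fold-change mass of DCEs that `v` does *not* regulate. As printed in
  the original formulation that term is a signed sum, which can zero or
  flip the denominator; the default here uses `sum(|FC_u|)` over unregulated
  DCEs, keeping the denominator positive and the score bounded. The strict
  signed reading is available via `strict_k = TRUE`.

Targets are ranked by sensitivity magnitude, then specificity, then id —
a total, deterministic order.

## Null model and significance

Randomized DCE lists preserve the cardinality and the exact fold-change
multiset of the observed list; only identities are redrawn, uniformly without
replacement among map elements of the same biological type. `n = 1000`
permutations per sample by default; one identity matrix is shared by all
phenotypes (or targets) of a sample. Every run is seeded and the seed is
recorded in the result object; sample `i` of a multi-sample run uses
`seed + i - 1`.

Because influence scores and fold changes need not be sign-balanced, the
null can have different spread above and below zero. Each direction is
fitted with a zero-centred half-normal whose scale is the root mean square
of the same-signed null values (method of moments); a direction with fewer
than two same-signed values borrows the other direction's scale (flagged).
The observed statistic is standardised against the direction-matched scale
and converted to a two-sided p-value by an in-package series expansion of
the normal integral: a Maclaurin series accumulated until the next term is
below `1e-18` for `|z| <= 6`, and a Laplace continued fraction for the Mills
ratio beyond that, where the series cancels catastrophically. `|z|` is
capped at 14, flooring attainable p-values at about `1.56e-44`.

Per sample, Benjamini–Hochberg correction runs across **all** enriched
elements before any user-side filtering, so filtering cannot bias the FDR.
Four p-value sources are offered per row: the ES null, the level null, or
the row-wise maximum or minimum of the two.

A property of the ES-based p-value worth knowing: ES is bounded in
`[-1, 1]`, so when the squared product mass `sum(I^2 FC^2)` is comparable to
or larger than `k`, its permutation null is platykurtic and the Gaussian
threshold `1.96 * sigma` may be unreachable — ES-mode p-values are then
conservative (anti-conservative never arises from this mechanism). The level
statistic is an unbounded sum and behaves like its Gaussian fit under
permutation; the package's calibration test therefore exercises the level
mode, and the adaptive `k` exists precisely to push the ES back into its
linear regime when fold changes are large.

## What the synthetic generator emulates — and what it does not

`make_network()` draws a layered map: signalling proteins feed TFs and each
other, TFs regulate genes transcriptionally, enzymes synthesize/consume
metabolites, and each phenotype owns a submap of genes and signalling
proteins wired as a shuffled chain with shortcuts into the phenotype. The
default spec (8 TFs, 20 genes, 5 enzymes, 6 metabolites, 8 signalling
proteins, 3 phenotypes, 30% negative edges, submaps of 6) mirrors the
composition of curated disease maps at roughly 1/100 scale. Negative-edge
fractions are realized exactly up to rounding by assigning a fixed count of
negative signs.

`make_null_dces()` draws identities independently of topology with
`FC ~ Normal(0, 2)` — the calibration condition. `make_planted_dces()`
plants a true regulator: a configurable fraction of its nonzero-influence
regulon responds with `FC = effect * sign(I) + Normal(0, noise_sd)`
(defaults: effect 2, responder fraction 0.5, noise 0.5 — a moderately noisy
but clearly powered experiment), everything else is pure noise, and adjusted
p-values are drawn uniformly below the significance threshold for responders
and above it otherwise. That p-value construction is a filtering device, not
a model of differential-expression testing; the generator also does not
emulate count noise, correlation between co-regulated genes, or
composition effects of real RNA-seq. Passing tests on these fixtures
demonstrate correctness of the statistics and recoverability of planted
structure — not performance on any particular real dataset.

Problem sizes used by the shipped checks (the package's own choices): oracle
comparisons run on 50–100 random graphs of 6–25 nodes; calibration runs 500
topology-free trials of 30 DCEs against a 200-element map with 1000
permutations each; recovery runs 100 replicates of the planted generator on
the default 50-element map.

## Known limitations

* The two-edge aggregation horizon is a modelling commitment, not a tuning
  parameter; elements further than two steps above every base-set member are
  invisible to the influence machinery by design.
* Path counting on phenotype submaps is capped at 8 edges; pathological
  submaps with relevant longer simple paths will undercount.
* The permutation null randomizes identities only; co-expression structure
  among DCEs is not preserved, so p-values are exact only under the
  independence-style null the permutation encodes.
* Levels are relative quantities; only their per-phenotype normalized
  profile across samples is interpretable.
* The upstream analysis judges candidates through the supplied influence
  table: regulators acting exclusively through mechanisms absent from the
  map cannot be recovered.
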