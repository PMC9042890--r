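# twodea

Two-dimensional enrichment analysis on signed molecular interaction maps.

Curated disease maps encode, interaction by interaction, how genes,
proteins, metabolites and phenotypes activate or inhibit one another.
`twodea` is for researchers who have such a map plus differential data
(gene symbols with log2 fold changes and adjusted p-values) and want
network-aware answers to two questions:

* **Downstream:** which phenotypes do my changed elements collectively push
  up or down?
* **Upstream:** which regulators (e.g. transcription factors) most
  specifically explain the changes I measured?

## The method in brief

The map is a signed directed graph: triples *(s, r, t)* with
*r ∈ {−1, +1}*, each edge classed as transcriptional, catalytic or generic.
A path's type is the product of its edge signs; a shortest path is
*consistent* when no equal-length path of opposite type exists (signed BFS
over *(node, sign)* states).

Every element *u* gets an **influence score** *I(u, v) ∈ [−1, 1]* on an
entity *v*. Direct regulators take their edge sign (TFs of a gene, enzymes
of a metabolite) or a topological path/element share (submap members of a
phenotype); anything at most two edges above a direct regulator inherits

&nbsp;&nbsp;&nbsp;&nbsp;*I(u,v) = Σ<sub>k∈Base(v), L(u,k)≤2</sub> I(k,v) · T(u,k) / 2<sup>L(u,k)</sup>*

with clamping/normalization keeping |I| ≤ 1. Influence and fold change then
combine per sample:

* **Level** = Σ I·FC (phenotype activity proxy, normalized per phenotype
  across samples),
* **Saturation** = Σ<sub>DCE</sub>|I| / Σ<sub>all</sub>|I|,
* **Enrichment score** ES = Σ(|I·FC|·I·FC) / (k + Σ I²FC²), the slope of a
  regression through the origin on diagonal-projected points with baseline
  counterweights (k = 2 ⇒ baseline points (±1, 0)); |ES| ≤ 1,
* **Sensitivity** = Σ I·FC / Σ|FC| and **Specificity** = mean(1 − |I|) over
  non-DCEs, ranking upstream targets,
* significance via a type-stratified permutation null (n = 1000) with
  per-direction half-Gaussian fits, z-scores (capped at 14, flooring p at
  ≈1.56e-44) and Benjamini–Hochberg FDR per sample.

Everything is seeded and deterministic; see the methods vignette
(`vignettes/two-dimensional-enrichment.Rmd`) for assumptions, parameter
semantics and limitations.

## Worked example

Everything below runs on a synthetic 50-element map; no downloads.

```r
library(twodea)

g <- make_network(network_spec(seed = 7))
g
#> <mim_graph> 50 elements, 95 interactions, 3 submap(s)
#>   bio types: gene=20, metabolite=6, phenotype=3, protein=21

inf_t <- build_influence(g, "transcriptional")   # TF -> gene scores

# simulate an experiment truly driven by TF07, then filter the data table
dat <- make_planted_dces(g, inf_t, "TF07", effect = 2,
                         responder_fraction = 0.8, seed = 21)
d <- filter_dces(dat, "s1", g)   # adj p < 0.05, symbols matched to the map

run_upstream(g, inf_t, d, target_filter = "tf", n = 1000, seed = 1)
#> <upstream enrichment> 1 sample(s) x 8 element(s); ...
#>   sample target sensitivity specificity     es      z      p adj_p polarity
#> 1 s1     TF07         1           0.857  1      2.36  0.0185 0.148 positive
#> 2 s1     TF03        -0.352       0.714 -0.587 -1.53  0.126  0.435 negative
#> 3 s1     TF02         0.311       0.857  0.514  1.40  0.163  0.435 positive
#> ...
```

The planted regulator comes back at rank 1 with sensitivity exactly 1 (it
pushes every significant gene in its measured direction), specificity 0.857
(it touches one non-significant gene), and the smallest permutation p-value
of all candidate TFs. Decoy TFs score lower on both axes; TFs with no edge
into the data sit at sensitivity 0. With only six DCEs against the
unregulated-fold-change baseline, FDR-adjusted significance is not reached —
as it should be for an experiment this small.

Downstream, the same data aggregate onto phenotypes:

```r
inf_p <- build_influence(g, "phenotype")
tidy(run_downstream(g, inf_p, d, n = 1000, seed = 1))
#>   sample phenotype level level_norm saturation    es     z  p_es p_level     p
#> 1 s1     PHEN01     1.06          1     0.0566 0.358 0.599 0.549   0.674 0.549
#> 2 s1     PHEN02     0              0    0      0     0     1       1     1
#> 3 s1     PHEN03     1.30           1    0.0723 0.460 0.814 0.416   0.590 0.416
```

`level` is the influence-weighted fold-change sum (a relative activity
proxy), `saturation` the share of each phenotype's regulatory mass present
in the data, and `p` comes from the selected permutation null. Data-free
exploration works too: `in_silico_perturbation(g, inf_p, c(G001 = 1))`
propagates an assumed change onto all phenotype levels.

Results are ordinary tibbles (`tidy()`, `glance()`) with `autoplot()`
methods: a phenotype-by-sample heatmap downstream, a
specificity–sensitivity plane upstream, plus `plot_regulation()` for the
influence–fold-change plane of a single entity.

A thin command-line driver wraps the same functions
(`inst/cli/twodea`, subcommands `paths`, `influence`, `downstream`,
`upstream`, `perturb`, `simulate`).

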