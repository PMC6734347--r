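# heatlink

Heat-diffusion link prediction on two-layer tumor–gene graphs.

`heatlink` predicts which genes are likely to be associated with a tumor
sample when that association has not (yet) been observed. It models the data
as a two-layer graph:

- **Layer 1** — a directed bipartite "hasGene" relation from tumor samples to
  genes (e.g. genes with observed methylation in a COSMIC tumor sample);
- **Layer 2** — an undirected gene–gene interaction network, weighted
  (STRING-style channel scores in (0, 1]) or unweighted (BioGRID-style
  physical interactions).

Each tumor seeds unit heat at its known genes, the heat diffuses over the
interaction network, and the per-gene heat after diffusion ranks candidate
tumor→gene links. The package also ships the classical link-prediction
baselines, edge-holdout cross-validation, and permutation-based significance
testing, plus a synthetic two-layer graph generator so everything is testable
without any database downloads.

## The model

For a tumor with binary seed vector *f(0)* over the *n* genes, the diffused
heat is

    f(1) = exp(α R) f(0),        R = γ H + (1 − γ) g 1ᵀ,   g = (1/n) 1

where α ≥ 0 is the thermal conductivity (α = 0 means no diffusion), γ is the
probability of *not* taking a uniform random jump (teleport, as in PageRank;
default γ = 0.85), and H is one of two heat matrices:

- **Unweighted** H\*\*: off-diagonal 1 per interaction edge, diagonal −d(gⱼ).
- **Degree-normalized** H\*: gene *j* passes wⱼᵢ/dⱼ of its heat to neighbor
  *i* and loses (τⱼ/dⱼ)·Σₖwⱼₖ in total, giving every gene unit influence.
  This is the default operator; it removes the high-degree bias of H\*\*
  (unweighted layers use implicit weight 1).

At scale the matrix exponential is replaced by the linear-cost discrete
scheme

    f(1) = (I + (α/M) R)^M f(0)

applied as M sparse matrix–vector products per tumor (cost O(M·|E|·T)).
Defaults: α = 1, M = 6, γ = 0.85.

## Worked example

The four-gene toy network: one tumor linked to genes A, B, C (not D), with
interaction edges A–B and C–D.

```r
library(heatlink)
g  <- toy_fixture()
H  <- build_heat_matrix_unweighted(g$layer2)
f0 <- seed_vector(g, "TumorX")          # A B C D -> 1 1 1 0
f1 <- diffuse_exact(H, f0, alpha = 1)
round(f1, 4)
#>      A      B      C      D
#> 1.0000 1.0000 0.5677 0.4323
score_tumors(g)
#>    tumor gene   score rank
#> 1 TumorX    D 0.15867    1
```

Gene D starts with no tumor link, but heat reaches it through its
interaction with gene C: its diffused heat 0.4323 (0.43 at two decimals) is
the evidence for the missing TumorX→D link, and D is emitted as the
top-ranked (here: only) novel candidate.

On a synthetic 200 × 150 cohort with a planted diffusion signal, 10-fold
edge-holdout cross-validation separates diffusion from chance:

```r
sim <- generate_two_layer(n_tumors = 200, n_genes = 150, seed = 42)
evaluate_method(sim$graph, "heat", k = 10, seed = 42)
#> <eval_result> method = heat, k = 10
#>   AUC-ROC: 0.8281 +/- 0.0382
#>   AUC-PR:  0.0569 +/- 0.0109
evaluate_method(sim$graph, "random", k = 10, seed = 42)
#> <eval_result> method = random, k = 10
#>   AUC-ROC: 0.5064 +/- 0.0544
#>   AUC-PR:  0.0019 +/- 0.0004
```

AUC-ROC here is the rank-comparison estimator (n′ + 0.5 n″)/n: the
probability that a held-out link outscores a non-existent link, with half
credit for ties.

Baselines (`evaluate_method(..., method =)`): `cn`, `jaccard`, `aa`, `pa`,
`ra` (bipartite-adapted neighborhood scores), `katz`, `ppr`, `random`.
Significance: `permutation_pvalues()` re-scores candidate pairs on
degree-preserving rewirings of either layer (p = Ω/N with strict-greater
counting) and applies a Bonferroni-corrected threshold.

A thin command-line wrapper with `build-graph`, `simulate`, `predict`,
`evaluate` and `permtest` subcommands is installed at
`inst/cli/heatlink` (see `system.file("cli", "heatlink", package = "heatlink")`).

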