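# dynafic

Dynamic functional influence computation on multi-layer gene networks.

`dynafic` is for computational biologists who have a differential-expression
table and want to know which genes *matter* in a condition — not just which
change the most. It integrates three molecular-interaction layers
(STRING-style protein–protein interactions, TRRUST-style transcription-factor
regulation, and Gene Ontology semantic similarity by the Wang measure),
diffuses expression-derived influence through the combined network over
discrete time steps with regulatory amplification, and ranks genes by a
composite influence score. Two conditions — the motivating application is
left- versus right-sided colorectal tumors — are then compared through
distributional, volatility and clustering statistics.

## The model

The combined network `G = (V, E_PPI ∪ E_TF ∪ E_GO)` carries pair weights
`Σ layer_weight × edge_weight` (1.0 / 1.5 / 0.5 for PPI / TF / GO); its
row-normalized adjacency `W` drives the diffusion

    x(t+1) ∝ γ·x(t) + (1−γ)·Wᵀ D x(t),      γ = 0.7,  t = 0…5,

renormalized to conserve total influence, where `D` is a diagonal operator
doubling the busiest transcription factor (`d_i = 1 + outdeg_i / max outdeg`).
The initial vector combines |log2FC|, capped `−log10(padj)` and a
tanh-transformed tissue-expression weight. Each gene is finally scored

    DynaFIC(i) = x_i(T) · CMI(i) · ω₁ + ω₂ · c_i,      ω₁ = 0.8,  ω₂ = 0.4,

with `c_i` its normalized degree centrality and `CMI` a context-modulation
index built from tissue weight, cancer-annotation enrichment (CGES) and mean
ontology depth (GDS): `CMI = tanh(θ₁·w·CGES) + θ₂·GDS/max GDS` (θ₁ = 2,
θ₂ = 0.1). Scores are log1p-scaled to a 0–100 range. Per-gene trajectory
statistics include a stability-volatility index (SVI: normalized trajectory
CV × affine centrality), functional heterogeneity (FH: neighborhood category
entropy × neighborhood fraction), outlier-resistant k-means trajectory
clusters with silhouette-selected k, and 1-D Wasserstein / permutation /
Welch comparisons between conditions.

## Worked example

No downloads are needed: the package generates complete synthetic input
bundles (STRING-, TRRUST-, OBO-, GTEx- and DE-table-style files) with
planted structure.

```r
library(dynafic)

dir <- tempfile()
sc  <- two_condition_scenario(dir, seed = 42)   # hierarchical vs hub-amplified
cfg <- dynafic_config(permutations = 199)

run <- function(b, out)
  run_score(de = b$paths[["de"]], ppi = b$paths[["ppi"]], tf = b$paths[["tf"]],
            obo = b$paths[["obo"]], annotations = b$paths[["annotations"]],
            expression = b$paths[["expression"]],
            cancer_terms = b$paths[["cancer_terms"]], config = cfg,
            out_dir = out)

left  <- run(sc$left,  file.path(dir, "L"))
right <- run(sc$right, file.path(dir, "R"))
head(right$scores[, c("gene", "log2fc", "x_T", "centrality",
                      "dynafic_scaled", "rank")], 3)
#>   gene log2fc    x_T centrality dynafic_scaled rank
#> 1 g021  1.590 0.0483      0.733          100.0    1
#> 2 r066 -1.379 0.0259      0.489           69.4    2
#> 3 r050 -0.742 0.0230      0.489           69.3    3
```

The planted hub (`g021`) tops the right-side ranking at a modest fold change
of 1.59 — influence earned through network position and regulatory
amplification, not expression magnitude. The two-condition report makes the
architectural contrast explicit:

```r
dynafic_compare(left, right, seed = 42, permutations = 199)
#> Two-condition comparison
#>   score Wasserstein = 15.4158 (permutation p = 0.005)
#>   SVI Welch t = -3.620 (p = 0.000509); means 0.163 vs 0.284
#>   expression-influence r: left 0.669, right -0.001
#>   FH Wasserstein = 0.2722; 1 disrupted gene(s) of 8 shared
```

The hierarchical (left) condition couples expression to influence
(r = 0.67); the hub-amplified (right) condition decouples them (r ≈ 0) and
carries significantly higher volatility (negative Welch t: right SVI mean
0.284 vs 0.163).

A thin command-line wrapper ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dynafic.R", package = "dynafic"))')
Rscript $CLI simulate --out bundle/ --seed 5
Rscript $CLI score --de bundle/de.csv --ppi bundle/ppi.tsv --tf bundle/tf.tsv \
    --obo bundle/ontology.obo --annotations bundle/annotations.tsv \
    --expression bundle/expression.tsv --out scored/
Rscript $CLI compare --left scored/ --right scored2/ --out report.json
```

See `vignettes/dynafic-methods.Rmd` for the full model description, the
design decisions behind every formula, and what the synthetic conditions do
and do not emulate.

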