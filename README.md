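# actionsc

Archetypal analysis of single-cell transcriptomes with a
specificity-weighted similarity kernel.

## The problem

Identifying cell types from single-cell RNA-seq hinges on how you
measure similarity between cells. Generic measures (correlation,
Euclidean distance) are dominated by universally expressed genes —
ribosomal and housekeeping machinery that every cell shares — while the
genes that actually mark cell identity are weakly expressed.
`actionsc` implements the ACTION approach for practitioners who want
cell-type structure, interpretable "primary function" profiles, and
per-function regulatory hypotheses out of a plain genes × cells
expression matrix:

1. **Kernel.** Cells are z-scored, the universal-expression direction
   `z_v` is projected out (`z_i^⊥ = (I − z_v z_vᵀ/‖z_v‖²) z_i`), genes
   are weighted by `w_i = û/u_i` where `u_i` is the normalized entropy
   of the gene's positive adjusted profile and `û` the crossing point of
   a two-Gaussian fit to the entropy distribution. The cell kernel is
   `K = (Z^⊥)ᵀ diag(w²) Z^⊥`.
2. **Archetypes.** Cells are modeled as convex combinations of a few
   extreme archetypes (`Y ≈ Y C H` with column-stochastic `C`, `H`).
   Candidate pure cells come from the preconditioned successive
   projection algorithm; the number of archetypes is chosen by an
   oversampling test on the archetype similarity graph (z-scored
   similarities, Erdős–Rényi component-density background); principal
   convex hull analysis refines the corners. Each cell's label is its
   dominant archetype.
3. **Regulatory networks.** Each archetype is orthogonalized against
   the positive parts of the others; genes are ranked by the residual,
   and transcription-factor regulons (TRRUST-style tables) are tested
   for enrichment near the top with the minimum-hypergeometric statistic
   and an exact dynamic-programming p-value.

A bundled simulator generates labeled datasets with the assumed
structure (dominant universal genes, weak exclusive markers, planted
regulons, expression-dependent dropout `P(drop) = 2^(−6x)`), so every
claim in the test suite is checked against planted ground truth.

See `vignette("actionsc-methods")` for models, parameter meanings,
numerical choices and limitations.

## Worked example

```r
library(actionsc)

# 500 cells, 5 types x 100 cells, 2000 genes, 20 weak markers per type
ds <- simulate_labeled_counts(simulation_config(seed = 1))
ds
#> labeled_dataset: 2000 genes x 500 cells, 5 types

dec <- action_decompose(ds$X)       # kernel -> k selection -> PCHA
dec
#> action_decomposition: k = 5 archetypes over 500 cells
dec$k_star
#> [1] 5

clustering_scores(dec$labels, ds$labels)
#> $ari
#> [1] 1
#> $nmi
#> [1] 1
#> $fscore
#> [1] 1

# planted regulon: TF_A shares 15/20 targets with type-1 markers
reg <- plant_regulons(ds, focal_type = 1, seed = 1)
trn <- build_trn(dec, reg, alpha = 0.05)
subset(trn$tf_table, tf == "TF_A" & significant,
       select = c(archetype, r, m, l_best, p_value))
#>    archetype  r  m l_best      p_value
#> 16         4 20 99     15 2.984279e-13
```

The automatic selection recovers the five planted types (`k_star = 5`),
dominant-archetype labels match the planted labels perfectly
(ARI = NMI = F = 1), and the planted TF is called with an mHG p-value
of about 3e-13 on the archetype dominated by its target type (here
archetype 4), with the optimal cut at its 15 marker targets.

A command-line wrapper over the same functions is installed at
`inst/cli/action` (subcommands `simulate`, `kernel`, `decompose`,
`markers`, `trn`, `evaluate`).

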