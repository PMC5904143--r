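---
title: "Methods: archetypal analysis of single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archetypal analysis of single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actionsc)
```

## The problem

A single cell's transcriptome is dominated by genes that every cell
expresses highly — the machinery of core cellular function. The genes
that actually distinguish cell types are typically expressed weakly.
Similarity measures that treat all genes alike (correlation, Euclidean
distance) are therefore driven by exactly the genes that carry no
identity information. `actionsc` implements a three-part answer:

1. a **cell similarity kernel** that removes the universal-expression
   direction and reweights genes by their specificity;
2. an **archetypal decomposition** of the resulting cell geometry, in
   which every cell is a convex combination of a small number of extreme
   "primary function" profiles, with the number of archetypes chosen
   automatically; and
3. **regulatory network inference** per archetype, ranking genes by
   residual expression and testing transcription-factor regulons for
   enrichment near the top of the ranking.

## The similarity kernel

Given a non-negative genes × cells matrix $X \in \mathbb{R}^{m\times n}$,
each cell profile is z-scored over its $m$ genes (sample standard
deviation, $m-1$ denominator). The universal signature $v$ is the row
mean of $X$; its standardized form $z_v$ is projected out of every
standardized profile:

$$z_i^\perp = \left(I - \frac{z_v z_v^T}{\|z_v\|^2}\right) z_i .$$

Gene specificity is measured on the positive part of $Z^\perp$: rows are
normalized to a stochastic matrix $P$ and each gene's **uniformity** is
its normalized Shannon entropy $u_i = -\sum_j p_{ij}\log p_{ij} /
\log n$. The normalizer is $\log(n_{\text{cells}})$ — the row length —
so that a perfectly uniform row attains $u = 1$ and a gene positive in a
single cell attains $u = 0$; the base of the logarithm cancels.

The distribution of $u$ is bimodal (specific genes low, universal genes
near 1). A two-component Gaussian mixture with unshared variances is
fitted with `mclust` (model `"V"`; its hierarchical initialization is
deterministic, which removes restart-to-restart variability that a
random-restart EM would need averaging over). The threshold $\hat u$ is
the equal-density crossing of the two weighted component densities,
found by bisection between the component means; when no sign change
exists in that interval (heavily overlapping or degenerate fits) the
midpoint of the means is used and a warning is raised. Gene weights are
$w_i = \hat u / u_i$ after clamping $u_i$ to $[1/\log n,\, 1]$: the
clamp keeps weights finite for genes positive in a single cell, and
genes whose positive row is entirely zero receive $w_i = 1$ (there is no
evidence either way). The kernel is

$$K = (Z^\perp)^T\, \mathrm{diag}(w^2)\, Z^\perp = Y^T Y,
\qquad Y = \mathrm{diag}(w) Z^\perp ,$$

a symmetric positive-semidefinite dot-product kernel. Expression is used
on whatever scale is supplied (TPM, log-TPM, normalized counts); because
each cell is z-scored first, a shared rescaling of all cells leaves $K$
unchanged.

## Archetypal decomposition

Cells are modeled as points whose cloud is (approximately) a simplex:
a few extreme **archetypes** generate every other cell as a convex
combination. Formally $Y = Y(:,S)H + N$ with $H$ column-stochastic and
bounded noise — the near-separable NMF model.

**Candidate selection.** For a given $k$, columns are reduced to $k$
dimensions by truncated SVD and preconditioned so that the
minimum-volume origin-centered ellipsoid of the (sign-symmetrized)
reduced columns becomes the unit ball. The ellipsoid is computed with
Khachiyan's barycentric coordinate-ascent algorithm (tolerance $10^{-2}$,
at most 10,000 iterations); the transform is the Cholesky factor of the
ellipsoid matrix. Preconditioning by any nonsingular matrix preserves
the separable support while improving the conditioning of greedy
selection. The successive projection algorithm (SPA) then repeatedly
picks the column of maximum 2-norm and projects all columns onto the
orthogonal complement of the pick; ties break to the lowest column
index, and selection stops early (with a warning) if the residual matrix
vanishes numerically.

**Choosing k.** Starting from $k_{\min} = 2$, each candidate set is
tested for **oversampling**: pairwise kernel similarities among the $k$
candidate cells are z-scored, pairs with $z > 1.96$ become edges of the
archetype similarity graph, and each multi-node connected component is
tested for excess density against an Erdős–Rényi background. The
background edge probability is the one the $z$-threshold itself implies
under the Gaussian null, $p_0 = 1 - \Phi(1.96) = 0.025$: a component
with $c$ nodes and $e$ edges gets p-value
$P(\mathrm{Binomial}(\binom{c}{2}, p_0) \ge e)$, Bonferroni-corrected
over multi-node components, significant at 0.05. (Estimating the edge
probability from the observed graph instead is self-defeating here: the
first oversampling event is a single duplicated pair, i.e. a 2-node
component with one edge, whose p-value would then equal the global edge
density and could never reach significance; with the Gaussian-implied
background the first duplicate is flagged as soon as it appears.) The
test requires $k \ge 4$ (at least six pairs); zero-variance similarity
sets yield all-zero z-scores and no edges. The chosen $k^\*$ is the last
value before the first flagged $k$; if nothing is flagged up to
$k_{\max} = \min(30, n-1)$, $k_{\max}$ is returned with a warning.

**Refinement.** Principal convex hull analysis (PCHA) relaxes the
selected corners: minimize $\|Y - YCH\|_F$ over column-stochastic
$C \in \mathbb{R}^{n\times k}$ and $H \in \mathbb{R}^{k\times n}$,
starting from $C$ = indicator of the SPA picks and $H$ assigning each
candidate cell to itself. Updates are alternating projected-gradient
steps — Euclidean projection onto the simplex column-by-column — with
backtracking: a step is accepted only if the objective decreases, and
step sizes adapt multiplicatively (×2 on success, ×0.5 on failure), so
the objective trace is non-increasing by construction. All updates are
expressed through the Gram matrix $S = Y^TY$, so the per-iteration cost
is $O(n^2 k)$ regardless of the number of genes. Convergence is declared
at relative objective decrease below $10^{-6}$ or 200 iterations. The
corner-relaxation radius `delta` (column sums of $C$ allowed in
$[1-\delta, 1+\delta]$) defaults to 0; the archetype matrix is $A = YC$.
Each cell's discrete label is its **dominant archetype**, the row
argmax of its column of $H$, ties to the lowest index.

## Regulatory network inference

For archetype $i$, the positive parts of all other archetypes are
projected out: $a_i^\perp$ is the least-squares residual of $a_i^{(+)}$
on the span of $A_{-i}^{(+)}$, computed with the Moore–Penrose
pseudoinverse so that duplicated or collinear archetypes (where the
normal-equations inverse does not exist) cleanly return a zero residual.
Genes are ranked by descending residual expression with deterministic
lexicographic tie-breaks.

Each TF's regulon is tested with the **minimum hypergeometric (mHG)**
statistic: for every cut $1 \le l \le m$ the hypergeometric upper tail
of the target count among the top $l$ is computed, and the score is the
minimum tail over all cuts ($l^{best}$ = the smallest minimizer; all
cuts are candidates, not just a top fraction). Significance of the score
accounts for the minimum over $m$ dependent tests: the exact p-value is
the probability that a uniformly random arrangement of $r$ targets among
$m$ genes reaches an mHG score at least as small, computed by the
lattice-path dynamic program that zeroes every prefix cell whose tail
already certifies the score and complements the surviving path mass.
Path counts are rescaled whenever they exceed $10^{250}$ (the
accumulated factor is carried in log space), so rankings of tens of
thousands of genes are handled without overflow; the blocking comparison
reuses the same `phyper` evaluations as the score, making the DP agree
with exhaustive enumeration to machine precision. The p-value always
lies in $[\text{score}, \min(1, m\cdot\text{score})]$.

The gene **universe** for testing is the intersection of the ranked
genes with the genes known to the regulon table, and $m$, $r$ are
recomputed per TF on that universe (the background set is otherwise
undefined). TFs with $p \le \alpha$ (default 0.05; a strict functional
activity level of $10^{-3}$ is conventional) contribute edges to their
targets ranked above $l^{best}$. Raw thresholds are the default;
Benjamini–Hochberg adjustment per archetype is available via
`adjust = "BH"`. Regulation modes (activation/repression) are carried
through from the input table but never used in scoring, as there is no
principled way to sign an enrichment of mixed regulons.

## The synthetic-data generator

`simulate_labeled_counts()` emulates exactly the structure the kernel is
built for — and nothing more:

* `n_universal = 200` of `m_genes = 2000` genes are universal, mean
  `universal_mean = 4` (log-TPM-like units) in every cell;
* each of `n_types = 5` types has `markers_per_type = 20` exclusive
  markers with mean `marker_effect = 2` in its own cells and 0
  elsewhere — deliberately half the universal mean, so type identity is
  a weak signal riding on a dominant shared background;
* all remaining genes are background with mean 0;
* values are Gaussian noise (`noise_sd = 0.5`) around these means,
  truncated at zero — a log-scale, zero-inflated continuous surrogate
  for log-TPM. The default population is 100 cells per type.

These defaults are the study conditions used throughout the test suite
(500 cells × 2000 genes for the five-type experiments; 1000 cells for
the rare-type sweep, four equal common types plus one rare type). The
generator does **not** model library-size variation, batch effects,
counting noise, or correlated gene programs; passing tests demonstrate
that the pipeline recovers planted convex/marker structure under
expression-dependent dropout, not that it is robust to every artifact of
real scRNA-seq data.

Dropout follows the expression-dependent removal model: each nonzero
entry $x$ is zeroed with probability $2^{-6x}$, so weak transcripts
vanish quickly while strong ones are effectively immortal.
`dropout_series()` repeats the pass until a target fraction of the
original nonzeros remains — the model implies a density floor equal to
the fraction of strongly expressed entries, so targets below that floor
are unreachable and the series stops at its pass cap.

`simulate_separable_instance()` plants exactly separable matrices
($k$ pure columns, the rest random convex combinations, optional
bounded noise) for which SPA's exact-recovery guarantee applies;
`plant_regulons()` builds a TRRUST-style regulon table whose focal TF
overlaps a chosen type's markers by a configurable count (default 15 of
20 targets) alongside decoy TFs with random non-marker targets.

## Evaluation utilities

`kernel_kmeans()` runs Lloyd iterations entirely in the kernel (squared
distance to a centroid expanded in kernel terms), from random
assignments, keeping the best of `n_init = 100` starts; an emptied
cluster is re-seeded with the point farthest from its centroid, and
results are deterministic given the seed. `clustering_scores()` returns
the Adjusted Rand Index, Normalized Mutual Information with
**arithmetic-mean** entropy normalization, and the **pairwise** F-score
(harmonic mean of precision and recall over co-clustered pairs) — both
conventions are stated because several variants exist in the
literature.

## Numerical choices and degenerate inputs

* Zero-variance cell profiles cannot be z-scored and raise an error
  naming the cell; an all-constant universal signature likewise.
* All-zero positive-projection rows get entropy `NA` and weight 1.
* The entropy clamp `u_min = 1/log(n)` bounds the largest possible
  weight at $\hat u \log n$, preventing a single near-private gene from
  dominating the kernel.
* SPA stops early when the residual norm falls below $10^{-12}$ of its
  initial maximum.
* PCHA accepts only objective-decreasing steps, so monotonicity holds in
  exact arithmetic and to $10^{-12}$ in floating point.
* The mHG DP and score share `phyper` calls, so DP = enumeration
  float-exactly on small grids.

## Problem sizes in the shipped tests

The test suite regenerates all data in code: five-type experiments at
500 cells × 2000 genes (10 replicates), the rare-type check at 1000
cells with a 2% subpopulation (5 replicates), separable-recovery at
m = 30, k = 4, n = 60 (20 replicates), and the complete mHG
enumeration grid up to m = 10. The acceptance script sweeps the rare
fraction over 1–5% at 1000 cells with 10 replicates per fraction.

## Known limitations

* The oversampling test needs $k \ge 4$; datasets whose true structure
  is 2–3 archetypes rely on the flag appearing at $k+1 \ge 4$, which it
  does in practice, but $k^\* = 2$ cannot be distinguished from
  $k^\* = 3$ when neither is flagged.
* The kernel is dense ($n \times n$); the implementation targets
  hundreds to a few thousand cells, not atlas-scale data.
* Archetype identity is only defined up to permutation; downstream
  comparisons should match archetypes by their profiles or dominant
  sets, as the tests do.
* The entropy threshold assumes the uniformity distribution is
  genuinely bimodal; on data with a single mode the midpoint fallback
  (with its warning) governs, and weights degrade gracefully toward a
  constant rescaling.
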