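---
title: "Replicate-based batch correction for mass cytometry: model, parameters and design"
author: "cytofbatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-based batch correction for mass cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the model the
correction fits, the assumptions it leans on, the parameters that matter
and their defaults, what the synthetic study generator does and does not
emulate, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The correction model

CyTOF expression values are first transformed to `asinh(intensity / 5)` —
the field's standard variance-stabilizing transform, with cofactor 5 for
mass (as opposed to fluorescence) cytometry — and then standardized so
every protein has zero mean and unit standard deviation across *all* cells
of the run. The standardization uses the sample standard deviation
(divisor `m − 1`); the convention is arbitrary but is applied and inverted
consistently, and the round-trip is exact to 1e−10 (tested).

On this scale the working decomposition is

$$Y_{ij} = X_i\beta_j + W_i\alpha_j + \varepsilon_{ij},$$

with cells \(i = 1..m\), proteins \(j = 1..n\). \(X\beta\) — the biology —
is never estimated. The method estimates only the low-rank unwanted term
\(W\alpha\) and subtracts it:

1. **Clustering.** All cells are partitioned into subpopulations using the
   lineage proteins only, on the arcsinh (not standardized) scale.
2. **Pseudo-replicates.** For each designated reference patient — a
   biological sample aliquoted into every batch — and each metacluster,
   the patient's cells in that cluster across all batches form one group.
   Under the replication design, systematic differences within such a
   group can only be technical.
3. **Residuals.** Each group's column means are subtracted from its
   members; every other cell contributes a zero row. Only replicate
   disagreement informs the fit.
4. **α̂.** The top-`k` right singular directions of the residual matrix,
   scaled by their singular values.
5. **Ŵ.** Every cell's profile is regressed on α̂ using *all* proteins as
   negative controls: \(\hat W = Y\hat\alpha^{\top}(\hat\alpha\hat\alpha^{\top})^{-1}\).
6. **Adjustment.** \(Y - \hat W\hat\alpha\), then the standardization is
   inverted.

Two algebraic facts shape everything downstream. First, with all proteins
as controls, \(\hat W\hat\alpha = Y V_k V_k^{\top}\): the adjustment is an
orthogonal **projection** of every cell onto the complement of the top-`k`
residual directions, and is invariant to any invertible reparameterization
of α̂ (tested to 1e−10). Second, because the projection is all-or-nothing
along those directions, biological variation that happens to lie along
them is removed together with the batch effect. This is inherent to the
estimator, not an implementation artifact; it is why `k` should be kept
near the true complexity of the batch effect and chosen by inspecting
diagnostics over a sweep (the CLI accepts `--k 5,10,15` and emits one
bundle per value).

### Assumptions

* At least one subpopulation of each reference patient is present in at
  least two batches. If none is, the replicate map construction stops with
  a named error — the method is simply not applicable.
* Batch effects are approximately additive and low-rank on the
  standardized arcsinh scale within the groups used.
* All proteins are usable as negative controls, i.e. no protein's
  *biology* differs between batches for the reference samples — guaranteed
  here by replication of the same material.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `cofactor` | 5 | raw intensity | standard for CyTOF |
| `k` | — (user) | 0 … rank(R) | dimension of unwanted variation; `k = 0` is the identity; requests above the numerical rank are capped with a warning |
| `n_meta` | 20 | clusters | typical subpopulation resolution for a PBMC panel |
| `grid_dims` | 10 × 10 | SOM nodes | the common cytometry configuration |
| `rlen` | 10 | epochs | batch SOM converges quickly on well-separated data |
| `bin_width` (EMD) | 0.1 | arcsinh units | the conventional binning for cross-batch EMD comparisons; exposed as a parameter |
| `subsample` (silhouette) | 100 | cells/sample | the silhouette is O(m²); 100/sample keeps it exact on a representative subsample with a recorded seed |
| `percentile` (baseline) | 95 | (0, 100) | the percentile-scaling baseline's anchor |

## Clustering choices

The field-standard clustering for CyTOF — a self-organizing map followed
by metaclustering, the FlowSOM recipe — is implemented here as a
batch-trained SOM plus metaclustering, with the stochastic consensus layer
replaced by deterministic average-linkage hierarchical clustering of the
codebook:

* **Batch (not online) SOM training** makes the result a deterministic
  function of (data, seed): the seed only draws the initial codebook from
  the data rows.
* **Gaussian neighborhood, linearly decaying radius.** A hard "bubble"
  neighborhood lets small maps collapse onto a shared mean under batch
  updates (every node sees the same weighted cell set); the Gaussian
  kernel always weights a node's own cells most, which prevents this
  degeneracy. In late epochs the radius falls below the inter-node
  distance and training becomes k-means-like refinement.
* **Nearest-code ties** go to the lowest node index, so assignment is
  reproducible bit-for-bit.
* Clustering always uses the lineage-class proteins on the arcsinh scale;
  metacluster ids are relabelled contiguously in order of first
  appearance.

## Evaluation metrics

* **EMD**: the 1D Wasserstein-1 distance between binned expression
  distributions on a shared grid spanning the pooled range, `Σ|ΔCDF|·h`.
  One closing bin is allocated so a point mass at the pooled maximum keeps
  its full distance. For a pure location shift the error is at most one
  bin width; as `h → 0` it converges to the exact W₁ (both tested).
* **Hellinger** distance on per-sample cluster proportion vectors, with
  the standard radical form \(H^2 = \tfrac12\sum_i(\sqrt{p_i}-\sqrt{q_i})^2\);
  0 for identical vectors, 1 exactly for disjoint support.
* **Silhouettes**: exact per-cell widths \((b_i-a_i)/\max(a_i,b_i)\) with
  Euclidean distances over all panel proteins, computed on a per-sample
  subsample. `s_batch` (batch labels) should fall after correction;
  `s_biology` (cluster labels) should not. The implementation is
  vectorized but agrees exactly with an O(m²) brute-force double loop and
  with `cluster::silhouette` (both tested).
* **ΔΔ medians**: for two-batch designs, per-marker medians over
  replicated patients' cells per batch, `Δ = M₂ − M₁`, and
  `ΔΔ = Δ_raw − Δ_norm`. Implemented literally, signs kept; an
  absolute-value variant is available behind an explicit flag. Clusters
  missing from a batch yield missing (`NA`) metric entries, never zeros,
  so summaries are not biased toward agreement.

## The synthetic study generator

`default_study("two_batch_paper_like")` emulates a replicated two-batch
design: 12 patients (9 healthy controls, 3 CLL) measured once per batch —
24 samples — with a 31-protein panel (19 lineage, 12 functional), 20
Gaussian subpopulations in arcsinh space, and 850 cells per sample (about
20k cells). The `twelve_batch` preset is the analogous
one-donor/two-condition design across 12 batches.

Generator choices, made once:

* **Subpopulation geometry.** Lineage markers follow random on/off
  patterns (means ≈ 0.4 vs ≈ 3.2, within-population sd 0.30), i.e. ~9 sd
  separation — deliberately clean so clustering failures cannot mask
  normalization behavior. Functional markers vary continuously across
  subpopulations.
* **Abundances** are condition-specific simplex profiles with per-patient
  jitter, constant across batches, so a patient's replicates differ only
  through the injected distortion plus multinomial sampling noise.
* **Batch effect**: rank-2 and additive in arcsinh space. Batch 1 is the
  identity anchor. The global direction is strong on functional proteins
  (magnitudes ~U(1.2, 2.2), signed) and mild on lineage proteins
  (~U(0.15, 0.40)); a second, subpopulation-modulated direction
  (~U(0.6, 1.2) on functional proteins, weights ~U(0.4, 1.2)) makes the
  effect genuinely rank 2 and cluster-dependent. The magnitudes encode the
  motivating observation that batch effects rival biological differences;
  they sit mainly on functional channels because large lineage shifts
  would destroy the shared clustering across batches that the method's own
  assumption requires — with global lineage shifts much above ~0.5 the
  cross-batch pseudo-replicate groups genuinely disintegrate and any
  correction method of this family degrades.
* **Raw-scale realism.** Values are inverse-transformed
  (`5·sinh(v)`) and written as FCS 3.1 float data, so synthetic studies
  exercise the real I/O path end to end. Strong negative shifts can drive
  a channel's raw intensities negative; `asinh` is defined on all reals
  and the loader passes such events through unchanged.

What the generator does **not** emulate: acquisition time-drift within a
run, doublets/debris/viability artifacts (gating is assumed upstream),
non-Gaussian marker distributions (real CyTOF channels are zero-inflated),
and multiplicative distortions are off (unit scale) in the presets so the
injected effect has an exact low rank. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not performance on
arbitrary real data.

### Identifiability of the recovered effect

The per-protein *mean* of an injected shift is absorbed by the global
standardization and cannot be attributed to any batch by the estimator;
only the column-centered part of the effect is identifiable. The
parameter-recovery check therefore correlates the estimated component
(`raw − adjusted`) with the column-centered true offsets. On the default
study this correlation and the reference sample's EMD reduction are
recomputed from scratch by `scripts/acceptance.R`.

## Numerical choices

* **Rank guard.** Requested `k` is capped at the number of residual
  singular values above `1e−10·σ₁`, with a warning. When the SVD is taken
  via the n×n cross-product of residuals (used when `m > 5n`; equality
  with the direct SVD is part of the oracle tests), eigenvalues at
  machine-precision level are zeroed first so the rank estimate is not
  inflated by `sqrt(eps)`-scale noise.
* **k = 0** yields an empty fit whose adjustment is the identity.
* **Degenerate inputs**: constant protein columns are rejected by name at
  standardization; an all-singleton replicate map is an error ("no
  residual information"); a replicate map whose groups all sit in one
  batch is an error ("no shared subpopulation across batches").
* **Percentile baseline**: a reference percentile that is zero or negative
  cannot be equalized by a positive scale factor; such proteins are left
  unscaled with a warning.
* **MDS** is classical (Torgerson); planar configurations are reproduced
  exactly up to rigid motion (tested to 1e−8). The t-SNE embedding is
  display-only — no metric consumes its coordinates — with the seed and
  subsample recorded in every diagnostic bundle.
* **LDA** is Fisher's discriminant on all panel proteins; a numerically
  singular within-class scatter is ridge-regularized with a warning, and
  two-class projections are padded to 2D with the leading within-class
  residual principal component.

## Design decisions

* The interactive exploration layer is replaced by a **static HTML report
  plus CSV exports** (`render_report`): every figure's underlying table is
  written next to it, regeneration with the same seeds is byte-identical
  on the data files, and the whole artifact is testable headlessly.
* The model core is exposed as a classic fitting function (`ruv_fit`) with
  `coef`/`fitted`/`residuals` methods — the adjusted data *are* the
  residuals of the unwanted-variation fit, which is exactly the model's
  semantics.
* Non-reference cells are singletons: they contribute no residual rows, so
  α̂ is estimated purely from replicate disagreement, but they receive a
  Ŵ row through the all-protein regression — that is what transfers the
  correction to the whole study.
* Ŵ columns are not explicitly centered before subtraction; because the
  standardized columns have zero mean and the adjustment is a projection
  applied to them, adjusted column means are provably zero anyway
  (tested to 1e−10).

## Problem sizes used by the tests

The suite exercises the full preset (≈20k cells) for the recovery,
clustering and end-to-end pipeline checks and scaled-down studies
(60–5000 cells, 5–8 proteins) everywhere a property does not depend on
size; silhouettes use 100 cells per sample. These sizes are the package's
own choices for a thorough-but-quick default test run.

## Known limitations

* Correction quality degrades gracefully as batch effects on *lineage*
  markers grow, and fails outright when no subpopulation remains shared
  across batches — the method's stated applicability boundary.
* The projection removes any biological signal that is exactly collinear
  with the estimated unwanted directions; on a null study (no batch
  effect) with a realistic panel, the median per-protein change is small
  (tested < 0.05 arcsinh units at k = 5) but the change on the few
  channels that happen to carry the top residual noise directions is not.
* `k` selection is deliberately not automated; the diagnostics exist to
  make the sweep easy to judge.
* Bridging designs (different reference samples in different batches) are
  out of scope.
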