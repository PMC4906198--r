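---
title: "Pan-specific binding-core prediction for HLA-DR: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-specific binding-core prediction for HLA-DR: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drpocket)
library(dplyr)
```

## The problem

MHC class II molecules such as HLA-DR present peptides to CD4+ T cells. The
binding groove is open at both ends, so a peptide of 11–23 residues can sit
in it in several registers; only a contiguous 9-residue stretch — the
*binding core* — actually occupies the groove's nine positions. Identifying
that core is the central difficulty of MHC II binding prediction.

Each of the nine core positions sits in a sub-cavity ("pocket") lined by a
fixed set of beta-chain residues (`pocket_definitions()`). Pockets 1, 4, 6,
7 and 9 are the *anchors* that dominate specificity. A pocket's binding
preference is summarised by a quantitative *profile*: 20 scores, one per
amino acid, in the TEPITOPE tradition of position-specific scoring matrices.
Crucially, alleles sharing a pocket *pseudosequence* (the concatenated
residues at the pocket's lining positions) share that pocket's profile —
which is what makes prediction *pan-specific*: profiles measured for a
handful of reference alleles can be transferred to any allele whose
beta-chain sequence is known.

## The model

Given a query allele, the package synthesizes a profile for each of the
anchor pockets 4, 6, 7 and 9 in three steps. Pocket 1 is conserved across
HLA-DR molecules, so one shared pocket-1 profile is configured once and
reused for every allele rather than synthesized.

**1. Similarity.** For a pocket with pseudosequence length $n$, each
pseudosequence is encoded as the concatenation of the BLOSUM62 rows of its
residues, a $20n$-dimensional vector ($V_a$). The sequence channel is a
Gaussian radial basis function of the encoding distance,

$$K_\mathrm{seq}(V_a, V_i) = \exp\!\left(-\frac{\lVert V_a - V_i\rVert^2}{2\sigma_\mathrm{seq}^2}\right),$$

and, when 3D coordinates of the pocket residues are available on both
sides, the structural channel applies the same kernel to the minimal RMSD
under optimal rigid superposition (Kabsch, reflections forbidden):

$$K_\mathrm{spa}(V_a, V_i) = \exp\!\left(-\frac{\mathrm{RMSD}(H_a, H_i)^2}{2\sigma_\mathrm{spa}^2}\right).$$

Both channels live in $(0, 1]$, with 1 exactly at identity. They are
combined by one of three rules:
$K_1 = \sqrt{(K_\mathrm{seq}^2 + K_\mathrm{spa}^2)/2}$,
$K_2 = (K_\mathrm{seq} + K_\mathrm{spa})/2$, or
$K_3 = K_\mathrm{seq} + K_\mathrm{spa}$. $K_1$ is the default. Note that
$K_3 = 2 K_2$: the two always order candidates identically, and because the
next step uses only the ordering, they are interchangeable in every result
this package produces. Entries without structural data (or a query without
coordinates) fall back to the sequence channel alone and are flagged.

**2. Rank weights.** The similarity vector over the $m$ registry entries is
sorted in descending order (stable; ties keep registry order). Weights come
from discretizing the gamma density at the ranks $i = 1, \dots, m$ and
sharpening with an exponent $\alpha$:

$$G(i) = \frac{1}{\theta^k\,\Gamma(k)}\; i^{\,k-1} e^{-i/\theta},
\qquad
\omega_i = \frac{G(i)^\alpha}{\sum_{j=1}^m G(j)^\alpha}.$$

With shape $k = 1$ the masses decay strictly in rank, so the most similar
entry always carries the largest weight. Raising $\alpha$ concentrates the
weights on the top ranks; as $\alpha \to \infty$ the weight vector tends to
an indicator on rank 1, so a query identical to a registry entry recovers
that entry's raw profile.

**3. Profile synthesis.** The synthesized pocket profile is the weighted
average of the raw profiles in rank order,
$\tilde P_a = \sum_i \omega_i \tilde P_i$ — a convex combination, so every
synthesized score stays within the range of the raw scores. Because the
weights attach to ranks rather than similarity magnitudes, any strictly
monotone transform of the similarity values leaves the profile unchanged.

**Core prediction.** A peptide of length $L$ has $L - 8$ candidate cores.
Each window is scored as the sum, over the scored anchor pockets, of the
profile value of the residue sitting in that pocket; non-anchor pockets
contribute nothing and an unknown residue `X` contributes zero wherever it
sits. The argmax window is the predicted core, ties broken to the leftmost
window. Evaluation compares predicted and annotated cores by exact 9-mer
string equality; offsets are not compared because identical 9-mers at
different offsets are indistinguishable in the benchmark listings.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `mode` | `"K1"` | channel combination rule (quadratic mean) |
| `alpha` | 3 | rank-weight sharpening exponent |
| `shape` (k) | 1 | gamma shape; 1 gives strictly decaying rank masses |
| `scale` (θ) | 1 | gamma scale, in rank units |
| `seq_bandwidth`, `spa_bandwidth` | median pairwise distance | RBF bandwidths |
| `include_pocket1` | `TRUE` | score pocket 1 with the shared profile |

`alpha = 3` and mode `K1` are the operating point selected by the α-sweep
experiment that `alpha_sweep()` reproduces (errors tabulated per mode over
α ∈ {1, 2, 3, 4, 5, 10, 15, 20}). The gamma shape and scale are not pinned
down by the source method description; `k = θ = 1` is chosen so that the
"more similar gets more weight" property holds unconditionally, and both
remain user-settable (and CLI-exposed) for sensitivity analysis.

Bandwidths default to the median pairwise distance among the registry's own
entries, per pocket and per channel: a scale-free choice that adapts to the
units of the encoding and is deterministic given the registry. A degenerate
median of zero (all entries identical) falls back to 1; the value only
matters through the similarity ordering, which a global bandwidth cannot
change for the sequence channel alone.

## Numerical choices

* Weights are computed on log masses (`dgamma(..., log = TRUE)` scaled by
  α, shifted by the maximum before exponentiation), so large α or large m
  cannot underflow: `gamma_weights(200, alpha = 20)` is exact to machine
  precision. The $1/(\theta^k\Gamma(k))$ constant cancels in the
  normalization and has no numerical effect.
* Superposition uses the SVD of the 3×3 cross-covariance with the
  determinant sign correction, so only proper rotations are considered.
  Fewer than 3 points, mismatched counts and all-collinear sets are
  rejected as distinct errors (a collinear set leaves the optimal rotation
  under-determined).
* Descending similarity sorts are stable with ties broken by registry
  order, making synthesis deterministic for tied similarities.
* There is no exact-match shortcut: a query identical to a registry entry
  still goes through the weighting (the large-α limit recovers the raw
  profile to < 1e-3), keeping a single code path.
* PDB extraction takes the Cα atom as the residue representative (centroid
  of heavy atoms as an option), uses the first alternate location in file
  order, and rejects insertion codes, since pocket numbering assumes plain
  beta-chain numbers. Nonstandard residues become `X` in pseudosequences
  and are rejected at encoding time with a clear error.

## The synthetic-data generator

Real TEPITOPE quantitative matrices are not redistributable and solved
pocket coordinates require downloads, so the test and acceptance
infrastructure runs on synthetic fixtures (`fixture_spec()`,
`generate_registry()`, `plant_core_peptide()`, `generate_benchmark()`):

* **Registries**: `m = 5` unique random pseudosequences of length `n = 6`
  per pocket — the size of the structure-bearing reference set the method
  operates with — and uniform profiles on $[-2, 2]$, mimicking the signed
  score range of TEPITOPE-style matrices.
* **Structures**: a fixed helical template (2.3 Å radius, 1.5 Å rise,
  roughly Cα-trace geometry); entry $i$ is the template plus a Gaussian
  displacement rescaled to an exact RMS magnitude of
  $i \times$ `coordinate_noise` (0.5 Å default), so the structural-distance
  ordering against the template is built in rather than merely expected.
* **Planted peptides**: scored anchor positions of the designated core take
  each pocket profile's best residue, flanks take the residue with the
  lowest worst-case contribution, and the construction is verified by
  exhaustive window scoring — the generator errors rather than emit a
  fixture whose margin falls below `profile_contrast` (2 score units by
  default, matching the profile range).

What passing these fixtures shows: the pipeline is internally consistent —
similarity ordering, rank weighting, convex synthesis and argmax scanning
compose correctly, and planted signal above the guaranteed margin is always
recovered. What it does not show: accuracy on real alleles, which depends
on the quality of the (unbundled) quantitative profiles and on how well
profile transfer across alleles reflects binding chemistry. The bundled
39-complex benchmark ships the published per-complex predictions as static
reference data so their error counts (4 of 30; 1 of 9 held out) can be
recomputed, but re-deriving those predictions from scratch would require
the original matrices and coordinates.

Problem sizes used by the test suite and acceptance script — registries of
5–7 entries, 20 brute-force superposition instances of 4–8 points, 50
planted-core instances, 1000 random weight draws — were chosen as the
smallest sizes at which each property is exercised across its parameter
range.

## Design choices on genuinely open points

* The source method's similarity formulas equate the sequence kernel with
  "BLOSUM" and the structural kernel with the RMSD itself; taken literally
  neither is a similarity (one is an unnormalized score difference, the
  other a distance). Both channels are therefore mapped through the same
  Gaussian RBF of their natural distances, which preserves the distance
  ordering — the only thing the rank-based weights consume — while keeping
  both channels in $(0, 1]$ as the combination rules assume. The raw summed
  BLOSUM alignment score is available via `alignment_score()` as an
  alternative sequence channel.
* The BLOSUM variant is unstated in the source; BLOSUM62 — the field's
  default — is bundled in NCBI text format and any NCBI-format matrix can
  be substituted.
* Whether pocket 1 is scored or merely held fixed is ambiguous; it is
  scored by default using the shared profile, with
  `include_pocket1 = FALSE` restricting scoring to pockets 4/6/7/9.
* The benchmark's two peptide↔PDB listings disagree for a handful of IDs
  (e.g. 1KLU/2FSE swapped); the bundled table follows the per-complex
  prediction listing, which is the one the annotated cores belong to, and
  says so in its file header. Two rows of the observed pocket-composition
  table are internally inconsistent (1BX2 position 13, 1FV1 position 71);
  they are transcribed verbatim and documented in the tests.

## Known limitations

* Only HLA-DR beta-chain pockets are modelled; no HLA-DP/DQ or class I.
* Pseudosequences are position-aligned by construction; there is no
  flexible or partial superposition and no sequence search.
* mmCIF input is not supported; PDB only, with author residue numbering.
* The registry skeleton for the eleven reference alleles ships without
  quantitative profiles; full benchmark reproduction requires the user to
  supply published TEPITOPE matrices via `read_profile_registry()`.
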