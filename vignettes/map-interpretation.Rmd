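---
title: "Locating phosphates and bases in nucleic-acid density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating phosphates and bases in nucleic-acid density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoblob)
```

## The problem

Automated model building for proteins is mature; for nucleic acids it is
not. A DNA or RNA crystal structure determined from an experimental
electron-density map needs its phosphates and bases located before any
backbone can be traced, and the two kinds of feature call for different
detectors: a phosphate group is a strong, compact, tetrahedral lump of
density, while a base is a flat plate whose centre (for a pyrimidine at
high resolution) is actually a local *minimum* of density — a plain peak
search finds neither reliably. `nucleoblob` implements a blob-based
interpretation pipeline for such maps and the backbone-geometry statistics
needed to chain the found pieces into strands.

The pipeline stages, in order:

1. **Preparation** — the map is normalized by its standard deviation so
   density reads in sigma units, and clamped at 4 sigma
   (`modify_density()`) so very strong peaks (e.g. a brominated uracil's
   Br) cannot dominate the later centroid and fitting steps. An optional
   protein mask (`mask_region()`) excludes an already-built protein model.
2. **Blob search** (`find_blobs()`) — voxels are visited in decreasing
   density order; from each still-valid voxel the centre of gravity of the
   positive density inside a 2.5 Å sphere is iterated until the shift
   drops below 0.11 Å (at most 20 iterations, at most 3.5 Å total drift).
   Each accepted centre consumes a 1.3 Å neighbourhood. The blob's shape
   is summarized by the eigendecomposition of a moments-of-density matrix
   `M = Σ ρ_i (|r_i|² I − r_i r_iᵀ)` over the positive voxels in the
   sphere — the density analogue of a rigid body's inertia tensor.
3. **Phosphate ranking** (`rank_phosphates()`) — each blob is scored by
   `P = exp(−k₁ (1 + cc_inv)/√Q) + exp(−k₂ (λ₁ − λ₃)/λ₁)`, where `cc_inv`
   is the Pearson correlation of density values at antipodal points on a
   1.56 Å sphere (the P–O bond length) and `Q` is the blob's positive
   density sum. Tetrahedral density anti-correlates under inversion
   (`cc_inv → −1`) and has near-equal moments eigenvalues, so both terms
   approach their maximum of 1 and `P` its supremum of 2.
4. **Base fitting** (`fit_bases_at_blob()`) — flat blobs (ranked by
   `Q · planarity`, where `planarity = (2λ₁ − λ₂ − λ₃)/(λ₁+λ₂+λ₃)` is 0.5
   exactly for a planar mass distribution) receive a standard purine and a
   standard pyrimidine template, aligned to the blob plane and scanned
   through 24 in-plane rotations of 15°. Each start is optimized by a
   Nelder–Mead simplex over the six rigid-body parameters, maximizing the
   correlation between atomic numbers and interpolated density; dummy
   positions with Z = −1 above and below the rings (and, for the
   pyrimidine, in the region a purine's second ring would occupy) stabilize
   the plane and sharpen the purine/pyrimidine contrast. The six best
   poses per kind are refined by BFGS on `S = Σ Z_i ρ'(x_i)` with the
   analytic gradient of the trilinear interpolant (dummies excluded here).
5. **Watson–Crick pruning** (`prune_by_pairing()`) — every cross-blob
   purine–pyrimidine combination is scored on the three G:C-type
   hydrogen bonds; each contributes `cos(180° − θ) − |d − d₀|` with
   `d₀ = 2.16 Å` for terminal-N donors and `1.85 Å` otherwise, so an ideal
   pair scores close to 3. Pairs are accepted greedily above a threshold
   (default 1.5), and paired blobs drop their remaining (false) cluster
   members. Base pairing is thus an independent chemical filter on the
   density fits.
6. **Geometry statistics** (`backbone_geometry()`, `assign_direction()`,
   `reference_table()`) — with C1' rigidly attached to every fitted base,
   chains of alternating P and C1' atoms are described by two distances
   (C1'→3'P and 5'P→C1'), two angles, and the pseudo-torsions η'/θ'
   (the classical η/θ with C1' replacing the sugar's flexible C4'). The
   two distance populations are asymmetric — B-DNA reference means 5.14 Å
   (5'P→C1') versus 4.29 Å (C1'→3'P) — which is what lets
   `assign_direction()` decide which way a traced chain runs; the same
   asymmetry is nearly absent when N9/N1 is used as the anchor, which is
   why C1' is the anchor of choice.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| blob radius | 2.5 | Å | covers a phosphate or pyrimidine; avoids bleeding into a stacked neighbour (3.4 Å away) |
| shift cutoff | 0.11 | Å | centroid convergence; about a quarter voxel at typical spacings |
| max iterations / drift | 20 / 3.5 | – / Å | rejects seeds with no nearby attractor |
| consume radius | 1.3 | Å | one blob per feature without suppressing the two lobes of a purine |
| density cap | 4.0 | σ | damps heavy-atom peaks; ordinary density is untouched |
| rotation step | 15° | – | 24 starts cover the in-plane search with the simplex bridging the gaps |
| cluster size | 6 | – | poses kept per kind per blob for the pairing filter to choose from |
| inversion radius | 1.56 | Å | P–O bond length: the antipodal shell runs through the oxygen peaks |
| H-bond targets | 2.16 / 1.85 | Å | mean H⋯A distances for terminal/internal N donors |
| k₁, k₂ | 12, 2 | – | phosphate-score shape constants (below) |
| pair threshold | 1.5 | – | half the ideal pair score; accepts distorted but genuine pairs |
| planarity floor | 0.25 | – | admits rendered base blobs (≈ 0.27–0.33) and rejects phosphates (≈ 0.07) |
| seed floor | 1.0 | σ | voxels below this never seed a blob search (cost control; features of interest peak ≥ 3σ) |

**On k₁ and k₂.** The phosphate score's anatomy is fixed by design
(two factors, each capped at 1; √Q damping of the inversion term so lone
heavy atoms do not dominate; supremum 2) but not its constants. With the
inversion factor written as `exp(−k₁(1+cc_inv)/√Q)`, small k₁ makes the
factor inert for realistic Q (hundreds to thousands): every strong-ish
blob saturates it and isotropic noise blobs tie with real phosphates. We
calibrated k₁ = 12 on the noisy duplex fixture, which separates true and
false positives by about 0.3–0.4 score units (mean true-positive score
≈ 1.6, false positives ≈ 1.3) — the behaviour a useful ranking score must
show on noisy maps, where false positives abound but should trail. k₂ = 2 suffices because the
eigenvalue-ratio argument already spans [0, 1).

## The synthetic module

Everything above is testable offline because `build_duplex()` and
`render_map()` fabricate ground truth:

* **Duplex geometry.** A flat, idealized Watson–Crick G:C pair
  (`ideal_pair()`, scoring ≈ 2.6 of 3) is stacked on a regular helix
  (B form: rise 3.38 Å, twist 36°; A form: 2.56 Å, 32.7°), with the
  complementary strand generated by the pair dyad, so the duplex is exactly
  antiparallel. The phosphate position is solved once per helical family by
  least squares so that the per-step distances reproduce the reference
  values (B: 4.29 / 5.14 Å; A: 4.77 / 5.34 Å) with symmetric glycosidic-N
  distances — the construction *bakes in* the direction asymmetry of real
  duplex geometry. Each P carries four oxygens at 1.56 Å in tetrahedral
  directions; a minimal two-carbon pseudo-sugar bridges C1' to its 5'
  phosphate, displaced radially outward as a real sugar is.
* **Density rendering.** Each atom contributes a Gaussian of width
  `0.425 × resolution`, summed with periodic wrapping. Fixture maps are
  scaled so an isolated carbon peaks at 3σ ("atomic" scaling): a synthetic
  cell is mostly empty, so the map-standard-deviation scaling used for
  real maps would put atoms at 30–40σ and the 4σ clamp would flatten them
  into featureless balls; experimental maps, full of solvent and noise,
  keep atomic peaks at a few sigma, and the fixtures reproduce that
  contrast. `render_map()` retains plain SD scaling as its default.
* **What the fixtures do not model:** phase error and solvent-flattening
  artifacts, anisotropy, non-P1 symmetry, sequence-dependent helical
  irregularity (propeller twist, roll, slide), and real sugar density.
  Passing the fixture suite therefore demonstrates the pipeline's
  correctness and its noise tolerance at 0.3σ, not its performance on
  experimental maps with realistic phase error.

## Numerical choices

* Trilinear interpolation everywhere density is read off-grid; its
  analytic gradient drives the BFGS refinement (rotation handled on the
  rotation group via the exponential map and its right Jacobian).
* Only positive density carries weight in centroids and moments — negative
  weights could expel a centroid from the feature it describes.
* Blob acceptance order is deterministic: seeds sort by density with ties
  broken by voxel index; all downstream stages preserve that order, so a
  rerun with the same configuration is byte-identical.
* Antipodal sampling uses a 64-point spherical Fibonacci lattice
  (deterministic, no RNG); degenerate (zero-variance) shells report a
  correlation of 0 with a flag.
* The bimodal splitter for Z-DNA-like angle distributions searches every
  threshold between consecutive sorted values and maximizes the
  count-weighted resultant-length sum `n₁R̄₁ + n₂R̄₂`; a split is called
  bimodal only if it improves on the unsplit objective by at least 1%.
* Gaussian histogram fits use Levenberg–Marquardt (via `minpack.lm`) with
  moment-based initialization; for two components the histogram is first
  cut at its antimode.
* Torsions follow the standard structural-biology sign convention
  (checked against an independent implementation); collinear points give
  a typed NA, not a number.
* Problem sizes in the test-suite: the end-to-end fixture is a 16-nt
  duplex rendered at 1.5 Å-equivalent on a 0.4 Å grid (≈ 4·10⁵ voxels),
  chosen as the smallest scene with interior stacked bases, both strand
  directions, and 14 phosphates.

## Known limitations

* Base identity beyond purine/pyrimidine is not assigned, and only the
  G:C-type Watson–Crick triple is scored; A:T/A:U pairs score on the same
  sites approximately and non-canonical pairs are not modelled.
* Maps must cover a full unit cell in P1 (mode-2 CCP4/MRC); symmetry
  expansion is the caller's responsibility.
* The purine ring system yields two blobs (one per ring); deduplication
  and pairing absorb the redundancy, but blob counts are not residue
  counts.
* Chain tracing itself (ordering phosphates and bases into a polymer) is
  out of scope; the geometry statistics and the direction classifier are
  the building blocks for it.
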