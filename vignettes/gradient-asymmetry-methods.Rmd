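---
title: "Methods: hemispheric asymmetry of connectivity gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemispheric asymmetry of connectivity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemigrad)
```

# The analysis

`hemigrad` quantifies left-right asymmetry in the low-dimensional
organisation of cortical functional connectivity (FC) and asks whether that
asymmetry runs in families.  The chain of models is:

1. **Hemispheric connectivity modes.**  Parcellated resting-state time
   series are correlated pairwise (Pearson), Fisher z-transformed
   (`atanh`), and averaged across sessions in z space.  Four modes result:
   LL and RR within a hemisphere, LR from left seeds to right targets, and
   RL = LRᵀ.
2. **Diffusion-map gradients.**  Each mode's matrix is sparsified row-wise
   (keeping the strongest entries), converted to a normalized-angle
   affinity `1 − arccos(cosine)/π`, anisotropically normalised
   (`W′ = D^−α W D^−α`, α = 0.5), row-normalised into a Markov operator,
   and eigendecomposed.  The leading non-trivial eigenvectors, scaled by
   `λ/(1−λ)`, are the gradients; G1 is the principal axis
   (unimodal-to-transmodal in real cortex).
3. **Template alignment.**  A group template is embedded from the
   group-mean reference mode (LL by default) and every individual gradient
   set is aligned to it by orthogonal Procrustes rotation *without
   scaling* — the template fixes only the order and direction of
   components.  Reflections are permitted: sign indeterminacy is exactly
   what alignment must resolve.
4. **Asymmetry index.**  AI = left − right aligned scores at homologous
   parcels (LL − RR intra-hemispheric, LR − RL inter-hemispheric);
   positive = leftward.  Per parcel, a one-sample t-test across subjects,
   Benjamini-Hochberg FDR within a component's map, and Cohen's
   d = mean/SD (so t = d·√n identically).  A normalized variant
   (L−R)/(L+R) is available after a common positivity shift.
5. **Heritability.**  For each parcel's AI, the AE model
   `y ~ N(Xβ, σ²g·K + σ²e·I)` is fitted by full maximum likelihood, where
   K is the expected additive relatedness (MZ co-twins 1, DZ 0.5,
   unrelated 0).  One eigendecomposition of K reduces the fit to a 1-D
   profile likelihood over h² ∈ [0,1]; the AE fit is compared to the
   environment-only fit by a likelihood-ratio test with the boundary
   ½χ²₀ : ½χ²₁ mixture.  Covariates: intercept, age, sex, age², age×sex.
6. **Spatial statistics.**  Correlations between parcel maps are tested
   against spin permutations: uniformly random rotations of the spherical
   parcel centroids (mirrored for the left hemisphere), nearest-centroid
   reassignment (duplicates permitted), two-sided p with the +1 correction
   so p is never exactly 0.
7. **Cross-parcellation / cross-species transfer.**  An effect map
   (Cohen's d, whose normalisation makes effect sizes comparable across
   samples) is carried through a supplied row-stochastic mapping; left-
   and right-alignment transfers are averaged; similarity is assessed with
   Pearson and Spearman correlations plus spin p-values on the target
   geometry.  Learning the mapping is out of scope — it is an input.
8. **Decoding.**  A normalized asymmetry map is divided into 20 equal-count
   bins; each activation term's suprathreshold (z > 0.5) activation is
   averaged per bin and summed against the bins' mean asymmetry, giving a
   signed lateralization score (leftward positive).  A parcel-level variant
   `Σ 1[z>0.5]·z·d` is co-reported because the binned and parcel-wise
   readings of the weighted score are both defensible; mask-then-mean is
   the default order.

# The synthetic twin cohort

Real inputs of this kind (large twin imaging cohorts) are access-restricted,
so the package ships a generator whose ground truth makes every stage
verifiable by parameter recovery.

**Geometry.**  `make_parcel_geometry()` places parcels evenly on a
spherical hemisphere (Fibonacci spiral through an equal-area projection)
and mirrors them across the midline, so homology is exact.  The *latent
functional axis* is a monotone quantile transform of one spatial
coordinate, scaled to [0,1].  The quantile (rather than affine) transform
gives parcels uniform density along the axis; with non-uniform density the
principal diffusion component is a visibly curved function of the axis and
recovery correlations understate the embedding's actual fidelity.

**Time series.**  Parcel i mixes shared smooth basis signals with Gaussian
kernel weights centred on its latent position (kernel width 0.2 axis
units, 12 basis signals), plus one shared *global axis signal* whose
loading is linear in latent position, plus white noise (SD 1 against unit
signal variance).  The global signal is essential realism: purely banded
(local-kernel) connectivity has a dense eigenspectrum with no dominant
principal gradient, whereas real FC concentrates ~24% of gradient variance
in G1.  With it, the synthetic template's G1 carries ~28% of variance and
is stable across seeds.  Defaults: 4 sessions × 300 timepoints — a
shortened version of a four-session resting-state design; long enough that
parcel-wise AI heritability is not drowned by FC sampling noise.

**Asymmetry.**  Subject j's left/right latent positions are shifted apart
by `±½·asym_scale·δᵢ·sⱼ`.  The spatial field δ (positive = leftward) is by
default the standardised `cos(π·latent)` — asymmetry organised along the
principal gradient, leftward at one pole and rightward at the other, which
is also the empirical picture in cortex (language/default regions at the
transmodal end lateralising opposite to frontoparietal regions).  This
choice is deliberate and matters: the AI measurement (difference of
aligned gradient scores) cannot attribute shift patterns that amount to a
uniform translation or affine stretch of the axis, and it scrambles high
spatial frequencies through eigen-mode mixing; a generic smooth random
field is therefore only partially recoverable (r ≈ 0.5–0.85) no matter how
the analysis is tuned.  Planting the pattern in the identifiable subspace
keeps recovery tests meaningful; arbitrary fields can still be injected
through `asym_field`.  `asym_scale` defaults to 0.1 axis units: large
shifts (≳0.2) visibly smear the group template itself.

**Subject shifts and twins.**  `sⱼ = 1 + gⱼ + eⱼ`: unit mean (so a group
mean asymmetry exists), total SD 0.6, with `var(g) = h2_target·SD²` split
so MZ co-twins share g exactly and DZ co-twins' g correlates 0.5.  The
zygosity effect lives on this scalar shift, giving one tunable h² shared
across the asymmetric region; per-parcel h² then scales with |δᵢ| and is
attenuated by measurement noise.  With the defaults the strongest parcels
reach estimated h² ≈ 0.2 against a 0.5 target — attenuation, not bias: on
the noise-free shift values the AE model recovers h2_target to ±0.05.

**Smooth fields.**  Spatially autocorrelated maps (atlas terms, species
fields, spin-test calibration maps) are kernel-smoothed white noise over
the sphere centroids with a 30° FWHM Gaussian (the neuroimaging convention
for quoting smoothing kernels; read as σ the maps would have ~5 effective
degrees of freedom, smoother than any parcel-level cortical effect map).

**What the generator does *not* emulate** — scanner artefacts, motion,
hemodynamics, vertex-level surfaces, distance-dependent noise, genuine
network topology beyond the single latent axis, and shared (C) environment.
Passing recovery tests therefore show the pipeline is correct and
well-calibrated under this model, not that any specific empirical claim
about real cortex is reproduced.

# Numerical choices

* |r| is clamped to 1 − 1e−7 before `atanh`; the LL/RR self-correlation
  diagonal is set to 0 (the affinity stage re-derives similarity, and
  atanh(1) is infinite).
* Sparsification keeps `ceil(density·p)` *largest signed* entries per row;
  ties break to the lower column index, making the operation deterministic.
* The row cut is matched by **retained-neighbour count**, not percentage,
  at desk scale: a 10% cut of a 180-parcel hemisphere keeps 18 rows, so
  60-parcel synthetic studies use `row_density_kept = 0.3` (18 of 60).  At
  10% of 60 rows the embedding becomes so discrete that asymmetry maps are
  dominated by threshold jitter.  The package default remains 0.10; the
  2p-node joint embedding uses 0.10 directly.
* The embedding solves the symmetric similarity transform of the Markov
  operator (exact, no iteration); the trivial constant eigenvector is
  dropped; variance explained is λ over the sum of positive non-trivial λ.
* Template orientation: each component is flipped so it correlates
  positively with a configurable anchor map (default: sparsified row
  degree; synthetic studies anchor on the known latent axis).  Making the
  convention explicit matters because replication datasets genuinely need
  hand-flipping otherwise.
* Procrustes: R = UVᵀ from the SVD of `sourceᵀ·template`; orthogonal, not
  special-orthogonal.
* AE optimisation: `stats::optimize` on h² ∈ [0,1] (tol 1e−8) with the
  endpoints checked explicitly; β and total variance are profiled
  analytically; no seeds anywhere in the fit.
* Spin p-values use `(1 + #{|null| ≥ |obs|})/(n_perm + 1)`; only map A is
  permuted; n_perm defaults to 1000.
* Normalized AI shift: `c = −min(all scores) + 0.01·range`, computed once
  over the pooled cohort scores per pattern.

# Design decisions that were genuinely open

* **AE, not ACE**: matches single-h² reporting; shared environment is out
  of scope.
* **Boundary LRT mixture** ½χ²₀:½χ²₁: verified empirically (type-I error
  0.05–0.06 at α = 0.05 over 500 nulls).
* **Duplicates allowed in spins** (nearest-centroid reassignment), the
  parcel-scale convention; calibration verified (rejection ≈ 0.05).
* **Mask-then-mean** for the decoding score; the parcel-level variant is
  always co-reported.
* **Joint-embedding caveat**: at 60 parcels per hemisphere the joint
  two-hemisphere AI estimator agrees with the per-hemisphere estimator
  only at r ≈ 0.86.  Both estimators are internally reliable (split-half
  r ≈ 0.99); the residual disagreement is systematic — in a 120-node joint
  graph the strong homotopic LR links couple homologous parcels and
  distort score differences — and shrinks only with much larger graphs.
  This is reported honestly rather than papered over; on large real
  parcellations the two estimators are near-identical.

# Problem sizes used by the shipped studies

The recovery and calibration studies run at: 100 subjects (25 MZ + 25 DZ
pairs) × 60 parcels for gradient/asymmetry recovery; 20 null cohorts of 30
subjects for FDR calibration; 400 twin pairs × 50 (recovery) and 500
(null) replicates for heritability; 500 map pairs × 500 spins for spin
calibration; 50 seeds for cross-species recovery.  These sizes give
Monte-Carlo error comfortably inside the asserted bounds while keeping a
full run in a few minutes on one CPU.

# Known limitations

* The AI measurement's blind spot (axis-affine shift components) is a
  property of any difference-of-aligned-embeddings analysis, not of this
  implementation; interpret real-data AI maps accordingly.
* Parcel-wise h² estimates are attenuated by measurement noise; the
  package reports them as estimated, without disattenuation.
* The spin null treats parcels as points (their centroids); parcel area
  and shape are ignored.
* The cross-species mapping is applied, never learned; conclusions about
  between-species similarity inherit whatever bias the supplied mapping
  carries.
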