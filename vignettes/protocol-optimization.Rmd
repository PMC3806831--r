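---
title: "Optimizing a multi-contrast vessel-wall MR protocol for soft-plaque segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing a multi-contrast vessel-wall MR protocol for soft-plaque segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqopt)
```

## The method

A carotid vessel-wall protocol derives nine contrast weightings (TOF, T1W,
T2W, PDW, STIR, MRDTI, DWT2, DWI, ADC) from six pulse sequences. `plaqopt`
scores every non-empty subset of those weightings — 511 candidate
protocols — by how well an automated pixel classifier, restricted to that
subset, reproduces per-patient soft-plaque volumes, and by the scan time the
subset costs. The result is a trade-off curve a protocol designer can act
on: most of the achievable segmentation performance is typically reached by
a small informative subset at a fraction of the full protocol's duration.

The pipeline per subset is:

1. **Normalization.** Each channel of each slice is divided by the median
   intensity of a 4 × 4 cm ROI centered on the lumen contour centroid.
   This makes intensities comparable across sequences of one subject and
   across subjects. The ROI is clipped at image borders; the median is
   taken over the clipped set. We treat "lumen center" as the polygon
   centroid of the lumen contour, and normalize per slice — both choices
   among reasonable alternatives the problem leaves open.
2. **ADC computation.** The diffusion acquisition yields the b = 0 image
   (DWT2) and the diffusion-weighted image (DWI, b = 500 s/mm²). The ADC
   map is the standard two-point mono-exponential fit,
   ADC = ln(S_b0 / S_bw) / Δb, in mm²/s; pixels with non-positive signal
   are zeroed and flagged.
3. **Features.** For every wall pixel — inside the outer-wall contour, outside
   the lumen contour, with an even-odd pixel-center rasterization rule and
   boundary pixels counted inside — the feature vector holds the normalized
   intensity plus the full 2D Gaussian jet {L, L_x, L_y, L_xx, L_xy, L_yy}
   at scales 0.25, 0.5, 1.0, 2.0 mm: 25 features per channel. Scales are
   physical (σ in mm, converted through the 0.39 mm pixel spacing);
   derivatives are in per-mm units; borders are mirror-reflected. A
   rotation-invariant reduced jet {L, |∇L|, ∇²L} is available via
   `feature_spec(jet = "rotation_invariant")`. The zero-order L at small
   scales is nearly collinear with the raw intensity; we keep both (the
   stated feature set) and let covariance shrinkage absorb the collinearity.
4. **Classification.** A two-class Mahalanobis-distance classifier:
   x is assigned to the class with smaller d²_k = (x − μ_k)ᵀ Σ⁻¹ (x − μ_k),
   no prior or log-determinant term, ties resolved to *not soft plaque* so
   plaque calls are conservative. Σ is the pooled within-class covariance
   with shrinkage Σ_reg = (1 − λ)Σ + λ·diag(Σ), λ = 10⁻⁴ by default —
   enough to keep 225 strongly collinear features invertible while
   perturbing well-conditioned problems negligibly.
5. **Evaluation.** Leave-one-out cross-validation at the patient level:
   each patient's pixels are predicted by a model trained on all other
   patients. Predicted soft-plaque volume per patient is pixel count ×
   pixel area × slice thickness, summed over slices. Volumes are compared
   with the reference standard by Pearson correlation; the 95% CI uses the
   Fisher z-transform tanh(atanh r ± z₀.₉₇₅/√(n−3)) and the p-value the
   exact t-statistic on n − 2 degrees of freedom.
6. **Scan-time budgeting.** Each weighting maps to its source sequence;
   a subset costs the sum over *distinct* sequences (T2W and PDW share one
   dual-echo acquisition; DWT2, DWI and ADC share the diffusion
   acquisition). Durations are printed rounded half-up to one decimal
   minute — half-up, not banker's, so that 2.95 prints as 3.0 and 7.65
   as 7.7, the way protocol tables are conventionally quoted.

## Why the pooled covariance is the default

Both covariance modes are implemented. With per-class covariances and a
pure argmin-d² rule, the class with the larger covariance claims a
disproportionate share of feature space: whenever between-patient
variability inflates the plaque class's covariance, nearly the whole wall
is called plaque and fold accuracy can drop below chance. The pooled
within-class metric — the classical Mahalanobis classifier, whose decision
boundary is the hyperplane midway between the class means in the metric of
the common covariance — has no such failure mode and is the default
(`cov_mode = "pooled"`); `cov_mode = "per_class"` remains available for
experimentation.

## The phantom: what it emulates, and what it does not

Clinical vessel-wall cohorts of this kind are generally not shareable;
the package instead generates a synthetic cohort with the same
structure and uses it as its test bed:

* **Geometry.** 15 patients × 5 slices on a 64 × 64 grid at 0.39 mm
  isotropic in-plane spacing and 3 mm slice thickness (the reference T1W
  grid). Each patient has an annular wall: concentric circle contours with
  lumen radius 1.3–2.2 mm and outer radius 3.8–5.0 mm. The walls are
  deliberately thick — these are surgical-grade diseased arteries — which
  also guarantees that lesion volume draws almost always fit the geometry.
* **Lesions.** Crescents bounded by the annulus and a chord at a random
  angle, spanning a contiguous run of slices. A lipid-like lesion occurs
  with prevalence 14/15 and volume log-normal with mean 142.0 and
  SD 115.8 mm³; a hemorrhage-like lesion with prevalence 4/15, mean
  75.6, SD 48.3 mm³ — the composition of the surgical population the
  phantom emulates (calcium is not modeled; the method does not classify
  it).
  Both lesion types are pooled into a single *soft plaque* class, as the
  method pools them. The chord offset is solved analytically from the
  drawn volume, so the target volume is exact up to one boundary pixel
  layer of discretization.
* **Intensities.** Per channel and tissue class (background, wall, plaque),
  Gaussian signals with class separations in pooled-SD units that encode
  the qualitative informativeness of the weightings: TOF 2.6, MRDTI 2.2
  and ADC 2.05 (the high tier — these are the weightings from which soft
  plaque components can be identified directly), T1W/T2W/PDW around 0.85–1
  (medium), STIR 0.3 and the raw b = 0 image 0.2 (low). The diffusion
  channels are generated through the forward model DWI = DWT2·e^(−b·ADC)
  from a class-conditional true ADC field, so the ADC map must actually be
  recovered by the preprocessing stage; DWI's own separation is whatever
  the forward model induces.
* **Nuisance structure.** Each patient gets one multiplicative receiver
  gain per *acquisition* (log-SD 0.2) — shared by T2W/PDW and by
  DWT2/DWI, so gain cancels exactly in the ADC ratio — which the median
  normalization must remove. Each patient additionally gets per-channel,
  per-class mean shifts of SD 0.6 pooled-SDs (`biovar`): inter-subject
  biological variability that normalization *cannot* remove. This term is
  essential to realism: without it, pixel noise averages out over ~10³
  wall pixels and even a 0.2-SD channel achieves near-perfect volume
  correlation, which no real cohort shows. With it, weakly separated
  channels produce patient-specific volume biases and their correlations
  collapse, while informative channels remain reliable — reproducing the
  qualitative ordering in which weightings earn their place in a protocol.
  An optional smooth in-plane bias field is off by default.

What the phantom does **not** emulate: MR physics (flow, coil profiles,
partial volume beyond grid discretization), registration error between
channels (channels are generated pre-aligned, as the manual alignment step
produced them), reference-standard uncertainty, and calcium. Passing tests
on the phantom therefore demonstrates the pipeline's correctness and its
qualitative selection behavior, not clinical performance on real images.

On phantom sweeps the volume correlations of good subsets saturate near 1
(the phantom lacks reference-standard noise), so which of several
informative subsets is argmax is decided by a few thousandths of r —
noise at n = 15, where correlation estimates carry wide, overlapping
confidence intervals. The package's checks therefore assert the robust
qualitative pattern (informative subsets outrank weak ones; the curve of
best-r versus subset size rises and then plateaus within 0.05) rather than
the identity of a single winning subset.

## Numerical choices

* **Rasterization.** Even-odd crossing-number rule at pixel centers
  (pixel (i, j) center at ((j − ½)·Δ, (i − ½)·Δ)); boundary points count
  as inside. Verified against an independent point-in-polygon oracle on
  hundreds of random star-shaped polygons.
* **Gaussian derivatives.** Separable correlation with sampled Gaussian
  kernels of radius 4σ, calibrated so constants, ramps and quadratics are
  differentiated exactly (kernel moments normalized); mirror boundary;
  matches dense 2D convolution to <10⁻³ relative error in the interior.
  Scales below half a pixel warn but compute.
* **Sufficient-statistic sweep.** The 511-subset sweep computes the full
  225-column feature matrix once, accumulates per-patient per-class sums
  and scatter matrices, and obtains every fold model of every subset by
  subtraction and column selection; Cholesky factorizations back the
  distance evaluations. This is algebraically identical to the naive
  per-subset fit — asserted in tests — and makes the full sweep run in
  about two minutes on one core at the default problem size
  (15 patients × 5 slices, ~19,000 wall pixels).
* **Determinism.** Cohorts are pure functions of their parameters
  (per-patient seeds derive from the master seed); sweeps are
  deterministic given the cohort and cacheable/resumable per subset.
* **Degenerate inputs.** Contours must be simple with nonzero area; an
  empty wall annulus, a missing channel, a training fold lacking a class,
  zero-variance volume vectors, and non-positive ROI medians all raise
  named errors rather than propagating nonsense.

## Problem sizes used in the checks

The test suite and the acceptance script run the sweep at the reference
cohort size (15 × 5, nine weightings, 511 subsets), a Monte-Carlo check of
the lesion-volume distribution at 1000 patients, and oracle-equivalence
checks at hundreds of small random instances. These sizes make the whole
suite complete in a few minutes on a single core while keeping every
statistical assertion comfortably inside its tolerance.

## Limitations

Real-data use assumes channels already resampled and aligned on a common
isotropic grid with contours in the documented plain-text format; no
registration, bias-field correction or DICOM ingestion is provided.
Anisotropic in-plane grids are rejected. The classifier outputs hard
labels, not posteriors, and class priors are not reweighted despite the
class imbalance (configurable covariance mode aside, this mirrors the
method's design). Exhaustive enumeration is intentional — 511 subsets are
cheap — but the implementation refuses more than 2²⁰ subsets.
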