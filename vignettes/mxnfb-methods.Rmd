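---
title: "Methods: quantifying cell arrangement and strain dynamics in nascent fruiting bodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cell arrangement and strain dynamics in nascent fruiting bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxnfb)
```

## The analysis problem

Starving *Myxococcus xanthus* cells build dome-shaped mounds — nascent
fruiting bodies (NFBs) — in which rod-shaped cells differentiate through a
transitioning-cell (TC) stage into round spores. When a C-signaling-deficient
*csgA* mutant is mixed with wild type (WT), the mutant can be rescued by the
WT's short-range signal and, under some initial mix ratios, can *cheat*:
attain a higher share of spores than its initial share of cells. Deciding
whether that happened, and when, requires counting and classifying
individual labeled cells of each strain in two-channel confocal z-stacks
near the bottom of NFBs, characterizing their radial arrangement, and
putting credible intervals on strain ratios and stage-specific rates.

`mxnfb` implements this pipeline end to end:

1. **Synthetic scenes** with known ground truth stand in for deposited
   confocal data, so every downstream stage is testable at desk scale.
2. **Segmentation**: Hessian-eigenvalue enhancement, Otsu thresholding on
   the center quarter of each image, 3D connected components, and a
   watershed split of touching cells.
3. **Morphology classification**: a three-component Gaussian mixture over
   shape features, mapped to rod / transitioning / spore by mean
   elongation.
4. **Radial statistics**: cell density per 1,000 µm³ with labeled-fraction
   correction, Gaussian-kernel neighbor alignment of rods
   (σ = 2.5 µm), and tangential orientation, as binned radial profiles
   with 90% credible bands.
5. **Population inference**: Gamma–Poisson posteriors for csgA/WT ratios
   and per-6-h-interval sporulation and disappearance rates.

## The synthetic scene generator

The generator defines the study conditions the test suite measures against.
It emulates: two strains at a configurable initial ratio, each with a
labeled fraction (1/2 by default; 1/4 in the early-time-point designs),
three morphological classes, a radially decreasing cell density around the
NFB center, tangential nematic orientation of rods, a 5 µm z-span above the
well bottom, and five-replicate time series in which spores accumulate
monotonically.

Key defaults and why:

* **Field and density.** 80 × 80 × 5 µm at 0.25 µm voxels; the radial
  density declines monotonically from 40 cells/1,000 µm³ at the center to
  7 at the edge. A dome (rather than a flat plateau) reflects the density
  profiles of real NFBs and keeps the radial center identifiable. Densities
  near the center are kept below the hard-core jamming limit for the
  default cell geometry (~45–48 cells/1,000 µm³); configured densities
  above that limit cannot be realized by any placement. The default scene
  carries ≈ 270–300 labeled cells.
* **Geometry.** Rods are spherocylinders 3–6 µm long and 0.4–0.6 µm wide;
  TCs 1.4–1.8 µm long and 0.8–0.95 µm wide; spores spheres of 1.0–1.6 µm
  diameter. Only rod widths are well constrained by observation; TC
  geometry in particular is a placeholder chosen to sit between rods and
  spores in elongation, and should not be treated as a biological claim.
* **Placement.** Cells are placed by rejection sampling against the radial
  density with a hard-core constraint (capsule surfaces at least 0.3 µm
  apart). When a proposed cell conflicts with a neighbor, new
  *orientations* are tried at the same position before the position is
  abandoned; abandoning crowded positions outright would deplete dense
  regions and bias the realized density below its target.
* **Orientation.** Rod and TC axes follow a nematic von Mises distribution
  (on the doubled angle) about the local tangential direction, with an
  optional local-alignment coupling to already-placed neighbors; the
  `tangential_kappa = Inf` limit is exactly tangential and is tested as
  such.
* **Imaging model.** A soft partial-volume capsule indicator, an isotropic
  Gaussian PSF (σ = 0.2 µm), Poisson shot noise, and Gaussian read noise.
  Only labeled cells emit; WT labeled cells appear in the green channel and
  csgA labeled cells in the red channel.

What the generator does **not** emulate: cell motility and tracking, mound
growth mechanics, photobleaching, depth-dependent PSF degradation,
autofluorescence structure, or touching/overlapping cells (the hard core
forbids contact). Passing recovery tests on these scenes therefore
demonstrates correctness of the geometry, statistics, and inference
machinery — not that the segmenter would reach the same accuracy on real
stacks, where cells touch and the PSF is anisotropic.

The fate simulator (`simulate_fates()`) draws per-cell transitions from the
closed-form two-hazard exponential race (`fate_transition_probs()`):
rods/TCs sporulate or disappear with competing per-capita hazards per 6-h
interval; spores are permanent, so trajectories are monotone by
construction, matching how the rate analysis groups rods and TCs.

## Segmentation

* **Enhancement.** The volume is Gaussian-smoothed at `scale` (default
  0.25 µm, about half a rod width) and the response is the magnitude of the
  most-negative eigenvalue of the voxelwise Hessian, clipped at zero —
  high inside bright tubular and blob-like structures, near zero in flat
  background. The closed-form symmetric-3×3 eigenvalue solution keeps this
  fully vectorized.
* **Thresholding.** Otsu's between-class-variance-maximizing threshold is
  computed from a 256-bin histogram of the *center quarter* of each
  xy-plane only (the central rectangle of half the width and half the
  height, pooled over z by default; per-plane thresholds are available).
  The center quarter contains the dense NFB core, so the histogram is
  well-bimodal there and bright clutter near the borders cannot move the
  threshold. The estimator is checked against an exhaustive brute-force
  maximizer in the tests.
* **Components and splitting.** Foreground voxels are grouped by
  26-connectivity (compiled code); components below 0.05 µm³ are dropped.
  Components larger than a single plausible cell are split by a watershed
  on the enhancement response with *prominence merging*: basins whose
  sub-peak rises less than `split_h` above the connecting saddle are
  merged. Measured on synthetic scenes, the valley between two merged cells
  is several times deeper than within-cell fluctuations, and the
  segmentation threshold itself is a natural prominence scale. When no
  response volume is available, a distance-transform watershed with
  erosion markers is used instead; its marker depth must exceed the voxel
  pitch (the distance transform is quantized at one pitch), hence the
  0.3 µm default at 0.25 µm voxels.
* **Features.** Per-cell moments are computed from voxel-center positions
  in physical units, regularized by the voxel second moment (so
  single-voxel cells stay finite and are flagged). Extents use the
  4·√eigenvalue full-width convention; elongation is major/minor extent.
  Voxel indices are 0-based with voxel centers at `(i + 0.5) · pitch`.

## Morphology classification

Features are log volume, **log** elongation, and planarity. Elongation
enters on the log scale because rod elongations (ratios of lengths to
widths) are strongly right-skewed; on the linear scale the rod cluster's
variance dominates the mixture likelihood.

The three-component full-covariance Gaussian mixture is fitted by EM seeded
from a morphology-informed partition: cells are initially split at apparent
elongations 1.35 and 2.5 (the spore and rod class boundaries), and EM
refines from there. This choice was made after observing that unsupervised
maximum-likelihood selection over random or agglomerative restarts
reproducibly prefers spending two components on the broad rod cluster and
merging the small TC class into the spores — a higher-likelihood but
biologically wrong optimum. The informed start is deterministic,
independent of the seed, and keeps EM in the meaningful basin. When a class
is very sparse the unregularized covariance can be singular; the fit then
falls back to the conjugate regularizing prior. Components map to classes
by descending mean elongation (rod > TC > spore); a tie is an error, never
a silent relabeling. Posteriors are evaluated analytically from the stored
model, so a JSON-round-tripped model classifies identically; exact ties
break by the fixed class order rod < transitioning < spore.

## Radial statistics

All statistics use the absolute cosine (nematic convention) because cell
axes are undirected: 1 means parallel (or tangent), 0 orthogonal (or
radial), matching the endpoints of the published definitions.

* **Neighbor alignment**: for rod *i*,
  `a_i = Σ_j w_ij |cos θ_ij| / Σ_j w_ij` over all other rods, with Gaussian
  weights `w_ij = exp(−d_ij²/2σ²)` on 3D centroid distance and σ = 2.5 µm.
  Weights beyond 4σ are truncated (< 10⁻³ of the peak, numerically
  immaterial); rods with no support are excluded and counted. Non-rod
  cells carry no meaningful axis and are excluded throughout.
* **Tangential orientation**: the rod axis is projected to the xy-plane
  and compared with the local circumferential direction; rods at the exact
  center or with near-vertical axes (projection norm < 0.1) are excluded
  with a logged count, rather than given meaningless values.
* **Density** per annular bin is labeled count / (annulus area × z-extent)
  × 1,000, multiplied by the reciprocal labeled fraction (×2 for 1/2, ×4
  for 1/4) to estimate all cells. Bins default to 3 µm from 0 to 60 µm.
* **Credible bands** are 90% equal-tailed posterior intervals: Jeffreys
  Gamma–Poisson draws on bin counts (density), Dirichlet(count + 1/2)
  draws (proportions), or within-replicate Bayesian-bootstrap draws of the
  bin mean (alignment, orientation), pooled across replicates with
  Dirichlet weights. An empty bin leaves the proportion band spanning the
  prior. The plain point estimate is reported alongside, and it — not the
  posterior median — satisfies exact identities such as density summing
  back to the labeled count.

**Center estimation.** The NFB center is the peak of a Gaussian-smoothed
(bandwidth 5 µm) 2D cell-count field, located as the centroid of the
field's excess above 40% of its maximum. The soft level set makes the
estimator stable on flat-topped mounds where a raw argmax wanders within
the plateau. Accuracy is sampling-limited: with the thousands of cells of a
real NFB stack it is sub-micrometer, but at a few hundred labeled cells any
peak estimator carries 2–4 µm of sampling error, which is the tolerance the
test fixtures assert.

## Population inference

Counts of classified cells within 60 µm of the center, per replicate ×
time × location × strain × class, feed two estimators. The posterior
machinery is deliberately simple and conjugate so every interval can be
checked against brute-force Monte Carlo or closed forms.

* **Ratios.** Per replicate, strain counts are modeled as Gamma–Poisson
  rates with the Jeffreys prior (posterior Gamma(count + 1/2, 1)); the
  csgA/WT ratio draws are pooled across replicates by Bayesian bootstrap.
  Reported: posterior median, 90% equal-tailed interval, and the one-sided
  exceedance probability against the initial mix ratio. The package treats
  this exceedance probability as its analogue of a published one-sided
  *P*; the equivalence with any particular publication's machinery is
  assumed, not guaranteed.
* **Rates.** With rods+TCs grouped, sporulation is (S(t₁) − S(t₀))/Δt and
  disappearance (N(t₀) − N(t₁))/Δt with N the total count, so
  disappearance excludes conversion to spores. Per-replicate Jeffreys
  Gamma posteriors on the observed increments are averaged with equal
  weights; sporulation draws are capped at the drawn rods+TCs pool, so no
  posterior draw sporulates more cells than exist. Equal-weight pooling is
  the default because it is *calibrated*: in the package's own simulation
  study (5 replicates, hazards in the simulator's default range), its 90%
  intervals cover the simulator-implied true rates close to 90% of the
  time, whereas adding Dirichlet replicate weights on top of the count
  noise covers ≈ 99% (the same sampling variation counted twice) and the
  bootstrap alone covers ≈ 74% at n = 5. Dirichlet pooling remains
  available for data with real between-replicate heterogeneity.
* **Comparisons.** Location comparisons use ratio-of-ratios posteriors;
  strain rate comparisons use paired draws (shared weights and indices)
  of the mean rate difference over named intervals.

## Numerical and reproducibility choices

* 256 histogram bins for Otsu over the observed response range; ties in
  the between-class variance break to the lowest threshold.
* EM tolerance 10⁻⁸ on the log-likelihood; covariance regularization only
  via the conjugate prior fallback.
* All randomness flows from explicit integer seeds; pipeline stages derive
  their seeds from one master seed, and rerunning a configuration
  reproduces byte-identical outputs (asserted in the tests).
* Inter-stage contracts are versioned CSV/JSON schemas on disk; no stage
  consumes another's in-memory internals.
* TIFF stacks are written as 32-bit float multi-page TIFF with intensities
  rescaled to [0, 1]; the scale factor, voxel sizes, and acquisition
  metadata travel in a JSON sidecar because plain TIFF cannot carry them.

## Problem sizes in the test suite

The suite exercises: a default 80 µm scene (~270–300 labeled cells) for
segmentation/classification recovery; 30–50 µm scenes for module tests; 50
placement-only scenes for density fidelity; 1,000 fate-simulation seeds for
the closed-form check; and 200 simulated five-replicate experiments for
rate-interval calibration. These sizes were chosen so the full suite runs
in a few minutes while keeping Monte-Carlo error well below the asserted
tolerances.

## Known limitations

* The feature set and mixture protocol are this package's choices; they
  are not guaranteed to be identical to any previously published
  segmentation protocol, and TC geometry in the generator is a placeholder.
* The segmenter assumes non-touching cells of near-known width; dense real
  mounds with contacting cells will merge more often than the synthetic
  benchmarks suggest.
* Bands on radial profiles pool replicates; they do not model spatial
  autocorrelation within an NFB.
* `find_center()` accuracy degrades on sparse or flat-topped scenes, as
  quantified above.
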