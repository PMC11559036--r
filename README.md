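# mxnfb

Quantifying cell arrangement and strain dynamics in *Myxococcus xanthus*
nascent fruiting bodies (NFBs) from two-channel confocal z-stacks.

Starving *M. xanthus* rods build mounds that mature into spore-filled
fruiting bodies. When a C-signaling-deficient *csgA* mutant is co-developed
with wild type (WT), the mutant can be rescued — or can *cheat*, taking a
larger share of the spores than its share of the initial mix. Detecting
cheating requires segmenting and classifying individual fluorescently
labeled cells of both strains in 3D, describing their radial arrangement
around the NFB center, and putting credible intervals on strain ratios and
stage-specific rates. `mxnfb` implements that pipeline for microbiologists
and image analysts working on myxobacterial development (or any radially
organized bacterial aggregate), together with a synthetic-scene generator
with known ground truth so that every stage is testable without microscope
data.

## What it computes

* **3D segmentation** — Hessian-eigenvalue enhancement (magnitude of the
  most-negative eigenvalue λ₃ of the intensity Hessian), Otsu threshold
  estimated on the *center quarter* of each image, 26-connected
  components, and a prominence-merging watershed for touching cells.
* **Morphology classes** — a 3-component Gaussian mixture over
  (log V, log elongation, planarity), mapped to rod / transitioning cell
  (TC) / spore by descending mean elongation.
* **Radial statistics** over 0–60 µm from the NFB center:
  * density: labeled cells per 1,000 µm³, multiplied by the reciprocal
    labeled fraction (×2 or ×4);
  * neighbor alignment of rods: aᵢ = Σⱼ wᵢⱼ |cos θᵢⱼ| / Σⱼ wᵢⱼ with
    Gaussian weights wᵢⱼ = exp(−dᵢⱼ²/2σ²), σ = 2.5 µm
    (1 = parallel, 0 = orthogonal);
  * tangential orientation: |cos φ| between a rod's in-plane axis and the
    local circumferential direction (1 = tangent, 0 = radial);
  each as a binned profile with a 90% credible band.
* **Population inference** — Jeffreys Gamma–Poisson posteriors for
  csgA/WT count ratios (median, 90% equal-tailed interval, one-sided
  exceedance probability against the initial mix ratio) and per-6-h-interval
  sporulation and disappearance rates with rods+TCs grouped.

See `vignettes/mxnfb-methods.Rmd` for the model details, assumptions, and
design choices.

## Worked example

Generate a synthetic NFB scene, segment both channels, classify, and
estimate the strain ratio:

```r
library(mxnfb)

scene <- generate_scene(scene_config(seed = 7))
cells <- rbind(segment_stack(scene$stacks$green),
               segment_stack(scene$stacks$red))
cells$strain <- ifelse(cells$channel == "green", "WT", "csgA")

model <- fit_morphology_model(extract_features(cells), k = 3, seed = 7)
model
#> <morphology_model> k = 3, n = 282, logLik = 351.26
#> components: spore (w = 0.38), transitioning (w = 0.09), rod (w = 0.54)
cells <- classify_cells(cells, model)
table(cells$class)
#>           rod         spore transitioning
#>           151           107            24

center <- find_center(cells)
round(center, 1)
#>    x    y
#> 40.0 39.7

al <- neighbor_alignment(cells, sigma = 2.5)
radial_profile(al, "alignment", center, bins = seq(0, 30, 10), seed = 7)
#>   bin_mid n_cells estimate  lo90  hi90
#> 1       5      18    0.862 0.821 0.895
#> 2      15      35    0.894 0.867 0.915
#> 3      25      42    0.938 0.923 0.950

counts <- count_cells(cells, center, radius = 60)
by_strain <- tapply(counts$count, counts$strain, sum)
ratio_posterior(by_strain[["csgA"]], by_strain[["WT"]],
                initial_ratio = 1, seed = 7)
#> <ratio_estimate> csgA/WT median 0.946 [90% CI 0.777, 1.15]; Pr(ratio <= 1) = 0.6759
```

Reading the output: 282 labeled cells were segmented from the two channels
and split into 151 rods, 24 TCs, and 107 spores; the estimated NFB center
(40.0, 39.7) µm is within a micrometer of the scene's configured center;
rods are strongly aligned with their neighbors (alignment 0.86–0.94 across
the first 30 µm, 1 being perfectly parallel); and the csgA/WT ratio of all
cells within 60 µm is statistically indistinguishable from the 1:1 mix the
scene was built with (interval spans 1, exceedance probability far from 0
or 1) — this scene models rescue, not cheating.

`run_pipeline()` (or the `inst/cli/nfb` script) chains these stages over
replicates and time points, writing versioned CSV/JSON outputs and a
manifest with checksums; reruns with the same configuration and master
seed are byte-identical.

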