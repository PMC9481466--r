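---
title: "Models and methods behind ldscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ldscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldscreen)
```

## The measurement

Many endoplasmic-reticulum (ER) membrane proteins relocate to the surface of
lipid droplets (LDs), some during droplet formation and some only on mature
droplets. Genome-scale RNAi imaging screens probe which genes this late
targeting step requires: cells stably expressing a fluorescently tagged
cargo (e.g. eGFP–GPAT4) are arrayed in 384-well plates (one dsRNA per well,
in duplicate), and each well is imaged in several fields across three
channels — the tagged protein, a nuclear stain, and a neutral-lipid stain.

The per-cell readout is the **LD targeting ratio**

$$ R_{\text{cell}} \;=\;
   \frac{\operatorname{mean}(I_{\text{protein}} \mid \text{LD mask} \cap \text{cell})}
        {\operatorname{mean}(I_{\text{protein}} \mid \text{cell} \setminus \text{LD mask})} , $$

computed on the autofluorescence-corrected protein channel. The well readout
$X_i$ is the median of $R_{\text{cell}}$ over all cells of all fields of the
well; knockdowns are compared through the robust Z-score

$$ Z_i = \frac{X_i - \operatorname{median}(X)}
              {1.4826 \times \operatorname{MAD}(X)},
   \qquad \operatorname{MAD}(X) = \operatorname{median}\left(\lvert X_i -
   \operatorname{median}(X)\rvert\right). $$

The package bundles the constants of the original genome-scale screen
(median 2.147287, MAD 0.113917) as the defaults of `screen_constants()`;
`score_screen()` can instead estimate both from the current run's library
wells (controls excluded, replicates pooled — per-replicate estimation is
available via `pool_replicates = FALSE`).

Hits are knockdowns with $Z < -2.5$ or $Z > +2.5$ (strict inequalities),
demoted to non-hits when the knockdown caused significant cell death
(cell-count robust Z below −2.5), extremely small LDs (relative-LD-area
robust Z below −2.5 by default — the threshold behind "extremely small" is
not standardized, so it is a parameter), or the gene belongs to an excluded
category (ribosomal, proteasomal, spliceosomal). Cell-count and LD-area
Z-scores use their own median/MAD over library wells. Demoted results keep
their Z-scores, so filtering is auditable. Where a gene is covered by
several dsRNAs, `gene_calls()` reports the reagent with the largest
$\lvert Z\rvert$, matching libraries that target genes one to two times.

## The analysis pipeline

Segmentation follows the screen's design: three random-forest pixel
classifiers (one per compartment; nuclei and cells from the nuclear-stain
channel, LDs from the LD-stain channel), each trained on a handful of
annotated images (seven by default). Features are a fixed filter bank (raw
intensity, Gaussians at scales 1/2/4 px, differences of Gaussians, gradient
magnitude, Laplacian); forests use 100 trees, class-balanced pixel sampling
and a fixed seed, and store their out-of-bag accuracy as the held-out
estimate. The original feature set and forest hyper-parameters are not
published; these are conventional choices, and all are configurable.

Cells are obtained by marker-seeded watershed: nuclei (8-connected
components of the nucleus mask, minimum area 50 px) seed a flood of the
inverted, smoothed cell-probability relief restricted to the cell
foreground, so every nucleus yields exactly one cell region carrying its
nucleus label, and foreground unreachable from any seed stays background.
LD components below 4 px are discarded; each LD is assigned to the cell
with the largest intersection area (ties to the smaller label), and
unassigned LDs are excluded. Cells touching the image border are flagged
but kept by default. Connectivity conventions are fixed once: 8-connected
components in 2D, 26-connected in 3D.

Per-cell ratios are undefined when a cell has no assigned LD pixels or a
non-positive outside mean; such cells still count toward the cell-death
filter but not toward $X_i$. The screen-style ratio uses the LD mask as-is;
the confocal variant (`confocal_targeting_ratio()`) follows the distinct
manual-outline protocol — Otsu threshold of the LD stain inside the drawn
outline, then one binary dilation with a 3×3 square element to include LD
surfaces (a cross-shaped element is available), with optional nuclear
exclusion for nucleoplasm-rich markers such as CCT1. Otsu and Huang
thresholds are computed on 256-bin histograms of in-ROI values with bin
edges at the in-ROI min/max; Huang's fuzzy-entropy method is implemented
from the histogram as in common image-analysis tools.

For 3D data, `segment_objects_3d()` labels 26-connected components after
per-slice background subtraction and a radius-1 median filter (the
published protocol names the steps but not the radii), keeping objects
strictly larger than 30 voxels. ERES–LD association is object-based: an
ERES counts as associated when its voxel set overlaps an LD ("zero closest
distance"). Boundary adjacency without overlap yields a distance of one
voxel, not zero — a potential divergence from plugin behaviour that the
`adjacency_counts_as_zero` flag exposes. Distances are minimum
boundary-to-boundary Euclidean distances using the anisotropic voxel
dimensions (0.3 µm z-step, 0.065 µm xy by default); a voxel-space mode
exists for parity testing, since the original analysis does not state its
anisotropy handling.

## The synthetic-data generator

Every stage is testable without external data because the generator
produces inputs with known ground truth at three levels.

**Plate layouts.** `generate_screen_layout()` reproduces the arrayed-library
geometry: 384-well plates, duplicate replicates with identical gene
placement, randomized library positions, and per-plate controls (8 LacZ
negative-control wells, one decrease and one increase positive-control
well, and 2 autofluorescence wells — control counts are a package choice
consistent with per-plate control totals of the original design). The
genome-scale configuration (66 plates × 384 wells × 2 replicates) yields
exactly 50,688 well records.

**Field images.** `simulate_field()` renders cells as smooth perturbed
disks (low-order radial harmonics), nuclei as interior disks, LDs as
distinct disks with a minimum 2-px edge gap — droplets are resolvable
puncta; without the gap, touching droplets merge under 8-connectivity and
object counts become meaningless. The protein channel is constructed so
that the ratio measured on the ground-truth masks equals each cell's true
ratio *exactly* before optics and noise: the reticular pool is uniform
across the cell and only the $(r-1)$ targeted excess is rim-weighted
(monolayer-surface localization), so non-targeted cells ($r = 1$) are
uniform. The nuclear-stain channel carries a weak cytoplasmic component
(`cell_marker_level`, 600 vs 3000 in-nucleus units) because the screen
segments *cells* from that channel, which requires cell-body signal.
Acquisition is Gaussian PSF blur, then Poisson shot noise on the scaled
signal plus additive Gaussian read noise (no camera model is published;
this is the standard Poisson–Gaussian approximation), plus a constant
additive autofluorescence offset on the protein channel; wells designated
`autofluorescence_control` express no protein and calibrate the per-plate
correction, with a configured fallback constant when a plate has no such
wells.

The default PSF (σ = 0.3 px) is deliberately sub-pixel. With 3–5 px
droplets, a realistic confocal PSF (σ ≈ 1–1.6 px at 0.065 µm pixels)
removes 13–40% of the LD-mask flux, so pixel-level ground-truth masks would
no longer be a valid oracle for the constructed ratio. Optical realism is
an explicit non-goal of the generator; the consequence — real images yield
systematically *lower* ratios than the idealized construction — is exactly
why passing tests here demonstrate correctness of the measurement code, not
accuracy of ratios on real microscopes. Other unmodelled features of real
data: aberrations, bleaching, stage drift, uneven illumination, 3D cell
shape, debris, and cell–cell contact geometry.

**Well-level screens.** Rendering 66 × 384 × 2 wells of images is not a
desk-scale exercise, so `simulate_screen_wells()` draws the well table
directly: $X_{ir} = r_g (1 + b_i + e_{ir})$ with a replicate-shared
position effect $b_i$ and independent within-replicate noise $e_{ir}$. The
default total relative sd is taken from the published screen's dispersion
($1.4826 \times 0.113917 / 2.147287 \approx 7.9\%$) and the shared-variance
fraction set to the published replicate correlation 0.7645, so by the
variance-ratio identity $r = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ the
simulated screen reproduces both the MAD and the replicate concordance of
the original by construction. Cell counts are Poisson around 160 per well
(20 cells × 8 fields) scaled by the knockdown's multiplier.

**Volumes.** `simulate_volume()` places LD spheres and ERES puncta at
requested boundary distances (voxel units), certifying each placement with
an exhaustive boundary-distance computation and accepting within half a
voxel; distance 0 is realized by centring the ERES on an LD boundary voxel
so the voxel sets genuinely overlap. ERES are kept non-adjacent to each
other so they remain distinct 26-connected objects.

## Numerical choices and degenerate inputs

* Determinism: every simulation accepts a seed; per-field seeds derive from
  (plate, well, field, master seed) via a stable 31-bit string hash, so any
  field regenerates in isolation and nothing depends on global RNG state or
  evaluation order. The caller's RNG state is restored after every call.
* Medians are the standard sample median (mean of central pair for even
  counts). `mad_raw()` is unscaled; the 1.4826 consistency constant enters
  only in the Z-score.
* A zero MAD (all readouts identical) is a degenerate screen and errors
  rather than returning infinities; all-undefined readouts likewise.
* Foreground classification thresholds at probability ≥ 0.5 by default;
  threshold 0 marks everything foreground.
* Otsu on constant input is an error; an empty post-threshold mask yields an
  `NA` ratio flag rather than an error.
* Image intensities are nonnegative camera units bounded by the 16-bit
  range; images and label masks are written as 16-bit TIFF with a JSON
  sidecar for pixel size.
* Coordinates are (z,) y, x with pixel centres at integer positions.

## Problem sizes used by the tests

The suite and the acceptance script run entirely on simulated data at desk
scale, the package's own choice of problem size: 160 × 160 px fields with 5
cells per field and 6 LDs per cell for image-based checks (20 wells × 2
fields per condition for ratio recovery across true ratios 1–10), seven
96–160 px annotated fields per classifier, one- and two-plate 384-well
layouts for hit-recovery and concordance checks, 5,000-well null screens
for Z calibration, and 64–72 px³ volumes for the 3D association oracle.
Layout arithmetic runs at the full 66-plate genome scale, which is cheap.
All empirical numbers quoted in the README are produced by those runs.

## Known limitations

* The pixel classifiers are trained and evaluated on the same generative
  model; their accuracies say nothing about transfer to real micrographs.
* The screen-level generative model is exchangeable across wells — no plate
  edge effects, dispensing gradients, or batch drift.
* The small-LD exclusion threshold is an operational choice (LD-area
  Z < −2.5); the original's numeric criterion is unpublished.
* Whether the original pipeline dilated the LD mask for the screen ratio is
  unstated; this package does not dilate in the screen path and does in the
  confocal path, with a flag to harmonize.
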