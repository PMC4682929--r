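---
title: "SUV resampling and the meaning of PET texture indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SUV resampling and the meaning of PET texture indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pettex)
```

## The problem

Texture indices (TI) summarize the spatial arrangement of FDG uptake inside
a tumor volume of interest (VOI) and are widely used as heterogeneity
biomarkers in PET radiomics. Every TI pipeline starts by discretizing the
continuous standardized uptake values (SUV) into a small number of gray
levels, and this step is not innocent. The customary scheme rescales each
VOI between its own minimum and maximum:

$$R_1(x) = \mathrm{round}\!\left(D\,\frac{I(x) - \mathrm{SUV}_{min}}
{\mathrm{SUV}_{max} - \mathrm{SUV}_{min}}\right),$$

with $D$ typically 64. We call this *relative resampling* (RR). Because the
bounds travel with the VOI, RR discards the absolute SUV scale: any VOI is
stretched over the full level range, however narrow its true uptake spread.
Two consequences follow. First, RR-based TI become strongly
volume-dependent for small regions — in a uniform object they trace out a
rising curve that only flattens beyond roughly a thousand voxels, so for
most clinical lesions the "heterogeneity" they measure is mostly size.
Second, RR erases exactly the information (the SUV dynamic range of the
lesion) that plausibly carries heterogeneity signal.

The alternative implemented here, *absolute resampling* (AR), fixes the
bounds once for all VOIs:

$$R_2(x) = \mathrm{round}\!\left(D\,\frac{\mathrm{clip}(I(x))
 - low}{high - low}\right),$$

with defaults $low = 0$, $high = 20$ SUV (the typical clinical range of
tumor SUV; presets with $high$ 15 and 25 probe the robustness of that
arbitrary choice). The bin width at the defaults is $20/64 = 0.3125$ SUV.
Discretizing with a fixed bin width $w$ and $D$ levels is the same map as
AR with $high = wD$ (a 0.5 SUV bin width with 64 levels is AR to 32 SUV),
so fixed-bin-width schemes are provided as an alias rather than a third
method.

Both maps use half-up rounding — relying on the platform default (banker's
rounding) would silently change matrices for values landing exactly on a
half bin. Raw rounding yields level 0, which would make the $1/i^2$ weight
of low gray-level emphasis undefined; both maps therefore shift levels by
+1, occupying $1..D{+}1$. A constant VOI maps to level 1 under RR — an
arbitrary but fixed convention that matters only for gray-level-weighted
indices on degenerate input. AR values outside the bounds are clipped to
the boundary levels and the clipped-voxel count is reported rather than
hidden.

## Texture matrices and indices

From the discretized VOI three classical matrices are built:

* the **co-occurrence matrix** (CM), accumulated symmetrically (both pair
  orderings) per displacement direction, at a distance of one voxel;
* the **gray-level run-length matrix** (GRLM), counting maximal collinear
  same-level runs per direction;
* the **gray-level zone-length matrix** (GZLM, size-zone matrix), counting
  3D connected components of equal level, computed once (no directions).

Directional matrices use the 13 sign-free displacement vectors with
components in $\{-1, 0, 1\}$, and each directional index is the unweighted
mean over directions. Directions with no valid voxel pair in a thin VOI are
*excluded* from the average rather than contributing zeros: a missing
direction is undefined, not homogeneous. Because the direction set is
closed under the 48 axis symmetries of the lattice, the averaged indices
are invariant under rotations and reflections of the volume (this is
verified by a property test).

Seven indices are reported per VOI, one per family of strongly correlated
candidates — homogeneity and entropy from the CM; short-run emphasis (SRE),
long-run emphasis (LRE) and run-length non-uniformity (RLNU) from the GRLM;
low and high gray-level zone emphasis (LGZE, HGZE) from the GZLM — plus the
CM contrast index, SUVmax and metabolic volume (MV). Entropy uses base-2
logarithms by default; the base only rescales entropy and leaves every
rank-based statistic untouched, so it is exposed as a parameter rather than
debated. Matrix extents equal the maximum level actually present: all
implemented indices are sums over occupied cells, so trailing empty rows
and columns are irrelevant. Zones use 26-connectivity, the 3D standard for
size-zone analysis (6-connectivity is available for sensitivity checks).

The entire engine is validated against independent brute-force enumerators
(explicit pair listing, line walking, flood fill) on hundreds of random
masked lattices to $10^{-12}$.

## Volumes of interest

Three VOI kinds mirror the study design:

* **Spheres** for the phantom, centered on a voxel, odd diameters 3–17
  voxels. A voxel belongs to the sphere when its center lies within
  $(d-1)/2$ voxel units of the center, so the sphere spans exactly $d$
  voxels across and diameter 3 gives the 7-voxel cross.
* **Adaptive-threshold segmentation** for tumors. The cited clinical
  pipeline uses a contrast-oriented adaptive threshold without printing
  its formula; we implement the Nestle-style rule
  $T = \beta\,\bar{I}_{70} + I_{bg}$, where $\bar{I}_{70}$ is the mean SUV
  of voxels above 70% of the local maximum and $I_{bg}$ a background
  estimate from a shell outside the search box, with $\beta = 0.3$ by
  default and a fixed-fraction-of-maximum fallback. The segmentation is the
  26-connected component containing the seed, the seed being snapped to the
  hottest voxel of the search box so that a click anywhere in a lesion —
  including inside a photopenic necrotic core — grows the same region. All
  segmentation parameters travel with the mask into the feature tables,
  because downstream results must record which segmentation produced them.
* **Relocation**: the tumor mask translated rigidly (integer voxels, no
  interpolation) into the liver, preserving voxel count and internal
  geometry exactly, so that tumor and reference-tissue indices are compared
  at identical VOI shape and size.

## What the simulators emulate — and what they do not

No patient data accompany this package; the study conditions are emulated
by two generators. Both produce *reconstructed-image statistics*, not
reconstructions: noise is modeled directly in image space, and no sinogram,
scatter or attenuation physics is involved.

**Uniform phantom.** A 20 cm high, 16 cm diameter FDG-filled cylinder on a
4 mm isotropic grid, mean SUV 3 inside, zero outside. Texture comes only
from noise: Gaussian white noise (15% of the mean) convolved with a 7 mm
FWHM Gaussian point-spread function and renormalized, giving the spatially
correlated field characteristic of reconstructed PET (lag-1 autocorrelation
well above 0.3). The phantom SUV level is arbitrary — a phantom has no body
weight — and is set so that AR20 occupies about ten of 64 bins, away from
clipping. The signal-to-noise difference between phantom and patient
acquisitions is absorbed entirely into the noise fraction, not modeled via
acquisition time.

**Synthetic NSCLC cohort.** Each patient volume (56³ voxels at 4 mm)
contains a low-uptake body background, a liver reference block, and one
tumor: a sigmoid-edged ball whose SUV rises to a subtype-drawn peak
(adenocarcinoma-like 4–10, squamous-like 6–16), with radius 10–24 mm and
11–26 mm respectively. With probability 0.7 a squamous tumor carries a
central necrotic core at 25% of its peak (radius 35% of the tumor radius) —
encoding the histological observation that necrosis concentrates in the
squamous subtype, which is the mechanism by which squamous heterogeneity
exceeds adenocarcinoma heterogeneity. Injection-to-scan delays follow a
truncated normal (75 ± 9 min within [60, 90]) and the exclusion filters
(delay window, 2.5 mL minimum segmented MV) are applied exactly as in the
clinical flow chart.

Three generator choices deserve explanation because they control what the
cohort can and cannot show:

* **Noise model.** All tissues share a multiplicative noise field at 10%
  relative amplitude, mixed from a PSF-correlated component and a
  voxelwise-uncorrelated component (mixing weight 0.6 on the white part).
  Iterative reconstruction leaves part of the voxel noise uncorrelated, and
  this fine-scale component dominates the neighbor-level transitions that
  min–max resampled indices see.
* **Liver texture.** Real liver is not a flat field: vasculature, lobular
  inhomogeneity and partial-volume effects give it smooth internal
  gradients. The liver block therefore carries a parenchymal variation
  field spanning evenly from 50% to 100% of the liver mean (a correlated
  Gaussian field pushed through its own CDF, so the stated range is filled
  uniformly, with 12 mm correlation length). Without it, a min–max
  resampled liver VOI is a pure noise patch whose gray-level histogram is
  Gaussian-bunched, and RR entropy would artificially separate liver from
  tumors — whose threshold-bounded edge gradient fills levels almost
  uniformly. With it, relative-resampled entropy is tissue-nonspecific, as
  observed in vivo; this calibration (together with the 1.2 mm tumor edge
  width) was fixed once at design time and is the package's statement of
  the study conditions, not a per-analysis dial.
* **Effect sizes.** Subtype contrasts (peak ranges, core probability and
  depth, radius ranges) are free parameters chosen so that the
  absolute-resampled indices separate the 28 + 13 subtype groups at the
  conventional 5% level while relative-resampled entropy does not — the
  qualitative contrast the cohort exists to demonstrate. They are defaults,
  not estimates of biology.

What passing cohort tests do **not** show: that AR-based TI separate real
histological subtypes at any particular power, that the specific p-values
have clinical meaning, or that the generator's tissue model is anatomically
faithful. The synthetic cohort demonstrates the *mechanism* — absolute
resampling preserves SUV-scale information that min–max resampling
destroys, and inherits far less volume dependence — under controlled,
reproducible conditions.

## The statistical layer

Volume and SUV dependence are profiled with Spearman rank correlations
(average-rank ties); tumor profiles are restricted to VOIs below 60 mL,
the regime where volume dependence matters clinically. A zero-variance
index yields $r = 0$ with a degeneracy flag instead of an error, so
profile tables always render. Tissue comparisons use the Wilcoxon
signed-rank test (tumor and relocated-liver VOIs are paired within
patient and share their geometry); subtype comparisons use the rank-sum
test. Exact p-values are computed for group sizes up to 25 and the normal
approximation with continuity correction beyond; both implementations are
checked against exact enumeration of sign and group assignments for small
samples. No multiple-testing correction is applied to the headline tables,
mirroring common practice in this literature, but a Holm-adjusted column is
emitted alongside every p-value column since the raw tables test eight
indices under four resampling schemes simultaneously.

A texture index is declared to have *plateaued* with volume when the change
of its per-diameter mean between the two largest sphere sizes is below 5%
of the full range of its means — a deliberately simple operational
criterion for "no longer volume-driven".

## Problem sizes and runtime

The default experiments are sized for a desk machine: phantom spheres of
diameter 3–17 voxels at 5 positions (80 extractions, about a second), and
a 41-patient cohort at 56³ voxels per patient (two VOIs × four resampling
schemes each, under ten seconds). All generators are bit-reproducible
given their seed.

## Known limitations

* The simulators model image statistics, not scanner physics; absolute
  noise levels are plausible rather than matched to any device.
* The adaptive threshold is a reconstruction of a rule the source pipeline
  only cites; segmented volumes therefore carry that modeling choice, which
  is why it is recorded in provenance.
* Anisotropic voxels are supported in metabolic volume and I/O but texture
  distances are expressed in voxel units, as is conventional for these
  matrices; strongly anisotropic grids would need resampling first.
* The logistic-regression combination of RR indices with SUVmax, histology
  association tables and any survival analysis are out of scope.

## A minimal session

```{r example, eval = FALSE}
ph <- simulate_phantom(phantom_spec(seed = 1))
ctr <- phantom_sphere_centers()
mask <- sphere_voi(ph, ctr[1, ], 9)
extract_ti(ph, mask, resampling_preset("rr"))
extract_ti(ph, mask, resampling_preset("ar20"))

pe <- run_phantom_experiment()
subset(pe$correlations, index == "rlnu")

ce <- run_cohort_experiment()
subset(ce$tumor_vs_liver, index == "entropy",
       select = c(method, p_value, median_tumor, median_liver))
```
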