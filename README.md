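# pettex — texture indices for PET volumes under relative and absolute SUV resampling

`pettex` is an R toolkit for heterogeneity texture analysis of 3D
<sup>18</sup>F-FDG PET volumes, built around one methodological question:
**how should standardized uptake values (SUV) be discretized before texture
matrices are computed?** The answer changes what the resulting indices
measure.

Texture indices (TI) are computed from gray-level matrices — the
co-occurrence matrix (homogeneity, entropy, contrast), the run-length
matrix (SRE, LRE, RLNU) and the size-zone matrix (LGZE, HGZE) — after the
SUV inside a volume of interest (VOI) are discretized to *D* = 64 levels.
Two discretizations are supported:

* **Relative resampling (RR)** — the usual min–max scheme,
  `R1(x) = round(D · (I(x) − SUVmin) / (SUVmax − SUVmin))`,
  rescaling every VOI between its own extremes. RR discards the absolute
  SUV scale; RR-based TI are strongly correlated with region volume for
  small VOIs and nearly independent of uptake.
* **Absolute resampling (AR)** — fixed bounds shared by all VOIs,
  `R2(x) = round(D · clip(I(x)) / 20)` at the default 0–20 SUV bounds
  (presets AR15/AR20/AR25; bin width 20/64 ≈ 0.3 SUV). AR preserves the
  SUV dynamic range in the levels; AR-based TI are far less volume-bound
  and track tissue identity instead.

The package implements the full pipeline — activity→SUV conversion, NIfTI-1
I/O, sphere / adaptive-threshold / relocated VOIs, both resampling schemes,
the three matrices in 13 directions with their seven indices plus contrast,
SUVmax and metabolic volume — together with two reproducible synthetic
test-beds (a uniform FDG cylinder phantom with spatially correlated noise,
and a two-subtype lung-tumor cohort with liver reference regions) and the
statistical layer that characterizes both schemes (Spearman volume/SUV
profiles, paired and unpaired Wilcoxon comparisons).

## Worked example

Simulate the uniform phantom, draw a 9-voxel-diameter sphere at its center,
and extract the texture vector under both schemes:

```r
library(pettex)
ph   <- simulate_phantom(phantom_spec(seed = 1))
mask <- sphere_voi(ph, phantom_sphere_centers()[1, ], 9)
extract_ti(ph, mask, resampling_preset("rr"))
#> <ti_vector> RR (D = 64), 257 voxels, MV = 16.448 mL, SUVmax = 3.825
#> homogeneity     entropy    contrast         sre         lre        rlnu
#>      0.1473      8.3730    259.0269      0.9869      1.0539    243.9629
#>        lgze        hgze
#>      0.0066   1596.4951
extract_ti(ph, mask, resampling_preset("ar20"))
#> <ti_vector> AR20 (D = 64), 257 voxels, MV = 16.448 mL, SUVmax = 3.825
#> homogeneity     entropy    contrast         sre         lre        rlnu
#>      0.5387      4.9407      3.0266      0.8626      1.7321    149.7965
#>        lgze        hgze
#>      0.0116    101.9667
```

The phantom is uniform, so all of this "texture" is reconstruction-like
noise. Min–max resampling stretches that noise over all 64 levels (entropy
8.4, homogeneity 0.15); absolute resampling keeps the sphere within the
few levels its true SUV range occupies (entropy 4.9, homogeneity 0.54).

The phantom experiment quantifies the volume dependence across sphere
diameters 3–17 voxels at five positions: run-length non-uniformity grows
strictly with voxel count under both schemes (Spearman r = 1 — it is a
size measure, not a texture measure), while homogeneity, entropy, SRE and
LRE plateau with volume under RR:

```r
pe <- run_phantom_experiment()
subset(pe$correlations, index == "rlnu")
#>  method index r n degenerate
#>    AR20  rlnu 1 8      FALSE
#>      RR  rlnu 1 8      FALSE
```

The synthetic cohort (28 adenocarcinoma-like + 13 squamous-like patients,
tumor VOIs segmented by adaptive threshold and relocated into the liver)
shows the discrimination contrast between the schemes — paired
tumor-vs-liver entropy:

```r
ce <- run_cohort_experiment()
subset(ce$tumor_vs_liver, index == "entropy",
       select = c(method, p_value, median_tumor, median_liver))
#>  method   p_value median_tumor median_liver
#>    AR15 2.517e-08        7.596        4.795
#>    AR20 2.517e-08        7.267        4.043
#>    AR25 2.517e-08        6.779        3.473
#>      RR 8.662e-01        8.919        8.892
```

Absolute resampling separates tumor from healthy tissue at any of the
three high bounds; min–max resampling cannot (p = 0.87), because both
tissues are rescaled onto the same level range. The same contrast holds
between subtypes (unpaired, homogeneity and entropy: AR20 p ≈ 4–6 × 10⁻⁵,
RR p = 0.65 and 0.25), and the direction of every AR20 median difference
matches the expected tissue pattern (tumors: lower homogeneity/LRE/LGZE,
higher entropy/SRE/RLNU/HGZE).

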