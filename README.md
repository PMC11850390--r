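# palatelev

Quantitative analysis of murine palatal shelf (PS) elevation.

During palatogenesis the palatal shelves grow vertically beside the tongue
and then remodel to a horizontal position above it in a remarkably short
developmental window. `palatelev` implements the two quantitative arms of a
time-resolved study of this process in mouse embryos, for developmental
biologists who stage embryo cohorts and quantify immunofluorescent PS
sections:

1. **Staging analytics.** Embryos from time-restricted matings are scored
   into three stages — bilaterally unelevated, unilaterally elevated,
   bilaterally elevated. The package tabulates stages per strain × age
   (× sex) stratum, reports integer percentages (half-away-from-zero, the
   reporting convention), estimates the elevation window per strain,
   contrasts the sexes with a two-sided Fisher exact test, and tests
   left/right side preference of unilateral elevation with an exact
   binomial test.
2. **Section quantification.** Two-channel confocal sections (DAPI +
   KI-67 or p-MLC) with a hinge/lingual/buccal/epithelium label mask are
   segmented (Gaussian smoothing → Otsu → distance-transform watershed);
   each nucleus gets a centroid, area, axial angle θ ∈ [0°, 180°) from
   second central moments, aspect ratio and marker intensity. From these
   the package computes the axial circular statistics behind the wedge
   diagrams — axial mean ½·atan2(⟨sin 2θ⟩, ⟨cos 2θ⟩), axial SD
   ½·√(−2 ln R₂) — and the 2D nematic order parameter
   **S = ⟨cos 2(θ − θ̄)⟩ ∈ [0, 1]** in both a region-global and a
   neighborhood-local variant, plus regional deviation-from-mean metrics
   (KI-67 positive fraction per nucleus; p-MLC mean intensity per pixel)
   compared across sections with two-tailed Welch t-tests.

Because no raw images are distributed with the study, the package ships a
synthetic-data generator: staged cohorts from designed multinomials, and
section images with elliptical nuclei whose axial orientations follow
doubled-angle von Mises distributions per region (expected
S = I₁(κ)/I₀(κ)), rendered with a Gaussian PSF and additive noise, with
full ground truth. Every stage of the pipeline has a parameter-recovery
test against this generator.

## Worked example

Staging analytics on the bundled reference tallies (time-restricted
C57BL/6J and FVB/NJ cohorts):

```r
library(palatelev)
tab <- reference_stage_table()
pct <- stage_percentages(tab)
subset(pct, sex == "all", c(strain, age_days, pct_unelevated, pct_elevated))
#>      strain age_days pct_unelevated pct_elevated
#> 1  C57BL/6J   14.000             97            3
#> 2  C57BL/6J   14.125             69           25
#> 3  C57BL/6J   14.250              9           80
#> 8    FVB/NJ   13.875            100            0
#> 9    FVB/NJ   14.000             66           17
#> 10   FVB/NJ   14.250             NA           75

elevation_window(tab, "C57BL/6J")$window_hours   # 6  (E14.0 -> E14.25)
elevation_window(tab, "FVB/NJ")$window_hours     # 9  (E13.875 -> E14.25)

sex_contrast(tab, "C57BL/6J", 14.25)$p_value     # 7.975602e-05
```

So 97% of C57BL/6J embryos are still unelevated at E14.0 and 80% have
completed elevation 6 h later; at E14.25 every non-elevated embryo is
female (Fisher p < 1e-4).

A full image round trip on synthetic data:

```r
sec <- simulate_section(section_spec(seed = 7))          # 74 nuclei + truth
labs <- segment_nuclei(sec$nuclear, sec$pixel_size_um)
nuc  <- nucleus_features(labs, sec$marker, sec$pixel_size_um)
nuc  <- classify_positive(assign_regions(nuc, sec$mask, sec$pixel_size_um))
match_to_truth(nuc, sec$truth)$f1                        # 1.0
orientation_summary(nuc)
#>    region n_used mean_angle_deg axial_sd_deg  S_global S_local_mean  tilt_deg
#> 1  buccal     22       93.31604     12.80909 0.9048746    0.8439366 -3.316037
#> 2   hinge     39       59.00154     22.33932 0.7378345    0.7310555 30.998462
#> 3 lingual     13       73.84609     25.89180 0.6646984    0.6743907 16.153907
```

The hinge region (generated at μ = 60°, κ = 2) is recovered tilted ~31°
toward the tongue with the lowest orientational order, the buccal region
(κ = 6) is near-vertical and highly ordered — the qualitative pattern the
wedge diagrams report.

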