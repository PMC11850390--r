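---
title: "Methods: staging statistics and section quantification in palatelev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging statistics and section quantification in palatelev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palatelev)
```

`palatelev` quantifies palatal shelf (PS) elevation in mouse embryos along
two independent tracks: categorical staging statistics over embryo
cohorts, and image-based quantification of coronal PS sections. This
vignette is the package's account of the underlying models, the parameter
choices that matter, and the limits of what its tests demonstrate.

## Staging model

Each embryo is a categorical observation: strain, sex, embryonic age at
1/24-day resolution (E14.125 = E14.0 + 3 h), and one of three elevation
stages — bilaterally unelevated, unilaterally elevated, bilaterally
elevated — with a left/right side recorded only for unilateral embryos.
Strata (strain × age, optionally × sex) are treated as independent
multinomials; litter membership is recorded but not modelled, since
cohorts pool embryos across litters. `tabulate_stages()` partitions
records exactly (empty strata are omitted, so totals always conserve the
input), and `stage_percentages()` reports both raw fractions and integer
percentages.

**Rounding.** Integer percentages use half-away-from-zero rounding
(`100 × 37/38 → 97`), the convention of printed staging reports; base R's
round-half-to-even would disagree on exact halves. Pre-rounding fractions
sum to one exactly; rounded percentages sum to 100 ± 1.

**Sex contrasts.** A stratum's 2×2 table (sex × stage group) is tested
with the package's two-sided Fisher exact test. The default grouping is
*elevated vs rest* — embryos that completed elevation against all others —
because "completed elevation" is the phenotype of interest at the late
timepoints; *unelevated vs rest* (initiation rather than completion) is
exposed as an option and is the right grouping at early timepoints. Both
groupings are emitted by the pipeline so the choice is visible.

**Elevation window.** The window of a strain runs between sampled ages
only; nothing is interpolated, because staging data exist only at the
sampled timepoints. The start is the latest sampled age at which the
cohort is still essentially all unelevated, operationalised as a rounded
unelevated percentage ≥ 95. A strict "all embryos unelevated" rule would
let a single early outlier (one precocious embryo in 38) erase the window
start, which contradicts how such windows are read in practice. The
completion age is the earliest sampled age whose rounded elevated
percentage reaches the threshold (default 75%). Applying thresholds to
the rounded integer percentage keeps the rule consistent with the
reporting convention: a cohort printed as "75% elevated" has, by
definition, completed at that age even if the raw fraction is 74.7%.

**Side preference.** Left counts among unilateral embryos are tested
against Binomial(n, ½) with the exact two-sided binomial test.

## Exact statistics

The three tests are self-contained implementations, kept independent of
`stats` so that `fisher.test()`, `binom.test()` and `t.test()` can serve
as cross-checking oracles in the test suite rather than as the
implementation.

- **Hypergeometric kernel.** Probabilities accumulate as
  log-binomial-coefficient sums (`lchoose`), overflow-safe to population
  sizes around 10⁶.
- **Two-sided rule.** Both exact tests use the point-probability
  convention: the p-value sums all outcomes no more probable than the one
  observed. A relative guard of 1e-7 absorbs floating-point ties — without
  it, outcomes that are mathematically tied with the observed one (equal
  pmf via different factorizations) would be dropped or kept
  unpredictably. Tables with a zero margin are degenerate: p = 1 with an
  explicit flag, never an error, since such tables legitimately arise in
  small strata.
- **Welch t-test.** t = (x̄−ȳ)/√(s²ₓ/nₓ + s²ᵧ/nᵧ) with
  Welch–Satterthwaite degrees of freedom; the two-sided tail is
  P(|T| > t) = I_{df/(df+t²)}(df/2, ½), evaluated with the regularized
  incomplete beta function. This is exact at the small group sizes (3–8
  sections) where a normal approximation would not be. Zero-variance
  inputs with equal means return p = 1, flagged degenerate.

## Synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed and are not tuning knobs.

**Cohorts.** Designed strata with stage multinomials and a left-side
probability for unilateral embryos. Degenerate designs (probability 1 on
one stage) are legal and exercised in tests.

**Sections.** A schematic coronal field, by default 250 × 200 µm at
0.5 µm/pixel: a dorsal hinge band (40% of the mesenchyme), the ventral
mesenchyme split into lingual (tongue side, +x) and buccal halves, a
ventral epithelial strip, and a 4 µm outside margin. Region geometry is
polygonal and user-replaceable; masks are rasterized at pixel centers.

Nuclei are placed region by region by hard-core rejection sampling
(minimum center distance 0.8 × mean major-axis length — simpler than
Poisson-disc sampling and adequate at these densities), with counts drawn
as Poisson(density × area). The default density, 1.5 nuclei/1000 µm²,
with major axes 8–12 µm and aspect ratios 1.5–2.5, gives a field that is
crowded enough to exercise watershed splitting but sparse enough to be
segmentable — the source sections' true density, nuclear size and SNR are
not published, so these are declared defaults calibrated only to make the
recovery tests meaningful, not reconstructions.

**Orientation model.** Nuclear long axes are axial (θ ≡ θ + 180°), so
angles are generated by the doubled-angle construction: θ = μ + φ/2 with
φ ~ von Mises(0, κ), the standard nematic analogue of a normal
distribution. Under this model the order parameter has the closed form
S = I₁(κ)/I₀(κ), which anchors all recovery tests (S(2) ≈ 0.6978).
Regional defaults — hinge μ = 60°, κ = 2; lingual μ = 75°, κ = 3; buccal
μ = 90°, κ = 6 — reproduce the qualitative biology: a tongue-tilted,
weakly ordered hinge and a vertical, highly ordered buccal region.

**Intensity model.** 16-bit scale with background at 5%, nuclear
foreground 60%, marker-positive foreground 70% of full scale;
per-nucleus brightness jitter ±15%; a single Gaussian PSF (σ = 0.6 µm);
additive Gaussian noise (σ = 0.06, i.e. SNR ≈ 10 on nuclear foreground)
clipped to [0, 1]. Two replicate-level variance terms make section-level
inference honest: a lognormal per-section staining gain (σ = 0.05) and a
lognormal per-section, per-region marker jitter (σ = 0.10). Without
them, region means over thousands of pixels would have vanishing
section-to-section variance and any Welch contrast would be trivially
significant; with them, per-section regional values scatter like
biological replicates.

**What the generator does not emulate:** 3D structure and optical
sectioning, chromatin texture, spatially correlated illumination or
staining gradients, nucleus shape irregularity (all nuclei are true
ellipses), and anatomically realistic region boundaries. Passing
recovery tests therefore demonstrates correctness of the measurement
code under a known generative model — not robustness to every artifact
of real cryosections.

## Morphometry

Segmentation is deliberately classical: Gaussian smoothing (σ = 0.8 µm)
→ global Otsu threshold → hole filling → distance-transform watershed
(tolerance 1) → area filter (10–150 µm²). The angle is
½·atan2(2μ₁₁, μ₂₀−μ₀₂) from second central moments, computed in a
physical frame with y increasing dorsally (raster rows flipped), and the
aspect ratio is √(λ₁/λ₂) of the moment matrix. Right-shelf sections are
mirrored in x so that "toward the tongue" is +x on both sides, making
tilts comparable across sides with a single sign convention
(tilt = 90° − mean angle; positive = toward the tongue).

Near-circular nuclei carry no reliable axis — the moment angle is
ill-conditioned as λ₁ → λ₂ — so nuclei with aspect < 1.2 are flagged
`angle_defined = FALSE`, excluded from orientation statistics but
retained for counting and positivity. At the default 0.5 µm sampling the
discretization bias of the moment angle on a clean 10 × 5 µm ellipse is
on the order of 1°; the unit test of the analytic example renders at
0.25 µm where the bias is well below the 1° tolerance, and the
pipeline-level angle criterion (MAE ≤ 10° at 0.5 µm) absorbs it.

KI-67 positivity is a per-section decision (Otsu on per-nucleus mean
intensities) because staining intensity varies section to section; a
global threshold would conflate staining batch with biology. The chosen
threshold is recorded in the run manifest. Epithelium exclusion is
mask-driven (label 4), so all quantification is restricted to the PS
mesenchyme.

## Orientation statistics

Regional summaries use doubled-angle circular statistics: mean
½·atan2(⟨sin 2θ⟩, ⟨cos 2θ⟩) in [0°, 180°), resultant length R₂ (which
equals the global order parameter S), and axial SD ½·√(−2 ln R₂) via the
wrapped-normal mapping. R₂ = 0 (perfect axial cancellation, e.g. {0°,
90°}) leaves the mean undefined and is flagged rather than silently
propagated.

Whether the published order parameter is neighborhood-local or
region-global cannot be determined from the available text, so both are
computed. The local variant S_i takes the angle-defined neighbors within
a fixed physical radius (default 25 µm, roughly two cell diameters; self
excluded) and requires ≥ 4 neighbors; the regional value is the mean of
defined S_i. Finite neighborhoods bias S_i upward (the sample resultant
length of n draws concentrates around √(S² + (1−S²)/n)), which is why
the local-recovery test allows 0.07 where the global one allows 0.05.

## Regional deviations and inference

"Change from the mean" metrics subtract the section-wide mean from the
per-region value: KI-67 as positive fraction per nucleus (fractions, not
raw counts, so sections of different sizes are comparable; raw counts
are emitted alongside), p-MLC as mean intensity per pixel, in both cases
excluding epithelium and outside pixels. Basis-weighted deviations sum
to zero per section by construction, which the tests assert to 1e-12 —
a useful integrity check on any refactor. Intensity deviations are
exactly invariant to global additive offsets and scale proportionally
under global gain, so uncalibrated acquisition offsets cannot create
spurious regional structure.

Inference across sections uses the Welch t-test with the **section** as
the independent unit (sets of 3–8 independent values per group);
embryo-level nesting is recorded but not modelled.

## Numerical and testing choices

Monte-Carlo sizes are chosen so that simulation noise is small against
each tolerance: 10,000 draws for distribution-level checks (binomial SE
≈ 0.5% on a 5% rate), 1,000 draws per seed for orientation recovery
(SE of Ŝ ≈ 0.015 at κ = 2, against a 0.05 band), 10,000 null pairs for
Welch calibration, 1,000 replicates for Fisher calibration on cohorts of
150 per sex, 200 replicates for the 4-vs-4 power check on 120 × 100 µm
sections at 1 µm/pixel (smaller than the default section purely to keep
the replicate count high). Determinism is by explicit seeds everywhere;
a fixed seed makes cohorts and sections bit-identical across runs.

The Fisher implementation is verified two independent ways: exhaustively
against a plain-arithmetic enumeration oracle on every 2×2 table with
total ≤ 40, and against `stats::fisher.test` on random tables. The exact
p-values of the two reference sex contrasts were frozen from the
enumeration oracle before the analysis code was wired to them.

## Known limitations

- Staging ages are categorical; the window estimator cannot resolve
  events between sampled timepoints, and its start rule depends on the
  declared 95% threshold.
- Fisher exact tests are conservative in small strata; the calibration
  test uses 150 embryos per sex where discreteness is mild.
- Segmentation has no learned component and will undersplit heavily
  overlapping nuclei beyond what the distance-transform watershed can
  separate; the generator's hard-core placement keeps it in the regime
  where the classical pipeline is reliable.
- The published asterisk p-values for the image-based figures are not
  reproducible (raw images are not deposited); the package substitutes
  property-based evidence — calibration, closed-form recovery, and
  power under designed effects — for them.
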