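---
title: "Region-stratified immunofluorescence quantification of synovial tissue: models and methods"
author: "SynoQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SynoQuant methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynoQuant)
```

# The analysis problem

Synovitis — inflammation of the soft-tissue lining of joint capsules — is a
driver of osteoarthritis, and macrophage surface markers such as CD14, CD16
and CD206 are used to characterize the cells involved. SynoQuant implements
a semi-automated quantification pipeline for immunofluorescence-stained
synovial membrane sections in which marker expression is stratified over
three manually delineated tissue regions:

* **ICL** — the intimal cell layer, the apical two-to-three-cell-thick
  lining of a synovial villus facing the joint cavity;
* **SI-V** — the subintimal tissue of the villous region;
* **SI-N** — subintimal tissue not associated with a villus.

A villus is identified morphologically by being taller than wide
(`villusShapeCheck()` tests the bounding box with a strict inequality).
Damaged tissue is delineated as EXCLUDED and never enters any numerator or
denominator.

The pipeline computes, per sample and region: marker-positive area
fractions (% of region area), pixel-level co-localization ratios
(double-positive area as % of the parent marker's area), intimal cell
density (cells/mm²) from manually marked centers, and vessel density
(BV/mm²) with outline perimeters. A normality-gated statistics stage
compares the three study groups (foals F, non-affected adult controls CTRL,
OA-affected adults OA), and a synthetic tissue-section generator with known
per-cell ground truth makes every stage testable without slides.

# Image primitives and their exact semantics

All coordinates are 0-based with x = column and y = row, origin top-left,
pixel centers at integer coordinates. The physical pixel size (µm/px)
carries every mm² denominator.

**Locally adaptive binarization.** A pixel is positive iff its intensity
*strictly* exceeds the unweighted mean of the square neighborhood of
half-width $w$ centered on it (window side $2w+1$), with symmetric reflect
padding at the borders. The default $w = 50$ px is the standard filter
width for this assay. Implementation notes: the local mean uses an integral
image on data centered at one pixel's value so a constant channel is exactly
all-negative; additionally, a pixel whose value equals the image minimum is
never positive (it cannot strictly exceed a mean of values that are all at
least the minimum) — enforcing this identity guards flat zero-background
areas against integral-image rounding. A window larger than the image
degrades to a global-mean threshold with a warning. Thresholding is
strictly monotone-invariant: rescaling a positive image leaves the mask
unchanged, and each channel is binarized independently with identical
parameters, so differing per-channel exposure gains do not matter.

**Co-localization.** Double-positive masks are the pixelwise product
(logical AND) of two binary masks. The co-localization ratio in a region is
`100 * |coloc ∩ region| / |parent ∩ region|`; if the parent marker has no
positive pixel in the region the ratio is undefined and propagates as a
flagged missing value — never 0 or 100 — so it cannot bias group statistics.
The package's convention follows the worked example: a parent area of 10
units with 8 double-positive units is 80 %.

**Seeded cell masks.** Cell masks are the watershed of the seed distance
transform restricted to disks of radius $r$ (default 15 px, the empirically
determined average lining-cell radius): each pixel within $r$ of at least
one seed joins its nearest seed (Euclidean distance pixel-center-to-seed),
ties toward the lower seed index, making the result seed-order
deterministic. This is mathematically the radius-constrained nearest-seed
(Voronoi) partition, and the implementation is verified pixel-for-pixel
against an exhaustive brute-force oracle. Cell density is the number of
seeds assigned to a region divided by the region's area in mm².

**Region rasterization.** A pixel belongs to a polygon iff its center lies
inside by the even-odd rule; overlaps resolve by the fixed precedence
EXCLUDED > ICL > SI_V > SI_N (the ICL band is drawn atop the villus, and
artefacts always win). Self-intersecting polygons are rejected with their
feature index. Point-to-region assignment floors both coordinates, and
points on EXCLUDED or BACKGROUND, or out of bounds, are flagged rather than
dropped.

**Vessels.** Vessel outlines are assigned to the region containing their
polygon centroid; the perimeter is the closed-ring arc length times the
pixel size. SI-N area denominators include vessel lumina; this is a
documented package choice.

# Statistics stage

For each variable × region, the three groups pass a Shapiro-Wilk normality
gate at α = 0.05 per group. If *all* groups pass: Welch's t-test (two
groups) or one-way ANOVA with Tukey HSD (three or more); otherwise Wilcoxon
rank-sum or Kruskal-Wallis with Dunn's post-hoc test (tie-corrected rank z
statistics, Bonferroni-adjusted). Descriptives follow the same gate: mean ±
SD when parametric, otherwise median with 25–75 % quantiles
(linear-interpolation type 7). Groups that are constant or have fewer than
three values make the gate indeterminate and route to the non-parametric
path; fully degenerate data report p = 1 rather than NaN. Significance is
declared at p < 0.050. The gate is a deterministic function of the data.

Analyte (cytokine/chemokine) tables are censored below their limit of
detection with a *strict* `value < LOD` rule (a value exactly at the LOD is
kept). Analytes censored in 100 % of samples are excluded from testing and
listed in a below-LOD report block; partially censored analytes are
analyzed complete-case. Substituting LOD/2 was deliberately rejected to
match the reporting convention of leaving undetectable analytes untested.

# The synthetic tissue generator

`generateSection()` builds one villus-shaped section with known truth:

* **Geometry.** The villus is a superellipse lobe (exponent uniform in
  [2, 3]) with bounding-box height/width ratio uniform in [1.3, 2.2],
  rooted on a basal SI-N band; the ICL is an apical band along the villus
  tip whose thickness is uniform in 2–3 cell diameters (cell radius 7.5 µm);
  a small EXCLUDED rectangle sits in the base to exercise precedence.
* **Cells.** Per region, cell counts are Poisson at the configured density
  times the rasterized region area; positions are uniform over region
  pixels, so rasterizing the stored polygons and querying any stored center
  reproduces its region class exactly.
* **Markers.** Each cell draws marker flags at region-specific
  probabilities. For configured pairs `A:B`, B is drawn with probability
  P(B|A) on A-positive cells and with the marginal-preserving complement
  `(pB − pA·P(B|A)) / (1 − pA)` on A-negative cells, so conditional
  co-expression and marginal calibration hold simultaneously.
* **Vessels.** Poisson counts per region; irregular 16-gon outlines with
  4–8 µm lumen radius; the recorded region class is the label under the
  outline centroid (the same rule the measurement stage applies).
* **Optics.** Each nucleus (DAPI) and each marker-positive cell renders a
  compact, isotropic order-4 super-Gaussian blob
  $a\,\exp(-d^4 / 2 s^4)$ with scale $s$ = 2.25 µm (4.5 px at the default
  0.5 µm/px), truncated where the profile falls below $10^{-4}$. The
  plateau-with-steep-shoulder profile models a surface-stained cell body
  rather than a diffraction-limited point. A pure Gaussian was rejected on
  methodological grounds: under strict local-mean thresholding of a
  zero-background field the threshold for sparse channels approaches zero,
  so a Gaussian's unbounded tail makes the detected footprint *grow* as a
  channel gets sparser, systematically compressing configured group
  contrasts. Bounded shoulders keep the detected footprint nearly
  threshold-independent.
* **Nuisances.** A multiplicative smooth illumination gradient (linear ramp
  in a random direction, default amplitude 0.3) and pure shot noise with
  standard deviation `noiseLevel * sqrt(intensity)` (default 0.2). Because
  the noise is signal-proportional, zero-background pixels stay exactly
  zero; there is no additive camera noise or autofluorescence term.

**Ground truth for recovery checks.** Per-cell flags and densities are
exact by construction. For *area* metrics the scenario configures per-cell
probabilities, not areas, so the area truth is defined as the strict
local-mean binarization of the *ideal* render (no noise, no gradient):
recovery tolerances then measure exactly the robustness of the measurement
to the modelled nuisances, not a tautology. The ICL density truth divides
the realized cell count by the analytic (shoelace) polygon area, so
comparing against the rasterized-map measurement isolates discretization
error.

**Group presets.** `scenarioPreset()` encodes the modelled study's
qualitative contrasts: CD14 highest in CTRL (ICL and SI-V), CD206 highest
in F, CD16 areas flat across groups, ICL cell density elevated in F
(5550/mm²) and OA (5650/mm²) versus CTRL (4300/mm²), vessels denser in SI-V
than SI-N with the OA SI-N elevated. The exact probabilities are package
calibration defaults, not claims about real tissue. Because the groups
differ in ICL cell density, a *constant* CD16 probability would produce
systematically unequal CD16 areas (denser intima → more stained cells and
boundary spillover); the CD16 probabilities are therefore slightly
density-compensated (ICL 0.45/0.345/0.345 and SI-V 0.40/0.39/0.39 for
CTRL/F/OA) so that the measured CD16 area — the study's observable — is
flat. Synovial-fluid analytes are drawn log-normally per group around the
study's reported medians with a common log-scale spread, and the four
analytes that remain undetectable (IL-1β, IFN-α, IL-4, CCL3; LODs 61, 12,
40, 5 pg/ml) are generated entirely below their LODs.

# Key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `windowPx` | 50 | px | adaptive-threshold neighborhood half-width |
| `cellRadiusPx` | 15 | px | maximum watershed cell radius |
| `alpha` | 0.050 | — | significance level throughout |
| `pixelSizeUm` | 0.5 | µm/px | typical 20× slide-scan resolution; 15 px = 7.5 µm |
| `noiseLevel` | 0.2 | — | shot-noise scale (sd = level·√I) |
| `illumGradientAmplitude` | 0.3 | — | multiplicative gradient depth |
| blob scale | 2.25 | µm | super-Gaussian cell-blob scale |
| `nPerGroup` | F 10, CTRL 11, OA 9 | — | the modelled study's group sizes |

# Validation design and problem sizes

The test suite validates every primitive against an independent brute-force
oracle (naive windowed means, even-odd point-in-polygon at every center,
exhaustive nearest-seed assignment, permutation reference for the omnibus
test, an independently computed Dunn fixture), checks ground-truth recovery
on synthetic sections (area fractions within 1 pp of truth noise-free and
2 pp at default noise; ICL density within 1 %; vessel counts exact), checks
type-I calibration of the gated comparison under a three-group null
(2000 replicates at n = 11/9/10, rejection rate required in [0.035, 0.065]),
and checks that the packaged presets yield the qualitative orderings in at
least 90 of 100 simulated cohorts. Sections are 512 × 512 px (256 × 256 µm)
— one villus per section; this desk-scale field is the package's chosen
simulation size and makes the ICL hold a few dozen cells, so preset effect
sizes were calibrated (on separate pilot seeds) to be detectable at the
study's group sizes. Note that the CD16 component of the preset check asks
an exact null to stay non-significant in two regions simultaneously, which
even a perfectly calibrated preset satisfies with probability ≈ 0.95² ≈
0.90 per cohort — that check therefore sits at the boundary of what its own
α allows, and the marker-ordering component is asserted separately.

# What passing tests do and do not show

The generator emulates region-structured marker expression, villus
morphology, illumination inhomogeneity and shot noise. It does **not**
emulate tissue autofluorescence or additive camera background, uneven
staining penetration, variable cell morphology or 3-D sectioning effects,
touching/overlapping nuclei beyond Poisson placement, multiple villi or
fragmented sections, or the HE appearance of vessels (vessel outlines are
consumed as annotations, as in the modelled workflow). Recovery results on
synthetic data therefore demonstrate the correctness and
nuisance-robustness of the computations, not performance on real slides;
in particular, the zero-offset strict-mean threshold would mark speckle on
a noisy additive background, and a threshold offset would be the first knob
to revisit for real data.

Other documented choices: no minimum-object-size filter is applied after
binarization; isotype-control channels, when present, are binarized
identically and reported only as a QC positive fraction, never subtracted;
each sample contributes one measurement row per variable (no within-joint
averaging); SI-N denominators include vessel lumina.
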