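# SynoQuant

Region-stratified, semi-automated quantification of immunofluorescence-stained
synovial membrane sections, for researchers studying synovitis and
osteoarthritis-related changes in joint tissue (equine or otherwise) who need
reproducible marker histomorphometry instead of ad-hoc image-tool workflows.

The synovium is analyzed in three manually delineated regions — the intimal
cell layer (**ICL**, the apical 2–3-cell lining of a villus), the subintimal
villous layer (**SI-V**) and the non-villous subintima (**SI-N**) — plus
EXCLUDED artefact zones. For each sample the package computes:

* **Marker-positive area fractions.** Each fluorescence channel (e.g. CD14,
  CD16, CD206) is binarized by locally adaptive thresholding: pixel positive
  iff `I(p) > mean(window(p))`, square window of half-width 50 px, reflect
  padding, strict inequality. Per region `R`,
  `fraction = 100 · |mask ∩ R| / |R|` (%).
* **Co-localization ratios.** Double-positive masks are products of binary
  masks; `ratio = 100 · |A⁺B⁺ ∩ R| / |A⁺ ∩ R|` — if CD14⁺ covers 10 units and
  CD14⁺CD16⁺ covers 8, the ratio is 80 %. Empty parents propagate as flagged
  missing values.
* **Intimal cell density.** Manually punctuated cell centers are assigned to
  regions; per-cell masks come from the watershed of the seed distance
  transform constrained to a 15 px cell radius (equivalently: radius-limited
  nearest-seed partition, ties to the lower seed index). Density =
  seeds in ICL / ICL area (cells/mm²).
* **Vessel metrics.** Vessel outlines are assigned by centroid;
  count/mm² and mean perimeter (µm) per region.
* **Group statistics.** Shapiro-Wilk gate per group at α = 0.050; all normal →
  Welch t-test / ANOVA + Tukey HSD; otherwise rank-sum / Kruskal-Wallis +
  Dunn (Bonferroni). Descriptives follow the gate (mean ± SD vs median
  [Q1–Q3]). Analytes below their limit of detection are strictly censored;
  fully undetectable analytes are excluded and reported in a below-LOD block.

A first-class synthetic-data module generates villus-shaped sections with
known per-cell ground truth (region-dependent marker probabilities,
conditional co-expression, Poisson cell placement, illumination gradients,
shot noise) so the whole pipeline is validated end-to-end without slides.

## Worked example

```r
library(SynoQuant)
cfg <- runConfig(nPerGroup = c(F = 4L, CTRL = 4L, OA = 4L), seed = 11L)
res <- runFull(cfg)            # simulate -> segment -> quantify -> compare
m <- res$measurements
aggregate(value ~ group + variable,
          m[m$region == "ICL" & m$flag == "ok", ], median)
```

Median ICL values over this 12-sample synthetic cohort:

```
              variable  CTRL      F     OA
        CD14_area_pct   5.30   3.25   2.01
  CD14_CD16_ratio_pct  59.84  54.61  84.88
 CD14_CD206_ratio_pct  67.99  84.42  24.76
        CD16_area_pct   8.44   7.71   7.75
       CD206_area_pct   6.31  12.20   6.39
         cell_density  4388   5131   5793
```

Reading it: the control preset expresses the most CD14 (5.3 % of ICL area vs
2.0 % in OA), foals the most CD206 (12.2 %), CD16 is flat (≈ 8 % everywhere),
and intimal cell density is elevated in foals and OA animals — the
qualitative contrasts the presets encode. The statistics stage flags them:

```r
rep <- res$stats$report
rep[rep$variable == "CD206_area_pct" & rep$region == "ICL", ]
#  gate       method        omnibus_p group1 group2  p_adj significant
#  parametric one-way ANOVA   0.00185   CTRL      F 0.0043        TRUE
#  parametric one-way ANOVA   0.00185   CTRL     OA 0.9693       FALSE
#  parametric one-way ANOVA   0.00185      F     OA 0.0031        TRUE
res$stats$belowLOD
# "CCL3"  "IFN-a" "IL-1b" "IL-4"
```

With an `outDir`, `runFull()` also writes `measurements.csv`,
`stats_report.csv`, `qc.csv`, `analytes.csv` (each headed by the config
hash) and `run.json` with per-stage timings. `runSimulate()` exports a
cohort as 16-bit TIFF channels, GeoJSON region/vessel polygons and seed
CSVs, and a thin command-line wrapper lives at
`inst/scripts/synoquant-cli.R` (subcommands `simulate`, `quantify`,
`stats`, `run`; flags `--window-px`, `--cell-radius-px`, `--alpha`,
`--pixel-size-um`, `--seed`, `--out`, `--force`).

See the methods vignette (`vignettes/synoquant-methods.Rmd`) for the exact
primitive semantics, the synthetic optics model and its rationale, preset
calibration, and known limitations.

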