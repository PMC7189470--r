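# tiquant

Quantitative pipelines for preclinical tumor-immunology studies:
registration-based immunohistochemistry morphometry, sequential
flow-cytometry gating of myeloid populations, and multiplex cytokine
calibration — plus the statistical layer that ties them together and a
synthetic-data generator with planted ground truth for end-to-end
validation.

## Who this is for

Groups quantifying treatment response in tumor models (e.g. antibody
therapy in HER2+ breast-cancer xenografts) from three data streams
collected on the same animals:

* **Serial stained sections** (H&E, CD31, α-SMA, F4/80, Ki67) — the
  package registers each section to its H&E reference with a similarity
  transform estimated from grayscale intensity differences, segments each
  stain by a single threshold calibrated from positive/negative controls
  (after color deconvolution), and reports six per-tumor metrics:

  | metric | definition |
  |---|---|
  | MVD | CD31+ vessel objects per mm² of viable tissue |
  | SMA density | α-SMA–coated vessel objects per mm² |
  | VMI | 100 · SMA density / MVD (vessel maturation index) |
  | F4/80 | % of viable-tissue area stain-positive |
  | Ki67 | % of tumor nuclei positively stained |
  | necrosis | % of tumor area necrotic (manual mask input) |

  Viable tissue is total tumor area minus necrotic area; densities use
  the physical pixel size (0.495 μm/px at 20×).

* **Flow-cytometry event tables** — compensation by inverse spillover,
  then a configurable sequential gate hierarchy: live (PI−) → CD45+ →
  macrophages (CD11b+ F4/80+), dendritic cells (CD11c+ MHCII+ F4/80−),
  G-MDSC (CD11b+ Ly6G+), M-MDSC (CD11b+ Ly6C-high Ly6G−), with
  CD38/CD206 quadrant phenotyping of macrophages (M0/M1/M2/co-expressing).

* **Multiplex bead assays** — per-analyte four-parameter logistic
  standard curves, y(x) = d + (a−d)/(1+(x/c)^b), fitted by least squares,
  inverted in closed form, with out-of-range flagging and protein
  normalization (pg cytokine per mg protein), for a 12-analyte murine
  panel.

The statistics module implements the matching analysis layer: exact
two-sided Wilcoxon rank-sum comparisons (normal approximation under
ties), mean ± SEM summaries, Pearson correlation with a regression line,
and the sample-exclusion rules (viability < 50%, or MAD outlier — more
than three absolute deviations from the median — in ≥ 4 myeloid
populations).

Because studies of this kind rarely deposit per-animal raw data, the
`synthetic` layer (`slide_spec()`/`generate_slide_set()`, `flow_spec()`/
`generate_flow_events()`, `bead_spec()`/`generate_bead_plate()`,
`study_design()`/`run_synthetic_study()`) generates every input with
machine-readable ground truth, so each stage is validated by recovery.

## Worked example

```r
library(tiquant)

## a synthetic tumor: 30 vessels, 25% SMA-coated, sections warped by a
## known similarity transform
set <- generate_slide_set(slide_spec(n_vessels = 30, sma_coated_fraction = 0.25,
  transform_truth = similarity_transform(1.01, 3, 5, -4), seed = 42))
thr <- calibrate_slide_thresholds(set$controls)
quantify_slide(set$images, set$masks$necrosis, thr,
               tumor_mask = binary_mask(set$masks$tumor, 0.495))
#> <slide_metrics> MVD 5740.1 /mm2 | SMA 1530.7 /mm2 | VMI 26.7% |
#>   F4/80 10.10% | Ki67 30.0% | necrosis 10.0% | viable 0.005 mm2
```

The planted truth for this seed is MVD 5740.1 /mm² and VMI 26.7% (8 of 30
vessels coated), so registration + segmentation recovered both exactly at
the printed precision; F4/80, Ki67 and necrosis match their planted 10%,
30% and 10%.

```r
fl <- generate_flow_events(flow_spec(n_events = 10000, seed = 42))
g <- apply_gate_tree(fl$events, default_gate_tree(auto_gate_thresholds(fl$events)))
g[, c("name", "count", "pct_of_parent", "pct_of_cd45")]
#>         name count pct_of_parent pct_of_cd45
#> 1       live  8541         85.41          NA
#> 2       cd45  3879         45.42      100.00
#> 3 macrophage  1129         29.11       29.11
#> 4         dc   309          7.97        7.97
#> 5      gmdsc   410         10.57       10.57
#> 6      mmdsc   260          6.70        6.70
```

85% of events are live, 45% of live events are CD45+, and 29.1% of the
tumor immune population are macrophages — all within sampling error of the
generator's planted fractions (85%, 45%, 30%). A rank-sum comparison of
two small groups:

```r
wilcoxon_rank_sum(c(9, 11, 12, 10, 13), c(19, 24, 22, 26, 21))
#> <rank_sum_test> W = 15 (U = 0), p = 0.007937 [exact]
```

p = 2/252, the exact two-sided tail for fully separated groups of five.

A complete synthetic study (four arms mirroring a dosing schedule, flow +
histology + cytokines per animal, exclusions, per-day comparisons and
cross-modality correlations):

```r
res <- run_synthetic_study(study_design(), run_config(seed = 1))
res$comparisons     # variable x day table: n, mean±SEM, W, p
res$correlations    # e.g. VMI vs %M1 Pearson r with regression line
```

A thin CLI wraps the same functions: see `inst/cli/tiquant.R`
(`synth`, `quantify`, `gate`, `fit`, `run` subcommands).

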