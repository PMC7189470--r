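---
title: "Quantifying treatment-induced vascular and immune remodeling: methods and design"
author: "tiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying treatment-induced vascular and immune remodeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tiquant)
```

## The problem

Preclinical studies of antibody therapy in HER2+ breast-cancer xenografts
read out treatment response along three axes measured on the same animals:

* **Histology** on serial tumor sections — microvessel density (MVD, CD31+
  vessel objects per mm² of viable tissue), smooth-muscle coverage of those
  vessels (α-SMA), their ratio (the vessel maturation index, VMI),
  macrophage infiltration (F4/80+ area fraction), proliferation (Ki67+
  nucleus fraction) and necrosis fraction;
* **Flow cytometry** of disaggregated tumors — sequential gating of live
  CD45+ events into macrophages, dendritic cells, G-MDSCs and M-MDSCs, and
  CD38/CD206 quadrant phenotyping of macrophages (M0 double-negative, M1
  CD38+/CD206−, M2 CD38−/CD206+, and co-expressing);
* **Multiplex cytokines** — bead-based immunoassay of 12 analytes read
  against per-analyte standard curves and normalized by total protein.

tiquant reimplements this quantification machinery as a tested pipeline.
Because studies of this kind rarely deposit raw per-animal data, the package
ships a synthetic-data generator that plants machine-readable ground truth
in every input, so each stage — and the pipeline end to end — can be
validated by recovery rather than by eyeballing.

## Histology model

**Stain representation.** Chromogenic stains combine linearly in optical
density (OD = −log₁₀ of transmittance). Images are unmixed by color
deconvolution onto fixed hematoxylin/eosin or hematoxylin/chromogen OD
vectors (the Ruifrok–Johnston convention). Working on the unmixed stain
channel is what makes *one scalar threshold per stain*, calibrated once
from positive/negative control tiles and reused uniformly across all
tumors, meaningful.

**Threshold calibration.** `calibrate_threshold()` takes the minimum-error
threshold between the control histograms (midpoint of the minimizing
interval). Controls that cannot be separated below a 25% misclassification
raise an error that reports the overlap, rather than silently producing a
useless threshold.

**Registration.** Serial sections are registered to the H&E reference with
a similarity transform (scale s, rotation θ, translation t), pixel-centred
about the image midpoint, mapping moving → fixed coordinates. The
criterion is the mean-squared grayscale difference over in-bounds pixels,
with a coverage penalty so the optimizer cannot shrink the overlap away.
Optimization is Nelder–Mead over a factor-of-two image pyramid, coarse to
fine; because near-elliptical tissue makes rotation multimodal at coarse
scale, the coarsest level is seeded from a small grid of rotation starts
and the best is refined. A final confirmation run defines convergence; a
non-converged fit is returned flagged with its criterion value, never
silently replaced by the identity.

Two registration profiles are used: the *precise* profile (3 pyramid
levels down to full resolution) recovers transforms to ≈0.003 scale /
0.1° / 0.1 px on synthetic pairs; the *study* profile (2 levels, capped
iterations, single rotation start) is accurate to ≈0.3 px and 0.2° on the
small warps typical of serial sections, which is ample for mask
arithmetic, at a fraction of the cost.

**Metrics.** A vessel is an 8-connected component of the segmented CD31
(or SMA) mask with size in [8, 10⁴] px; components straddling the
necrotic boundary count when the majority of their pixels are viable.
Densities divide by the viable area (tumor − necrosis, in mm² via the
physical pixel size; 0.495 μm/px at 20× means ≈4.08 million px per mm²).
VMI = 100 · (SMA+ vessel density) / MVD: "coverage" is read as *object
density* of coated vessels, the reading consistent with expressing VMI as
a ratio of two densities; an area-based variant would be a one-line
change on the segmented masks. Necrosis is an *input* mask (annotated
manually in practice; the generator emits its planted necrosis mask to
stand in for that annotation). Nuclei are detected on the hematoxylin
channel by threshold plus distance-transform watershed to split touching
blobs; Ki67 positivity tests each nucleus centroid against the segmented
Ki67 mask.

## Flow model

Compensation multiplies event rows by the inverse spillover matrix. The
default gating tree is the conventional murine myeloid hierarchy — live
(PI−) → CD45+ → {macrophage CD11b+F4/80+; DC CD11c+MHCII+F4/80−; G-MDSC
CD11b+Ly6G+; M-MDSC CD11b+Ly6C-high Ly6G−} — and is fully configurable
(YAML or `gate_node()` lists), since published gate geometries are rarely
recoverable exactly. Two conventions are fixed: events exactly at a
threshold are positive, and a child gate only ever sees events its
ancestors passed, so quadrant counts partition the macrophage count
exactly. Thresholds on synthetic data are placed at the valley of each
asinh-transformed channel (cofactor 150): a deterministic 2-means split
initialized at the data extremes (robust to minority modes of a few
percent, e.g. a small dead-cell PI mode) locates the two states, and the
kernel-density minimum between the centres is the cut. Doublet/debris
scatter gates are out of scope — the synthetic tables carry no scatter
channels — and are an extension point.

## Cytokine model

Standard curves are four-parameter logistic,
y(x) = d + (a − d)/(1 + (x/c)^b), the Luminex convention (a 5PL option
exists). Fitting is least squares (Levenberg–Marquardt) with
deterministic initialization from the data: plateaus from the extreme
mean responses, c from mid-response interpolation, b = 1; optional 1/y²
weighting. Inversion is the closed form
x = c·((a−d)/(y−d) − 1)^(1/b); responses at or beyond the asymptotes have
no finite inverse and are flagged, and responses outside the standards'
measured range are reported but flagged `in_range = FALSE` rather than
censored. Protein normalization is conc · volume / protein (pg per mg).

Recovery statements for noisy plates are about the *estimator* (replicate
wells averaged, error summarized as mean relative error per analyte and
overall): single wells carry replicate noise of cv, and the inversion
multiplies that by roughly 2/b near the inflection, so no correct
implementation can bound every individual well at 2·cv.

## Statistics

Group comparisons use the two-sided Wilcoxon rank-sum test: the exact
distribution whenever the data are untied (verified against exhaustive
enumeration in the tests), otherwise mid-ranks with the normal
approximation and continuity correction. Summaries are mean ± SEM
(sd/√n). Correlations are Pearson r with the least-squares line and a
t-based two-sided p on n − 2 df. No multiple-testing correction is
applied, matching the analysis style the pipeline mirrors.

Exclusion rules: a sample is dropped if viability < 50% (strict) or if it
is an outlier in ≥ 4 myeloid populations, where an outlier is a value
more than three absolute deviations from the median. "Absolute deviation"
is read as the **unscaled** MAD (median of |x − median|, no 1.4826
normal-consistency factor), because the wording names the deviation
itself; the scaled variant and a mean-absolute-deviation variant are
options. Screening runs within treatment-group strata; with fewer than 3
samples in a stratum nothing is flagged. A zero MAD (over half the values
identical) flags nothing and warns.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions.

* **Slides.** An anisotropic, lobed tumor boundary (low-order harmonic
  modulation of an ellipse) on a glass background; one simply connected
  necrotic disk; vessels as non-overlapping annuli (outer radius 4–8 px,
  ring thickness 3 px) with the first k = round(fraction·n) vessels
  SMA-coated, so SMA ⊂ CD31 exactly; nuclei as disks in viable tissue
  with exactly round(fraction·n) Ki67-positive; F4/80 as blob texture
  grown to an exact positive-pixel count. All non-H&E sections are warped
  by one known similarity transform. Two features exist specifically so
  that cross-stain intensity registration is *identifiable*, and both are
  also realism: the irregular boundary, and shared counterstain structure
  (a smooth tissue-density texture plus the same nuclei visible in every
  section's hematoxylin). With circularly symmetric tumors and disjoint
  per-stain content, the grayscale MSD minimum is genuinely displaced
  from the true rotation — no optimizer can fix that — which is a useful
  reminder that intensity registration needs shared structure, not just
  shared outlines.
* **Flow.** Events carry latent population labels drawn from the
  specified mixture; marker intensities are two-state log-normal per
  channel (the paper-style panel: CD45, CD11b, CD11c, MHCII, Ly6C, Ly6G,
  F4/80, CD38, CD206, PI), then mixed through the spillover matrix
  (identity by default; a mild preset exercises compensation). A
  live/dead fraction drives the PI channel.
* **Beads.** Per-analyte 4PL truth with realistic parameter ranges, a
  seven-point 1:4 standard series in duplicate, multiplicative
  (mean-preserving log-normal) well noise at the stated cv, and unknown
  samples drawn near each curve's inflection. The default panel is the
  12 murine analytes of the panel (VEGF-A, TNF-α, IL-1β,
  CCL21, CCL7, CXCL10, IL-6, IL-4, IL-10, IL-13, IL-23, MMP-12).
* **Study arms.** The default design mirrors a typical short dosing
  schedule — Day 0 baseline; Day 4 (24 h after two doses); Day 7 (96 h
  after two doses); Day 7 (24 h after three doses); control vs treated,
  n = 5 — with group-level truths at magnitudes typical of trastuzumab
  response in HER2+ xenografts (e.g. macrophages 30.5→45.9% of CD45+ on
  Day 4; M1 13.4→31.1% and VMI 11.1→22.6% after three doses) and
  animal-level log-normal variability (cv 0.15).

What the generator does **not** emulate: photorealistic histology,
scanner artifacts, stain-vector variability between slides, 3D tissue,
flow scatter channels, doublets, acquisition drift, or bead-level
aggregation. Passing recovery tests therefore demonstrates that the
*algorithms* are correct and calibrated on data obeying their model
assumptions; it does not certify performance on real slides or real FCS
files, where segmentation and gating error are dominated by the realism
gaps above.

## Numerical choices and degenerate inputs

* Coordinates are pixel-centred; transforms map moving → fixed; rotation
  is counter-clockwise in pixel coordinates.
* Ties at segmentation thresholds: stain channel must *exceed* the
  threshold; flow events *at* a gate threshold are positive.
* Degenerate cases are errors or flags, never silent: empty viable mask,
  zero MVD (VMI undefined), zero nuclei, empty event table, singular
  spillover, inseparable controls, infeasible vessel packing, responses
  beyond 4PL asymptotes, n = 1 SEM.
* Determinism: every generator takes a seed and restores the caller's
  RNG state; a study run derives per-animal seeds from the master seed,
  so reruns are byte-identical.

## Problem sizes

The validation experiments run on: 256–320 px canvases (20 registration
pairs at 256 px; the metric-recovery slide at 320 px with 40 vessels and
200 nuclei); 30 event tables of 10⁴ events; 10⁴ null simulations for the
rank-sum size; 12-analyte plates in duplicate; and 20-seed replicates of
two-arm, 5-per-arm studies for the planted-correlation and null-design
properties. These sizes give stable recovery statistics (binomial SDs of
a few tenths of a percent) while keeping a full validation run on a
laptop-class single core in the tens of minutes.

## Known limitations

* Cross-stain registration accuracy depends on shared counterstain
  content; sections with almost no common structure will register poorly,
  and the flagged criterion value should be checked.
* The α-SMA "coverage" reading (object density, not area) changes VMI's
  scale; comparisons across studies must use one convention.
* The valley thresholder assumes each gated channel is two-state; truly
  trimodal channels (e.g. Ly6C with an intermediate population) need an
  explicit gate tree rather than automatic thresholds.
* Exact rank-sum p-values require untied data; heavily discretized
  measurements silently fall back to the normal approximation (the
  `method` field says which path ran).
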