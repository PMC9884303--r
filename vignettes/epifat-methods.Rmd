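---
title: "Methods: CT adipose-tissue quantification, segmentation QC and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT adipose-tissue quantification, segmentation QC and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifat)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage computes, which parameters matter,
what the synthetic generators do and do not emulate, and where the design
was genuinely open.

## EAT quantification

Epicardial adipose tissue is defined voxel-wise: a voxel belongs to the
depot when it lies inside the pericardial sac, outside the heart chambers,
and its attenuation falls in the adipose window. Three choices deserve
comment.

**Window endpoints are inclusive.** The adipose window defaults to
[−190, −30] HU written as a closed range; a voxel at exactly −30 HU
counts as fat. Nothing in standard practice suggests an open endpoint, and
an inclusive rule is the only one under which "the window" and "its
endpoints" select the same voxels. The phantom palette (lung −800, chest
wall +30, blood +40, fat −70) deliberately straddles both window
boundaries so edge behaviour is exercised by tests.

**Volume uses the slice increment, not the thickness.** Cardiac protocols
often reconstruct 3 mm slices at 50 % overlap; consecutive slices are then
1.5 mm apart, and summing `N · dx · dy · thickness` would count every
tissue element twice. `compute_volume_ml()` therefore takes the per-axis
*spacing* of the voxel grid, with the axial entry understood as the
inter-slice increment (`slice_increment(3, 0.5)` = 1.5 mm). Volume is
exactly linear in each spacing component, which the tests assert.

**Voxels are all-or-nothing.** No partial-volume weighting is applied:
the measurement is plain thresholding, and the median attenuation is the
exact sample median of the selected voxels (midpoint convention for even
counts), computed on the native grid without resampling. An empty
selection is an error for `median_attenuation()` and a missing value in
`quantify_eat()` — never a numeric sentinel. Incomplete image stacks are
not extrapolated; the package measures only what is on the grid.

## Segmentation quality check

Failed heart segmentations tend to be grossly implausible in 3-D shape —
spurious lumps far from the heart or large missing wedges. The QC stage
encodes that intuition morphologically:

1. erode the heart mask by `erode_mm` (default 15 mm),
2. keep the largest 26-connected component,
3. dilate by `dilate_mm` (default 35 mm),
4. flag if segmentation volume outside this region exceeds `cutoff_ml`.

**Millimetres, not voxels.** Erosion and dilation threshold an exact
Euclidean distance transform computed with per-axis physical spacing
(separable lower-envelope algorithm, implemented in C++). On a
1 × 1 × 1.5 mm grid, "15 mm in all dimensions" is then truly isotropic in
space, which iterated structuring elements are not. Whether the original
procedure used a metric or a structuring element was not specified; the
metric reading is the one that honours the phrase on anisotropic grids.
Out-of-grid space is treated as neither foreground nor background, so a
mask touching the image border is not eroded from that side.

**The cut-off is a free parameter.** The published procedure selected a
numeric cut-off from manual review rounds without printing it. The default
here is 1.0 ml, chosen once so that multi-millilitre spurious blobs flag
while intact convex anatomies do not (the net erode-then-dilate margin of
+20 mm guarantees a convex heart checked against itself has exactly zero
outside volume). A heart that disappears under 15 mm erosion is flagged as
degenerate (`eroded_empty`) rather than raising an error: such an anatomy
is itself implausible, and the flag is the informative outcome.

**"Heart" means the pericardial interior including chambers** — the
outermost cardiac structure available to the pipeline, and the only mask
for which "the 3-D shape of a heart" is a meaningful prior.

## Abdominal VAT/SAT separation

A single slice at the L4 level (5 mm thickness, informational) is
thresholded with the same fat window — whether the original abdominal
analysis used an identical window was not stated, and reusing it is the
parsimonious default, configurable per call. Lean tissue defaults to
[−29, +150] HU, its floor abutting the fat ceiling. The inside-lean-tissue
filter is operationalised as: morphologically close the lean mask (default
5 mm, bridging small wall defects), then fill the non-lean background from
the image border with face connectivity; fat in the unreached interior is
visceral, everything else subcutaneous. The partition is exact by
construction (VAT ∪ SAT = fat, VAT ∩ SAT = ∅). A wall gap wider than the
closing can bridge makes the interior reachable, so all fat becomes
subcutaneous — tested in both directions. Fat pixels covered by the closed
wall itself (only possible in bridged-gap geometries) are classified
subcutaneous; they are not "inside" lean tissue.

## Synthetic phantoms

The cardiac phantom paints concentric ellipsoids — pericardium, chambers,
and the fat shell between them — on a 128 × 128 × 144 grid at
1 × 1 × 1.5 mm, with lung background, chest-wall slabs, and additive
Gaussian HU noise clipped to [−1000, 1000]. The default shell encloses
≈ 105 ml, an adult-scale depot. Ground truth is an exhaustive voxel count
of the painted fat label times the voxel volume, independent of any HU
window, so a noiseless phantom is recovered *exactly* by the quantifier
and the discretised shell volume converges to the analytic
`4/3·π·(a₁b₁c₁ − a₂b₂c₂)` as spacing shrinks (verified over three
resolutions). The z extent (216 mm) leaves room to place failure blobs at
50+ mm offsets beyond the heart surface, which the QC sensitivity studies
require. Noise defaults to 10 HU; at that level the painted tissue classes
sit ≥ 4 standard deviations from the window boundaries, so truth and
measurement differ by at most a handful of voxels.

What the phantom does **not** emulate: real cardiac anatomy, ECG gating,
dose modulation, reconstruction kernels, motion or beam-hardening
artefacts. Passing tests demonstrate correctness of the measurement
operators, not robustness to scanner physics.

Failure injection is deliberately exact: `add_blob` unions in precisely
`round(magnitude·1000/voxel_volume)` background voxels nearest to a centre
placed `offset_mm` beyond the surface (the direction is chosen as the axis
with most grid headroom), so the volume change matches the request to
within one voxel; `delete_wedge` removes the same count nearest to a
surface anchor; `leak_to_chest_wall` drags the blob centre along the image
x-axis to form a connecting finger. The published failure modes are
described only qualitatively; three parameterised corruptions are the
smallest family that exercises both "including" and "omitting" errors plus
a connected leak.

The abdominal phantom is a disc (visceral fat, −88 HU), a lean annulus
(+40 HU) and an outer fat annulus (subcutaneous, −106 HU) — the painted
attenuations reproduce the observed ordering (visceral denser than
subcutaneous). Requesting an open wall together with an enclosed visceral
disc is rejected: the truth labels would be ill-defined under the very
filter being tested. Gap-robustness is instead tested on directly
constructed masks.

## Synthetic cohort

The cohort generator exists so the statistics pipeline has data with known
structure at realistic scale. Five groups (NGT, IFG, IGT, CGI, T2D; sizes
1012/414/321/128/73) are drawn independently; within each group a Gaussian
copula over `(EATV, VAT area, BMI, waist, HOMA-IR, age)` supplies the
joint ranks, and marginal transforms match published medians and IQRs:
log-normal for the right-skewed variables (EATV, VAT area, HOMA-IR;
`σ = asinh(IQR/2·median)/z₀.₇₅`), normal for BMI and waist
(`σ = IQR/1.349`), and for age a median-matched piecewise-linear warp of
uniform 50–64 (the recruitment age band). The latent correlation matrix is
an explicit, editable assumption: only a few pairwise correlations were
published (EATV–BMI ≈ 0.58 up to EATV–VAT ≈ 0.74 in the reference group),
and the remaining entries are set to conventional anthropometric values
and checked for positive definiteness at generation time.

**Attenuations are tied to volume.** EATA and VAT attenuation are linear
in EATV with built-in slopes −0.082 and −0.129 HU/ml plus residual noise
sized so the group IQRs still hit their targets; the intercept per group
places the attenuation median at its published value. This makes the
pooled regression slope a *parameter-recovery* target: over 20 seeds the
fitted EATA-on-EATV slope recovers −0.082 to within ±0.005. SAT
attenuation is drawn independently — the data it emulates showed
subcutaneous fat decoupled from the visceral depots.

**Known confounder effects.** Mean-centred effects on log-EATV (male
+0.15, current smoking +0.08, physical activity −0.10, age +0.006/year)
give the confounder-qualification step a ground truth: age, sex, smoking
and physical activity qualify at p < 0.10 given VAT adjustment; season,
alcohol, education and lipid-lowering medication have no built-in effect
and qualify only at the false-positive rate of the test itself. The copula
component of EATV is shrunk so the total spread still matches the target
IQR. VAT/SAT attenuation medians are published only for the NGT and IGT
groups; the other three follow the stated monotone trend and are
assumptions, not calibrated claims. Likewise, fasting glucose medians per
group (5.2/6.3/5.4/6.5/7.3 mmol/L) are clinically plausible choices used
only to decompose HOMA-IR into an insulin–glucose pair whose product
identity holds row by row.

Missingness is injected completely at random; an entry ≥ 1 in the rate
vector is an absolute count, so published missingness bookkeeping (4
missing VAT leaving 1944; 28 missing HOMA-IR leaving 1916 complete cases)
can be reproduced exactly. All downstream models are complete-case, and
each fitted model reports the n it actually used.

What the cohort does **not** emulate: recruitment enrichment, family
history, oral-glucose-tolerance dynamics, or any within-subject
longitudinal structure.

## Statistical battery

Group summaries report median and IQR (quantile type 7) per group,
differences of medians versus NGT, pairwise two-group Kruskal–Wallis tests
against NGT (read from the "group vs. NGT" footnote convention;
equivalent to Mann–Whitney, no multiplicity correction because none was
reported), and Pearson chi-square across groups for categorical variables.

The ordinal trend uses Kendall's tau-b with the tie correction in both
margins, over the coding NGT = 0, IFG = IGT = 1, CGI = 2, T2D = 3 (the
published ordering ties the two isolated pre-diabetes states at one rank).
The p-value comes from the tie-corrected normal approximation of the
concordance statistic without continuity correction; the confidence
interval is a seeded bootstrap percentile interval (2000 resamples by
default) because no interval method was specified — a normal-approximation
alternative is available and the method used is recorded in the output.
The implementation counts concordances per ordinal-level pair in
O(levels² · n log n), and tests pin it to an exhaustive all-pairs oracle
(and to the independent implementation in base R) up to n = 200.

Staged regressions: Model 1 is outcome ~ exposure (four group indicators
with NGT reference, or HOMA-IR untransformed — a log option exists but no
transform was reported); Models 2–4 add BMI, waist and VAT area *one at a
time* ("one by one" is read as non-cumulative); Model 5 adds the qualified
confounders to the VAT-adjusted model — the source says only that "the
remaining confounders were introduced", and attaching them to the
VAT-adjusted model matches the presentation order of its forest plots
where VAT is the last co-variate before the confounder row; Model 6
(attenuation outcome only) additionally adjusts for EATV, testing whether
an attenuation association is independent of depot size. Fits are ordinary
least squares with analytic 95 % CIs; rank-deficient designs raise an
explicit collinearity error naming the aliased columns rather than
silently dropping them. Categorical covariates are reference-coded with
the largest category first (male, never-smoker, no-activity, high-school,
moderate alcohol, fall season, no lipid medication).

On the calibrated cohort the qualitative published pattern reproduces: the
T2D (and CGI) coefficients on EATV are strongly positive in Model 1 and
the T2D coefficient attenuates to null once VAT area enters (Model 4). The
IGT coefficient is borderline by construction — its EATV excess is smaller
than its VAT excess predicts — so assertions about the attenuation pattern
are made on the T2D/CGI contrasts, where the effect is unambiguous.

## Numerical choices and degenerate inputs

- Distance transforms are exact (no chamfer approximation); morphology on
  an empty mask returns an empty mask; erosion of an all-true grid is the
  identity (no virtual background outside the image).
- Component labelling breaks size ties by scan order, deterministically.
- Masks must be exactly binary; stray labels are an error listing the
  offending values, never silently thresholded.
- Blob injection uses nearest-voxel selection with index tie-breaks, so
  repeated runs are bit-identical.
- All generators take a mandatory integer seed; a fixed seed and
  configuration yield byte-identical pipeline outputs, which the I/O tests
  assert at the file level.

## Problem sizes used in the test-suite studies

Oracle-equivalence studies run on grids up to 16³ (quantification) and
≈ 12 × 10 × 9 (pairwise-distance morphology), sizes at which the naive
oracles are exact and fast; QC sensitivity/specificity studies use 10
corrupted and 50 intact full-size phantoms; cohort calibration uses 20
seeds at the published group sizes (n = 1948), and the null-size study of
the group test uses 500 replicates of a 400-subject five-group design.
These sizes were chosen so each study is statistically informative while
the whole suite stays interactive.

## Known limitations

- Geometry proxies only: no anatomical realism in either phantom.
- The QC cut-off, lean-tissue window and abdominal fat window are
  defensible defaults, not calibrated against scanner data.
- The copula's unpublished correlation entries and the non-NGT/IGT
  attenuation medians are assumptions; conclusions drawn from the
  synthetic cohort are about the pipeline, not about patients.
- Single-slice abdominal areas only; no volumetric abdominal fat.
- Pericardium/chamber segmentation itself is out of scope; masks are
  inputs.
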