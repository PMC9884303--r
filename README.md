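# epifat

Quantification of epicardial adipose tissue (EAT) on non-contrast cardiac CT,
with a morphological quality check for heart segmentations, visceral /
subcutaneous abdominal fat separation, and the cohort statistics used to
relate these fat depots to glucose derangement — all exercisable end to end
on synthetic phantoms and a calibrated synthetic cohort, so the whole
pipeline is testable without patient data.

## Who this is for

Researchers in cardiometabolic imaging who need a transparent, testable
implementation of the standard EAT measurement chain:

- **EATV / EATA** — epicardial adipose tissue volume (ml) and median
  attenuation (HU) are computed from a CT volume plus pericardium and
  chamber masks as all voxels *inside the pericardium, outside the
  chambers*, with attenuation in the adipose window **[−190, −30] HU**
  (endpoints inclusive). Volume integration uses the inter-slice
  *increment* — 1.5 mm for 3 mm slices reconstructed at 50 % overlap — so
  overlapping slices are not double-counted:
  `EATV = N · dx · dy · dz_increment / 1000`.
- **Segmentation QC** — a heart mask is eroded by 15 mm (Euclidean distance
  in physical millimetres, anisotropy-aware), reduced to its largest
  26-connected component, and dilated by 35 mm; segmentation volume outside
  that region above a cut-off (default 1 ml) flags the segmentation as
  potentially failed.
- **VAT / SAT** — on a single L4-level slice, fat is thresholded in the same
  HU window and split by an inside-lean-tissue filter: the lean mask is
  morphologically closed and its enclosed interior (not reachable from the
  image border) is visceral; the rest is subcutaneous.
- **Statistics** — five-group summaries (NGT, IFG, IGT, CGI, T2D) with
  differences of medians versus NGT, Kruskal–Wallis and chi-square tests,
  tie-corrected Kendall tau-b ordinal trend, confounder qualification
  (association with EATV independent of VAT area at p < 0.10 in the NGT
  group), staged linear models (exposure alone; + BMI; + waist; + VAT area;
  + confounders; EATA models additionally adjusted for EATV), HOMA-IR =
  insulin × glucose / 22.5.

Synthetic generators supply ground truth: a cardiac phantom (ellipsoid
pericardium/chambers with a fat shell at −70 HU, known volume by exhaustive
voxel count), an abdominal annulus phantom, parameterised segmentation
failures (blobs, wedges, leaks), and a Gaussian-copula five-group cohort
whose medians, IQRs and depot correlations are calibrated to published
population values.

## Worked example

```r
library(epifat)

# a cardiac phantom with known truth
ph <- generate_cardiac_phantom(seed = 1)
ph$truth$true_eatv_ml
#> [1] 105.528
quantify_eat(ph$volume, ph$truth$pericardium_mask, ph$truth$chamber_mask)
#> <fat_measurement> EATV 105.523 ml; EATA -70.0692 HU (70349 voxels)

# corrupt the segmentation and let the QC flag it
bad <- inject_segmentation_failure(ph$truth$pericardium_mask,
                                   failure_spec("add_blob", 5, offset_mm = 50),
                                   ph$volume$spacing)
qc_check(bad, ph$truth$pericardium_mask, ph$volume$spacing)
#> <qc_report> outside volume 5 ml (cutoff 1 ml); FLAGGED

# synthetic cohort and the ordinal trend of EAT volume across glucose groups
coh <- generate_cohort(seed = 1)
kendall_trend(coh, "eatv_ml", n_boot = 2000, seed = 1)
#> <kendall_trend> tau-b = 0.141, 95% CI [0.106, 0.176] (bootstrap), p = 2.27e-15, n = 1948
```

The phantom's 105 ml depot is adult-scale; the trend coefficient (~0.14)
says EAT volume rises monotonically from normal glucose tolerance through
pre-diabetes to type-2 diabetes in the calibrated cohort, while the same
test on attenuation gives a negative tau (fat gets radiologically lucent as
glucose control worsens).

A command-line wrapper over the same functions is installed at
`inst/cli/epifat.R` (subcommands `synth-phantom`, `synth-cohort`,
`quantify-eat`, `quantify-abdominal`, `qc-check`, `run-stats`, `run-all`).

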