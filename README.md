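# phrenicmap

Simulation and analysis pipeline linking endocardial pacing **capture
thresholds** of the right phrenic nerve (RPN) to the true **3D distance**
between pacing sites and the nerve.

During atrial-fibrillation ablation, operators pace from endocardial sites
(up to 50 mA / 2 ms) and bracket the RPN capture threshold at 10/20/30 mA,
labelling each site with one of five ordered categories (≤10, >10–≤20,
>20–≤30, >30–≤50 mA, or non-capture at 50 mA). The capture threshold grows
with the size of the virtual electrode needed to reach the nerve, so it
predicts the endocardium-to-nerve distance — the quantity that decides
whether radiofrequency delivery at a site is safe. This package rebuilds
that analysis chain on synthetic data with known ground truth:

* **geometry** — exact point-to-segment/polyline/mesh distances (the
  "shortest 3D distance" primitive), with brute-force oracles in the tests;
* **registration** — rigid map-to-CT fusion: Kabsch landmark alignment +
  point-to-point ICP, plus seeded perturbations for misregistration studies;
* **nerve volume** — rasterize the nerve path into a Hounsfield volume as a
  5-voxel-wide 900 HU tube, segment it back by thresholding, extract an
  ordered centerline via graph-geodesic ordering;
* **capture model** — Weiss–Lapicque strength–duration × quadratic
  strength–distance threshold law, `T(d, w) = (I0 + c d²)(1 + τ/w)`, with
  lognormal observation noise and protocol classification;
* **synthetic cohorts** — (a) a geometric atrial anatomy with an epicardial
  nerve course, and (b) a calibrated cohort drawn from truncated normals
  matching published per-category distance summaries (n, mean, SD, min);
* **diagnostics** — category summaries, Spearman rho, Welch t-tests,
  tie-corrected rank-sum AUC with bootstrap CI, and the per-cutoff
  sensitivity/specificity panel for predicting distance > 10 mm.

## Worked example

```r
library(phrenicmap)

# one calibrated cohort of 1033 sites and its diagnostic panel
cohort <- generate_calibrated_cohort(seed = 1)
summarize_categories(cohort)$capture_share_percent
#> [1] 70.2

roc <- roc_analysis(cohort, distance_cutoff_mm = 10, n_boot = 2000, seed = 1)
round(roc$auc, 3)
#> [1] 0.872
roc$by_cutoff
#>   cutoff sensitivity specificity
#> 1 >10 mA   0.9825073   0.1786744
#> 2 >20 mA   0.8367347   0.8097983
#> 3 >30 mA   0.7011662   0.9308357
#> 4 >50 mA   0.4329446   0.9682997
```

The panel reads: non-capture at 50 mA is highly specific (a close site
almost never shows it) but insensitive; a >10 mA threshold is sensitive but
nearly unspecific — the clinically relevant asymmetry.

The replicate-averaged reproduction (200 cohorts):

```r
report <- run_calibrated_reproduction(n_replicates = 200, seed = 42, n_boot = 0)
round(report$aggregate[c("auc", "se50", "sp50", "rho", "mean_cat1")], 3)
#>       auc      se50      sp50       rho mean_cat1 
#>     0.861     0.433     0.974     0.694     7.509
```

The geometric end-to-end scenario, with the capture model calibrated to the
published category means:

```r
cal <- calibrate_capture_params(reference_category_summaries()$categories, seed = 1)
rep <- run_geometric_endtoend(geometric_config(seed = 1, capture = cal$params))
max(abs(rep$sites$distance_measured_mm - rep$sites$distance_mm))  # vs ground truth
#> [1] 0.08688912
round(rep$stats$diagnostics$auc, 3)
#> [1] 0.834
```

Narrative drivers live under `analysis/` (`01_calibrated_cohort.R` …
`04_misregistration_sensitivity.R`); each writes its tables under
`results/`.

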