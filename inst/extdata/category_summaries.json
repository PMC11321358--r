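{
  "description": "Published site-level summaries of the reference pace-mapping cohort: 45 patients, 1033 endocardial pace-mapping sites near the expected right-phrenic-nerve course. Per capture-threshold category: site count and the mean, SD and minimum of the measured shortest 3D site-to-nerve distance (mm). These values are the calibration targets of the truncated-normal cohort generator.",
  "n_patients": 45,
  "total_sites": 1033,
  "sites_per_patient_mean": 23,
  "sites_per_patient_sd": 16.4,
  "region_counts": {"LA-septal": 872, "SVC/RA": 161},
  "categories": [
    {"category": "<=10 mA",     "n": 74,  "mean_mm": 7.5,  "sd_mm": 3.0, "min_mm": 1.0},
    {"category": ">10-<=20 mA", "n": 319, "mean_mm": 8.6,  "sd_mm": 4.5, "min_mm": 2.0},
    {"category": ">20-<=30 mA", "n": 135, "mean_mm": 11.5, "sd_mm": 3.7, "min_mm": 4.1},
    {"category": ">30-<=50 mA", "n": 197, "mean_mm": 16.5, "sd_mm": 4.5, "min_mm": 5.7},
    {"category": "non-capture", "n": 308, "mean_mm": 19.2, "sd_mm": 6.5, "min_mm": 9.4}
  ],
  "la_sites_within_3mm": 34,
  "la_sites_within_10mm": 302,
  "reported": {
    "auc": 0.846,
    "auc_ci": [0.821, 0.870],
    "spearman_rho": 0.692,
    "table2": [
      {"cutoff": ">10 mA", "sensitivity": 0.968, "specificity": 0.150},
      {"cutoff": ">20 mA", "sensitivity": 0.808, "specificity": 0.775},
      {"cutoff": ">30 mA", "sensitivity": 0.680, "specificity": 0.916},
      {"cutoff": ">50 mA", "sensitivity": 0.424, "specificity": 0.976}
    ]
  }
}
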