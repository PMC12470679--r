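# liradsq

Arithmetic, software-assisted LI-RADS v2018 assessment of liver lesions on
co-registered multi-phase contrast CT.

Hepatocellular carcinoma (HCC) is diagnosed on imaging through the LI-RADS
v2018 major features — arterial-phase hyperenhancement (APHE),
non-peripheral washout, enhancing capsule, threshold growth and size — and
two of these are, at heart, density comparisons that radiologists perform
by eye. `liradsq` makes them explicit arithmetic on mean Hounsfield Units:

* **APHE**: Δ = HU<sub>lesion,art</sub> − HU<sub>liver,art</sub>; present
  iff Δ > 0 (strict).
* **Washout**: the percentage attenuation ratio
  PAR = HU<sub>liver</sub> / HU<sub>lesion</sub> in each venous phase;
  present iff max(PAR<sub>pv</sub>, PAR<sub>del</sub>) > 1, i.e. > 100%.
* **Threshold growth**: diameter increase ≥ 50% within ≤ 183 days; without
  a qualifying prior exam the answer is "no".

Around this core the package provides the full workflow a quantitative
LI-RADS reading needs:

* a **synthetic 4-phase CT phantom** (`phantom_config()`,
  `generate_phantom()`, `phantom_cohort()`) with ellipsoidal lesions of
  known enhancement, noise and ground-truth flags, so every downstream
  stage is testable without patient data;
* **sphere-seeded 3D segmentation** (`sphere_seed()`,
  `segment_sphere_seed()`) — seed statistics, band-limited 26-connected
  region growing confined to the operator's sphere, closing / hole filling
  / largest component — plus per-phase measurements (`lesion_metrics()`):
  mean/SD HU, volume, axial caliper diameters and first-order histogram
  texture;
* the **LI-RADS v2018 CT decision table** (`classify_lirads()`,
  `batch_classify()`) with ancillary-feature adjustment (upgrades capped at
  LR-4) and a machine-readable rationale trace;
* **agreement statistics** (`mcnemar_bowker()`, `sign_test()`,
  `percent_agreement()`, `counts_from_percentages()`) for comparing visual
  and arithmetic readings, including reconstruction of published
  percentage tables back to counts;
* **structured reporting** (`render_report()`, `export_registry_row()`)
  and NIfTI/CSV/JSON interchange (`read_study()`,
  `read_measurements_csv()`, …);
* a one-call pipeline (`run_pipeline()`) and a thin CLI
  (`inst/cli/lirads.R`) with `phantom`, `segment`, `quantify`, `classify`,
  `agree`, `report` and `run` subcommands.

## Worked example

```r
library(liradsq)

cfg <- phantom_config(noise_sigma_hu = 10, rng_seed = 42)   # 32x28x24 mm lesion,
ph  <- generate_phantom(cfg)                                 # Δ=+25 HU, PAR 1.10/1.15

run <- run_pipeline(list(
  study          = ph$study,
  study_id       = "demo",
  seed_center_mm = cfg$lesion_center_mm,
  seed_radius_mm = max(cfg$lesion_radii_mm),   # snug operator sphere
  best_phase     = "portal_venous"))

run$result
#> <lirads_result> LR-5 (base LR-5)
#>   - base table: APHE yes, size 32.9 mm (bin >=20), 1 additional feature(s) [washout] -> LR-5
#>   - not-evaluable feature(s) counted as absent: capsule
```

The report (`cat(run$report)`) prints the per-phase density table and the
feature block; on this phantom the measured
arterial delta comes out at +18.1 HU for a configured +25 and the
delayed-phase PAR at 110% for a configured 1.15: the snug-sphere mask
admits a thin shell of liver at this contrast-to-noise ratio, which pulls
both measurements toward isodensity without ever flipping their sign, so
the feature flags match the phantom truth. Agreement between two readings of a cohort:

```r
t <- counts_from_percentages(matrix(c(87, 7, 4, 2), 2, byrow = TRUE), 46)
t$counts                      # 40 3 / 2 1
mcnemar_bowker(t)             # chi2 = 0.2, df = 1, p = 0.65
percent_agreement(t)          # 89.13% -> 89
```

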