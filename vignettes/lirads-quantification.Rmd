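---
title: "Arithmetic LI-RADS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arithmetic LI-RADS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liradsq)
```

## The problem

Hepatocellular carcinoma (HCC) is diagnosed on multi-phase contrast CT
through the LI-RADS v2018 major features: non-rim arterial-phase
hyperenhancement (APHE), non-peripheral washout in a venous phase, an
enhancing capsule, threshold growth, and size. Clinically these are judged
by eye. `liradsq` replaces the two density-based judgements with explicit
arithmetic on mean Hounsfield Units (HU) measured in a segmented lesion and
in the background liver, runs the v2018 decision table on the result, and
quantifies how such an arithmetic reading agrees with a visual one.

## The arithmetic model

Let $\mathrm{HU}_{l,p}$ and $\mathrm{HU}_{L,p}$ be the mean density of the
lesion and the background liver in phase $p$.

* **APHE.** $\Delta = \mathrm{HU}_{l,\mathrm{art}} -
  \mathrm{HU}_{L,\mathrm{art}}$; the feature is present iff $\Delta > 0$,
  strictly. An isodense lesion ($\Delta = 0$) is *not* hyperenhancing.
* **Washout.** The percentage attenuation ratio in a venous phase is
  $\mathrm{PAR}_p = \mathrm{HU}_{L,p} / \mathrm{HU}_{l,p}$ (1.0 = isodense
  = 100%). Washout need only be present in one venous phase, so the
  decision uses $\max(\mathrm{PAR}_{pv}, \mathrm{PAR}_{del}) > 1$,
  strictly. A non-positive lesion mean makes the ratio sign-meaningless and
  is refused.
* **Threshold growth.** Diameter increase of at least 50% within at most 6
  months, interpreted as 183 days. Without a qualifying prior exam the
  result is "no" (not "not evaluable"): an unknown history cannot upgrade a
  lesion. The same-phase/same-plane requirement of the two measurements is
  a declared input; it cannot be verified from a single record.
* **Size.** The maximum axial diameter in the reader-chosen best phase.
  Choosing the arterial phase warns, because arterial sizing tends to
  overestimate.

Ties classify negative at both decision boundaries, and HU values are kept
at full float precision — nothing is rounded before a comparison.

The background liver is the average of two circular 2-cm ROIs, one per
lobe, each on a single axial slice. ROI centres are reader-supplied; the
automatic fallback (two lateral ROIs on a low slice) exists for phantom
volumes whose background is liver everywhere, and is not meant for
clinical images.

## Segmentation

The operator model is the clinical one: click the lesion centre, drag a
sphere to the lesion edge. The sphere is *snug* — its radius is the
largest lesion semi-axis — and it both initialises and bounds the
segmentation:

1. seed statistics: mean $m$ and SD $s$ of HU in a ball of radius
   $\min(5\,\mathrm{mm}, r/2)$ around the centre;
2. 26-connected region growing from the centre, accepting voxels with HU in
   $[m - k s,\; m + k s]$, confined to the sphere; $k = 2.5$ by default and
   exposed as a parameter — masks are nested in $k$;
3. morphological closing (1-voxel ball), hole filling, largest connected
   component.

The procedure is deterministic and suited to homogeneous, well-defined
lesions. Its failure mode is honest: if the grown region has fewer than 10
voxels, a segmentation-failure error is raised rather than a degenerate
mask, and a manual-override mask can be supplied instead. The snug-sphere
convention matters quantitatively: when the lesion-liver contrast is near
$k\sigma$ of the image noise, roughly half the background voxels inside
the sphere fall inside the acceptance band, so a loose sphere (e.g. 1.5
times the lesion radius) dilutes the mask badly, while the snug sphere
keeps the Dice overlap against ground truth above 0.8 even at contrast
$= 2.5\sigma$. On noise-free phantoms the band collapses to the exact
lesion intensity and the segmentation equals the analytic ellipsoid voxel
set.

Diameters follow the clinical caliper: the longest point-to-point distance
within a single axial slice, plus one in-plane voxel extent so a single
voxel has nonzero size; the perpendicular diameter is taken on the same
slice. Volume is voxel count times voxel volume. First-order texture
features (min, max, median, skewness, kurtosis, entropy of a 64-bin
histogram) summarise the HU distribution inside the mask.

## The decision table

`classify_lirads()` implements the v2018 CT table on (APHE, size bin,
count of {capsule, washout, threshold growth}). One cell needs care: for
a 10–19 mm lesion with APHE and exactly one additional feature, capsule
alone gives LR-4 while washout or threshold growth gives LR-5. Ancillary
features shift the category by one step — upgrades are capped at LR-4
(there is no ancillary path to LR-5), opposing ancillary evidence cancels,
and not-evaluable entries never adjust. Not-evaluable *major* features
count as absent: a category should not rise on unevaluable evidence.
LR-1/LR-2 are reachable only through an explicit benign-diagnosis input,
outside the arithmetic path. Every result carries an ordered rationale
trace naming the table cell and any adjustment.

## Agreement statistics

Visual-vs-arithmetic agreement uses the McNemar–Bowker symmetry test
($\chi^2 = \sum_{i<j} (n_{ij}-n_{ji})^2/(n_{ij}+n_{ji})$ over non-empty
pairs), the exact two-sided sign test for paired sizes, and percent
agreement with half-up integer rounding for reporting. No continuity
correction is applied: for the 3-vs-2 discordant washout split at $n=46$
the uncorrected statistic gives $\chi^2 = 0.2$, $p = 0.65$ (reported as
0.7), which the corrected statistic would not reproduce. The uncorrected
statistic is anti-conservative for tiny discordant counts, however: at
splits like 7-vs-1 it rejects at $\alpha = 0.05$ where the exact binomial
test does not. Both routes are exposed, and the test suite prints the
disagreeing splits rather than hiding them. `counts_from_percentages()`
inverts published percentage tables back to counts with a conservation
check, so printed tables can be re-analysed directly.

## The phantom

Published cohorts rarely ship per-patient HU data, so validation rests on
a synthetic four-phase phantom with known truth. The phantom is
deliberately minimal: a uniform liver background with phase-dependent mean
HU (defaults 55/75/110/100 for native/arterial/portal-venous/delayed — no
published background values exist, so these are plausible round numbers),
one axis-aligned ellipsoidal lesion, independent additive Gaussian voxel
noise, and optional enhancing rim and lobulated surface perturbation.
Enhancement is parameterised in exactly the units the arithmetic reads:
the arterial delta, the two venous PARs, a native offset of −10 HU (the
native lesion density is not constrained by any published value; a mildly
hypodense default is typical of HCC). Identical geometry across phases
models perfect co-registration.

Cohort draws (`phantom_cohort()`) use prevalences from the arithmetic arm
of a 46-lesion LR-5 cohort — APHE 45/46, washout 38/46, capsule 9/46,
threshold growth 8/46 — with APHE-positive deltas of 10–50 HU,
washout-positive delayed-phase PARs of 1.05–1.30 (portal-venous PAR may
stay below 1: washout is often confined to the late phase), largest
semi-axes of 7–16 mm spanning the 10–19 mm and ≥20 mm bins, and noise SD
10 HU, typical of abdominal CT. Default cohort volumes are 64×64×48
voxels at 1 mm isotropic — small enough that a 46-lesion cohort runs the
full pipeline in well under a minute, large enough that the lesion mean HU
has a standard error below 0.3 HU.

What the phantom does *not* model: CT reconstruction texture and
correlated noise, beam hardening, respiratory misregistration between
phases, peripheral or heterogeneous enhancement patterns, and infiltrative
lesion margins. Passing phantom tests therefore demonstrates that the
arithmetic, the segmentation logic and the decision table are correct
under the stated noise model — not that segmentation of irregular,
ill-defined clinical lesions will succeed (in the clinical workflow such
cases fail segmentation and are excluded or manually corrected).

## Numerical choices

* Voxel indices are 0-based in physical convention: the coordinate of
  voxel $(i,j,k)$ is $(i,j,k) \times$ spacing, axial slices along the
  third axis.
* The acceptance band carries a $10^{-6}$ HU tolerance so noise-free
  (exact-equality) inputs are stable against float representation.
* Half-up rounding (`floor(x + 0.5)`) is used wherever integer percentages
  are reported, matching how published tables round 86.96% to 87%.
* Morphological closing uses the 6-neighbour cross (the 1-voxel digital
  ball); connectivity is 26 for region growing and components, 6 for hole
  filling.
* The mask is clamped to the 1-voxel-dilated seed sphere after closing, so
  the confinement invariant survives morphology.

## Worked example

```{r example, eval = FALSE}
cfg <- phantom_config(noise_sigma_hu = 10, rng_seed = 42)
ph <- generate_phantom(cfg)
run <- run_pipeline(list(
  study = ph$study, study_id = "demo",
  seed_center_mm = cfg$lesion_center_mm,
  seed_radius_mm = max(cfg$lesion_radii_mm),
  best_phase = "portal_venous"))
run$result     # LR-5 with rationale
cat(run$report)
```

## Known limitations

Mean-density arithmetic cannot see *where* enhancement happens: rim APHE,
peripheral washout and an enhancing capsule are spatial patterns that an
average erases, which is why the capsule remains a manual tristate input
here. The segmentation is a single fixed algorithm, not a reproduction of
any vendor tool; only workflow equivalence is claimed. LR-M, LR-TIV and
treated-lesion categories are out of scope, as are DICOM networking and
MRI features.
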