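---
title: "Methods: models, parameters and design choices in hepatobase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hepatobase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatobase)
```

hepatobase implements a non-invasive protocol for characterizing a healthy
rat liver — indocyanine green (ICG) plasma-clearance kinetics, Doppler-derived
hemodynamic indices, and Hounsfield-unit (HU) threshold volumetry on micro-CT
volumes — together with the reference-interval aggregation needed to turn a
small healthy cohort into baseline values. Healthy baselines matter because
they let later disease-model studies reuse a characterized control population
instead of enlarging every control group (the "reduction" arm of the 3Rs).
Since no raw animal data are distributed with such protocols, the package
ships seeded synthetic generators that reproduce the *statistical structure*
each analysis stage assumes, plus the published per-animal summary tables as
plain data frames, so every stage is testable end to end.

## ICG plasma-clearance kinetics

ICG is cleared from plasma almost exclusively by hepatocytes, so its
disappearance rate indexes hepatic function and perfusion. After a bolus
injection the dye distributes within seconds and then decays exponentially;
in the rat the exponential (elimination) phase spans roughly the first five
minutes, after which clearance decelerates. The package models only the
elimination phase of a one-compartment system with no absorption term:

$$C(t) = C_0 \cdot 10^{-kt},$$

with $C_0$ in µg/mL and $k$ per minute. Three related quantities are
reported:

* **ICG-K** (`fit_icg_k`): the negated least-squares slope of
  $\log_{10} C$ versus $t$ over the exponential window. With exactly two
  usable points the fit reduces algebraically to the two-point formula.
* **retention fraction** $d = 10^{\mathrm{slope}}$ and **decay rate**
  $R = 1 - d$ (`decay_rate`): the fraction of circulating dye remaining,
  respectively removed, per minute.
* **clearance percent** (`clearance_percent`):
  $100\,(1 - C(t)/C(t_{\mathrm{ref}}))$, zero at the reference time by
  construction.

Parameter choices:

* **Logarithm base.** Base 10 throughout. $R$ is invariant to the base used
  in the $d$ formula because the exponentiation and the logarithm cancel;
  the tests assert this identity, so the choice is cosmetic.
* **Window.** Default `c(1, 5)` minutes: the first sample in the protocol is
  drawn at one minute, and decay is exponential only through minute five.
  The window is configurable; including the 10-minute point would mix the
  post-exponential deceleration into the slope.
* **Reference time.** The first sampled time (1 min) by default. Protocol
  descriptions sometimes conflate "time of injection" with the 1-minute
  sample; setting `ref_time`/`t1` to 0 is supported for sensitivity
  analysis.
* **Group summaries.** Whether a published group decay rate was computed on
  the averaged concentrations or averaged over per-subject rates is usually
  ambiguous. `icg_group_summary` returns both; they differ because the mean
  of ratios is not the ratio of means.
* **Detection limit.** Non-positive values (or values at or below a
  configurable limit) cannot be log-transformed; they are dropped with a
  warning, never silently imputed.

A documented irreproducibility: applying the two-point formula to the
published average concentrations (155.99 µg/mL at 1 min, 31.01 at 5 min)
yields $R \approx 0.33$ per minute, not the "approximately 38% per minute"
that accompanies those averages in print. The formula is authoritative here;
the package returns 0.332 and the tests pin that value.

## Doppler waveform features and hemodynamic indices

`detect_cycles` locates systolic peaks by prominence-based peak picking on a
lightly smoothed trace: candidate local maxima are thinned to a minimum
separation of 80% of the shortest plausible cycle (from a configurable
heart-rate band, default 150–500 bpm — brackets anesthetized-rat rates), and
kept when their prominence exceeds 25% of the trace's dynamic range. Cycles
are delimited peak-to-peak, and at least five consecutive cycles are required
before averages are reported, matching standard practice. Per cycle
(`cycle_features`): PSV is the maximum, EDV the minimum *between* successive
systolic peaks (the verbatim field definition, not the pre-peak diastolic
foot), VTI the trapezoidal integral of velocity over the cycle, and
TAV = VTI / cycle duration, so `vti == tav * duration` holds exactly.

Derived indices:

* `resistance_index`: $RI = (PSV - EDV)/PSV$. Published per-animal RI values
  are not exactly recoverable from the published per-animal PSV/EDV (e.g.
  0.59 printed where the formula gives 0.6126), indicating unprinted
  underlying summaries; the package adopts the standard formula and does not
  attempt to reverse-engineer the discrepancy.
* `portal_congestion_index`: portal area / portal average PSV, in
  mm² per (mm/s); rises with portal hypertension.
* `ap_ratio`: hepatic-artery over portal summary velocity. "Average" is
  ambiguous; the default compares PSV to PSV, with TAV/TAV selectable in the
  pipeline configuration.
* `renal_blood_flow`: $HR \times VTI \times \pi r^2 / 1000$ mL/min, with
  $r$ half the averaged caliper diameter. Published per-animal RBF differs
  from this formula on the published (rounded) inputs by up to ~3%,
  consistent with unrounded source data; tests allow 4% there.
* `cardiac_output`: $SV \times HR$ (stroke volume is an input; ventricular
  volumetry from images is out of scope).

Units are kept dimensionally consistent — velocities mm/s, VTI mm, areas
mm², flows mL/min, RI and A/P dimensionless — even where source tables label
indices with mixed units (e.g. "mm²/s" on a dimensionless RI).

## Micro-CT volumetry

`ct_volume` wraps a 3D HU grid with its voxel pitch. Voxel indices in the R
API are 1-based (R convention); world positions use the voxel-center rule
origin + (index − 0.5)·pitch. Conventional HU limits (−1000 air, +1000 dense
bone) are treated as a sanity range: violations warn, they do not error.

* `voi_stats` computes mean/SD attenuation over a cubic volume of interest
  (default side 2 mm, the conventional 8 mm³ VOI), after removing voxels in
  an optional exclusion mask so macroscopic vessels do not bias parenchyma
  statistics. An empty post-exclusion VOI is an error, not a zero.
* `threshold_segment` keeps voxels inside a closed HU window. The
  "3D isocontour" organ-outlining step is operationalized as thresholding
  followed by retention of the largest connected component (26-connectivity
  by default; 6/18/26 configurable), computed in compiled code with a
  breadth-first search and cross-checked in the tests against an independent
  label-propagation oracle. The mean HU of an empty mask is `NA` and
  flagged, never 0.
* `threshold_sweep` varies the **lower** bound (default 0, 50, 100, 120 HU —
  0 HU excludes fat) against a fixed open upper bound (+1000 HU). Published
  descriptions of this sweep state both "upper limit pre-set at 120 HU" and
  mean attenuations above 150 HU at the 120 setting, which a 120 upper bound
  makes impossible; sweeping the lower bound under an open upper bound is
  the only self-consistent reading, and is what the package implements.
  Raising the lower bound can only shrink the mask, so volumes are
  non-increasing and mean HU non-decreasing — both are checked and reported.
* Volume is exact bookkeeping, `n_voxels * pitch^3 / 1000` cm³.

Stated voxel geometries in this protocol family are mutually inconsistent
(0.2 mm³ voxels, 0.125 mm voxel size, 8 mm³ VOIs containing >4,900 voxels —
the latter implies a pitch near 0.117 mm). The package defaults to an
isotropic 0.125 mm pitch (the edge-length reading) and keeps pitch fully
configurable; at that pitch an 8 mm³ VOI holds 4,096 voxels.

## The synthetic world

The generators encode the stated experimental conditions; their defaults are
fixed once and are not tuned against test outcomes.

* **ICG series** (`simulate_icg_series`): noise-free mean
  $C_0 10^{-kt}$, defaults $C_0 = 155.99$ µg/mL and $k = 0.1754$/min (the
  published cohort averages; no injected-dose-to-$C_0$ mapping is published,
  so $C_0$ is a free parameter), sampled at 1/5/10 min. Measurement noise is
  multiplicative lognormal with a stated CV (plate-reader-like,
  mean-unbiased), default CV 0.1 with 3 technical replicates — a realistic
  spectrophotometric plate-reader spread.
* **Velocity traces** (`simulate_velocity_trace`): a raised-cosine systolic
  pulse (width 40% of the cycle) on a flat EDV baseline. The pulse shape is
  not dictated by any source; the raised cosine is differentiable, has an
  unambiguous per-cycle max/min, and an analytic VTI
  ($EDV \cdot T + (PSV-EDV)\,wT/2$) that the trapezoid extraction must
  reproduce to $O(f_s^{-2})$. Defaults use the first animal's hepatic-artery
  truth (PSV 864.37, EDV 424.33 mm/s, HR 331.5 bpm), 2 s at 2 kHz (≥ 11
  pulses), additive Gaussian noise.
* **Liver phantom** (`generate_liver_phantom`): an ellipsoidal parenchyma
  (default semi-axes 5 × 4 × 3.5 mm so a 96³ grid at 0.125 mm pitch holds it
  with margin, keeping default tests around a second) with Gaussian HU about
  135 (the center of the published 134–137 HU hepatocyte range), a thin
  capsule shell drawn uniformly from 150–200 HU, axis-aligned cylindrical
  vessels at 40 HU (blood), spherical fat pockets at −100 HU, air background
  at −1000 HU, and a co-registered label volume for exact ground truth. The
  default per-voxel noise SD of 12 HU reflects the broad parenchyma
  histograms of real micro-CT at this scale: wide enough that each step of
  the 0/50/100/120 sweep removes some voxels (as real sweeps do), narrow
  enough that essentially no parenchyma falls below 0 HU.

What the phantom deliberately is **not**: anatomically realistic lobes,
reconstruction artifacts, beam hardening, partial-volume blur, speckle. A
green phantom test therefore establishes that the *segmentation and
bookkeeping* are correct (volumes exact, sweep monotone, component selection
equal to an independent oracle, recovery within 5%/2 HU at stated noise) —
not that the absolute volumes or attenuations of any real scan are
reproduced. Published whole-liver sweep values (volumes 21.08 → 13.67 cm³,
attenuation 113.51 → 151.67 HU) come from real scans and are used only as
the qualitative monotone pattern the sweep must exhibit.

## Reference intervals

`reference_interval` reports n, mean, SD, median and range. The SD uses the
$n-1$ denominator (this reproduces the published weekly weight SDs, e.g.
370.68 ± 29.39 g). With cohorts of six animals these are descriptive
summaries: no parametric 95% reference limits are computed, and formal
reference-interval methodology (CLSI EP28-style) is out of scope. Weight
gain is percent change against the previous measurement, and final gain
percent change from first to last week — at the group level applied to the
mean weights. `flag_against_interval` compares strictly against ordered
bounds with boundary values reported "within". Exclusion rules
(`apply_exclusions`) flag analyte-weeks with a reason (e.g. discarding early
prothrombin determinations after a laboratory handling problem) and excluded
or censored entries never enter summaries; below-detection-limit analytes
(no limit value published) are carried as censored rather than imputed.

Known source inconsistencies handled in the bundled tables: one animal's
printed week-3/4 gain percentages disagree with its own printed weights (the
formula values are used); the printed week-3 mean weight disagrees by 0.33 g
with the mean of the printed per-animal weights; a narrative "7.48%" gain
conflicts with the tabulated 7.88 (the table wins).

## Pipeline, I/O and numerical conventions

Long-format CSV is the canonical tabular interchange (one value per row;
schemas validated with line-numbered errors, duplicate keys rejected).
Volumes travel as single-file NIfTI-1; because no NIfTI package could be
assumed in the runtime environment, a minimal int16/float NIfTI-1
reader/writer (both endiannesses on read) is built in, with bitwise
round-trip tests. `run_pipeline` validates its configuration against a
closed schema before any computation (unknown keys are errors), executes the
selected stages, and writes per-stage CSVs at full precision, a Markdown
report rounded to 2 decimals, and a manifest (seed, config, config hash,
versions) sufficient to reproduce any output; identical config and seed
yield byte-identical CSVs. All numeric output uses period decimal
separators regardless of locale.

## Limitations

* The ICG simulator omits the distribution phase entirely; fits that
  include samples earlier than ~1 min in real data would see distribution
  kinetics the model does not represent.
* Cycle detection assumes a dominant systolic peak per cycle; heavily
  multiphasic venous spectra (e.g. caval waveforms) would need a dedicated
  detector.
* The phantom's capsule is a geometric shell on an ellipsoid; capsule
  thickness below one voxel pitch is unresolvable and warned about.
* Published per-animal RI/AP/RBF values embed unprinted intermediate
  summaries and are reproduced only approximately, as documented above.
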