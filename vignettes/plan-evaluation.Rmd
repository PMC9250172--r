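---
title: "Dosimetric evaluation of single-isocenter multi-target SRS plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetric evaluation of single-isocenter multi-target SRS plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsdosim)
```

## The problem

Stereotactic radiosurgery (SRS) of multiple brain metastases from a single
isocenter trades delivery efficiency against dose spill into normal brain.
Plan quality is judged on a small set of dose-volume metrics: how
conformal the prescription isodose is to each target, how fast dose falls
off outside it, and how much healthy brain is exposed to intermediate
doses. The volume of healthy brain receiving at least 12 Gy (V12Gy) is the
standard surrogate for radionecrosis risk after single-fraction SRS, and
the clinically interesting comparisons are paired: the same patient
planned with two techniques that differ in falloff steepness and low-dose
bath.

`srsdosim` implements this evaluation end to end on voxel dose grids:
structure handling, the dosimetric indices, a clinical plan-acceptance
policy, paired cohort statistics, and a synthetic cohort generator with
analytically controlled gradients so that the whole pipeline can be
validated against closed-form oracles without any patient data.

## Indices and metrics

All metrics are computed on a regular voxel grid by exact voxel counting,
with voxel membership decided by the voxel-center test. "Volume receiving
at least x Gy" uses the closed threshold `dose >= x`: for continuous dose
fields the boundary has measure zero, and the convention keeps the DVH and
all V_xGy metrics consistent with each other.

* **Coverage**: percentage of PTV volume with dose at or above the
  prescription (PD). The policy requires at least 98% per PTV.
* **Paddick conformity index**:
  CI = (V_PI,PTV / V_PTV) x (V_PI,PTV / V_PI), where V_PI is the volume
  covered by 100% of PD, and V_PI,PTV its intersection with the PTV. The
  first factor is coverage, the second selectivity; CI = 1 exactly when
  the prescription isodose voxel set equals the PTV.
* **Gradient index**: GI = V_50% / V_PI, both counted over the whole grid
  (the definition carries no structure restriction). A step dose gives
  exactly 1; GI >= 1 always.
* **Healthy brain**: brain minus the union of GTVs (not PTVs). Mean dose
  and V5/V8/V10/V12Gy are reported on it. A PTV-based variant is a
  one-line change (`mask_subtract` with the PTV union) but is not the
  default because the GTV-based definition is the one the V12Gy
  radionecrosis literature uses.
* **V12Gy clusters**: the supra-threshold healthy-brain voxels are
  decomposed into 26-connected components, each assigned to every GTV
  whose immediate neighborhood touches it. Shells of adjacent lesions
  that bridge merge into one cluster tagged with all its GTVs; cluster
  volumes always sum to total V12 (partition property, tested).
  26-connectivity is the default because isodose shells are thin and
  frequently diagonal-connected.
* **D2%**: computed by exact voxel sorting (the dose such that at least
  2% of the structure receives it), not from an interpolated histogram;
  this makes results grid-exact and reproducible across bin choices.

### Multi-target plans

For plans with several targets and possibly different prescriptions
(18 vs 20 Gy) there is no universal convention for a single per-plan CI
and GI. The package reports per-target values and aggregates as follows:
each voxel is attributed to its nearest target (PTV centroid distance, the
only isocenter-free choice); per-target CI counts V_PI inside that cell at
the target's own prescription; the plan CI is the PTV-volume-weighted mean
of per-target CIs; the plan GI is the ratio of summed local V_50% to
summed local V_PI, which reduces to the plain global ratio when all
targets share one prescription. PTVs closer than 5 mm are merged into a
single target first (transitive closure of the pairwise relation — a chain
of close targets becomes one structure), mirroring the clinical practice
of merging adjacent PTVs to keep the bridged maximum dose under control; a
merged PTV takes the maximum prescription of its members.

### Acceptance policy

`check_policy()` applies the clinical acceptance rules: per-PTV coverage
>= 98%; per-PTV D2% < 130% of PD as a soft (warning) limit; D2% of the
cumulative PTV <= 135% of PD as a hard (rejection) limit; and maximum
doses of 12, 8 and 2 Gy to brainstem, optic apparatus and lens. The
two-tier D2% rule means a plan can warn without being rejected; all limits
are parameters of `policy_limits()`.

## Geometry

Margin expansion (`expand_margin`) is implemented as Euclidean-ball
dilation on physical coordinates — exact for anisotropic spacing and
identical to the standard distance-transform approach (verified against
`scipy.ndimage.distance_transform_edt` on shared fixtures). One numerical
property deserves emphasis: a binary mask samples its structure at voxel
centers, whose outermost layer sits on average ~0.3 x spacing inside the
continuous surface, and at margins comparable to the spacing the lattice
offers no offsets between 1.0 and sqrt(2) times the spacing. Binary
margin expansion therefore *underestimates* the continuous Minkowski
volume by roughly 5-15% for millimetre-scale structures at 1 mm spacing,
for any standard algorithm. The tests pin the operation to its exact
brute-force distance oracle instead of to continuous volumes, and the
synthetic generator sidesteps the bias entirely by rasterizing PTVs from
the analytic lesion geometry (sphere of radius r + margin), which is the
exact continuous expansion — the route clinical systems take when they
expand contours rather than masks.

Surface distance between structures is the minimum distance between
boundary voxel centers (0 when masks share a voxel); it drives both the
5 mm PTV merging rule and the "lesion within 5 mm of hippocampus"
subgroup flag.

## The synthetic cohort

The generator emulates a 36-patient single-isocenter multi-met series:

| parameter | default | rationale |
|---|---|---|
| lesions per patient | lognormal(log 9, 0.55), rounded, in [2, 25] | median ~9, roughly balanced 2–10 vs >10 strata |
| GTV volume | lognormal(log 0.16, 0.45) cm^3, in [0.07, 2.1] | per-lesion median 0.16 cm^3; totals ~1.3-1.5 cm^3 |
| prescription | 20 Gy (18 Gy with probability 11/367) | single-fraction multi-met convention |
| GTV->PTV margin | 1 mm | standard setup-uncertainty margin |
| PTV merging | < 5 mm surface distance | clinical close-target rule |
| near-hippocampus patients | 1 in 6 | proximity subgroup; controlled, see below |
| brain | ellipsoid, ~1400 cm^3 | adult brain volume |

Lesions are placed uniformly in the (eroded) brain with center separation
at least the sum of the two PTV radii — so PTVs may just touch, which
keeps both regimes (isolated and bridged/merged) represented — and with
clearance from brainstem, optic apparatus and lens scaled to the expected
12 Gy shell radius, because clinical plans meet those OAR maxima by
construction. The "<5 mm from hippocampus" subgroup is a controlled
parameter: one forced lesion per flagged patient is seeded just outside a
hippocampus, and all other lesions keep clearance beyond the proximity
band, so the subgroup size tracks the configured fraction rather than the
geometry of uniform placement.

### The dose kernel

Each lesion contributes a radially symmetric kernel: a linear peak inside
the target radius R (hot ratio x PD at the center, PD at R), a power law
PD (R/r)^k outside, and an exponential taper (scale 8 mm) beyond 1.25x
the half-prescription radius R 2^(1/k). The power-law region fixes the
isolated-target gradient index in closed form — GI = 2^(3/k), because the
50% isodose sits at exactly R 2^(1/k), inside the untapered region — which
is what makes the generator a genuine oracle for the dosimetry module.
The far-field taper models the fast distal falloff of real beam
arrangements; without it, superposed power-law tails of 10-25 lesions
flood the brain with mid-range dose (mean brain doses near half the
prescription), which no clinical plan shows. Plans are composed by
summation over lesions (superposition), which reproduces dose bridging
between adjacent targets — the central mechanism that inflates V12Gy in
many-lesion plans — plus a technique-specific low-dose bath
`bath_fraction x PD x exp(-d/50 mm)` centered on the isocenter.

The two default techniques are calibrated so their isolated-target GIs
bracket the values reported for clinical DCAT vs VMAT multi-met plans:

* steep arm ("DCAT-like"): k = 1.383 (GI 4.50), hot ratio 1.20, bath 4% of PD;
* shallow arm ("VMAT-like"): k = 1.207 (GI 5.60), hot ratio 1.22, bath 10% of PD.

Both arms of a patient share anatomy and lesions exactly; only the kernel
differs. Per-lesion distance fields are computed once and reused across
arms.

### What the generator does and does not emulate

It reproduces the cohort structure (lesion counts, volumes, pairing), the
gradient/bath contrast between techniques, dose bridging, and the
resulting ordering and rough magnitude of V5-V12Gy and hippocampal doses.
It does not model arc geometry, MLC apertures, tissue heterogeneity, or
anatomically realistic lesion locations (placement is uniform; real
metastases favor the gray-white junction of the lobes). Superposition
also exaggerates target hot spots when lesions are close enough to merge:
part of the synthetic cohort legitimately fails the cumulative-D2% policy
rule, which mirrors the clinical difficulty that motivated PTV merging
but means policy pass rates should not be read as calibrated to clinic
rates. Passing tests therefore validate the *evaluation pipeline* and
the *direction and stratification* of technique effects, not absolute
agreement with any clinical series.

## Statistics

The paired comparison uses the two-tailed Wilcoxon signed-rank test as
implemented in `wilcoxon_signed_rank()`: zero differences discarded
(Wilcoxon's original treatment), midranks for ties, exact p by full
enumeration of the 2^n sign assignments for effective n <= 12 (valid in
the presence of midrank ties, where the classical exact tables are not),
and the tie-corrected normal approximation with continuity correction
otherwise. The exact path is pinned in tests to an independent
enumeration oracle and, on tie-free data, to `stats::wilcox.test`. The
measured worst-case gap between exact and approximate p over random
paired normal samples at n = 10-12 is 0.017, so the approximation is fine
for screening but the exact path is used whenever it applies.

Percent differences are reported as 100 (b - a)/b with the
shallow-gradient arm b as denominator, matching the convention "arm a
achieves an x% reduction". Stratification uses <= 10 vs > 10 lesions (the
minimum lesion count is 2, so "1-10" and "2-10" coincide) and a 2 cm^3
total-GTV threshold for the small-volume many-lesion subgroup. The
significance threshold is 0.05 with no multiplicity correction, matching
common clinical-dosimetry practice; all p-values are reported, so any
correction can be applied downstream.

## Problem sizes and runtimes

Single-target oracle checks run at 1 mm spacing (with a 0.5 mm refinement
for the kernel-GI convergence check, which tightens from within 5% to
within 2% of 2^(3/k)). Cohort-scale analyses and tests run the generator
at 2 mm spacing, the package's chosen simulation scale: a 36-patient
paired cohort evaluates in about a minute, and the V-metric headline
(paired V5-V12Gy comparison and its lesion-count stratification) is
checked across 20 independent seeds. The qualitative conclusions are
unchanged at 1 mm; only the per-lesion shell volumes carry coarser
quantization at 2 mm.

## Known limitations

* Binary-mask margin expansion underestimates continuous expanded volumes
  at margins comparable to the voxel spacing (see Geometry); use contour
  or analytic geometry when sub-voxel accuracy matters.
* The per-plan CI/GI aggregation for multi-target plans is a convention
  (nearest-target attribution, volume weighting); per-target values are
  always reported alongside.
* The generator's policy pass rate is not calibrated; superposition
  inflates bridged hot spots relative to a replanned merged target.
* DICOM-RT import is not provided; volumes are exchanged as NIfTI with
  JSON sidecars (explicit spacing, no affine ambiguity on the axis-aligned
  grids used here).
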