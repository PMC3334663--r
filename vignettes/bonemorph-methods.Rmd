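---
title: "Quantifying subchondral bone architecture: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subchondral bone architecture: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonemorph)
```

## Scope and model system

`bonemorph` quantifies subchondral bone architecture in in-vivo micro-CT of
the rodent knee, for longitudinal paired-limb designs such as the low-dose
monosodium iodoacetate (MIA) osteoarthritis model: one knee receives the
insult, the contralateral knee serves as the within-animal control, and both
are imaged repeatedly (here: 2, 6 and 10 weeks). The package covers the
computational chain only — segmentation, volumes of interest, 3D
morphometry, subchondral plate metrics and the paired inferential recipe.
Scanner physics and reconstruction are out of scope; the input is a
reconstructed 8-bit image stack with isotropic voxel spacing (the default
geometry is 8.7 µm voxels, 1,800-slice stacks, 52-slice analysis windows
spanning 0.45 mm).

Because no scan data ship with the package, every stage is validated on
synthetic phantoms with analytic ground truth and on simulated cohorts whose
group means and SDs follow the published study tables.

## Segmentation

Bone is segmented with one uniform global threshold (`apply_threshold`); the
bone rule is `intensity >= t`, fixed so results are bit-exact. A study-wide
threshold — either user-fixed or chosen once on a designated calibration
volume by `suggest_threshold` (the split maximising between-class variance of
the pooled 3D histogram) — is reused across all limbs and timepoints for
longitudinal comparability. `suggest_threshold` deliberately pools the whole
volume histogram rather than thresholding per slice: a per-slice choice
would make the longitudinal series incomparable. Optional `despeckle`
removes 26-connected bone islands and fills 6-connected marrow cavities
below a size cutoff (the standard complementary connectivity pair); it is
disabled by default.

## Volumes of interest

VOIs are stacks of per-slice polygons (medial and lateral compartments, kept
disjoint; total is their union). Rasterisation uses 0-based voxel-centred
coordinates and includes a voxel when its centre is inside *or on* the
polygon boundary — the even-odd rule with explicit on-segment handling —
so a square drawn from (0,0) to (9,9) contains exactly 100 voxels at any
resampling. The axial placement of the window (e.g. "starting below the
subchondral plate") is deliberately user input (`voi_window`): the original
protocol drew it manually against anatomical landmarks that a mask alone
cannot supply. Exclusion of cortical bone and the growth-plate interface is
likewise the ROI author's responsibility, mirroring the manual protocol.

## Direct-3D thickness

Tb.Th, Tb.Sp and Pl.Th use the maximal-sphere (direct) method: the local
thickness at a voxel is the diameter of the largest sphere fully contained
in the domain that covers the voxel. The implementation (in C++) computes
the exact Euclidean distance transform (Felzenszwalb–Huttenlocher separable
algorithm), prunes to the distance ridge (spheres contained in a
neighbour's sphere are dropped), and propagates spheres largest-first.

Numerical conventions, fixed so tests are reproducible:

* Thickness is `2 × EDT`, with EDT the distance from a domain-voxel centre
  to the nearest non-domain voxel centre. Phantoms rasterise solids by
  strict-interior centre inclusion, under which slab and rod thickness is
  recovered exactly at integer voxel multiples. The floor of the map is
  `2 × spacing` — an isolated voxel reports that value.
* The image border always bounds the fitted spheres. For bone this treats
  out-of-field space as marrow (conservative: structures touching the border
  are not artificially thickened); for the marrow domain it acts as a hard
  wall (separation never extends out of field). Consequently voxels near
  field corners are slightly under-estimated; means should be taken over a
  VOI clear of the corners when exact values matter.
* Tb.Th is the volume-weighted (arithmetic) mean over bone voxels in the
  VOI; Tb.Sp is the same over `VOI \ bone`.
* Tb.N is derived as `(BV/TV)/Tb.Th` with explicit unit conversion
  (fraction over millimetres), per animal — group Tb.N is the mean of
  per-animal ratios, not the ratio of group means, since the latter does
  not always reproduce a table computed per animal.

All internal lengths are micrometres; BV/TV is a percent; Tb.N is 1/mm.

## Subchondral plate

The plate is separated from trabecular bone by a column scan
(`separate_plate`): within the analysis region, each in-plane column is
scanned from the articular (low-z) side; the plate runs from the first bone
voxel to the first marrow gap longer than `gap_bridge` (default 52.2 µm,
six voxels — a declared assumption, since the referenced separation software
has no published algorithm). Shorter gaps are intra-plate pores and are
bridged. The plate normal is assumed parallel to z within the small
analysis rectangles (1.5 mm medio-lateral × 2.5 mm antero-posterior,
anchored at the posterior edge of the compartment bounding box and
user-adjustable).

Pl.Th is the direct-3D mean thickness over plate voxels (pores excluded
from the domain by construction). Pl.Por is pore volume over total plate
envelope volume, where the envelope spans each column from first to last
plate voxel. Columns with no plate bone belong to the envelope only when
they are enclosed by plate-bearing columns on all four in-plane sides:
drilled through-pores are interior holes and must count as pore volume,
while no-bone columns outside the plate footprint must not. Enclosed
no-bone columns take the median span of the plate-bearing columns, which is
exact for the flat plates analysed here and approximate for strongly tilted
plates — a known limitation. Total-compartment plate values are the
arithmetic mean of medial and lateral.

One caveat worth knowing: the column scan will classify bone under a
through-pore as plate (the first bone it meets in that column lies below
the pore). On real anatomy this is a sub-voxel-fraction effect; phantom
validation of the separation therefore uses pore-free geometry, and
porosity is validated directly on drilled plate volumes.

## Phantoms: what they do and do not show

* `make_slab_phantom` — parallel slabs; analytic Tb.Th, Tb.Sp, BV/TV.
* `make_rod_phantom` — square lattice of z-aligned cylinders centred on
  voxel centres; analytic Tb.Th and (pre-discretisation) BV/TV. The
  maximal-sphere separation of this geometry is the diagonal pore diameter
  `√2·pitch − 2·radius`, not `pitch − 2·radius`.
* `make_grf_phantom` — Gaussian random field (white noise smoothed with a
  Gaussian kernel of σ = correlation length) thresholded at the empirical
  quantile, so the achieved BV/TV is exact to one voxel regardless of kernel
  normalisation.
* `make_subchondral_phantom` — solid plate with drilled cylindrical
  through-pores (pixel-exact pore fraction) over a rod compartment, with a
  blurred noisy grayscale rendition for segmentation tests.

These phantoms validate geometry recovery, not biology: real trabecular
bone is anisotropic, rough-surfaced and partial-volume-blurred, and real
plates are curved. Passing phantom tests shows the estimators are correct
on known geometry within one voxel; accuracy on tissue remains bounded by
segmentation quality and resolution.

## Cohort simulation

`simulate_cohort` draws one value per animal × limb × timepoint × parameter
from the design's cell means and SDs with a shared per-animal Gaussian
effect: `value = µ + σ(√ρ·aᵢ + √(1−ρ)·ε)`. This is the simplest model that
makes paired tests more powerful than unpaired ones, matching the paired
design. The inter-limb correlation ρ defaults to 0.7 — a stated assumption,
not a published estimate. Growth over time is encoded purely by
per-timepoint means (the study reports only per-timepoint summaries, so a
parametric growth curve would add unsupported structure).
`mia_table_design()` carries the published group means/SDs for the five
trabecular parameters and plate thickness; plate porosity is omitted
because the source table prints only its percent differences.

## Inference

The recipe mirrors the published analysis:

1. Shapiro–Wilk screening per parameter (`check_normality`).
2. Two-way repeated-measures ANOVA (`rm_anova`), both factors
   within-subject, computed directly from cell and marginal means; each
   effect is tested against its own subject-interaction error term.
   Sphericity is uncorrected by default (the source is silent);
   Greenhouse–Geisser is available via `gg = TRUE`.
3. Paired t-tests per timepoint (`paired_tests`), gated on the ANOVA: the
   default gate `"any"` runs them when any ANOVA effect is significant,
   which reproduces a table that reports comparisons for every parameter
   (the time effect was significant throughout); `"interaction"` is
   stricter, `"none"` is for simulation studies.
4. Holm stepdown adjustment (`holm_adjust`), with the family defined as the
   timepoint comparisons within one parameter × compartment — matching the
   repeated-over-time structure; the family policy is configurable.
   Between-timepoint within-limb tests (`timepoint_tests`) use one family
   per parameter × compartment × limb.

Degenerate cases are explicit: zero-variance differences give p = 1 when
all differences are zero and p = 0 otherwise; single-animal datasets are
refused; incomplete pairings are reported with the offending animals.

## Problem sizes and tolerances used in validation

The test suite recovers phantom truth at 128-voxel-scale volumes (about
1.1 mm cubes at 8.7 µm) with thickness/separation asserted within one voxel
and volume fractions within 0.5 percentage points; Monte-Carlo calibration
uses 500 replicate cohorts of 12 animals for type-I error (0.05 ± 0.02) and
power (> 0.8 for the published 2-week total Tb.Sp effect under ρ = 0.7);
the Holm implementation is checked against `stats::p.adjust` on every
sorted p-vector of length ≤ 4 over a 0.01 grid plus random permutations.
These sizes keep the full suite in the minutes range on one CPU while
leaving the discretisation error of the thickness estimators clearly below
the asserted tolerances.

## Known limitations

* The column-scan plate separation assumes the articular surface faces the
  low-z slices and the plate normal is near-axial within the analysis
  rectangle.
* Thickness values carry the `2 × EDT` voxel-centre convention; comparing
  against tools with a different convention can shift values by up to one
  voxel.
* No adaptive thresholding, no beam-hardening correction, no atlas
  registration; ROI placement is manual by design.
* Structure model index, connectivity density and anisotropy are not
  computed.
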