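# bonemorph

Subchondral bone morphometry from small-animal micro-CT, for longitudinal
paired-limb osteoarthritis studies.

In rodent models of osteoarthritis — such as a single low-dose intra-articular
monosodium iodoacetate (MIA) injection with the contralateral saline knee as
within-animal control — the disease remodels the bone directly beneath the
joint surface: early trabecular loss, later sclerosis, and thickening and
perforation of the subchondral plate. In-vivo micro-CT can track these
changes in the same animal over weeks, provided the image analysis is fixed
and reproducible across limbs and timepoints. `bonemorph` implements that
analysis chain:

- **Segmentation** — one uniform global threshold for the whole study
  (`apply_threshold`, `suggest_threshold`), bone rule `intensity ≥ t`.
- **Volumes of interest** — stacked per-slice polygon ROIs for the medial and
  lateral tibial compartments, rasterised with a voxel-centre inclusion rule
  (`rasterize_voi`, `voi_window`); e.g. 52 slices at 8.7 µm span
  `voi_height(52, 8.7) = 0.45` mm.
- **Trabecular morphometry** — BV (mm³), BV/TV (%), and direct-3D
  Tb.Th/Tb.Sp (µm) by maximal-sphere local thickness (exact Euclidean
  distance transform, distance ridge, sphere propagation, in C++), with
  Tb.N = (BV/TV)/Tb.Th in 1/mm (`compute_morphometry`).
- **Subchondral plate** — column-scan separation of plate from trabeculae
  with gap bridging (`separate_plate`), plate thickness Pl.Th (µm) and
  porosity Pl.Por (%) per compartment, total = mean(medial, lateral)
  (`plate_thickness`, `plate_porosity`, `total_compartment`).
- **Phantoms & cohorts** — slab, rod, Gaussian-random-field and
  plate-over-rods generators with analytic ground truth
  (`make_slab_phantom`, …), and paired-limb cohort simulation from published
  group means/SDs (`mia_table_design`, `simulate_cohort`).
- **Inference** — Shapiro–Wilk screening, two-way repeated-measures ANOVA
  (time × limb, both within-subject), ANOVA-gated paired t-tests per
  timepoint, Holm stepdown adjustment, percent differences, and
  publication-style summary tables (`rm_anova`, `paired_tests`,
  `holm_adjust`, `build_tables`, `run_study`).

## Worked example

Generate a known subchondral geometry (a 104.4 µm plate over a rod lattice),
segment its noisy grayscale rendition, and quantify:

```r
library(bonemorph)

ph   <- make_subchondral_phantom(104.4, 0, 8.7, dims = c(60L, 60L, 72L), seed = 1)
thr  <- suggest_threshold(ph$gray)       # 105
mask <- apply_threshold(ph$gray, thr)

med <- array(FALSE, dim(mask$voxels)); med[1:30,  , 41:60] <- TRUE
lat <- array(FALSE, dim(mask$voxels)); lat[31:60, , 41:60] <- TRUE
compute_morphometry(mask, list(medial = voi_mask(med, "medial", 8.7),
                               lateral = voi_mask(lat, "lateral", 8.7)))
#> Trabecular morphometry (direct 3D)
#>  compartment   bv_mm3  tv_mm3 bvtv_pct tbth_um tbsp_um tbn_per_mm
#>       medial 0.003912 0.02371    16.50      87   117.9      1.897
#>      lateral 0.004267 0.02371    18.00      87   117.5      2.069
#>        total 0.008179 0.04741    17.25      87   118.1      1.983
#> threshold: 105

sep <- separate_plate(mask, gap_bridge_um = 52.2)
plate_thickness(sep$plate)               # 103.3 um  (construction: 104.4)
```

The VOI sits in the rod compartment, so Tb.Th recovers the 87 µm rod
diameter exactly and BV/TV the lattice fill fraction; the plate thickness is
recovered within one voxel (8.7 µm). A plate drilled with 20 % through-pores
reports `plate_porosity` of exactly `20`.

Simulating the published 12-animal cohort and running the full recipe:

```r
st  <- run_study(run_config(seed = 1, out_dir = "out"))
top <- st$tables$comparisons_rounded
top[top$parameter == "Tb.Sp" & top$compartment == "total", ]
#>  parameter compartment week mia_mean mia_sd ctl_mean ctl_sd pct_diff p_raw p_holm significant
#>      Tb.Sp       total    2      273     11      253     20      7.7 0.001  0.001        TRUE
#>      Tb.Sp       total    6      253     15      218     18     15.8 0.000  0.000        TRUE
#>      Tb.Sp       total   10      249     25      220     18     13.2 0.000  0.000        TRUE
```

Each row is one timepoint's paired MIA-vs-control comparison: group means ±
SD, the percent difference `100·(OA − CTL)/CTL`, and raw and Holm-adjusted
paired-t p-values (adjusted within the parameter × compartment family,
α = 0.05). The elevated trabecular separation in the MIA limb at every
timepoint mirrors the design the cohort was simulated from.

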