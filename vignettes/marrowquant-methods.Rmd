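---
title: "Quantifying myeloma bone-marrow involvement from CT and FDG-PET: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myeloma bone-marrow involvement from CT and FDG-PET: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowquant)
```

## The problem

In healthy adults the medullary cavities of the long bones contain fatty
marrow, which on CT attenuates between about −200 and −30 Hounsfield units
(HU). Plasma-cell infiltration in multiple myeloma replaces adipocytes with
cellular tissue and raises attenuation into the −30 to 120 HU range;
cortical bone lies above 120 HU. Low-dose CT acquired as part of a routine
[18F]FDG PET/CT therefore carries a quantifiable signal of marrow
involvement in the appendicular skeleton, at no extra dose. `marrowquant`
implements two CT statistics built on these bands, the standard PET
uptake metrics read alongside them, the IMPeTUs rule-based scoring used for
structured PET reporting in myeloma, threshold-based whole-skeleton MTV/TLG,
and the nonparametric statistics used to relate all of these to clinical
covariates — together with a synthetic phantom generator that provides
ground truth for validation, since clinical trial images of this kind are
generally not publicly deposited.

## CT statistics

**Tissue classification.** `classify_voxel()` partitions finite HU into
`fat_marrow` [−200, −30], `infiltrated` (−30, 120], `cortical` (120, ∞) and
`out_of_range` (−∞, −200). The literature states the bands without boundary
semantics; the half-open convention here is a design choice that guarantees
every value belongs to exactly one class, and the boundary values −200, −30
and 120 are pinned by explicit tests.

**Manual CTv.** Clinically, readers place circular ROIs over high-density
marrow and record the highest ROI-mean HU. Human placement is not
reproducible, so `manual_ctv()` replaces it with an exhaustive sweep:
axial-disc (or spherical) ROIs of each candidate radius (default 3–6 mm)
are centered on every working-mask voxel, ROIs not fully contained in the
mask are discarded, and the maximum ROI-mean is returned with its center
and radius. This is a deterministic surrogate that upper-bounds a reader's
value. Ties are broken by lowest (z, y, x) center index, then smaller
radius, so results are reproducible to the bit.

**Semi-automated cCTv.** The working volume is the medullary cavity minus
epiphyses minus any voxel above 120 HU (`medullary_working_mask()`; the
cavity voxel at exactly 120 HU is kept, the exclusion is strict). Voxels in
the infiltrated band form the myeloma (MM) compartment. The published
formula — "cumulative voxel HU × total volume of MM / total volume of BM
cavity" — is dimensionally inconsistent as printed: an HU-sum times a
volume ratio does not carry HU units at the reported ~5 HU magnitude. The
default interpretation implemented here is

$$\mathrm{cCTv} = \frac{\left(\sum_{v \in MM} \mathrm{HU}_v\right) \cdot V_{voxel}}{V_{cavity}} = \overline{\mathrm{HU}}_{MM} \cdot \frac{V_{MM}}{V_{cavity}},$$

which has HU units and reproduces the reported magnitude; the literal
product reading is available via `interpretation = "literal"`. On a
noise-free phantom with constant lesion HU $\mu$ and infiltrated fraction
$f$ this identity gives $\mathrm{cCTv} = \mu f$ exactly, which is the basis
of the recovery tests. Voxels in the fat band contribute zero to the sum by
construction. cCTv is computed over whatever working mask is supplied —
pooling voxels across bones (pass the union) or per bone (pass each mask)
is the caller's choice; the pipeline pools.

## PET metrics

`compute_suv()` applies body-weight SUV normalization
($\mathrm{SUV} = C / (D/W)$, concentration in kBq/ml, dose in MBq, weight
in kg); decay correction is assumed upstream, and lean-body-mass variants
are out of scope. `voi_stats()` reports exact SUVmax/mean/median and VOI
volume. Masks defined on the CT lattice are carried to the PET lattice by
`resample_mask()` using nearest-neighbor lookup in world coordinates —
labels are never interpolated — and the transfer is idempotent on matching
grids.

## IMPeTUs scoring

`deauville()` grades target uptake on the five-point scale against
mediastinal blood pool (M) and liver (L) SUVmean. Two readings required
decisions:

* the published wording leaves the interval $(L, 1.1L]$ unassigned (score 3
  stops at the liver, score 4 starts above liver + 10%). The default scores
  this gap 3 — conservative, since score 4 then strictly requires exceeding
  liver + 10% — and `gap_score = 4` overrides it;
* "score 5: well above liver (twice)" is operationalized as $t > 2L$, with
  score 4 capped at $2L$ — the only quantitative reading available;
* "score 1: no uptake at all" has no printed threshold; it is
  operationalized as target ≤ background-VOI mean when a background VOI is
  supplied, else target exactly 0;
* the comparison statistic is target SUVmax against reference SUVmean
  (common reading practice; configurable via `target_stat`).

Focal (Fx) and lytic (Lx) lesion counts band at 0 / 1–3 / 4–10 / >10.
Lesion detection itself is a visual task and out of scope: counts and the
PMD/EMD/fracture flags are inputs (or phantom ground truth).
`impetus_report()` assembles the items, enforces that a hottest-lesion
score is present exactly when focal lesions are, and round-trips through a
versioned JSON schema.

## MTV and TLG

The automated whole-skeleton pipeline replaces its upstream CNN organ
segmentation with mask inputs (no trained weights are shipped; phantom
masks serve as ground truth). `skeletal_working_mask()` removes the skull
and then erodes by a configurable ball radius (default 2 mm) as a surrogate
for the unspecified spillover-mitigation step — PET's limited resolution
smears adjacent activity into the bone mask, and erosion trims the
vulnerable shell. `mm_threshold()` is the liver SUVmedian;
`segment_and_quantify()` counts working-mask voxels with SUV ≥ threshold
(inclusive, per the stated rule), giving MTV in ml and
TLG = SUVmean × MTV in g. The TLG identity, threshold monotonicity and
inclusivity are property-tested.

## Cohort statistics

Spearman correlation, Wilcoxon rank-sum, Wilcoxon signed-rank,
Kruskal–Wallis, Pearson chi-square and Cohen's kappa wrap base R's
implementations behind a uniform `stat_result` row, with these conventions:
midranks for ties; exact p-values for rank tests up to n = 25 and
tie-corrected normal/chi-square approximations beyond; for the signed-rank
test an exact sign-flip null is computed by dynamic programming over
doubled midranks, because the stock exact path refuses tied absolute
differences; pairwise deletion of missing data with the used n reported; no
multiplicity adjustment (mirroring descriptive-study practice); paired
baseline/follow-up contrasts use the signed-rank test, since pairing by
patient must be respected even though only the rank-sum test is named for
two-group settings in the source methodology. Every test is checked against
independent enumeration or hand-formula oracles on tiny inputs, and each
holds its nominal 5% size within the binomial 99% band over 1000 null
replicates.

## The phantom generator: what it emulates, and what it does not

`make_ct_phantom()` builds an idealized long bone: a cylindrical cortical
shell (default 1000 HU) around a medullary cavity on a configurable grid,
with epiphyseal segments occupying a stated fraction of bone length at each
end (default 0.15 — the anatomical boundary is nowhere defined in the
source methodology, so a length fraction is the honest parameterization).
Cavity voxels receive fatty-marrow HU (normal, clamped to the fat band);
an exactly-counted subset of `round(f · N)` voxels receives
infiltrated-band HU. Patterns: `diffuse` scatters the subset uniformly,
`focal` grows spherical lesions from random seeds to the target count,
`mixed` splits the budget. Exact-count sampling (rather than voxelwise
Bernoulli) was chosen so that noise-free recovery tests are exact
identities; the realized fraction differs from the requested one by less
than $1/N$.

`make_pet_phantom()` adds the uptake model: uniform background, liver and
mediastinal reference boxes placed away from the bone, a high-uptake skull
region standing in for brain activity, and marrow SUV = background +
slope × (infiltration indicator) + noise. Defaults (liver ≈ 2.3, blood pool
1.5, background 0.8, infiltrated marrow ≈ 5.8) sit in clinically familiar
SUV ranges.

`make_cohort()` plants the statistical structure the analysis assumes:
baseline infiltration ~ Beta(3, 7) (median ≈ 0.29), follow-up infiltration
= baseline × (1 − treatment_effect) with a default effect of 0.8 — chosen
so the induction-scale simulations contrast 0.30 against 0.06 — monotone
covariate links (plasma-cell % = 100·√f, giving ≈ 55% at the median;
β2-microglobulin = 0.9 + 6.3·f mg/L, ≈ 2.8 at the median) with Gaussian
noise, a logistic MRD-negativity model calibrated to ≈ 40% negativity after
induction, negative-binomial lesion counts with binomial thinning at
follow-up, and per-scan seeds derived once from the cohort seed. Volumes
are realized lazily (`realize_patient()`) so 100-replicate simulations
stream rather than hold 80 volumes in memory.

What the phantom deliberately does **not** model: anatomical bone shape,
trabecular texture, marrow heterogeneity beyond the two-component mixture,
PET point-spread/partial-volume effects, reconstruction noise correlation,
patient motion, or any coupling between treatment arm and outcome (the
source substudy found none). A green simulation test therefore establishes
that the estimators recover what the stated generative model plants — not
that they are unbiased on real patients.

## Numerical choices

* Degenerate inputs fail loudly: empty masks, ROIs that fit nowhere,
  constant vectors, zero-margin tables and all-zero paired differences all
  raise errors rather than returning NaN.
* `manual_ctv` tie-break: lowest (z, y, x) center, then smaller radius.
* Erosion treats out-of-grid voxels as background (border voxels erode).
* NIfTI-1 I/O is implemented in base R (no R NIfTI package is available in
  the target environment) and is cross-validated against Python's nibabel
  in the test suite; axis-aligned affines only, which is sufficient for
  the phantom world and typical resampled clinical exports.
* All simulations are seeded; identical spec + seed is bitwise
  reproducible, and the pipeline writes byte-identical CSVs under a fixed
  config.

## Known limitations

* The cCTv "density" interpretation is an inference from units and reported
  magnitudes, flagged as such — the literal reading stays available.
* The ROI sweep upper-bounds a human reader; absolute CTv values are not
  comparable with reader studies, though within-pipeline contrasts are.
* Whether cCTv should pool voxels across bones or average per-bone values
  is unstated in the source methodology; this package pools by default.
* Erosion radius (2 mm) is an uncalibrated surrogate for the unspecified
  spillover-mitigation procedure.
* The phantom's lesion-count and flag distributions are plausibility
  choices, not calibrated fits to any cohort.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(infiltration_fraction = 0.25, lesion_hu_mean = 40,
                     lesion_hu_sd = 0, fat_hu_sd = 0, seed = 7)
ph <- make_ct_phantom(spec)
wm <- medullary_working_mask(ph$ct, ph$masks$medullary_cavity,
                             ph$masks$epiphysis)
compute_cctv(ph$ct, wm)       # cCTv = 40 x 0.25 = 10 HU exactly
manual_ctv(ph$ct, wm)         # highest ROI-mean HU and the winning ROI

pp <- make_pet_phantom(pet_spec(seed = 7), ph$masks, ph$truth)
liver <- voi_stats(pp$pet, pp$masks$liver)
skel <- skeletal_working_mask(pp$masks$skeleton, pp$masks$skull, 2)
segment_and_quantify(pp$pet, skel, mm_threshold(liver))
```

The full cohort pipeline is driven by a JSON config; see
`system.file("extdata", "demo_config.json", package = "marrowquant")` and
`run_pipeline()`.
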