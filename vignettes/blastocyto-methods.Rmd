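---
title: "Methods: nucleus-level image cytometry for blastocyst confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleus-level image cytometry for blastocyst confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastocyto)
```

## The problem

Immunofluorescence of preimplantation mouse embryos (E3.5 and E4.5
blastocysts, and embryos arrested in diapause) gives multi-channel confocal
z-stacks in which nuclei of the inner cell mass are small, bright and
tightly packed. Questions such as "is active STAT3 (pY705) elevated in the
embryonic region of diapaused embryos relative to E4.5?" require a
*per-nucleus* readout: every nucleus segmented in 3D, its position, volume
and per-channel integrated density measured, bad segmentations removed, and
stage groups compared with statistics that do not assume normal,
equal-variance data. `blastocyto` implements that pipeline end to end,
together with a ground-truthed simulator of blastocyst-like stacks so the
whole chain is testable without microscope data.

## Segmentation by z-linking

Nuclei are segmented *per 2D slice* and then assembled into 3D objects by
tracking detections through the z-stack — the natural decomposition when
axial sampling (2 µm optical sections) is much coarser than lateral
sampling, so a nucleus appears as a short stack of similar 2D profiles.

Per slice, on the DNA (DAPI) channel:

1. **Unsharp mask** `out = (I − w·G_σ(I)) / (1 − w)` with σ = 15 px and
   w = 0.6, clipped to the input range. This sharpens nuclear boundaries
   against the diffuse inter-nuclear background.
2. **Percentile normalization**: the 1.0th percentile maps to 0, the 99.9th
   to 1, values clipped to [0, 1]. A constant slice maps to all zeros.
3. **Detection**: threshold the normalized slice at 0.2, fill holes, and
   split touching nuclei by a watershed. Candidates overlapping above
   0.2 IoU are suppressed (keeping the brighter one), and the per-slice
   area filter keeps only candidates with calibrated area strictly inside
   (5, 30) µm².
4. **z-linking**: greedy nearest-neighbour matching of detections between
   consecutive slices on xy centroid distance, accepting links up to
   `max_link_dist_um` (default 3 µm — on the order of a nucleus radius).
   Ties break deterministically by smaller distance, then smaller detection
   index. Tracks must be slice-consecutive (`max_gap = 0` by default;
   configurable) and tracks spanning fewer than 6 slices — i.e. not
   strictly more than 5 — are discarded. This duration filter is what makes
   the scheme robust: noise produces isolated 2D detections, but rarely six
   vertically aligned ones.

The retained tracks are rasterized into a 3D label volume (voxels claimed
by two tracks go to the nearer track centroid), which is then the
measurement mask.

### Why the watershed runs on intensity, not the distance transform

For touching *convex masks* the classical choice is a watershed on the
distance transform of the binary image. On compact ICM clusters this
under-splits: when two or three nuclei overlap deeply, the merged mask is
nearly elliptical and its distance transform has a peak-to-saddle height of
only ~1 px, indistinguishable from discretization noise at any tolerance.
The *brightness* valley between adjacent nuclei is far deeper — nuclear
fluorescence falls off steeply at the nuclear boundary — so the default
detector runs the watershed on the smoothed normalized intensity
(`watershed_smooth_px = 1.5`, tolerance 0.1 on the [0, 1] scale). In a
15-embryo validation battery this recovers every planted nucleus, where the
distance-transform variant loses 3–5 ICM nuclei per embryo in compact
clusters. `split_method = "distance"` keeps the classical variant
available.

### Parameter units

The area filter ">5, <30" and the QC volume window "(150, 700)" carry no
units in the protocol this pipeline automates; `blastocyto` interprets them
as calibrated µm² / µm³ (the natural reading when calibration is set), with
`volume_units = "voxels"` as an override. The linking distance is likewise
unspecified upstream; the default of 3 µm is tied to the default nucleus
radius and exposed as configuration.

## Measurement and quality control

For each labelled 3D object the package reports the unweighted voxel
centroid in physical units (0-based voxel indices; `z = slice × 2 µm`; y
grows downward), the voxel count and calibrated volume, and per channel the
mean intensity and the **integrated density** — the sum of all voxel values
of the object in that channel. `intden = mean × voxel_count` holds by
construction (to one floating-point rounding of the mean).

QC removes erroneously segmented objects with two open-interval windows:
mean DAPI signal in (2, 10) and volume in (150, 700) µm³. Boundary-equal
values are removed — "upper/lower limit" is read as a strict bound, a
documented and configurable convention. The DAPI window is an 8-bit-era
setting on a 0–10 scale; the package applies it to the nucleus mean DAPI
rescaled by bit depth (`mean/255 × 10`), which is deterministic per record
and independent of what else is in the stack; `dapi_scale = "raw"` applies
the window to raw 8-bit means instead.

The "embryonic region" restriction mirrors the manual cropping that removes
the mural trophectoderm: a 3D boolean ROI mask, with membership decided by
nucleus centroid (cheap, deterministic, and faithful to cropping
semantics). The pipeline crops first, then applies QC.

## Stage statistics

Marker levels are compared across E3.5, E4.5 and diapause on per-nucleus
integrated densities of in-region, QC-passed records. Because the pooled
distributions are right-skewed and bimodal (the retained polar
trophectoderm is low for every marker), the battery is rank-based:

* Brown–Forsythe Levene (median-centred) and per-group Shapiro–Wilk as
  diagnostics motivating the non-parametric tests;
* one Kruskal–Wallis across all stages (tie-corrected H, chi-square p;
  all-tied data degenerate to H = 0, p = 1);
* all pairwise two-sided Wilcoxon rank-sum tests: exact enumeration when
  the smaller group has ≤ 8 observations and there are no ties, otherwise
  the tie-corrected normal approximation *without* continuity correction —
  which makes the two-group Kruskal–Wallis H exactly the squared
  standardized rank-sum statistic, a property the test suite checks.

P-values map to stars as ns (p > 0.05), `*` (≤ 0.05), `**` (≤ 0.01),
`***` (≤ 0.001), `****` (≤ 0.0001). Pairwise p-values are reported
unadjusted by default (the convention for pairwise annotations over violin
plots); Holm adjustment is one flag away. The unit of analysis is the
nucleus, pooled across embryos within a stage — exactly what the violin
plots show — and `per_embryo = TRUE` provides the conservative per-embryo-
mean alternative, since pooling inflates n when nuclei within an embryo are
correlated.

## Gating and in-silico embryos

Records live in a co-expression feature space (e.g. NANOG vs pY705
integrated density). Two gate types select subsets: a threshold gate
(strictly above a cut) and a polygon gate in a 2D channel space. Polygon
membership uses a crossing-number test with an explicit on-boundary check;
points exactly on an edge or vertex count as inside — an interactive
selection tool has no such convention, so the package fixes one and the
tests verify it against an independent winding-number oracle. Polygons must
be simple (non-self-intersecting), validated at construction.

`reconstruct()` turns a table into an "in silico embryo": one point per
nucleus at its centroid, colour-coded by any measured channel, with
selected cells flagged — the spatial map-back of a gene-expression-space
selection. `region_enrichment()` quantifies how strongly a selection
concentrates in the embryonic region (ratio of in-region fractions, plus a
one-sided hypergeometric p — an added quantification beyond the visual
claim, labelled as such in the output). Per-embryo summaries and a
Spearman size-vs-mean-intensity correlation round out the per-embryo view;
Spearman is the default to stay consistent with the pipeline's rank-based
stance (Pearson by flag).

## The synthetic embryo generator

`render_stack()` draws a blastocyst-like embryo: `n_te` trophectoderm
nuclei on a spherical shell (default radius 30 µm), and an inner cell mass
(epiblast + primitive endoderm) cluster displaced 14 µm toward the
embryonic pole. Each nucleus is an anisotropic Gaussian blob truncated at
2.5 σ, with per-channel peak amplitude drawn from a lognormal distribution
per lineage × channel × stage. Positive support and right skew match IF
readouts; the stage structure encodes: pY705/TFCP2L1 in the epiblast
ordered diapause > E3.5 > E4.5; NANOG reduced in the epiblast at E4.5;
trophectoderm low for every marker (the source of bimodality); DAPI
identical everywhere. Absolute amplitude scales are free parameters — no
reference data pin them — chosen so the DAPI channel sits comfortably
inside the default QC window, and overridable per channel and lineage.

Rendering adds Poisson-scaled shot noise (Gaussian approximation,
`photon_scale = 0.5`) and Gaussian read noise (`read_sd = 2`), clips to
[0, 255] and quantizes to 8-bit. The ground truth records each nucleus's
lineage, true centroid, truncation-ellipsoid volume and pre-noise rendered
total signal per channel, so conservation (`voxel sum = truth total`, up to
quantization) is testable. The default test geometry is a 256 × 256 × 40
stack at 0.4 µm pixels and 2 µm sections; the full 1024 × 1024 acquisition
frame is available via `slice_shape`.

Three geometry choices deserve explanation:

* **Nucleus shape** (σ_xy 1.35 µm, σ_z/σ_xy = 3.2). The filter set the
  segmentation defaults implement — per-slice area strictly inside
  (5, 30) µm², duration > 5 sections of 2 µm, volume inside (150, 700) µm³
  — is mutually consistent only for objects with small xy cross-section
  and an axial span above 12 µm. The default nucleus was designed
  analytically to satisfy all three windows simultaneously; it is best
  read as "the object the filter set describes", not as an optically
  realistic nucleus.
* **z-flattened ICM with xy separation.** Segmentation-by-z-linking
  cannot, by construction, separate two nuclei stacked along the optical
  axis at the same xy position — their detection columns merge into one
  track. The generator therefore places ICM centres in a z-flattened
  ellipsoid (`icm_z_flatten = 0.35`) and enforces a minimum *xy-projected*
  separation of 5 µm unless two nuclei are ≥ 22 µm apart axially (farther
  than the full blob extent plus one section). Placement is rejection
  sampling with bounded retries and restarts; infeasible requests error.
* **Cohort count variation.** `make_cohort()` and
  `simulate_intensity_table()` draw per-embryo lineage counts from Poisson
  distributions around the spec means (truncated to the packable
  envelope). Beyond realism this matters statistically: with fixed counts
  every simulated group shares an identical lineage mixture, and pooled
  rank tests become strongly conservative under the null — an artefact of
  stratified composition, not a property of the tests. With Poisson counts
  the Kruskal–Wallis type-I error is calibrated at the nominal 5%.

What the simulator deliberately does **not** model: optical point-spread
blur across slices, spectral bleed-through, depth-dependent attenuation and
fluorescence quenching during acquisition, irregular (non-ellipsoidal)
nuclear shapes, and nuclei touching along z. Passing tests on synthetic
data therefore demonstrate that the pipeline's logic is correct under its
own stated assumptions — not that it will reach the same fidelity on real
stacks, where detection and splitting are harder.

## Numerical and reproducibility choices

* All randomness flows through per-object seeds; a cohort derives
  per-embryo sub-seeds by hashing `(seed, index)`. Seeds are passed through
  a multiplicative hash before `set.seed()`, because nearby integer seeds
  hand the Mersenne Twister correlated initial states — measured at r ≈ 0.7
  between draws from consecutive raw seeds — which would couple replicates
  in calibration studies. Package functions save and restore the caller's
  RNG state.
* Identical spec + seed ⇒ bit-identical stacks; identical inputs + config
  ⇒ byte-identical pipeline outputs. Tables are written with 17 significant
  digits so CSV round trips are lossless.
* TIFF carries no portable z-spacing or channel-axis metadata through
  baseline readers, so stacks are written with a JSON sidecar; reading
  without a sidecar requires explicit calibration and errors by naming the
  missing field. 16-bit label volumes cap at 65535 nuclei.
* Degenerate inputs have defined behaviour: constant slices normalize to
  zero, empty label volumes measure to empty tables, all-tied groups give
  H = 0 / p = 1, empty gate selections report an undefined enrichment
  ratio rather than NaN arithmetic.

## Problem sizes used in validation

The validation suite exercises the full chain on 256 × 256 × 40 stacks
with ~27 nuclei per embryo (15-embryo cohorts for recovery scoring; a
further 15-embryo diapause cohort for per-embryo analyses), 1,000
enumerable linking instances against a brute-force assignment oracle,
exhaustive Wilcoxon enumeration up to group sizes 6, and 200-replicate
calibration/power studies at the intensity-table level. These sizes were
chosen to give stable estimates at desk scale; all of them are functions of
ordinary parameters and scale up freely.

## Known limitations

* The 2D detector is a classical threshold + watershed; it inherits that
  family's weaknesses (sensitivity to contrast inversion, no learned shape
  prior). A learned detector can be substituted behind `detect_nuclei_2d()`
  without touching the rest of the chain.
* No gap closing by default: a single dropped slice splits a track. The
  duration filter then discards both halves; `max_gap` exists but is 0
  unless asked for.
* Pooling nuclei across embryos inflates n; the per-embryo mode is
  provided, and serious inference on real cohorts should consider
  embryo-level random effects (out of scope here).
* The enrichment p-value treats cells as exchangeable across the region
  boundary; it ignores within-embryo spatial correlation.
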