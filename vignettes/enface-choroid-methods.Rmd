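---
title: "Depth-resolved enface quantification of the choroid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved enface quantification of the choroid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enfacechoroid)
```

## The measurement problem

Swept-source OCT at 1050 nm penetrates the full choroid, and a 3D macular
raster can be resampled into *enface* planes parallel to a reference
surface. Viewed this way, the choroidal vasculature changes texture with
depth: immediately below the retinal pigment epithelium (RPE) the
choriocapillaris and its feeding arterioles and draining venules (here
"CC") form a fine reticular pattern whose individual capillaries are
unresolvable at a 30 um lateral pitch, while the deeper choroidal vessels
("CV", Sattler's and Haller's layers together) appear as interwoven dark
lumens of growing calibre. Beyond the choroidal-scleral interface (CSI)
the sclera is homogeneous. `enfacechoroid` turns this qualitative
description into a measurement pipeline:

1. merge repeated acquisitions of an eye (`merge_volumes()`),
2. segment the RPE/Bruch's complex as the reference surface
   (`segment_rpe()`),
3. flatten the volume and extract planes every axial pixel — 4.13 um —
   from the surface (`flatten_volume()`, `extract_enface_stack()`),
4. locate the CC-to-CV transition and the CSI from plane texture
   (`detect_boundaries()`),
5. convert boundary levels to absolute (um) and relative (%) thicknesses
   (`quantify_eye()`, `average_eyes()`), and
6. compare age groups and validate the method statistically
   (`group_compare_report()`, `validate_internal()`, `validate_external()`).

Because no imaging data are distributed with the package, a first-class
synthetic-data module (`sample_cohort()`, `render_volume()`,
`render_subject()`) generates layered, speckled volumes with exact ground
truth; every accuracy claim in the test suite is made against that truth.

## Geometry and units

A volume is indexed `[z, y, x]` with `z = 0` vitreous-most and depth
increasing toward the sclera. The instrument defaults are a 12 x 12 mm,
400 x 400 A-scan raster (30 um lateral pitch) with a 4.13 um axial pixel
and ~6 um axial resolution in tissue (PSF sigma about 1.5 px). Offsets in
the enface stack are integer pixels from the reference surface; a layer
spanning `k` levels is `k x 4.13` um thick, and that arithmetic is kept
exact by using nearest-neighbour (single-pixel, not slab-averaged) plane
extraction. The macular area is the 6 mm diameter circle centred on the
fovea and the foveal area the central 1 mm circle.

Desk-scale analyses use a 64 x 64 x 192 voxel grid at native pitch — a
central crop of the full raster. The shipped tests and the acceptance
script run a 20-eye cohort (10 subjects) at this size; the identical code
path supports 400 x 400 x 512.

## The synthetic scene

`render_params()` stacks, from the vitreous down: a retina band; a bright
RPE band (3 px, peaked at its centre — the brightest structure in the
volume, as in real scans); a CC band whose texture is a thresholded
difference-of-Gaussians field at a 1-2 px scale (capillaries are
sub-resolution, so only their reticular aggregate is modelled — the dark
blobs are deliberately below the 4 px classification cutoff); a CV band
of dark tubular lumen segments whose radii grow linearly from 1.8 to 5 px
with depth and whose per-level areal density grows from 25% to 55% of the
central disc (the deep choroid is vessel-dominated); and homogeneous
sclera beyond the CSI. Segments are randomly oriented inside the macula
and radially oriented outside it. Retinal vessels are modelled as thin
straight shadow chords attenuating whole A-scans (default 4 chords at
x0.15). The scene is blurred axially by the PSF and multiplied by gamma
speckle of mean 1 (shape `k = 4` by default, the package's standard noise
condition; `k = Inf` disables noise for exactness tests).

Cohort thicknesses are drawn per group from truncated normals (defaults:
younger TC 379.4 +/- 72.0 um, CC 81.2 +/- 17.0 um; older TC 305.0 +/-
51.5 um, CC 56.4 +/- 11.8 um; 14 vs 12 subjects; age cut-off 40 years).
Fellow eyes share a latent subject value plus independent eye noise
scaled so their correlation is 0.95 — the simplest model consistent with
high inter-eye agreement, chosen over inventing richer structure. Three
truncations keep scenes renderable and anatomically sensible: CC and CV
are each at least four axial pixels (16.52 um), and TC is at most 600 um
(an eye whose choroid exits the instrument's usable axial window is not
analysable and is redrawn). All are > 3-sigma events under the defaults,
so the sampled moments still match the nominal ones (verified at
n = 2000 in the tests).

Choroidal thickness varies smoothly over the field (1 px peripheral
thinning by default) with the sampled value imposed exactly at the foveal
centre, where all quantification happens. The generator does not attempt
biophysically realistic OCT formation: no depth-dependent signal
roll-off, no motion artefacts beyond a rigid axial shift between repeat
acquisitions, no blood-flow effects on thickness, and no watershed-zone
topology. Passing tests therefore demonstrate that the *measurement
logic* recovers known structure under speckle, not that the renderer
fools a clinician.

## RPE segmentation

Each A-scan is scored by `w_i * I + w_g * G` with equal default weights:
`I` is the profile min-max normalised over the central 80% of depth, and
`G` the positive (dark-to-bright) axial derivative, normalised likewise.
Two numerical choices matter:

* **Speckle suppression.** Multiplicative speckle is axially white, so a
  pointwise derivative is noise-dominated. The scorer smooths each
  z-slice laterally (sigma 1.5 px; the surface is laterally smooth) and
  each profile axially (sigma 1 px) before scoring. Shadowed A-scans are
  excluded from the lateral average so they do not dim their neighbours.
* **Gradient look-back.** For any band of finite width the maximum slope
  sits about one resolution element *above* the band centre, so a
  pointwise gradient term drags the argmax one pixel shallow — and that
  bias would propagate into every thickness. The gradient term therefore
  credits a depth with the strongest rise within the preceding 3 px
  (`gradient_lookback`), letting the intensity term fix the peak
  location. On noise-free phantoms recovery is then exact.

A-scans whose energy falls below 30% of the median are treated as
shadowed. The raw surface is regularised (`regularize_surface()`):
entries deviating more than 6 px from their 5 x 5 local median are
rejected, iterating to a fixed point so clustered failures erode from the
rim inward; a robust quadratic trend surface (the posterior pole is
dome-shaped) catches gross clusters hugging the grid edge; remaining
holes are inpainted by nearest-neighbour diffusion and the filled values
box-smoothed. Valid non-outlying entries pass through unchanged, making
the operation idempotent. If more than half the A-scans are unusable the
volume is rejected outright. Automatic rejection-plus-inpainting replaces
the manual correction step of a semi-automatic workflow; it is
reproducible, which a human edit is not.

## Boundary detection

`compute_plane_features()` classifies lumen pixels and summarises each
plane by its dark areal fraction and the split of dark area into *fine*
(equivalent diameter < 4 px, about 120 um — capillary scale) and *coarse*
components.

The classifier is a local adaptive threshold, `pixel < local mean -
0.3 * local SD` over a 15 px window, with two amendments that the speckle
statistics force. First, planes are smoothed laterally (sigma 1.2 px)
before classification. Second, a pixel must also fall below `(1 - 0.2) *
local mean`. Without the relative contrast floor the rule is scale-free
in the noise SD and marks a fixed ~38% of any homogeneous speckled region
(e.g. sclera) as "dark", making a vessel-free plane undetectable in
principle; with the floor, the false-dark rate in smoothed sclera drops
to below 1% while true lumens (about 4-5x darker than the stroma) remain
classified. Both amendments vanish on noise-free input. Retinal-vessel
shadow columns project dark vessel-shaped artefacts onto *every* plane,
so the pipeline excludes the shadowed lateral positions (identified by
the same A-scan energy rule as segmentation) from all plane statistics —
the automated counterpart of a reader ignoring shadows.

The **transition level** operationalises "features of both layers in
equal proportions": fine and coarse fractions are smoothed across depth
(moving average, window 3) and the transition is the smallest offset at
which the coarse fraction reaches the fine fraction — a 50/50 mixture at
the crossing — with dark structure present, persisting for 2 consecutive
offsets (speckle debounce). Without a crossing the midpoint of the
dark-fraction plateau is returned flagged low-confidence.

The **CSI** is the smallest offset beyond the transition at which the
dark fraction of the *foveal* circle stays below 5% for 3 consecutive
offsets — vessels vanishing from the foveal area, with the macular circle
as fallback when the foveal planes are mostly invalid. No qualifying
offset is a hard failure: the choroid exceeds the stack. Inner and outer
choroid (Sattler vs Haller) are deliberately not separated; their
transition is a gradient with no computable boundary.

Detection is deterministic given a stack. Because levels are integers,
small parameter perturbations often change nothing at all — the
two-observer analogue below can legitimately return perfect agreement.

## Quantification and statistics

`quantify_eye()` sets CC = transition level, CV = CSI - transition, TC =
CC + CV (exact by construction), and percentages that sum to 100 exactly.
Fellow eyes are averaged arithmetically; percentages are averaged *as
percentages* rather than recomputed from averaged micrometres — the
convention is not dictated by the arithmetic, so it is declared here and
fixed by a test. Subfoveal TC is read at the foveal median rather than a
single A-scan, for robustness to speckle.

The independent B-scan measurement (`measure_tc_bscan()`) re-derives TC
on the horizontal section through the fovea without touching any enface
output: the section is smoothed in 2D, pixels below 70% of the median
sub-surface intensity are dark, and the per-A-scan CSI is where the
deepest sustained (>= 2 px) dark run ends; TC is the foveal median. A
sliding local mean is deliberately *not* used here because deep vessels
fill the window and the threshold collapses.

The statistical layer implements the classic pooled-variance unpaired
t-test (computable from raw values or from printed n/mean/SD — the two
routes agree to machine precision and the summary route reproduces
published group p-values from summary tables alone), ICC(A,1) (two-way
random effects, absolute agreement, single measures, McGraw-Wong F-based
95% CI; a consistency form is available by flag — the agreement form is
the declared default since the use-case is agreement), and Bland-Altman
bias with 1.96 SD limits. Significance is 5%, two-sided, with no
multiple-testing correction. The ICC implementation was cross-checked
against an independent two-way ANOVA implementation on a frozen fixture.

"Two observers" for internal validation are two boundary-parameter
profiles (observer 2 scales the lumen threshold `alpha` by +20% by
default); no second human exists in an automated run, and the jitter
magnitude is config-visible.

## Reproducibility and I/O

Every random draw descends from one master seed: identical configuration
and seed give byte-identical `thickness.csv`. Stage artifacts are not
cached between runs — desk-scale runs take seconds per eye and
`run_pipeline()` is a pure function of its configuration.

Volumes are stored as multi-page TIFF (one page per z-slice) with a UTF-8
JSON sidecar (`<stem>.meta.json`) carrying voxel spacing, subject
metadata and an intensity scale. Pages use the TIFF backend's 32-bit
sample depth as fixed point with a power-of-two scale: the quantisation
step is ~2.3e-10 of the dynamic range (finer than single precision),
division by the scale is exact, and a write-read-write cycle is
bit-stable. `read_volume()` applies the instrument defaults (4.13 um /
30 um) when sidecar fields are absent.

## Known limitations

* The "equal proportions" reader criterion has no published numeric
  definition; the fine/coarse crossing is this package's declared
  surrogate, and no calibration against the original readers' images is
  possible.
* The merge is a per-A-scan axial alignment, a desk-scale stand-in for
  full 3D orthogonal-raster motion correction; it corrects rigid axial
  shifts only.
* Renderer realism is limited as described above; absolute accuracy
  figures quoted by the tests are accuracies *on synthetic scenes*.
* Arteries and veins, the inner/outer choroid boundary, extramacular
  thickness maps, and regression of thickness on continuous age are out
  of scope.
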