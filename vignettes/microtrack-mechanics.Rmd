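---
title: "Quantifying cell-matrix mechanics in collagen microtracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-matrix mechanics in collagen microtracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmech)
```

## The measurement problem

Tumor cells migrating through linear channels ("microtracks") ablated in
fibrillar collagen both respond to and rework their confinement: in narrow
tracks they push the walls apart by severalfold, in wide tracks they grip
both walls and pull them inward, in either case converging on a track
diameter matched to the cell body. The forces behind this remodeling can be
read out from the collagen itself: the reflection channel of a confocal
time-lapse shows a speckle texture that deforms with the matrix, so
tracking speckles yields matrix displacement, displacement yields strain,
and a linear elastic model converts strain into traction force.

`trackmech` implements that entire chain as testable code: a seeded
synthetic-scene generator with exact ground truth, drift stabilization,
the channel filtering recipe, kymographs, automated track-width
measurement, normalized-cross-correlation speckle tracking, strain and
force estimation, migration kinematics, nuclear morphometry, and the
matching nonparametric statistics.

## The synthetic scene and its mechanical model

A `scene()` describes a single z-plane: a speckled collagen field at
0.32 µm/pixel with one dark track of width $w_0$ along the x axis, imaged
every 4 minutes, plus one elliptical cell (cytoplasm and nucleus channels)
crawling along the track at constant speed.

The prescribed mechanics are deliberately the *simplest* field consistent
with a scalar linear stress–strain relation:

* The wall displacement at axial position $x$ and time $t$ is
  $d(x,t) = d_\text{peak}\,\mathrm{env}(x - x_\text{cell}(t))$ with a
  raised-cosine envelope of support `contact_length` (20 µm, matching the
  assumed 20 µm contact square). A traveling envelope avoids the
  discontinuities that would break tracking.
* Collagen displaces perpendicular to the wall, decaying linearly from the
  wall value to zero at `clamp_distance` $L$ (default 40 µm), where the
  matrix is treated as held fixed. True strain at the wall is then
  $d/L$ *by construction*, and the prescribed force obeys the closed form
  $d_\text{peak} = F/(EA)\cdot L$ (`scene_d_peak()`), with $E = 340$ Pa
  (6 mg/ml collagen) and $A = 400\ \mu m^2$.
* `deformation_sign` selects pulling (walls converge) or pushing; a
  `plasticity` fraction of the largest displacement seen at a position
  persists after the cell has passed (0 = fully elastic recovery,
  0.5 emulates the partial persistence seen in untreated cells).

Validation rejects fold-over: $d_\text{peak}$ must stay below both the
clamp distance and, for pulling, the track half-width — a 40 nN pull
($d_\text{peak} \approx 11.8$ µm) is only physical on a wide track.

The reference length $L$ is a construct of this package, not a measured
quantity: the linear relation only defines strain once a gauge length is
chosen, so absolute forces depend on the speckle pair used. We keep $L$
explicit and report it with every force series rather than resolving this
ambiguity.

Speckles are sampled as a Poisson process (default 4 per 100 µm², mean
spacing ≈ 5 µm) with heterogeneous brightness (amplitude 0.25–0.75 above a
0.5 background), size, elongation and orientation — short fibril-like
anisotropic Gaussians. The heterogeneity matters: identical round spots
would make frame-to-frame correspondence formally ambiguous for any
tracker (including a human), whereas distinctive shapes are what manual
speckle tracking actually relies on. Channel noise is additive Gaussian,
default 5% of the dynamic range; identical scene + seed yields
byte-identical stacks, and generation restores the caller's RNG state.

### What the generator does not emulate

No fibre-network micromechanics (the displacement field is prescribed, not
solved), no strain stiffening, no 3D (a single analyzed z-plane), no
photobleaching or focus drift, no cell shape change beyond the prescribed
ellipse, and no collagen densification texture at the walls. Passing tests
therefore demonstrate that the *measurement chain* is correct and
self-consistent under realistic imaging statistics — not that the linear
elastic model is an accurate constitutive law for collagen.

## Stabilization

Drift correction is translation-only phase correlation of each reflection
frame against the reference frame, with two numerical choices that took
deliberate calibration:

* the cross-power spectrum is *whitened* — plain cross-correlation is
  marginally more precise on strictly rigid scenes but is dominated by the
  highest-energy structure, and during strong wall deformation it locks
  onto the moving dark band and reports spurious shifts of tens of pixels;
* the whitened spectrum is attenuated by a Gaussian low-pass (σ = 0.15
  cycles/px), because whitening alone amplifies noise-dominated high
  frequencies.

The integer peak is refined on a 20× upsampled local DFT grid with a final
parabolic polish. On 5%-noise scenes this recovers injected drifts of up
to 10 px to better than 0.05 px; flat frames get a zero shift and a
warning flag.

## Filtering

Fluorescence channels are median-filtered with radius 2 px; the reflection
channel is mean-filtered over ±1 px in x,y and ±2 frames in t, truncating
the window at the sequence ends. One caveat discovered during validation:
the *temporal* part of that recipe is right for kymographs and width
measurement but wrong for speckle tracking, because averaging five frames
smears a wall moving several pixels per frame into a streak and biases
tracked displacements low. The tracking branch therefore runs on
spatially-only filtered frames (`preprocess(stack, refl_t = 0)`).

## Speckle tracking

`track_speckles()` matches a fixed frame-1 template (default 7×7 px,
never updated, so drift cannot accumulate) by zero-mean normalized
cross-correlation inside a search window centred on the previous position.
Three estimator details carry most of the accuracy:

* **Sub-pixel peak**: a 2D log-domain quadratic fit (with cross term) on
  the 3×3 neighbourhood of the integer peak. A plain parabola shows pixel
  locking on sharp speckles; separable 1D fits are biased for *rotated
  anisotropic* peaks because the axis slice through the integer peak does
  not pass through the true optimum.
* **Ensemble second pass**: the frame-1 template carries its own noise
  realization, which biases every match in the same direction. A second
  pass against the average of the matched windows cancels it; the ensemble
  template is re-anchored by matching frame 1 itself so its implicit
  centre cannot bias displacements.
* **Motion prior**: the integer peak is selected on
  $\mathrm{NCC} - 0.05\,(r/r_\text{search})^2$. In dense fields two
  speckles can score within 0.01 of each other; the prior prefers the
  motion-consistent candidate while leaving the reported quality (raw
  correlation) and the sub-pixel fit untouched. Trajectories whose peak
  correlation falls below 0.3 are flagged lost from that frame on.

At the default 5% channel noise the per-displacement localization error of
a compact bright speckle is ≈ 0.1 px (1σ) — essentially the
information-theoretic floor for a few-pixel Gaussian feature observed
twice through noise — so single displacements scatter to ±0.25 px while
per-trajectory RMS stays below 0.2 px. Strain and force estimates inherit
this as a ≪1% error because they integrate over a ~30 µm baseline.

## Strain and force

`compute_strain()` is the pairwise speckle-distance strain:
$s(t) = (\lVert p_a(t)-p_b(t)\rVert - L_0)/L_0$ against the frame-1
separation, positive when the separation grows. For a pair lying on one
transverse ray with both members inside the linear decay zone this equals
the wall strain $d/L$ *exactly*, independent of where the two speckles sit
— which is why `select_strain_pairs()` picks a wall-adjacent speckle
(3–7 µm from the wall, clear of the moving edge so the template is not
contaminated) and a far speckle near the clamp, both close to one axial
position so they share the contact envelope.

`compute_force()` applies $F = E\,|s|\,A$ with the nN conversion
(1 Pa · µm² = 10⁻³ nN) and a pull/push direction flag.
`recover_wall_force()` chains the whole pipeline and reports the median
peak force over up to five speckle pairs; the median is robust to the
occasional mismatched speckle in a dense field. On the benchmark scenes it
recovers prescribed peaks of 10, 20 and 40 nN within a few percent.

The benchmark scenes (`force_scenario()`) use a wide 32 µm track and a
slow 0.2 µm/min crawl. Both are physical requirements, not conveniences:
an 11.8 µm pull would fold a 22 µm track across its centreline, and
observed traction builds over one to two hours — with the traveling
envelope, a 0.7 µm/min cell would impose ~5 µm wall motion per 4-min
frame, beyond the mean speckle spacing, making frame-to-frame
correspondence ill-posed for any tracker at that sampling rate.

## Track width

`measure_track_width()` averages the reflection intensity over a 2 µm
axial window, takes the 5th/95th percentiles of the transverse profile as
robust floor/plateau, and places both edges at the 50% level by linear
interpolation — a scale-invariant criterion, verified to ±0.5 µm against
rendered gaps and invariant to global intensity scaling. A profile with
less than 30% relative contrast yields an explicit "no track" result
distinct from width zero. `width_phase_summary()` labels each
(position, frame) measurement before/during/after by whether a cell body
(rear-to-leading span) overlaps the position, with `during_single` vs
`during_collective` decided by the number of overlapping cells;
before/after binning is done manually in interactive workflows, so
per-frame overlap labelling is this package's own convention.

## Migration kinematics

Speed is total path length over total elapsed time — stop phases count
their time but no length, which is the convention behind the ~0.5 µm/min
(narrow) to ~0.7 µm/min (wide) scale. Persistence is path length over
beeline, ≥ 1 by the triangle inequality, with an explicit
"returned cell" flag instead of a number when the beeline is below 1 µm.
Nuclear position projects the nucleus onto the rear→leading axis as a
percentage of cell length, clipped to [0, 100] so off-axis excursions
cannot inflate it; cells average below the configurable 30% threshold are
flagged rear-nucleated (rear-nucleation is conventionally indicated
graphically rather than by a published cutoff, so the threshold must be
explicit here). Metrics are
computed over the full supplied trajectory; windowing is left to the
caller.

## Nuclear morphometry

`segment_nuclei()` is Otsu thresholding, a Euclidean distance transform,
and watershed splitting, followed by rule-based exclusion in place of
manual curation: area < 10 µm², border contact, or solidity < 0.5, each
with a reason code. Shape descriptors use binary masks: ellipse axes from
second moments (+1/12 px² quantization term), perimeter from the
8-connected oriented contour after a window-5 circular moving average
(which removes the direction quantization of the pixel chain) plus a π
half-pixel boundary offset per closed contour — <1% error and ~0.5%
rotation wobble on rasterized discs and ellipses — and solidity against
the convex hull of pixel centres, clamped at 1 since the pixel-count area
of a convex digitized shape slightly exceeds that hull.

The nuclear irregularity index is defined here as

$$\mathrm{NII} = (1 - \text{circularity}) + (1 - \text{solidity}),$$

zero for an ideal disc, increasing with elongation (perimeter term) and
contour concavity (solidity term). Published irregularity indices combine
different term sets; this formula matches their qualitative use
(sensitivity to nuclear elongation and shape deviation) but is not
numerically interchangeable with any of them, and we use binary rather
than intensity-weighted moments and say so.
The proteolysis index is background-corrected mean signal per nucleus,
clipped at zero with a flag.

## Statistics

Group comparisons use the nonparametric conventions standard for this
kind of data: tie-corrected Kruskal–Wallis (via `stats::kruskal.test`)
with hand-implemented Dunn pairwise z tests on pooled ranks,
Bonferroni-adjusted by default (configurable to Holm or Šidák —
commercial statistics packages adjust for multiplicity without always
naming the method); and a two-sided
Mann–Whitney test that is exact when the smaller group has ≤ 8
observations and no ties, tie-corrected normal approximation otherwise.
Summaries and box plots use medians, 25th/75th and 5th/95th percentiles
with type-7 linear interpolation; plotting-software percentile conventions
differ slightly and are not matched bit-exactly. The omnibus test holds
its nominal 5% size to within Monte-Carlo error over 2000 null
replicates.

## Problem sizes and determinism

The shipped tests and the acceptance script render scenes of 352×256 to
384×256 px with 15–40 frames and a few hundred speckles — small enough
that the full suite runs in minutes on one core, large enough that every
stage (registration, tracking, width measurement, segmentation) operates
in its intended regime. All randomness flows through explicit seeds;
identical configuration and seed reproduce stacks and every downstream
table bit for bit.

## Known limitations

* Absolute force scales with the chosen gauge length (`clamp_distance`);
  only the displacement field, not the true gauge, is observable.
* The tracker is translation-only per speckle; it tolerates the smooth
  prescribed deformation but would lose badly sheared or rotating texture.
* Track-width measurement assumes one dominant dark band per transverse
  profile; branching or doubled tracks are out of scope.
* The NII is this package's formula, comparable within analyses done by
  this package but not across published NII values.
* Statistics are limited to the two nonparametric families used here; no
  mixed models or repeated-measures corrections.
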