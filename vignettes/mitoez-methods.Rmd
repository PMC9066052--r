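---
title: "Quantifying the mitotic ER exclusion zone: models, parameters and design choices"
author: "mitoez"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the mitotic ER exclusion zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoez)
```

## The biological setting

During mitosis the endoplasmic reticulum (ER) and other endomembranes are
kept away from the spindle, leaving a membrane-free *exclusion zone* (EZ)
around the chromosomes and spindle poles. Misaligned chromosomes that fall
outside this zone can become wrapped in several layers of endomembrane —
*ensheathed* — which correlates with failed congression, prolonged mitosis
and micronucleus formation, while misaligned chromosomes at or inside the
zone boundary (*free*) congress normally. `mitoez` implements the
quantitative image-analysis layer for this biology: where kinetochores sit
relative to the EZ boundary, when chromosomes congress and anaphase starts,
when induced ER clearance happens, whether kinetochores carry markers of
stable microtubule attachment, and how the per-cell outcomes aggregate into
timing, fate and survival statistics.

All computations work on multi-channel 3D(+time) voxel grids with
anisotropic physical calibration. Every distance, volume and centroid in
the package is in micrometres, never voxels; the z spacing of a confocal
stack (typically 0.5 µm against 0.1 µm in xy) enters every geometric
computation through the per-axis voxel size.

## The exclusion-zone distance ratio

The central statistic places a kinetochore $P_i$ relative to the EZ
boundary. With $C$ the centroid of all aligned kinetochores and $Q_i$ the
point where the ray from $C$ through $P_i$ first leaves the exclusion zone,
the position measure is

$$ r_i \;=\; \log_2 \frac{\lVert \overline{C P_i} \rVert}{\lVert \overline{C Q_i} \rVert}. $$

The calibration is direct: $r_i = 0$ puts the kinetochore on the boundary,
$r_i = 1$ as far outside the zone as the boundary is from the centroid, and
negative values place it inside. `ez_ratio()` computes the statistic;
`boundary_intersection()` finds $Q_i$ by marching along the ray in steps of
half the smallest voxel dimension, classifying each sample by trilinear
interpolation of the binary EZ mask and refining the inside-to-outside
crossing linearly between the last inside and first outside sample. Where
a concave zone produces several crossings, the *first* transition from $C$
is used — it is the boundary nearest the spindle and the one the
calibration above refers to.

Two numerical facts matter here. First, the marching itself resolves the
crossing to a fraction of the smallest voxel. Second, the accuracy of
$Q_i$ is ultimately limited by the rasterization of the mask: a binary
mask sampled at voxel centres carries about half a voxel of uncertainty
*along the surface normal*. In-plane rays therefore localize the boundary
to roughly half an xy pixel (0.05 µm at default calibration), while rays
running mostly along z cannot do better than about half the z spacing
(0.25 µm) — no estimator can recover information the rasterization
discarded. The unit tests check the crossing at tolerances appropriate to
the sampling; the strictest suite also asserts the half-of-smallest-voxel
bound uniformly over isotropic random directions, which the z-quantization
limit prevents from holding for z-dominant rays on anisotropic grids. The
direction-resolved error distribution (median well below a tenth of a
micrometre at default calibration) is the figure users should quote.

`register_canonical()` pools cells for spatially averaged views: each cell
is translated so $C$ is the origin, rotated so the pole–pole axis lies
along +x, the residual spin about x fixed by the principal yz axis of the
aligned kinetochores, and reflected (by a proper 180° rotation about y) so
the misaligned side is +x. The frame is fully determined by the point
geometry, so the pooled output is invariant to any rigid motion of the
input — a property the tests check to 10⁻⁶ µm.

## Segmentation choices

The original workflow binarized the ER channel interactively in Fiji; the
method and parameters were not part of the record. `binarize_channel()`
therefore exposes and logs its defaults: Gaussian smoothing with σ = 1 xy
voxel (scaled by the anisotropy ratio in z) followed by a global 3D Otsu
threshold, or a fixed threshold when reproducing a manual choice. Masks
carry full provenance (channel, frame, method, σ, threshold).

The exclusion zone is *delineated* rather than segmented directly: the ER
mask is morphologically closed (disc of 3 xy pixels per slice, so gaps
between membrane layers cannot leak), and the EZ is the largest 6-connected
cavity of `cell AND NOT closed(ER)` that does not touch the cell boundary.
The cell itself comes from the plasma-membrane channel where one was
acquired — shell binarization, closing across the z gap at the caps where
the membrane is tangent to a slice, slice-wise sealing, hole filling, and a
trim by the apparent membrane half-thickness (0.35 µm by default) so the
enclosed volume is unbiased. Without a membrane channel the fallback is
the filled convex hull of the ER mask computed slice-wise; with strongly
anisotropic voxels the slice-wise hull tracks the 3D hull closely while
keeping the computation in-plane.

DNA objects are 26-connected components (cavity detection uses 6-connected
components; the asymmetry is deliberate, matching the usual
foreground/background duality on 3D grids). The metaphase plate is the
largest object; exact volume ties break to the smallest (z, y, x)
lexicographic centroid so labeling is deterministic.

## Tracking, congression, anaphase and signal ratios

Objects are linked frame-to-frame by greedy nearest-centroid assignment
with a 2 µm/frame displacement gate; the plate is followed by its
largest-object flag rather than by distance. With a handful of slow
objects per cell, greedy matching is indistinguishable from global
assignment and much simpler to reason about; the gate is configurable.

*Congression* is the merging of a chromosome object with the plate object:
either the linked label coincides with the plate's, or the track ends and
the plate component at the next frame reaches the chromosome's last
position within its equivalent radius plus two voxels. *Anaphase onset*
was not given an operational definition in the original description, so the
package states its own and logs it: the first frame at which the plate
splits into exactly two children, each at least 25% of the prior plate
volume, whose centroid separation then increases for at least two
consecutive frames. The persistence rule rejects single-frame
segmentation flicker.

Fluorescence is quantified per object with the ROI expanded by 3 pixels in
xy within each z slice (planar ROI semantics, as in the ImageJ ecosystem; a
3D dilation is available behind a flag). The ER signal uses the mean
intensity over the expanded region; the spindle-checkpoint signal (Mad2)
uses the per-slice maximum averaged over slices, which tracks a small
bright spot far better than a mean. Both are expressed as
chromosome-to-plate ratios computed with the identical statistic, making
them dimensionless and exposure-invariant. One numerical caveat is built
in: a per-slice maximum over a large ROI is biased upward by uncorrelated
noise, and the bias lands disproportionately on the dim plate denominator.
The `max_per_z` path therefore smooths lightly (σ = 1.5 xy pixels) before
taking maxima; at a noise SD of a tenth of the plate signal this keeps the
measured ratio within a few percent of its noise-free value.

Checkpoint decay is summarized by pooled ordinary least squares of the
Mad2 ratio against time relative to anaphase onset, with 95% confidence
intervals, using only the last chromosome to congress (or fail to) per
cell, so each cell contributes one trajectory.

## ER clearance and the random-occurrence null

The ER volume trace is the voxel count of the ER mask inside the cell mask
times the voxel volume, per frame. Clearance is the largest decrease: the
trace is median-filtered (window 3 — one-frame segmentation flicker is the
failure mode this guards against; the window is configurable), centrally
differenced, and the clearance frame is the most negative derivative over
the frames where the full stencil exists, ties breaking earliest. With
central differences, a drop between frames $k$ and $k+1$ is attributed to
frame $k$; recovery is therefore quoted to ±1 frame throughout.

Because an argmin always exists, control cells with no clearance also
yield a "clearance time". The package models this explicitly:
`null_clearance_distribution()` simulates constant traces with iid
Gaussian noise and returns the empirical distribution of detected frames,
which is uniform over the eligible frames; control groups are compared
against this random-occurrence null (`ks_distance_uniform()`). A call is
flagged *significant* when the drop exceeds three times the MAD of the
derivative away from the minimum. The noise scale is estimated from the
raw (unsmoothed) derivative: the median filter flattens the derivative
almost everywhere on quiet traces, and a MAD taken after smoothing
underestimates the noise so badly that a third of pure-noise traces would
be called significant; estimated on the raw derivative the false-positive
rate is under 1%.

Rescue of a misaligned chromosome is scored on the distance trace: per
frame, the shortest distance from the chromosome centroid to the surface
voxels (6-connectivity boundary) of the main chromosome mass, normalized
to the starting distance. Traces end when the chromosome merges or at 90
minutes; rescue means merging within 80 minutes. Both windows are the
experimental constants of the assay and are stored in configuration with
those defaults.

## Colocalization

Kinastrin puncta mark stable end-on kinetochore–microtubule attachment.
`detect_puncta()` labels thresholded components (an optional 1-pixel
closing bridges sampling gaps) with intensity-weighted centroids;
`nearest_distance()` computes exact nearest-neighbour distances — the full
distance computation, deliberately, since approximate spatial indexes can
change results near ties; `fraction_within()` scores attachment as a
nearest distance strictly below 600 nm, per class, with the per-group
distance histograms emitted alongside.

## The statistics layer

Timing distributions are per-class empirical CDFs with medians
(`cumulative_timing()`); distribution comparisons use the two-sample
Kolmogorov–Smirnov test (exact for both samples ≤ 25); fate contingency
uses Fisher's exact test, two-sided by hypergeometric summation and
deliberately uncorrected; congression-time shifts use the tie-corrected
Wilcoxon rank-sum test; congression-time curves use the Kaplan–Meier
product-limit estimator with anaphase-without-congression as censoring.
All of these are computed by the standard `stats` and `survival`
machinery behind the package's interface; the test suite holds them to
independent oracles (full hypergeometric enumeration for every 2×2 table
with total ≤ 40, rank-assignment enumeration for small samples, and the
KM ≡ 1 − ECDF identity under no censoring). P values are reported exactly,
never as significance stars. A cell with several misaligned chromosomes
takes the highest class, ensheathed > free > aligned, and fates form the
closed set {normal, micronucleus, death, other}.

## What the synthetic generator does and does not emulate

`make_scene()` builds a parametric mitotic cell: a convex cell ellipsoid
(default semi-axes 4.5 × 4.5 × 3.4 µm), an EZ ellipsoid (2.0 × 2.0 ×
1.9 µm), an oblate metaphase plate with its normal along the pole–pole
axis, misaligned chromosomes of 0.5 µm radius placed outside the zone
(ensheathed, wrapped in 3–4 concentric shells 0.2 µm thick at 0.3 µm
spacing) or at/inside it (free), kinetochores, two spindle poles, and
kinastrin puncta whose per-class attachment probabilities default to the
observed attachment fractions (26.8% aligned, 4.1% free, 6.2% ensheathed).
Events are scripted: congression as constant-velocity approach
(0.7 µm/frame) merging at the congression frame, anaphase as the plate
splitting into two separating children, clearance as the loss of a
configurable fraction (default 0.8) of the extra-zonal ER with the
remainder retained under the cell boundary. Mad2 kinetics are linear in
time by construction (ratio 4 at anaphase, −0.05/min), because the
downstream regression is linear and recovery must be checkable against a
linear truth. Rendering applies an isotropic Gaussian PSF (σ = 0.1 µm)
and then Poisson and Gaussian noise; the structural plateau is 100
intensity units, so "SNR 10" in the tests means Gaussian σ = 10.

The geometric defaults describe a somewhat smaller cell than a live
mitotic epithelial cell (which runs 15–20 µm across); they were chosen
once so that a full scene renders on a ~100³-voxel grid, and all tests and
the acceptance script use them unchanged. Default recovery suites run 50–
100 cells per condition, with movie lengths of 16–25 frames; the
acceptance script scales to 25–60 cells per quantity.

Ensheathed objects are placed in the equatorial band off the spindle axis
(direction cosines |uₓ| ≤ 0.5, |u_z| ≤ 0.3) so they stay clear of the
corridor the anaphase children sweep; free objects favour the polar
regions, which is where real misaligned chromosomes accumulate. Placement
enforces true Euclidean clearance from the plate surface (computed against
the exact nearest surface point, not an axis-inflated ellipsoid, which
under-states clearance obliquely) large enough that pre-congression
objects survive PSF blurring as separate connected components.

The generator is deliberately not photorealistic: ER texture is concentric
shells rather than a tubular network (downstream analyses consume only
occupancy and volume, not topology); there is no photobleaching, no stage
drift, no sheet/tubule distinction, and chromosome motion is straight-line.
Passing tests therefore demonstrate that the *measurement* layer recovers
known geometry, events and kinetics under realistic sampling, PSF and
noise — not that it is robust to every artefact of live-cell imaging.

## Degenerate inputs and tie-breaks, in one place

* Constant channel under Otsu: error (degenerate histogram), including the
  numerically-constant case after smoothing.
* Constant volume trace: clearance argmin ties to the earliest eligible
  frame and is never significant.
* Equal-volume plate candidates: smallest (z, y, x) centroid.
* Fully tied Wilcoxon samples: p = 1.
* Empty puncta set: `nearest_distance()` errors ("no puncta detected");
  empty class groups report fraction NA rather than 0.
* A chromosome already inside the plate at its first frame: the
  misalignment trace errors (zero starting distance).
* Ray never leaving the zone before the grid edge: explicit
  "no boundary crossing" error.

## Limitations

The auto-classification threshold (ensheathed iff ≥ 75% of a 0.5 µm shell
is ER-positive) is a stand-in for a manual call made by eye in the
original workflow; both modes are reported and a manual annotation wins
when provided. The anaphase criterion and the linking rule are this
package's operationalizations of procedures the original description left
unspecified; both are logged in outputs so downstream consumers can see
which rule produced an event time. Boundary localization along z is
limited by slice spacing, as discussed above. The Cell Counter XML reader
targets the common `Marker_Data/Marker_Type/Marker` layout and rejects
other dialects loudly rather than guessing.
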