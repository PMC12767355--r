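---
title: "Quantifying junction integrity and mechanical signatures in epithelia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying junction integrity and mechanical signatures in epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epijunction)
```

## The measurement problem

During cranial neural tube closure, the neuroepithelium bends under
actomyosin-generated forces while cells constrict apically, divide, and
rearrange into transient multicellular rosettes. Whether cell-cell adhesion
holds up under these forces is read out from microscopy in a handful of
standardized quantities:

* **junction-network morphometrics** — vertices classified as tricellular
  (3 cells), 4-cell, or 5+-cell (rosette) junctions; edge orientations
  relative to the mediolateral (ML) axis; apical cell areas;
* **planar polarity of junctional intensity** — the mean background-
  subtracted intensity of ML edges (chord within 0-15 degrees of the ML
  axis) over that of anterior-posterior edges (75-90 degrees);
* **tricellular-junction (TCJ) enrichment** — a disk mean at the vertex
  over the average of line means along the three connected bicellular
  junctions, both background-subtracted;
* **junctional gaps** — circular regions of lost junctional signal, counted
  per 50 x 50 um region, stratified by junction order, and cross-referenced
  between the adherens-junction (AJ) and tight-junction (TJ) channels;
* **laser-ablation recoil** — the separation of the two vertices flanking a
  cut edge, sampled every 2 s for 8 s; the peak instantaneous velocity is
  the relative tension proxy;
* **time-lapse behaviors** — rosette formation and the fate of central
  gaps, whether dividing cells re-establish a junction-positive interface
  within 90 minutes, and the percent decrease of tracked apical area at
  1.5 h and 3 h.

`epijunction` implements all of these as testable functions operating on a
cell-label image (the product of any segmentation tool) plus co-registered
intensity channels. Because raw embryo imagery is not at hand, the package
pairs the analysis with a ground-truthed synthetic epithelium generator:
every statistic can be validated as a round trip, by generating data whose
true parameters are known and checking that the measurement recovers them.

## The synthetic epithelium

`make_mesh()` builds a Lloyd-relaxed Voronoi tessellation (3 iterations by
default), which reproduces near-hexagonal epithelial packing without a
mechanical model. Higher-order junctions are engineered by contracting
short tessellation edges to a point: one contraction makes a 4-cell vertex,
two adjacent contractions make a 5-cell rosette vertex. Two constraints
keep the result resolvable in the raster (0.25 um/px, typical of a 40-63x
confocal):

* a proximity cleanup iteratively contracts the closest pair of interior
  vertices until every pair is at least 1.1 um apart — vertices closer
  than that are indistinguishable from a single higher-order vertex at
  this sampling, both for the extractor and for a human;
* a quota contraction is rejected if any incident cell would be left with
  a wedge angle below ~28 degrees at the merged point (sub-pixel wedges
  make one vertex rasterise as a string of 3-cell corners), or if the
  merged point would land within 0.9 um of any other vertex or planned
  merged point.

`render_channels()` lays junctional signal over a uniform cytoplasmic
background: ~2 px edge strips at `edge_intensity_base` (x `polarity_factor`
for ML-binned edges), 0.5-um vertex disks at `tcj_enrichment` x base, and
additive Gaussian noise. Absolute intensities are nominal (base 100 a.u.
over background 50 a.u., noise sd 4 a.u.) since no absolute junctional
intensities or SNR are reported anywhere for this system; all are exposed
in `generator_config()`.

`inject_gaps()` voids a disk (back to background) at each interior vertex
independently, with an order-specific probability, the radius drawn from a
truncated normal (mean 0.6, sd 0.2, minimum 0.45 um). The lower truncation
sits just under two pixels: a void smaller than the pixel pitch cannot be
resolved by any detector operating on the same raster, so smaller "gaps"
would be unmeasurable by construction rather than by biology. TJ gaps are
drawn only at AJ gap sites, at half the AJ radius, reflecting their
consistently smaller size and strict co-occurrence.

### Preset calibration

The named presets encode the study conditions as printed cohort statistics:

| preset | gap probabilities (3/4/5+) | expected gaps per region |
|---|---|---|
| `mutant_late` | 0.18 / 0.49 / 0.78 | 35 |
| `control_late` | 0.05 / 0.14 / 0.32 | 18 |
| `mutant_early` | scaled profile | 12 |
| `control_early` | scaled profile | 4 |

The per-order probabilities and the per-region totals are not independent:
their link is the junction census of a 50 x 50 um region. The presets
therefore fix the mesh density so that the census lands inside the reported
ranges (81-175 three-cell, 21-57 four-cell, 7-19 five-plus-cell junctions
per region) *and* the probability-weighted census reproduces the printed
totals: ~(91, 25, 8) junctions per region for the mutant-density mesh
(0.18*91 + 0.49*25 + 0.78*8 = 35) and ~(148, 45, 15) for the denser control
mesh (giving 18.5). The early-stage presets print totals but no per-order
fractions, so their probabilities are the late-stage order profile scaled
to the totals with `scale_gap_probs()` — this is also the implementation of
the rule that a configured per-region target overrides absent
probabilities.

Movie presets carry the printed dynamic rates: new-interface failure in
49% vs 1% of divisions, neighbor-contact gaps in 73% vs 8%, central gaps in
71% vs 11% of rosettes (with mutant fates split 20/33 repaired, 7/33
persistent, 6/33 expanding), and apical-area decreases of 17% at 1.5 h and
22% at 3 h. Division counts per movie (~50 mutant, ~20 control in a
100 x 100 um field of 220 cells) are generator choices sized so that the
recovery experiments reach their nominal event counts (at least 200
divisions, at least 100 rosettes) within a handful of movies; real
acquisitions of this kind yield far fewer events per cohort (tens of
divisions), which changes precision but not the estimand.

## Graph extraction choices

`extract_graph()` must work from pixels alone. The skeleton band (label 0)
is first assigned to the nearest cell by exact Euclidean offset distance
with a fixed direction order on ties, so the fill does not depend on label
values. Vertices come from a 2 x 2 corner scan (3+ distinct labels at a
pixel corner), single-linkage clustered within 1.5 px. A discrete 4-fold or
5-fold point is unstable under rasterisation — it generically splits into
3-fold corners joined by a spurious 1-2 px contact — so cluster centroids
closer than `vertex_merge_um` (0.85 um, safely below the generator's 1.1 um
minimum edge) are re-merged. Vertex order is the number of distinct labels
within `order_radius_um` (0.6 um) of the vertex *united with* the cells of
all incident edges; the union makes the order robust to thin wedges whose
pixels only appear away from the vertex. On generator meshes this pipeline
recovers the census to ~1% and individual orders at ~99% agreement (the
residual confusion is a handful of 4-versus-5 calls per thousand
vertices); no pixel rule for junction order is stated in the source
methods, so the disk radius is exposed as a parameter.

Cells touching the image border are excluded from area statistics (their
areas are truncated), and a vertex or gap belongs to a region iff its
center lies in the half-open box `[origin, origin + size)`, so tiling
regions never double-count. Bin boundaries at exactly 15 or 75 degrees are
bin members (closed bins), matching the inclusive printed ranges.

## Intensity measurement choices

* Per-edge means are taken over a pixel strip of full width 0.5 um around
  the edge polyline, excluding 1 um at each end so TCJ enrichment does not
  leak into bicellular means (strip width and exclusion are parameters; the
  source methods drew lines by hand and state neither).
* The background estimate averages the mean intensity of 20-40 circular
  ROIs placed automatically at cell-interior points; manual ROI placement
  is replaced by the cell centroid with a farthest-from-boundary fallback.
* The TCJ disk radius for measurement is 0.35 um, deliberately smaller
  than the 0.5 um rendered disk so that sub-pixel vertex-localisation
  error stays inside the enriched region; on noise-free renders the
  enrichment ratio is then recovered exactly.
* Line profiles are sampled by bilinear interpolation, background
  subtracted, and normalized to their maximum; a line whose maximum does
  not exceed background is returned unnormalized and flagged.

## Gap detection

The source protocol scores gaps by eye ("clear loss of signal"); the
algorithmic stand-in is: a vertex is gapped when the lower quartile of the
background-subtracted junctional-band pixel intensities within 0.45 um
falls below `threshold_fraction` (default 0.3) of the region's median
background-subtracted per-edge intensity. The lower quartile rather than
the mean makes the call robust to sub-pixel vertex-localisation error,
which otherwise lets bright surrounding pixels mask a gap at high-order
vertices. The threshold is recorded in every output. The gap radius then
grows along each incident edge until signal recovers. This rule cannot be
validated against the original images — only against generator truth,
where it reaches ~100% sensitivity with a zero false-positive rate at the
default noise level.

Overlapping gap circles are replaced by the exact minimum enclosing circle
of the component (solved in closed form from 1-, 2- and 3-circle
candidates), iterated to a fixed point so merging is idempotent. Merged
gaps keep their constituents, and per-junction statistics (the stratified
fractions) are computed on the constituents so that merging never hides a
gapped junction. Bicellular gaps are scored separately and excluded from
per-region totals by default, following the counting convention for
tricellular and multicellular gaps.

## Recoil kinetics

Traces follow the exponential (Kelvin-Voigt) relaxation
`d(t) = L0 + A (1 - exp(-t / tau))`. Velocities are frame-to-frame
differences including the pre-ablation interval (whether the original
analysis used the pre-frame or frame-to-frame differences is unstated;
frame-to-frame including the pre-frame is implemented). The peak velocity
of a noiseless trace is its first-interval velocity and underestimates
`v0 = A / tau` by the factor `tau (1 - exp(-dt/tau)) / dt`; the package
asserts this identity in its tests. The optional fit profiles tau by
golden-section search with the linear parameters solved exactly at each
candidate, which is deterministic and exact to ~1e-9 on noiseless traces.
The discard rule for "no measurable recoil" defaults to a zero noise floor
(no number is printed); a pre-frame-variance floor is available.

## Time-lapse scoring

Movies are assumed registered. The trackers use only label and intensity
frames:

* the movie renderer widens edge strips to 1.5 px half-width and vertex
  disks to 0.7 um so that every skeleton-band pixel carries signal (stray
  unrendered band pixels would otherwise read as tiny spurious gaps);
  contact gaps are only scheduled on contacts at least 3.5 um long between
  a dividing cell and a non-dividing neighbor, because a shorter contact
  is fully covered by its flanking vertex disks and a gap there would be
  unobservable by construction (and a contact between two dividing cells
  would be double-counted);
* divisions are followed by frame-to-frame footprint overlap; completion is
  the first frame the daughter-daughter interface reads above the gap
  threshold; events without a junction-positive interface within 90 min
  are right-censored and scored as failures. Contacts are scored by the
  lower quartile of their boundary pixel values after trimming up to
  0.8 um at each end — the flanking vertex disks would otherwise push a
  fully voided short contact above threshold.
* a rosette track starts at the first frame a 5+-order vertex appears;
  linking is nearest-neighbor within 3 um with deterministic tie-breaks,
  time-gapped fragments are re-joined, and parallel duplicates absorbed.
* the central-gap area at a rosette is the connected component of voided
  band pixels seeded at the center — distant voids (for example at a
  dividing neighbor) do not count until they genuinely merge with the
  central gap. A fate is `expanding` only when the area grows by more than
  12% per frame over two consecutive frames, because a constant-radius gap
  in a constricting tissue shows a slow apparent growth that must not
  count; `repaired` requires the gap to stay absent for the remainder of
  the movie (at least 2 frames).
* apical-area trajectories sum the areas of cells trackable from frame 1
  to the checkpoint (same label, border-free at both ends; divided cells
  drop out because both daughters get fresh labels) and report the percent
  decrease; fewer than 50% trackable cells flags the result unreliable.

## What passing tests do and do not show

The generator emulates polygonal packing, polarized junctional intensity,
TCJ enrichment, order-dependent gap statistics, uniform constriction,
divisions and rosettes with configurable failure modes, and exponential
recoil — the statistical structure the estimators assume. It does not
emulate curved 3D tissue, a point-spread function (a blur option exists but
defaults off), photobleaching, shot noise, segmentation errors, or
mechanically realistic rearrangement dynamics. Recovery of preset
parameters therefore demonstrates that the estimators are unbiased and
correctly calibrated on data satisfying their assumptions; it does not
certify performance on real microscopy, where the by-eye gap criterion and
the segmentation itself dominate the error budget.

## Problem sizes used in validation

The validation suite runs the full pipelines at the scales the recovery
targets call for: fields are accumulated until the rarest graded class
(4-cell junctions) exceeds 2000 vertices (~80 fields of 50 x 50 um; the
5+ class reaches ~650 at that point and is asserted at its realized
binomial precision), per-region counts use 50+ independent fields, and
movie statistics pool five 3-hour movies per cohort (~250 divisions and
~125 rosettes for the mutant preset). All tolerances are three standard
errors at the realized n, never a fixed percentage.
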