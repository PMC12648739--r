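---
title: "Tracking root emergence and scoring seed vigor with germtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking root emergence and scoring seed vigor with germtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

germtrack quantifies seed germination from overhead time-lapse imagery of
seed lots on germination paper: it tracks every root tip through time,
derives seed-, root-, and seedling-level traits, and condenses them into a
per-genotype vigor score that combines germination *speed* with
germination *uniformity*. This vignette explains the models and
procedures, the parameters that matter, and the design decisions taken
where the problem left genuine freedom.

## The data model

An acquisition is an `image_series`: hourly RGB frames (default interval
1 h) at a known scale (default 0.05 mm/px, about 5,000 px per wheat
seed). Segmentation is consumed as per-frame *label maps* with four
classes — background (0), seed body (1), root (2), seedling (3) — either
produced externally (e.g. by a learned segmentation model) or by the
built-in classical fallback (`segment_frame_classical()`), which matches
the paper colour with an HSV model, detects green seedlings by the
excess-green index, and separates the compact seed body from thin roots
by a morphological opening sized above the root width. Per seed, a label
map crops to a `mask_triplet`: seed body, full plant, seedling.

Germination phases follow the standard seed-testing vocabulary:
imbibition (IMB), protrusion (PRO, roots visible but radicle < 2 mm),
radicle emergence (RE, radicle ≥ 2 mm — the ISTA "germinated" rule; 10 mm
marks an established root system), and seedling establishment (SE, the
coleoptile is visible). A lot enters a phase at the first hour at which
at least 75% of its seeds have (`lot_phase_time()`, with optional
standardized sampling of 15 seeds so lots of different sizes are
comparable — with 15 seeds the rule needs ⌈0.75·15⌉ = 12).

## Root-tip tracking as a temporal directed graph

Each root is a growing path, tracked as a temporal graph. Before
emergence the graph is empty; at the frame before emergence (`t_e − 1`)
it holds a single vertex — the skeleton point where the root meets the
seed coat; from `t_e` on, each frame may append the current tip position
and the skeleton route connecting it to the previous tip.

Per frame, the root mask (full plant minus seed body minus seedling) is
thinned to a 1-px skeleton. We use Guo–Hall thinning followed by
template-based staircase removal: Zhang–Suen-style thinning erases
2-px-wide diagonal runs entirely and leaves staircase pixels that
masquerade as branch points, both of which are fatal for tip topology.
Endpoints (one 8-neighbour) outside the dilated seed body and seedling
masks (3 px dilation, a guard against boundary roughness) are the tip
candidates; per seed-adjacent component, the skeleton pixel nearest the
seed body is the root's origin.

A candidate tip `P` extends a track when

* the route from the current tip to `P` has minimum weight among
  candidates, where skeleton pixels weigh 0 and all others weigh 1
  (8-connected uniform-cost search; full geometric length breaks ties);
  a route costlier than `max_route_weight = 3` off-skeleton pixels is
  considered no continuation of this root at all — it would have to jump
  onto a disjoint skeleton;
* the turn angle between the previous growth direction and the direction
  to `P` is at most 60° (`cos ≥ 0.5`). 60° is the default because an
  overhead view constrains in-plane turning; a 90° gate is exposed as
  configuration for side-view conventions. Growth directions are taken
  tip-to-tip between accepted vertices; to avoid 8-neighbour
  quantisation noise at slow growth the reference vertex is the most
  recent one at least 4 px back.

If no candidate qualifies, the frame records zero growth; a tip
undetected for more than 5 consecutive frames closes the track, as does a
tip reaching the ROI border. Once any crossing involves a seed's roots,
no *new* tracks are opened for that seed (existing ones continue); this
deliberately trades completeness for reliability. Root indices (1 =
radicle) follow emergence order, with simultaneous emergences ordered by
clockwise angle from the seed centroid starting at 12 o'clock.

### Crossing resolution

Where roots intersect, the skeleton develops branch points (≥ 3
8-neighbours). Two branch points within 5 px merge into an *equivalent
branch point* at their midpoint (a thick crossing thins into two nearby
Y-junctions); larger clusters are treated as one candidate region at
their centroid. Around each centre the skeleton is cut into arms, and
each arm's direction is estimated over a 15-px window — direction to the
far tip would be unstable for curved arms. Regions with 3 or 4 arms are
resolved; tangles with more arms are flagged and excluded.

Arms are paired with preference for pair angles closest to 180°: for
4-arm regions the disjoint pairing minimising the summed deviation from
180° wins. The summed deviation ties *exactly* between the two crossed
pairings whenever all four arms fall within a half-circle, so a
deterministic secondary criterion (the pairing whose best single pair is
most collinear, then pairing order) breaks ties; when the best and
second-best pairings differ by under 5°, the tracks' previously recorded
growth directions pick the more consistent continuation. A route through
a resolved region must enter and leave along a paired continuation or
the candidate is rejected; when a route starts at the region centre (the
tip reached the crossing this frame), the track's previous direction
stands in for the entry direction.

### Length accounting

Cumulative root length is the on-skeleton geometric length of the route
from the root's origin to the current tip (plus the small origin-to-coat
gap that thinning removes), converted to mm. Two choices matter here:

* *One measurement per frame, not a sum of increments.* The accepted
  routes tile the origin→tip path, so measuring it in one piece is
  equivalent in the ideal case — but summing many short segments between
  noisy per-frame tip positions accumulates a random-walk inflation of
  roughly +0.4 px per frame, which is material for slow-growing lateral
  roots.
* *Corner-corrected chain length.* Raw Freeman chain steps (1 per axial,
  √2 per diagonal) overestimate the length of a digitised curve by up to
  8% depending on orientation (worst at 22.5°). The default estimator
  applies the standard corner-corrected coefficients
  0.980·n~axial~ + 1.406·n~diagonal~ − 0.091·n~corner~, which is
  unbiased to under 1% on straight digital lines at every orientation.
  `step_weights = "freeman"` restores the raw accounting (a straight
  100-px axial route at 0.05 mm/px then measures exactly 5.0 mm).

Growth rates are centred finite differences of moving-average-smoothed
lengths (window 5 frames); applying the same operator to the rate gives
its derivative, whose absolute argmax is the time of fastest rate
change.

## Traits and event times

Seed morphology comes from the seed-body mask: area (pixel count ×
scale²), length and width as the sides of the minimum-area rotated
bounding rectangle (deterministic and rotation-invariant, unlike an
axis-aligned box), W/L ratio, and roundness 4πA/P². The perimeter
estimator is the Douglas–Peucker-simplified (1 px tolerance) boundary
contour through pixel centres plus π for the half-pixel outward offset of
a convex boundary; this recovers both smooth outlines (rasterised disk:
roundness within 2% of 1) and polygonal ones (axis-aligned rectangle)
where raw or globally corrected chain codes fail one or the other. Seed
colour is the per-channel mean over the mask; change rates are
percentages relative to frame 1.

Event times are reported at the frame grid (1-h resolution, first
crossing, no sub-frame interpolation): protrusion (first root pixels),
2 mm and 10 mm radicle crossings, coleoptile emergence (first overlap of
the seedling mask with the seed body — for single-label maps, whose
classes are exclusive by construction, touching within 1 px counts),
seedling establishment (first nonempty seedling mask), and chloroplast
biogenesis. The greening threshold is the mean excess-green value
(ExG = 2G − R − B on raw 8-bit channels; no chromatic normalisation) over
all seedling pixels of the *lot* at the 80th hour — the lot-wise pooling
is more robust than a per-seed mean, which remains available via
`scope = "seed"`. A seed turns green at the first hour its seedling
pixels exceed the threshold; the literal "any pixel" rule is guarded by a
5-px minimum exceedance count against salt noise. Events never reached
within the horizon are censored, and truncating a series can only censor
an event, never move it earlier.

## Speed, uniformity, and the vigor matrix

Per genotype, mean radicle-length profiles (with a central-75% dispersion
band) are clustered by Ward-linkage agglomerative clustering of the
curves into quick / medium / slow speed groups, labelled by ascending
mean time-to-2-mm. Event-time distributions (e.g. chloroplast-biogenesis
hours) are clustered without a preset cluster count by affinity
propagation on per-genotype summary vectors (median, IQR, censored
fraction; damping 0.5, preference = median similarity); emerging clusters
are ordered by median hour and, if more than three emerge, merged to
three by adjacency on the hour axis, choosing the contiguous 3-partition
with minimal within-group sum of squares. Affinity propagation is
implemented in the package (standard responsibility/availability message
passing) and validated against a deterministic partitioning oracle; with
only two genotypes the message passing is degenerate and the two are
ordered directly.

The uniformity score of a set of event hours is the ratio of the modal
histogram-bin fraction (bin width = the frame interval) to the central
75% span expressed in bins (at least 1): it is 1 exactly when all
uncensored events share one bin, decreases as the central span widens,
and always lies in [0, 1]. Censored seeds are excluded and reported
separately rather than penalising the score — the alternative would
conflate speed with uniformity. The published scores of the original
wheat study use an unstated normalisation and are not comparable number
for number; this construction is the package's own calibration with the
stated guarantees.

The vigor matrix awards 3 / 2 / 1 points for quick / medium / slow per
phase (PRO, RE, SE — mapped to protrusion, 2-mm, and seedling-emergence
times), multiplies by the phase's uniformity score, and sums the three
phase scores into an overall score in [0, 9]. Overall classes (high /
medium / low) come from affinity propagation on the *log* overall scores:
points and uniformity enter multiplicatively, so tiers separate by
ratios, and clustering on the raw scale would systematically split the
widest tier instead. Summing phase scores (rather than clustering the
three-dimensional phase-score vectors) keeps the aggregate monotone:
improving any phase's group or uniformity can never lower a genotype's
overall score.

## The synthetic germination simulator

Every stage above is testable without any image archive through
`simulate_lot()`: seeds are rendered as ellipses (~60 × 40 px) on a
configurable paper colour, swelling by a factor 1.3 in area over the
first 20 h of imbibition; each root grows along a jittered polyline
(width 3 px, 2° per-2-px heading jitter) whose arc length follows a
logistic law anchored at a stochastic emergence hour (radicle ≈ N(40, 5²)
h, matching the canonical exemplar of radicle emergence at the 40th
hour; laterals later and shorter); seedlings appear at the seed apex and
switch to green albedo at their greening hour; label maps render
noise-free while RGB frames add Gaussian pixel noise (sd 8). The
logistic family was chosen because observed radicle profiles are
sigmoid: a gradual rise that slows near the end of the monitoring
window. The radicle's maximum length defaults to 13.5 ± 0.8 mm so that
the 10-mm establishment threshold is crossed mid-slope, as in wheat;
a greening transition is rendered as instantaneous so ground-truth event
hours are crisp (real greening is gradual, so on real data the
chloroplast time inherits the threshold's resolution).

Ground truth records every root's emergence frame, per-frame true arc
length, crossing events, and per-seed event hours, in the same schemas
the pipeline writes, so recovery tests are column-wise comparisons.
Three presets drive the package's end-to-end checks: `no-crossings`
(4 × 4 independent seeds), `one-crossing` (2 × 2, each horizontal pair
steered toward exactly one radicle–radicle crossing, desynchronised by
±6 h so the crossing forms on an existing root), and `three-tier-vigor`
(an event-level scenario of 21 genotypes in three designed tiers of
seven — fast-uniform, middling, slow-dispersed — with 40 seeds per
genotype; the larger per-genotype sample keeps the sampling noise of the
uniformity score below the designed tier separation, and the slow tier's
late seedling events censor past the 96-h horizon).

What the simulator does *not* emulate — photorealistic texture, root
hairs, moisture reflections, seed movement, segmentation errors of a
learned model — bounds what passing tests show about real data: they
validate the tracking, measurement, and scoring machinery on clean masks
of realistic geometry, not robustness to imaging pathology.

## Problem sizes, numerics, and limitations

The package's own validation runs 20 simulated lots of 16 seeds × 96
hourly frames for length-recovery statistics and six two-pair lots for
crossing robustness; these sizes give several hundred roots while keeping
a full check affordable on a laptop. Route searches are restricted to
the bounding box of the skeleton plus source and candidates — a
restriction that is cost-exact for 0/1 node weights, since clamping any
path into that box never increases its weight. Ties anywhere
(route costs, pairings, cluster labels) break deterministically, and all
stochastic steps take explicit seeds, so identical inputs and
configuration reproduce identical outputs bit for bit.

Known limitations: tangles of five or more arms are excluded rather than
resolved; roots are not re-identified after total occlusion; root hairs
are not suppressed beyond what the mask provides; no seed-position
correction is applied beyond whole-frame registration (translation by
phase correlation, optional ±2° rotation search); and the PRO/RE
boundary of a visual phase detector is approximated by the 2-mm rule, so
externally supplied phase labels may disagree near that boundary.
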