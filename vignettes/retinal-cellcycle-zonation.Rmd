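---
title: "Methods: cell-cycle phase calling and vascular zonation in FUCCI retina images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle phase calling and vascular zonation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinocycle)
```

## The measurement model

The PIP-FUCCI reporter encodes cell-cycle state in two nuclear fluorophores.
mVenus–Cdt1(1–17) carries the PIP degron: it is expressed in G1/G0,
degraded abruptly at the G1/S transition, and re-expressed at the start of
G2. mCherry–Geminin(1–110) is expressed in S and G2 and destroyed at
mitosis. Classifying a nucleus therefore reduces to two binary positivity
decisions: venus+/cherry− is G1/G0, venus−/cherry+ is S, double-positive is
G2 (the reporter cannot separate G2 from M, so "G2" throughout means
G2-through-M; `G2M` is accepted as an input alias), and double-negative
nuclei are *unlabeled* — they carry no phase information (unexcised
reporter cassette, or cells caught at the very start of G1 or S) and are
excluded from every phase denominator. `UNCALLED` is kept distinct from
`UNLABELED` so that "not yet classified" can never be silently conflated
with "classified as reporter-negative".

The measurement unit is the endothelial nucleus: the ERG stain marks all
endothelial nuclei, and each nucleus's mask is the region over which the
reporter channels are averaged (mean fluorescence intensity, MFI). MFIs are
raw mask-means by default — no background subtraction — because the
positivity thresholds are estimated from the same distribution and a
constant offset would cancel; an optional constant-background flag exists
for data where it does not.

## Segmentation and its parameters

Nuclei are segmented from the ERG channel classically: Gaussian smoothing
(`sigma`, default 2 px), a global Otsu threshold, hole filling, removal of
objects under `min_area` (default 30 px), and an optional
distance-transform watershed to split touching nuclei. Defaults suit
nuclei of roughly 10–20 px diameter; all are exposed in `seg_params()`.
Two choices deserve comment:

* **Watershed control.** The split is parameterized by the watershed's
  height tolerance on the distance transform (`watershed_tolerance`,
  default 1 px) rather than a peak minimum distance; smaller values split
  more aggressively. Two nuclei whose centers are closer than about one
  nucleus diameter produce a mask without a neck and cannot be split by any
  shape-based method — this bounds what "recovers the seeded count"
  can mean on crowded data.
* **Border nuclei.** Nuclei touching the image border are partially
  observed, biasing both area and MFI, so `exclude_border = TRUE` by
  default. This is a pipeline choice, not a claim about how any particular
  dataset was originally measured.

Label IDs are assigned in raster order of each object's first pixel, so
identical inputs always yield identical IDs.

## Threshold estimation

Reporter positivity thresholds are estimated *per retina*, because
expression level and staining intensity vary between animals. The default
method is Otsu's criterion on `log1p(MFI)` per channel: expressing and
non-expressing nuclei form two well-separated modes on the log scale, and
Otsu's between-class-variance maximum lands between them. When a channel's
distribution is degenerate (effectively unimodal — for instance a retina
with no S-phase cells at all would have a near-empty cherry-on mode), the
estimator falls back to a background-mode + k·MAD rule (k = 3 by default)
with a warning; that rule is also available as an explicit method. An MFI
exactly equal to the threshold counts as positive — an arbitrary but fixed
tie-break that is measure-zero on real intensities.

## Zonation

Vascular zones are consumed as drawn, never inferred: polygon outlines for
primary arteries and veins (PA/PV), arterioles and venules (Art/Ven),
angiogenic front capillaries (AFC) and mature capillaries (MC), plus
explicit nucleus-ID lists for tip and stalk cells, which are identified
per cell rather than per region. Assignment is by nucleus centroid (the
recorded per-nucleus coordinate), with a fixed precedence: tip list, stalk
list, then PA, PV, Art, Ven, AFC, MC in polygon order, else `UNASSIGNED`.
Multiple polygons of one zone act as a union (all polygons of a zone are
merged per retina). Hand-drawn polygons of different zones can overlap even
though the classification is conceptually exclusive; the precedence order
makes the outcome deterministic and every overlap is surfaced as a warning
rather than silently resolved. A nucleus listed as both tip and stalk is an
error. Capillary nuclei falling between drawn AFC and MC polygons are
reported `UNASSIGNED` rather than guessed into either zone; they still
count in whole-retina statistics.

The point-in-polygon test is the even-odd ray-crossing rule with boundary
points counted inside (a nucleus sitting on a drawn line should not vanish
from the analysis). It is verified in the test suite against an
independent winding-number implementation on 10^4 random point/polygon
pairs.

## Zone statistics

The retina is the experimental unit. For each retina × zone, the package
reports counts and percentages of labeled nuclei in G1/G0, S and G2
(percentages sum to 100 within a row), and two count ratios, G2/S and
G2/G1. Ratios are computed per retina and then averaged across retinas —
never pooled — and a zero denominator with a positive numerator yields the
cap value 10, so a retina whose tip zone has G2 cells but no S cells still
contributes a (right-censored) ratio instead of an infinity that would
silently drop it. The same cap is applied to G2/G1, an extrapolation of the
stated G2/S rule to the parallel statistic. A 0/0 ratio contributes 0 and
is flagged, rather than dropped, so n stays constant across retinas.
Reported ratio means are rounded half away from zero, to 1 decimal at ≥ 1
and 2 decimals below 1, matching how such ratios are conventionally quoted
(base R's round-half-to-even would turn a mean of 9.25 into 9.2 rather
than 9.3).

Marker concordance (EdU, Ki67) is a cross-tabulation over labeled nuclei
only: per phase, the share of marker-positive cells falling in that phase,
and the marker-positive fraction within the phase. Group comparisons use
standard machinery — one-way or two-way ANOVA with Sidak-adjusted pairwise
contrasts via `emmeans`, and paired t tests pairing on retina.

## Live-trace segmentation

Single-cell traces (10-minute frames) are segmented within one
cytokinesis-to-mitosis span, bounded by externally supplied mitosis events
(scored from an H2B channel or annotation — the reporter itself is not used
to detect mitosis). The venus trace is min-max normalized within the span
and median-smoothed over 3 frames; hysteresis thresholds then locate the
transitions: after the trace has exceeded `theta_on` (default 0.5), the
first frame below `theta_off` (default 0.2) is G1/S, the first subsequent
frame back above `theta_on` is S/G2, and G2 ends at the closing mitosis.
Two thresholds instead of one prevent chatter when noise straddles a single
cut. The cherry trace must exceed its own threshold somewhere in the
detected S interval; if not, the span is flagged low-confidence rather than
rejected, accommodating the documented accumulation lag of the
Geminin-fragment signal after S entry. Spans with no venus drop, or a flat
venus trace, are unsegmentable and rejected outright. Because boundaries
sit on the frame grid, G1 + S + G2 durations tile the intermitotic interval
exactly.

Per-phase migration velocity is the mean frame-to-frame displacement over
the frame interval. The "normalized distance" metric expresses each phase's
path length per time window equal to the cohort's mean G2 duration
(`path / duration × mean-G2-window`); this is our interpretation of
distance-per-time normalized to the average G2 interval, chosen so that
phases of very different lengths are compared on a common time base.

## The synthetic-data generator

The generator exists so that every pipeline stage has ground truth. It
builds a stylized radial retina — artery/vein spokes and arteriole/venule
branches inside a capillary annulus (MC), an angiogenic-front annulus
(AFC), and a tip/stalk band at the outer edge — places nuclei uniformly
inside their zone with a minimum center spacing of 2.5 nucleus radii,
draws each nucleus's phase from its zone's mixture after an independent
unlabeled coin flip, and renders each channel as Gaussian spots with
additive noise. Reporter amplitudes are lognormal given phase (strictly
positive and right-skewed, like fluorescence), with "on" and "off" modes
separated far beyond 4 sigma in log space by default. ERG amplitude is
phase-independent.

Defaults are the study conditions the pipeline targets: ~3800 nuclei per
retina; an 18% unlabeled fraction; per-zone phase mixtures with G2-enriched
tip (17.3%) and stalk (18.9%) cells against 8.4% in AFC, S-rich AFC
(15.5%) against 7% in MC and ~2% in arteries, and S-poor tip cells (1%);
marker models P(EdU+|S) = 0.89 and P(EdU+|G2) = 0.05 (EdU is a per-phase
Bernoulli — the small G2 probability stands in for cells labeled in S that
reached G2 within a 2-hour labeling window, rather than simulating the
window explicitly), and P(Ki67+|G1/G0) = 0.24 with cycling phases
essentially Ki67-positive. The count-weighted aggregate of the per-zone
mixtures is close to, but not exactly, the canonical whole-retina 86:9:5
mixture; analyses that need exactly 86:9:5 set a uniform mixture across
zones, as the acceptance script does. The trace generator draws per-phase
durations from truncated normals with means 8.1, 5.8 and 1.8 h (G1, S,
G2), snapped to the frame grid so truth boundaries are exact; venus is a
square wave (high–baseline–high), cherry rises during S after a 0.5 h lag
and collapses at mitosis, and positions follow a per-phase random walk
with G1 speed twice the S/G2 speed.

What the generator does *not* emulate bounds what passing tests show:
nuclei are isotropic Gaussian spots without shape variation, overlap is
limited by the spacing rule rather than true crowding, illumination is
flat, zones never overlap, and annotations are error-free. Recovery
results on this data demonstrate the pipeline's correctness, not its
robustness to segmentation-hostile real images.

## Problem sizes, variance, and numerical choices

The test suite and acceptance script run at the scale of the study design:
one ~3800-nucleus whole retina for mixture recovery, and cohorts of four
zoned retinas with ~40 tip and ~40 stalk nuclei each (about 33 labeled
after unlabeled thinning) for front-zone statistics. At that size the
across-retina mean of a tip or stalk percentage has a multinomial standard
error of ~3.3 points, so zone-level recovery values fluctuate by a few
points from seed to seed; AFC quantities (~330 labeled nuclei per retina)
are an order of magnitude tighter. For the same reason, detecting the
tip-vs-AFC G2 gap with only 4 retinas of ~40 tip cells has limited power
(~0.6 for a paired one-sided t at alpha 0.05 by simulation); the
Monte-Carlo power property in the test suite therefore runs at 150 cells
per front zone, where power exceeds 0.95.

Other numerical choices: coordinates are 0-based pixel indices (x = column
rightward, y = row downward) shared by images and polygons, eliminating
off-by-one between mask and annotation; CSV is the canonical nucleus-table
format and GeoJSON the polygon format (plain text, diffable); 1-D Otsu uses
256 histogram bins; generator randomness flows from a single config seed
through an isolated RNG scope, leaving the caller's RNG state untouched;
and all-zero or constant images segment to zero nuclei rather than
erroring, so empty fields of view flow through the pipeline.

## Known limitations

* Phase calling is threshold-based and per-retina; partial-volume effects,
  flat-field variation or strongly overlapping intensity modes would
  require calibration the package does not attempt.
* The double-positive state conflates G2 and M; no mitosis detection is
  attempted on still images.
* Zonation trusts the annotations; there is no automatic vessel tracing or
  front detection.
* Trace segmentation assumes one clean venus drop and re-rise per span;
  cells with aberrant reporter dynamics are rejected rather than
  rescued.
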