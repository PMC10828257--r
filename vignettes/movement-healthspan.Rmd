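---
title: "Measuring C. elegans healthspan from population movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring C. elegans healthspan from population movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plategazer)
```

## The assay

*C. elegans* loses mobility long before it dies, so the decline of
population movement is a direct, early readout of ageing. plategazer
implements a desk-scale version of an automated plate-imaging assay: each
6-cm agar dish of ~30 worms is imaged in bursts ("imaging windows") of 200
frames over 160 s (one frame every 0.8 s), one burst every 5 minutes, from
the L4 stage for 7–14 days. Nothing touches the plates during the run;
movement is inferred purely from pixel changes.

Per window the analysis is:

1. **Temporal background subtraction.** The 200 frames are averaged per
   pixel; a pixel counts as *changed* if it deviates from that mean by at
   least `diff_threshold` (default 15 gray levels on 8-bit) in at least
   one frame. The OR-accumulation of changed pixels is the *motion mask*:
   a high-contrast image of everything that moved during the window.
   A worm that never moves matches the mean everywhere and vanishes —
   this is what makes the assay specific to movement.
2. **Object extraction.** 8-connected components of the mask are the
   *motion smears*. Components below `min_area_px` (default 5) are noise
   residue; components whose centroid falls outside a circular ROI (the
   dish interior) are ignored.
3. **Length and speed.** The length of a smear is measured as the chain
   length of its morphological skeleton (axial steps count 1 pixel,
   diagonal steps √2), and speed = length / 160 s. Objects slower than
   `v_min_um_s = 10` µm/s are discarded: worm trails in the bacterial
   lawn and other slow intensity drift fall below this threshold.

Per window and plate this yields the three population outputs:
*fraction moving* = objects / worms plated, *mean speed of moving worms*
(undefined when nothing moves — never coded as 0), and their product, the
*mean speed of all worms*. Worms are deliberately **not** tracked across
windows; population-level metrics are sufficient to measure ageing and
avoid the hard identity-maintenance problem.

## From windows to endpoints

Per-plate series are optionally censored (windows around plate transfers
or restarts create spurious movement bumps), smoothed with a centred
moving average (default half-width 6 windows ≈ 1 h at the 5-min period),
and aggregated across dishes into condition curves with a per-time SEM.
Endpoints are trapezoidal AUCs over day ranges (day 0 = L4 placement;
"days 2–7" means t ∈ [2, 7]): the AUC of fraction moving is the average
time spent moving (days); the AUC of mean speed of all worms, × 86.4,
is the average distance moved (mm). AUCs are computed per plate on the
smoothed series and then averaged, so that a per-dish spread (and hence a
SEM) exists for the comparison step — not as the AUC of the mean curve.

Two conditions are compared by Gaussian error propagation: the difference
of mean AUCs carries SE √(SEM₁² + SEM₂²), and the difference expressed in
SE units (z) maps to one-sided significance stars at 1.64 (\*), 2.33
(\*\*) and 2.83 (\*\*\*). The first two are the one-sided normal critical
values for p < 0.05 and p < 0.01; note that 2.83 does not exactly match
the p < 0.002 often quoted with three stars (the 0.998 quantile is
2.878) — the z thresholds are treated as authoritative, and stars are
assigned from z, never from p. Boundaries follow the wording "less
than / between / greater than": z = 1.64 earns \*, z = 2.33 and z = 2.83
earn \*\*, and \*\*\* requires z > 2.83 strictly. No multiple-testing
correction is applied; every comparison is against a declared control.

Two behaviours of the metrics are intentional and worth calling out:

* **Fraction moving can exceed 1.** The denominator is the nominal
  plated count, not a per-window census, so occasional false positives
  can push a window above 100%. Clamping would hide a known anomaly of
  the method.
* **Rule for undefined speeds.** The condition-level mean speed of
  moving worms is undefined at any time where *any* contributing dish
  had zero movers, and the series is truncated from the first time this
  holds persistently — mirroring how speed data end for short-lived
  strains while fraction moving continues. Mean speed of all worms uses
  0 for empty windows and never truncates.

## The synthetic plate simulator

`sim_params()` + `simulate_worms()` + `render_window()` generate image
stacks with exact per-worm ground truth. Worms are persistent random
walkers (heading diffusion 0.15 rad·s^−1/2^) rendered as sinusoidally
undulating polylines (wavelength ≈ body/1.5, amplitude ≈ body/10, arc
length 1 mm) whose undulation phase advances with travel, so a paused
worm is truly static. The scene is a light lawn with low-frequency
texture, optional cumulative trail darkening along worm paths, and
Gaussian read noise (default σ = 3 gray levels), quantised to 8 bits.
Determinism is strict: every (plate, worm) pair draws from its own
substream (`substream_seed()`), so adding dishes or worms never perturbs
existing ones, and identical configurations are bit-identical on disk.

Behavioural defaults emulate the assay's phenomenology: the moving
probability declines logistically from 0.6 (midpoint day 5, steepness
0.6/day), crawl speed starts at 20 µm/s (on-food, dwelling-dominated
locomotion — well above the 10 µm/s threshold, far below roaming speeds)
and decays at 0.12/day, and death times are logistic around day 14. The
early-adult *rise* to the movement peak near day 2 is not modelled; the
simulator starts on the decline side, which is the regime the endpoints
integrate.

**Geometry.** The spec of a real rig pairs a 25 µm/px camera with a 6-cm
dish. For ground-truth recovery we image the *whole* dish at reduced
magnification: 512×512 px at 100 µm/px (51.2 mm field, ROI radius 24 mm).
This matters: 30 worms cropped into a 12.8-mm sub-field is ~17× the true
areal density of a real dish, and at that crowding the time-aggregated
motion smears of independent worms overlap so often that blob counting is
biased low by far more than any detector could repair. At true dish
density, smear overlap costs only ~1 merged pair per window near the
movement peak. Full-dish imaging at 25 µm/px (2400×2400) is supported but
not used in tests for runtime reasons.

Recovery runs use 20 frames at 8-s spacing over the same 160-s window and
one window per hour for one simulated day (24 windows/dish, 10 dishes).
The mask and length definitions are frame-count agnostic; the only
discretisation cost is that F frames span (F−1)/F of the window, a −5%
length factor at F = 20 (−0.5% at the nominal F = 200).

## Known measurement biases

* **Skeleton length over-reads speed.** A motion smear spans the worm's
  path *plus* one body extent, so skeleton-mode speed carries a positive
  bias of ≈ body/(v·T) — about +20% at 30 µm/s and +6% at 100 µm/s —
  plus the digital chain-length overestimate (≤ ~8%, maximal near
  tan θ ≈ 0.414) and skeleton wiggle from the undulating smear outline.
  This is intrinsic to measuring the aggregated smear, not an
  implementation artefact; it cancels in within-assay comparisons.
* **Centre-of-mass tracking is the unbiased alternative.**
  `detect_moving_objects(..., length_mode = "centroid")` follows the
  deviation-weighted centre of mass of each object's changed pixels
  frame by frame (keeping only pixels above half the frame's peak
  deviation, which isolates the body from the faint mean-depression
  residue along the path). On simulated dishes it recovers speeds within
  a few percent, and it is the mode used wherever agreement with
  ground-truth speed is asserted. The skeleton remains the default
  because the assay's own output is the length of the aggregated object.
* **Blob merging under-counts.** Two worms whose smears intersect count
  as one object. At realistic density and dwelling speeds this costs a
  few percent of the fraction-moving level; it grows quadratically with
  the number of movers and with path length.

## Numerical and design choices

* Thinning is iterative with N/S/E/W subcycles: boundary candidates are
  taken from a snapshot per subcycle, then deleted sequentially when
  8-simple (Yokoi connectivity number 1) and not endpoints. Endpoint
  preservation keeps the full midline of elongated blobs (a 41×3 px bar
  thins to its exact 41-px midline), and sequential deletion with a live
  simplicity test cannot break a component.
* Component labelling is sparse min-label propagation with pointer
  jumping over the true pixels only (masks are ≪1% full).
* **Occlusion bridging.** A mover crawling across a motionless worm
  leaves no pixel change where the static body occludes it, so its smear
  arrives cut in two (and the fragments read as spurious slow objects).
  By default, constantly-dark pixels (mean frame more than twice the
  difference threshold below the median level — static bodies) may
  *connect* smear fragments during labelling, while never contributing
  pixels, area or centroid to any object. Disable with
  `detection_params(bridge_occlusions = FALSE)`.
* The smoothing window truncates at edges and never reaches across
  censored or undefined points, so exclusions cannot leak information.
* AUC gap policy: gaps ≤ 6 h are bridged linearly (the trapezoid rule
  does this naturally); longer gaps split the integral with a warning and
  contribute nothing.
* `diff_threshold = 15` suppresses σ ≤ 3 read noise at a false-pixel rate
  < 10⁻⁶ per pixel-frame; an adaptive mode (`5 × MAD`-based σ̂, floored at
  15) is available for noisier cameras.
* Plate coordinates are micrometres with the origin at the ROI centre;
  pixel coordinates are (row, col), with row = centre_row + y/µm_per_px.

## What passing tests do and do not show

The simulator shares the pipeline's geometric assumptions (dark worms on
a light static background, additive Gaussian noise). Passing recovery
tests therefore validates the measurement chain — masks, labelling,
lengths, metrics, integration, statistics — under those assumptions. It
does not validate robustness to condensation, lawn boundary drift,
burrowing, progeny, or illumination flicker; on real data those appear
as censored plates and windows, which is exactly why censoring is a
first-class input. Test problem sizes (10 dishes × 30 worms × 24 windows
at 512²) are the package's chosen desk-scale study conditions; the
statistics do not depend on them beyond the stated tolerances.
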