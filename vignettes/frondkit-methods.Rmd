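---
title: "Methods: plate quantification, growth models and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate quantification, growth models and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frondkit)
```

frondkit quantifies duckweed growth from top-down photographs of petri
dishes and fits the downstream models a duckweed laboratory needs:
dose–response curves, relative growth rates, storage-viability decay and
significance groupings. This vignette explains each method, the tunable
parameters and their defaults, the numerical choices, what the built-in
synthetic generator does and does not emulate, and the design decisions
that were genuinely open.

## Plate quantification

### Assumptions

One circular, transparent dish per image, photographed top-down on a
uniform background at a constant distance. Duckweed fronds float and
spread in two dimensions, so the green surface area of a dish is a good
proxy for biomass; roots are not quantified.

### Dish detection

`detect_dish()` runs a circular Hough transform on an edge map of a
downscaled copy of the image (long side at most 220 px): every
edge pixel votes for candidate centres along both senses of its gradient
direction across the admissible radius band, the vote map is smoothed, and
the radius is read off a histogram of edge-to-centre distances. The coarse
circle is then refined at full resolution by an iterated algebraic
least-squares (Kåsa) circle fit to the edge pixels within a narrow annulus
of the current estimate; iterating re-centres the annulus and removes the
bias a misplaced band would introduce. On rendered scenes this recovers
the centre to well under a pixel and the radius to ~0.05%.

Parameters:

* `expected_radius_frac` (default 0.30–0.49): admissible dish radius as a
  fraction of the minimum image dimension. The band both rejects small
  spurious rings and keeps the search cheap. A dish photographed to fill
  most of the frame sits near 0.44.
* `min_support` (default 0.25): minimum fraction of the circumference
  covered by edge pixels; a uniform image (no dish) fails this cleanly
  rather than returning a spurious circle.

### Cropping, calibration and segmentation

The dish's bounding square is cropped (clamped to the frame with a warning
if the dish touches the border) and resized to `target_width` px (default
700). The physical calibration uses the dish's known outer diameter,
default 95 mm for a standard deep-well petri dish:
`scale_mm_per_px = diameter_mm / (2 * radius_px_after_resize)`. The exact
downscale width is not critical — areas measured at 400 and 800 px agree
within 2% — it trades speed for boundary fidelity.

Green pixels are classified by fixed hue/saturation/value bounds,
`green_thresholds()`: hue 70–170° (the equivalent of 35–85 in the 0–179
convention used by common computer-vision tooling), saturation ≥ 60/255,
value ≥ 40/255. A manually tuned threshold is standard practice for this
kind of assay; the defaults here are a reproducible starting point and are
exposed both per call and in `run_config()`. Everything outside the
detected dish circle is forced to background, and connected components
smaller than `min_speck_px` (default 10 px at the default 700 px crop,
settable to 0) are removed as sensor-noise specks.

`measure_area()` is deliberately trivial — `count × scale²` — and is
checked in the tests against a literal per-pixel counting loop. The area
is bounded above by the physical dish area π(D/2)², which rasterisation
can overshoot by a fraction of a mm² on a saturated dish.

### Frond dissection

`analyze_fronds()` processes photographs of fronds manually separated onto
a white card: green connected components are labelled, components with
area < 30 px or circularity 4πA/P² < 0.5 are discarded (debris and stipe
fragments; intact fronds are near-circular, with circularity well above
0.5), and each frond is sized by its minimum enclosing circle (computed
from the farthest pair of convex-hull points, exact for near-circular
shapes, plus one pixel for the raster extent). `n_ramets` has **no
default**: source protocols differ on whether three or five ramets are
dissected per dish, so the count of clonal units on the card must always
be stated by the caller.

## Growth models

### Curves and ratios

`build_growth_curve()` re-bases times to the first image (t = 0) and
averages duplicate same-day measurements. `normalized_growth()` is final
area over initial area; `compute_rgr()` is the same ratio at the time
point nearest `window_days` (default 10). The nearest-point rule, with
ties broken towards the later image, accommodates the irregular imaging
schedules of real labs (a "day 10" image taken on day 11 is used as-is).
Both ratios are dimensionless and scale-invariant. Replicate aggregation
(`replicate_series()`) uses the unweighted mean and the sample standard
deviation (n − 1), left undefined where fewer than two replicates share a
time point.

### Hill dose–response

`fit_hill()` fits R(c) = bottom + (top − bottom)/(1 + (c/EC50)^n) by
Levenberg–Marquardt least squares. The zero dose is handled by evaluating
the limit (R(0) = top for n > 0), so the fit works in linear dose with a
dose-0 anchor rather than dropping the control. Starting values: top =
mean response at dose 0, bottom = minimum response, EC50 = median positive
dose, n = 1; EC50 and n are bounded positive. All-equal responses are
rejected as degenerate before fitting. The default response variable is
per-replicate day-10 normalized growth; per-treatment means can be fitted
by aggregating first.

### Storage-viability decay

`fit_storage_decay()` fits RGR(t) = r₀·e^(−kt) to revival growth rates
against storage duration, initialised from a log-linear regression on the
positive values (and checked against that independent oracle in the
tests). The default model has no offset — RGR tends to 0 for very long
storage, consistent with revival assays where no growth is detectable
after several months — and an offset variant is available via
`offset = TRUE`. If RGR increases with storage the rate is clipped at 0
with a warning and the limit is reported as unbounded.

The **viability limit** is where the fitted curve crosses
`viability_threshold`. The threshold defaults to RGR = 1: final area
equals initial area, i.e. the revived culture shows no net growth. This
choice is exposed as a parameter because "viable" could reasonably be set
anywhere between 1 (no net growth) and the uninhibited rate. Under the
emulated experiment conditions (below) the limit lands near 28 days.

### ANOVA + Tukey letters

`anova_tukey()` is a thin composition of `stats::aov` and
`stats::TukeyHSD`; only the compact letter display is authored here, by
the standard insert-and-absorb sweep (split every letter set containing a
significantly different pair, then absorb subsets), which yields a minimal
cover with lexicographic letters ordered by first group. Pairs with
undefined p-values (zero variance everywhere) are treated as
non-significant, so identical groups share one letter. The display is
cross-checked against the multcomp implementation in the test suite.
Note the familywise logic: among k statistically identical groups, some
pair will be declared different in about α of repeated experiments — a
property of Tukey's test, not of this implementation.

## The inventory layer

The store mirrors the data model that scripted image analysis depends on
in a LIMS: samples (genotypes), items with unique sequential IDs, a
status, and parent links forming a forest; append-only timestamped
key–value data associations, optionally file-valued; and plans holding
operations with typed input/output item references. `transfer_duckweed()`
creates daughter dishes with lineage links (the parent is kept by default
and discarded only on request — the conservative action for a stock
culture); `log_contamination()` attaches the evidence photo and notes and
discards the item, keeping contamination queryable per month;
`define_plate_treatment()` stores one treatment map per item per plan
(redefinition is a conflict); `query_plan_images()` returns every image
association on duckweed containers of a plan joined to its treatment,
sorted by item and date — the exact retrieval pattern an analysis notebook
starts from. Persistence is one human-readable JSON document plus files
on disk; latest-wins resolution happens only at query time, never by
overwriting history. Dates are ISO-8601, day-granular for image capture
and second-granular for association timestamps.

## The synthetic benchmark

`render_plate()` draws a dish (light media disc, dark rim annulus over a
uniform background, mild vignetting) with elliptical green frond blobs and
Gaussian sensor noise (default sd 3/255); the returned ground-truth mask
is exactly the rendered frond pixels. Frond colours are drawn from the
interior of the segmentation gamut (20% margin) so that the default
thresholds succeed; an adversarial palette places colours near the gamut
boundary for robustness checks. `render_dissection()` places separated
green discs on a white card, refusing spacings under 3 px.
`simulate_experiment()` produces the three experiment designs:

* **dose_response** — triplicate dishes at 0/50/100/150/300 mM NaCl,
  imaged every 2 days for 10 days, A₀ = 100 mm², uninhibited rate
  0.2/day, EC50 = 100 mM, Hill n = 2, 5% multiplicative replicate noise.
  By default the Hill curve is placed on the normalized-growth scale (top
  = e^(0.2·10), bottom = 1) and each dish grows exponentially at
  ln(RGR)/10 — so the growth curves are exactly exponential *and*
  refitting the Hill model to day-10 normalized growth recovers the
  generating EC50 exactly; inhibiting the rate itself is available as
  `response_model = "hill_rate"` (the two differ because the exponential
  map does not preserve the Hill form).
* **storage** — replicate RGRs drawn from r₀·e^(−kt) on the
  0/6/28/232/310-day storage grid with r₀ = 6, k = 0.064/day and 10%
  multiplicative noise, giving a closed-form viability limit
  ln 6/0.064 ≈ 28.0 days.
* **recovery** — mock and salt-treated arms; the treated arm's growth
  rate is 0, so its normalized growth stays at 1.

The noise defaults are the package's own calibration: 5% replicate noise
is a typical coefficient of variation for dish-level area in a controlled
assay, and 10% reflects the larger spread of revival growth rates across
biological replicates. Each generator is a pure function of its spec and
seed (the caller's RNG stream is saved and restored), so identical specs
give byte-identical images.

What the generator does **not** emulate: uneven illumination beyond mild
vignetting, shadows and reflections on the dish rim, overlapping or
mutually occluding colonies, colour drift between cameras, and non-green
tissue (senescent fronds). Passing the synthetic closure tests therefore
demonstrates the internal consistency and calibration of the pipeline,
not its robustness to every artefact of real photographs — on real data
the segmentation thresholds are expected to need manual adjustment, which
is why they are plain parameters.

## Numerical choices and problem sizes

Nonlinear fits use Levenberg–Marquardt (up to 200 iterations) with
box constraints keeping EC50, n, r₀ and k in their meaningful ranges;
noiseless recovery is exact to solver tolerance (residual sums of squares
below 1e−12 in the tests). Dish detection ties are broken towards the
larger radius, then the more central circle. Pixel coordinates are
0-based with x = column, y = row; masks are logical rasters whose pixel
centres decide membership.

The test-suite and acceptance problem sizes are chosen for a laptop-class
single core: the area-recovery sweep uses 50 scenes at 420–520 px (the
full 800 px case is exercised separately), Monte-Carlo Hill recovery uses
100 refits, and image-directory workflow tests render 300 px plates. These
sizes keep the whole suite under a minute of compute while leaving every
tolerance at its scientifically motivated value (2% area recovery, 1%
noiseless parameter recovery, 15% on the noisy median EC50).

## Known limitations

Single dish per image; circular vessels only; a green/non-green split with
no health scoring; no per-frond tracking over time; no mixed-effects or
Bayesian growth modelling; the inventory layer is a desk-scale
single-user document store, not a multi-user server.
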