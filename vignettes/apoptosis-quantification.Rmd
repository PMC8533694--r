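---
title: "Quantifying apoptotic staining in confocal stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apoptotic staining in confocal stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoptoquant)
```

## The problem

Apoptosis in a tissue is usually quantified from fluorescence images:
TUNEL marks fragmented DNA and gives a punctate nuclear signal, while
antibodies against cleaved effector caspases stain the whole cytosol, so
adjacent apoptotic cells fuse into one stained object. Quantification with
a particle analyzer requires a binary 2D image, which forces three
processing steps on a confocal z-stack: noise filtering, z-projection, and
thresholding. Each step has defensible variants, and the choice --
especially of the threshold -- dominates the accuracy of the final
readout. `apoptoquant` implements this whole workflow headlessly, with
every convention pinned down, and ships a synthetic scene generator with
exact ground truth so that each claim about the workflow is testable
without microscope data.

Two readouts are supported. The **count readout** (number of connected
stained objects) equals the number of apoptotic cells as long as objects
do not touch. The **area readout** (total stained area, in µm²) is robust
to object merging and is the appropriate choice for cytosolic stains at
high apoptotic rates: merging makes the count readout underestimate dense
conditions more than sparse ones, flattening true between-group
differences.

## Image model and containers

A raw acquisition is an `ImageStack`: a `(z, y, x)` intensity volume with
a lateral calibration in µm/pixel (x = y assumed), a bit depth (8, 16 or
float), and identifiers (`image_id`, `channel`, `group`). Filtering and
projection produce a `CalibratedImage` (2D, floating point, with an
append-only provenance trail), thresholding a `BinaryMask`. Pixel
coordinates are 0-based with x along columns; pixel `(r, c)` occupies the
unit square with centre `(c + 0.5, r + 0.5)`.

TIFF is the input standard (multi-page = z). Calibration is read from
resolution metadata when present and can always be overridden; because the
TIFF writer used here does not embed resolution tags, calibration written
by this package travels in the manifest CSV. A missing calibration is an
error rather than a default, because the size filter is specified in µm.

## Noise filtering

Both filters use the square (Chebyshev) neighbourhood of side `2r + 1`
with replicate-edge padding, applied per slice *before* projection:

* `mean_filter()` -- arithmetic mean of the window. An isolated
  aberrant-high pixel is attenuated but its mass is smeared over every
  window that contains it, so a bright artifact becomes a 3×3
  suprathreshold patch instead of disappearing.
* `median_filter()` -- median of the window (odd count, so always an
  order statistic of the input). With radius 1 it carries a guarantee:
  any pixel whose 8 neighbours all lie at or below a level `T` maps to a
  value at or below `T`, which removes isolated hot pixels outright while
  preserving object edges.

The protocol default is the median filter with radius 1. For radius 1 the
square window is exactly "the pixel and its direct neighbours"; for
r ≥ 2 some implementations use disc-shaped kernels instead, a documented
divergence (the square window is kept here for its simpler, testable
definition).

## Z-projection

`z_project()` reduces the stack per pixel by `average`, `max` or `sum`.
The monolayer geometry of the target tissue means projection does not
conflate distinct objects. Max-intensity projection is the default: it
preserves the full contrast of punctate signal that average projection
dilutes, widening the usable threshold range. Sum projection
(`sum = n_slices × average`, an exact identity used as a test invariant)
is provided for workflows that prefer integrating signal.

## Thresholding

`binarize()` turns a projected image into foreground/background with the
strict convention *foreground ⇔ intensity > T* (switchable to `>=` for
cross-checking). Four classical histogram algorithms are implemented on a
256-bin equal-width histogram of the (optionally ROI-masked) image range,
with the threshold reported as the lower edge of the selected bin and all
ties broken to the lowest bin:

* **Otsu** maximizes the between-class variance
  $\omega_0\omega_1(\mu_0-\mu_1)^2$ by exhaustive scan.
* **Moments** (Tsai's moment-preserving rule) matches the first three
  histogram moments with a two-level image and thresholds at the
  cumulative fraction $p_0$; the crossing is taken at the first bin whose
  cumulative mass *reaches* $p_0$ (`>=`), consistent with the lowest-tie
  rule. Implementations that use a strict `>` pick the upper bin on an
  exact tie.
* **IsoData** iterates $T \leftarrow (\mu_{\le T} + \mu_{>T})/2$ from the
  overall mean to a fixed point (tolerance 1e-9, cap 1000 iterations).
* **Intermode** smooths the histogram with a 3-bin moving average
  (replicated ends) until exactly two strict local maxima remain (cap
  10000 passes, then an error) and returns the midpoint of the modes.

Otsu and Moments are the algorithms worth considering for apoptotic
staining; IsoData and Intermode are included deliberately as the classic
failure modes that motivate manual thresholds. Degenerate histograms
(fewer than two occupied bins, e.g. from a constant image) are refused.

Manual thresholds are file-based in this headless setting: the threshold
phase exports preview images and a template CSV that an operator fills
in. `consensus_threshold()` implements the uniform-threshold option: the
median of per-image thresholds within each group, then the median of the
group medians. Group-first aggregation keeps a group with more images
from dominating the consensus; medians make the value invariant to
duplicating records within a group. Whether operators set thresholds on
whole or ROI-cropped images is a free choice; the default here is whole
images (the threshold phase performs no zone selection), configurable
through the histogram `mask` argument.

## Particle analysis

`quantify_image()` composes binarize → ROI intersection → 8-connected
labeling → measurement → size/circularity filtering. Conventions:

* Connectivity 8 by default (diagonal pixels touch), 4 available.
* ROI rasterization: a pixel belongs to the polygon iff its centre is
  inside under the even-odd rule, boundary centres included. One ROI per
  image; quantifying two zones means duplicating the manifest row.
* Perimeter: chain-code length of the traced outer boundary, straight
  steps 1 and diagonal steps $\sqrt 2$; an isolated pixel uses its
  unit-square outline (4). This estimator slightly overestimates smooth
  digital boundaries, so circularity $\min(1,\; 4\pi A/P^2)$ of a digital
  disc sits near but below 1 (a radius-20 disc measures ≈ 0.91); the cap
  at 1 absorbs small objects where the chain code underestimates.
* Size limit: the "objects larger than 2 µm" rule is interpreted as a
  strict minimum on the equivalent-circle *diameter*
  $2\sqrt{A/\pi}$ -- a length, directly comparable to a nucleus
  diameter. Because some particle analyzers filter on area instead, an
  area mode (µm²) is also provided; at 0.5 µm/pixel the 2 µm diameter
  limit sits between a 12-pixel (removed) and a 13-pixel (kept) object.
  The limit is a property of the smallest biological object of interest
  and must be re-derived for other stains or cell types.
* Filtering happens after measurement, so kept + removed particles
  conserve the foreground area exactly -- a tested invariant.

## Group statistics

Per-image readouts are compared between groups with the two-sided
Mann-Whitney/Wilcoxon rank-sum test (`rank_sum_test()`), exact by
enumeration when both groups have ≤ 10 observations and no ties,
otherwise the normal approximation with continuity and tie corrections.
Two-sided tests are the conservative default and p-values are reported
raw, without multiple-testing correction. Summaries report mean, n−1 sd,
min, max and median; `concordance()` (OLS slope, R², slope t-test)
quantifies the agreement between two raters' threshold series.

One numerical finding from the test suite is worth recording: comparing
the exact two-sided p with the continuity-corrected normal approximation
over *every* attainable value of U shows a maximum discrepancy of 0.0109
at n = 8 per group (attained only near the distribution centre), 0.0095
at n = 9, 0.0086 at n = 10 and 0.0071 at n = 12. Agreement to 0.01 thus
holds from n = 9 upward but is marginally violated at n = 8 -- a property
of the classical approximation itself, independent of implementation.

## The synthetic generator

`simulate_scene()` builds the study conditions: a calibrated stack
(default 0.5 µm/pixel, 8 slices of 512×512 -- tests use smaller fields so
each scene takes well under a second) with objects confined to the middle
half of the z range, emulating a monolayer. Two geometries:

* *nuclear*: spots of default diameter 3.5 µm (nucleus-sized; the true
  value for any given tissue is unknown and this default is a documented
  placeholder), with guaranteed ≥ 1 px background separation when
  `cluster_strength = 0`;
* *cytosolic*: discs of default diameter 7 µm placed by a Thomas-like
  parent-offspring process; a single knob (`cluster_strength`) moves the
  offspring scatter from uniform placement (0) to tight aggregation (1),
  so overlap probability rises with both density and clustering.

Objects are soft-edged discs: a flat top with a 1-pixel raised-cosine
shoulder whose half-maximum sits exactly at the nominal radius. This
makes the ground-truth mask (the disc of the nominal radius) exactly what
a mid-range threshold recovers, so both count *and* area are meaningful
oracle quantities; a long-tailed profile such as a pure Gaussian would
make the recovered area an artifact of the threshold choice. Defaults
signal 3000, background 300, noise sd 30 at 16-bit depth give a
high-but-realistic contrast; ground truth (count, per-object masks, union
area -- overlaps counted once) is computed from the noiseless,
defect-free signal, so the efficacy of defect removal is measurable.

The three defect classes are generated explicitly: Gaussian background
noise; isolated hot pixels at 98 % of the dynamic range with all 8
neighbours untouched; and compact hot clusters (3×3 blocks, 5-pixel plus
shapes) whose equivalent diameter stays strictly below the 2 µm size
limit. Every injected coordinate is inventoried.

What the generator deliberately does **not** emulate: the microscope PSF
and optical blur, photobleaching, depth-dependent attenuation, tissue
folding, autofluorescence texture, or the unknown true signal-to-noise of
real discs. Passing tests therefore demonstrate that the *workflow logic*
is correct under controlled conditions -- filters remove exactly the
defect classes they claim to, thresholds sit between background and
signal, counts and areas agree with ground truth, merging behaves as
predicted -- not that any particular threshold algorithm will segment a
given real dataset well. That judgement remains with the experimenter,
which is precisely why the workflow keeps the manual and consensus
threshold modes.

## The two-phase pipeline

`run_threshold_phase()` (filter → project → determine thresholds, or
export previews + template) and `run_quantify_phase()` (re-process →
apply thresholds → ROI → quantify → summarize → compare) communicate only
through files: threshold table, results tables, run logs. This phase
separation is tested by running Part 2 from a freshly constructed
configuration, and full-run determinism by byte-comparing the CSVs of two
identical runs. The run log records every parameter and is sufficient to
reproduce a run; the uniform-threshold options that let an operator
decide after seeing 50 %/25 %/10 % of images are generalized to a
`consensus_fraction` applied to the sorted manual table. Requesting
consensus mode without a filled threshold table is an explicit error.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 96--256 px fields, 1--8
slices, 20 seeds per stochastic claim, 100 random images per filter
oracle and 200 random histograms per threshold oracle; these sizes were
chosen so each property is exercised across its degrees of freedom while
a full run stays in the seconds-to-minutes range. All simulation
randomness flows from a single seed per scene, and per-image seeds of an
experiment derive deterministically from a master seed.

## Known limitations

* For filter radius ≥ 2 the square window diverges from disc-kernel
  implementations (identical at radius 1, the protocol default).
* The chain-code perimeter biases circularity for very small objects;
  circularity-based filtering below ~10 px area should be avoided.
* Algorithm thresholds in the quantify phase come from the
  threshold-phase table (whole-image histograms); ROI-restricted
  histograms are available through `compute_histogram(mask = )` but are
  not wired into the batch pipeline.
* `.lif` and other proprietary containers are out of scope; convert to
  TIFF upstream.
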