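---
title: "Quantifying glial cell arrangement in brainstem nuclei: methods and design"
author: "glioquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial cell arrangement in brainstem nuclei: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioquant)
```

## The problem

During early postnatal development, oligodendrocytes redistribute within the
nuclei of the superior olivary complex (SOC) — the MNTB, MSO, LSO, the
periolivary dLSO wedge, and reference control regions. Their positions are
recorded manually: an annotator outlines each nucleus on the structural
(VGluT1) channel and places a point on every marked soma. The quantitative
questions are spatial: how dense are the cells per nucleus and age, how are
they arranged along the tonotopic axis, which marker combinations label
them, how close do they sit to calyx of Held synapses, and how do individual
cells' process arbors grow. `glioquant` implements that analysis chain as
composable, tested functions, and ships seeded generators that emulate each
input class so every step can be validated against planted ground truth.

Because nuclei differ in size and shape across sections and ages, almost all
spatial statistics are computed in a *normalized frame*: the axis-aligned
bounding box of the nucleus outline is mapped to $[0, 100]\%$ on each axis.

## Coordinate conventions

Image annotations come in pixel coordinates with row 0 at the top, while
anatomical convention puts dorsal up. The package converts once, at ingest:
when a `section_frame` carries the image height, `read_marks()` flips
$y_\text{anat} = H - y_\text{px}$. When the height is unknown, the flip can
instead be applied inside the normalized frame
(`normalize_coordinates(invert_y = TRUE)`), which re-anchors $y$ at the ROI
bounding box — the two routes give identical normalized coordinates because
normalization is affine per axis.

Left-hemisphere sections are mirrored so that $+x$ always points laterally.
The mirror is applied in the normalized frame ($r_x \to 100 - r_x$, keyed by
the ROI's hemisphere flag) rather than on raw pixels: it needs no image
width, and in the bounding-box frame the two operations are equivalent.
Image line scans mirror analogously by reversing the profile.

Marks exactly on an ROI boundary count as *inside*. Manual marks placed on a
faint nuclear border should not be silently dropped; the winding-number
oracle used in the tests follows the same convention.

## Density maps

For each section and nucleus, marks inside the polygon (not merely inside
its bounding box) are normalized and binned into a fixed $20 \times 20$ grid
of 5% increments. Bins are half-open $[5k, 5k+5)$ except the last, which
closes at 100 so no mark is lost. The grid is then divided by its own
maximum bin count, giving a normalized density in $[0, 1]$ whose maximum is
exactly 1 for every non-empty section; section grids are averaged
element-wise per nucleus and age group. Rendering maps density 1 to gray 0
(black) and 0 to 255 (white), with half-up rounding, dorsal edge at the top.

The grid size is fixed, not configurable: cross-section averaging is only
well defined if every section uses the same bins. Two consequences are
deliberate:

* Sections with zero marks in a nucleus are excluded from grid averaging
  (max-normalization is undefined at zero) but still contribute count 0 and
  density 0 to the per-section records.
* Edge bins that a non-rectangular outline covers only partially keep their
  raw counts — they are *not* rescaled by covered area. This reproduces the
  binning procedure as described but under-weights edge bins; treat edge
  values of the maps as conservative.

Cell density per section is simply count over ROI area; areas come from the
shoelace formula times the squared pixel size and are reported in µm² and
mm².

## Tonotopic profiles

A 1-D profile along the tonotopic axis is the mean normalized density over
an orthogonal band, sampled at the 20 bin centers (2.5, 7.5, …, 97.5%). The
default band covers the central 50% of the orthogonal axis (25–75%); the
description "centered at 50% ± 10%" is read as a *center tolerance*, exposed
as `center_shift` (limited to ±10%), with 50% total width. For the LSO's
bent axis, `curved_profile()` follows a user-supplied control-point
polyline, re-sampled uniformly by arc length; at each sample the transverse
window spans ±15% (half the 30% local width) perpendicular to the local
tangent and half a sampling step (at least half a bin) along it. A straight
path therefore reproduces `band_profile()` at the same width, which the
tests check explicitly. The freehand path itself is an input — the package
does not pretend to infer an annotator's hand.

Edge comparison averages each section's profile over relative locations
$[5, 15]$ and $[85, 95]$. With bin-center sampling these windows contain
exactly the samples at 7.5/12.5 and 87.5/92.5% — stated explicitly because
interval membership at bin edges is otherwise ambiguous. The two per-section
samples then go through the normality-gated dispatch below. No smoothing is
applied to profiles before averaging.

Image line scans (`line_scan()`) average a rectangle's pixel columns over
its height, one value per column, per channel — the standard "plot profile"
operation — with locations in µm from the medial edge.

## Co-labeling and calyx proximity

Manual counts from two marker channels are overlaid by greedy
mutual-nearest-neighbor matching: repeatedly pair the globally closest
unmatched pair within a distance tolerance. The procedure is deterministic
and order-independent, and on planted scenes with realistic jitter it agrees
exactly with an exhaustive optimal-assignment oracle (tested up to 10 cells
per channel). The tolerance is deliberately prominent configuration, not a
constant — the original overlays were visual judgments: defaults are 5 µm
for somata (about a soma radius) and 1 µm for axon profiles in the
20 × 20 µm counting square.

Calyx proximity uses the sampling-circle rule: the circle drawn around a
VGluT1-positive calyx is widened by the average S100 soma diameter (17 µm),
and a cell counts when its soma disc fits fully inside:
$d(\text{cell}, \text{calyx}) + r_\text{soma} \le r_\text{sampling}$. Cells
without a measured diameter get the configured default (17 µm). Somata are
approximated as discs, consistent with summing diameters.

## Single-cell morphometry

Processes are polylines with a class each: *primary* (from the soma),
*secondary* (from a primary; the topology is validated), *blind* (ending
without myelinating). Lengths are polyline arc lengths — whether "length"
means arc length or straight-line extent was open; arc length is used, and
the chord is still available from the endpoints. The diameter of a process
is the mean of widths at arc-length fractions 0.1, 0.3, 0.5, 0.7, 0.9 (the
centers of five equal sub-segments); where a center falls in a stretch
flagged unmeasurable (overlapping processes), the nearest measurable
position substitutes. Width can also be measured from an image chip as full
width at half maximum above the local background. Orientation is the chord
angle to the medio-lateral axis folded to $[0, 90]°$ — an undirected
convention chosen here, not a given.

The coverage polygon is the convex hull of all trace points: deterministic
and a conservative superset of a manual "most outer processes" outline (a
concave alpha-shape variant is out of scope). Feret descriptors come from
exact computational geometry: the maximum Feret is the hull diameter, the
minimum is the smallest edge-aligned caliper width (for convex polygons the
minimum width is always perpendicular to an edge), the Feret angle is the
maximum's direction in $[0, 180)°$. The test oracle is an independent
projection sweep; note that the caliper width has a *linear* cusp at its
minimum, so a 0.1° sweep alone localizes the minimum only to ~10⁻⁴
relative — the oracle refines recursively around the coarse extremes to
reach 10⁻⁶.

The myelin detector encodes the qualitative criterion "low center intensity
flanked by two high peaks" with explicit thresholds, all config-exposed:
peaks must be topographically prominent (≥ 10% of the chip's dynamic range),
exceed 2× the background median, number exactly two, and the valley between
them must sit in the central third at ≤ 0.6× the lower peak. Chips are
averaged along the process axis (`chip_profile()`) before detection, which
suppresses pixel noise roughly by the square root of the chip height. At
SNR 5 the detector is validated at ≥95% sensitivity and specificity on 200
generated chips.

## Statistical dispatch

Every comparison runs through one rule: each group is screened with
Shapiro–Wilk at α = 0.05; only if *all* groups pass does the parametric
branch run (unpaired t test, or one-way ANOVA with Holm–Šídák post-hoc
pairwise comparisons using the pooled SD), otherwise the non-parametric
branch (Mann–Whitney U, or Kruskal–Wallis with Dunn's rank z-tests,
tie-corrected, Holm–Šídák-adjusted). The per-group screening rule and α are
the conventional reading and are exposed as configuration; screening pooled
residuals instead would be a one-line change. Groups with zero variance
cannot be screened and route non-parametrically.

Centers are reported as mean (parametric) or median (non-parametric), both
paired with SEM $= s/\sqrt{n}$. SEM next to a median is statistically
unusual but reproduced deliberately as the reporting convention of this
analysis style; `median_boot_ci()` provides a clearly-labeled bootstrap
alternative. The underlying tests are standard published procedures and are
called from `stats::`; the package's contribution is the gated dispatch and
the reporting format. Holm–Šídák and Dunn are implemented here because base
R's `p.adjust` does not provide the Šídák step-down and no Dunn
implementation is available among the package's dependencies; both are
checked against hand computations and invariants (monotone adjusted
p-values, antisymmetric z).

The gate's end-to-end calibration is itself tested: under a two-group
standard-normal null at n = 15, the full dispatch rejects at 5% ± 2% over
2,000 seeded replicates.

## What the generators emulate — and what they do not

* `gen_points()`: fixed-count (default, since sections report counts) or
  Poisson point patterns in a polygon, with an optional linear density
  gradient along one normalized axis, sampled by rejection so the planted
  intensity is exact. Emulates soma-center marks; does not emulate soma
  overlap, clustering, or annotation error.
* `gen_mso_image()`: Gaussian-ridge bands for the somatic (MAP2-like),
  input (VGluT1-like, dendritic or perisomatic) and Olig2-like channels
  plus Gaussian noise. Emulates band geometry, not microscope optics — no
  PSF, no spectral bleed-through, no tissue texture.
* `gen_tube_chip()`: 5.55 µm chips with a hollow or filled vertical tube at
  a stated SNR. The cross-profile is an idealized step template; real
  sheaths curve and vary in intensity along their length.
* `gen_calyx_scene()`: somata uniform in an annulus around a calyx, with
  multinomial marker categories and a containment truth computed by an
  independent in-generator oracle.
* `gen_oligo_cell()`: straight radiating processes whose lengths, angles
  and linear width tapers are planted analytically, so every morphometric
  output has an exact expectation. Real arbors curve and branch more
  deeply; recovery tests on these cells therefore validate the measurement
  chain, not biological realism.

All generators isolate the RNG (the caller's state is restored), are
bit-reproducible given a seed, and default to the study's physical scales:
nucleus boxes 150–500 µm, soma diameter ~17 µm, chip size 5.55 µm, scan
rectangle 359 × 72 µm. Passing recovery tests on this synthetic data shows
the pipeline measures what it claims on inputs of the declared structure;
it cannot certify behavior on features the generators omit (irregular
outlines are covered by the star-polygon fixtures in the tests, but e.g.
annotation bias is not modeled).

## Numerical choices and degenerate inputs

* Pixel sizes are configuration, never inferred: published pixel↔µm pairs
  for the same instrument are not perfectly consistent (the overview-scope
  rectangles imply ≈0.6 µm/px), so the pipeline takes the value it is
  given. The validation suite uses 0.598 µm/px for the overview scope.
* Self-intersecting ROI polygons, zero-extent bounding boxes, all-zero
  count grids, empty overlays, groups under 3 values, and zero-length
  chords are errors (or `NA` with a warning where a single missing value
  should not abort a batch); flat profiles are `FALSE` for the myelin
  detector, not errors.
* Grid maxima need no tie-breaking (division by a shared maximum);
  `which.max` ties elsewhere resolve to the first index, documented by
  tests only where the result is observable.
* Width tapers may reach exactly zero at the tip; negative widths are
  invalid.
* Validation problem sizes (chosen once for the suite): 100 replicates for
  gradient detection and null control at 14 sections × 150 marks, 50
  scenes for co-labeling recovery, 200 chips for the detector, 2,000
  replicates for dispatch calibration, 10⁷ Monte-Carlo samples for the
  area oracle.

## Known limitations

* The convex hull overestimates concave coverage areas.
* Raw edge-bin counts under-weight the nucleus border in density maps (see
  above).
* Greedy matching can differ from optimal assignment in adversarial
  geometries (chains of equidistant marks); at soma scales with ~1 µm
  jitter the tests show exact agreement, but the tolerance should be kept
  near the soma radius.
* Intensity normalization of density-map profiles is per-section
  max-normalization; if the original figures normalized per profile
  instead, absolute profile levels differ while edge comparisons are
  unaffected.
* No 3-D handling: all inputs are single planes or maximum projections;
  densities are per area, not per volume.
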