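---
title: "Horizon plots for longitudinal microbiome data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Horizon plots for longitudinal microbiome data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microhorizon)
```

## The problem

Host-associated microbial communities are compositional (each sample is a
vector of relative abundances summing to 100%) and highly dynamic in time.
Plotting many taxa from one subject — or one taxon across many subjects — as
stacked line or stream graphs fails quickly: large proportional swings in a
taxon averaging 0.5% are invisible next to a taxon averaging 25%, and facet
stacks of ordinary area charts waste vertical space.

A horizon plot solves this by folding each series. Deviations from a
reference value (the *origin* or *horizon*) are sliced into equal-width
*bands*; negative bands are mirrored above the axis; and all bands are
overlaid in one short facet, with color depth encoding the band. The result
is a compact small-multiples display in which sustained shifts, comovement
between taxa, and periodicity are visible at a glance.

## The transform

For one taxon in one subject, let \(v_i\) be the percent relative abundance
at day \(t_i\), and let \(o\) be the origin. With band thickness \(w > 0\)
and \(n\) bands per side (default \(n = 4\)), each deviation
\(d_i = v_i - o\) is folded into

* a **band index** \(b_i = \operatorname{sign}(d_i)\cdot
  \min(\lceil |d_i|/w \rceil, n)\), clamped to \(\pm n\);
* **band fills** \(f_{ik} = \operatorname{clamp}(|d_i| - (k-1)w,\; 0,\; w)\)
  for \(k = 1, \dots, n\).

The fills are monotone non-increasing in \(k\), bounded by \(w\), and
conserve the deviation: \(\sum_k f_{ik} = \min(|d_i|,\, n w)\). Band \(k\) is
drawn as an area of height \(f_{ik}\) from the facet floor, in blues for
\(d_i > 0\) and reds (mirrored upward) for \(d_i < 0\), deeper bands on top.

**Defaults.** The origin is the median of the taxon's *observed* values
(even counts average the two middle order statistics). The automatic
thickness is \(\max_i |d_i| / n\), i.e. the bands are four equal-width
slices of the deviation range, *relative to the extreme value* — not the
distribution's quartile statistics. With these defaults the most extreme
point lands exactly in band \(\pm n\) with a full fill vector, a property
the test suite asserts.

**Boundary tie-break.** A deviation exactly on a band edge \(kw\) belongs to
band \(k\) (the ceil convention, with a \(10^{-9}\) floating-point guard).
This keeps the auto-scaled extreme in band \(n\) instead of overflowing.

**Fixed scales.** Setting `origin` and/or `band_thickness` in
[horizon_spec()] puts facets on a common absolute scale and emphasizes
abundant taxa (e.g. origin 1%, thickness 10% per band); shrinking the
thickness pushes more points into the clamped \(\pm 4\) bands, accentuating
rare taxa. `fixed_scale = TRUE` instead pools deviations across all panels
into one shared automatic thickness; median origins stay per-series unless
fixed, since a shared data-driven origin has no single natural definition
for taxa whose medians differ by orders of magnitude.

**Degenerate series.** A constant series has zero extreme deviation; its
thickness is set to a sentinel of 1 so every fill is zero, and the panel is
flagged degenerate with a warning rather than aborting a multi-panel figure.

## Inputs and units

All parameters are percent-denominated, so the internal unit is percent
(0–100). Count tables are converted by per-sample closure
(\(100 \, c_{ij} / \sum_i c_{ij}\)); a sample with zero total reads has
undefined composition and is an error. Under `units = "auto"` a table whose
columns all sum to \(100 \pm 0.5\) is taken as percent, one whose columns
all sum to \(1 \pm 0.005\) as proportions (rescaled by 100), anything else
as counts; tables mixing regimes raise an error rather than being silently
misread. The hint flag overrides detection.

Metadata rows map samples to subjects and ISO-8601 collection dates; extra
metadata samples are tolerated with a warning (studies routinely have more
metadata than sequenced samples), but abundance-table samples without
metadata, and two samples sharing a (subject, date) pair, are fatal.
Taxonomy is accepted either as seven rank columns or one semicolon-delimited
lineage string; lineages must be prefix-complete (no genus under a missing
family).

## Filtering

Taxon selection within the chosen subject uses two inclusive thresholds:
*prevalence* (percent of selected samples with abundance > 0 — the standard
microbiome meaning) and *mean relative abundance* ("at least", so a mean of
exactly 0.75% passes a 0.75 threshold). Both are evaluated on observed
samples only, never on interpolated points, and both are monotone: raising
a threshold can only remove taxa, a property the suite verifies on random
tables. Auto-selected taxa are ordered by descending mean abundance so
panel order is deterministic; the single-taxon and explicit-list modes
bypass thresholds entirely. Single-taxon mode places no restriction on
per-subject schedules (subjects need not share collection days), although
aligned designs are where cross-subject comparison is most readable.

## Irregular sampling

Dates become integer day offsets from the subject's first sample. A new
segment starts after any gap *strictly* greater than `max_gap` days
(matching "greater than": a gap equal to `max_gap` is not a break). Within
each segment, output points sit at `segment_start + k * regular_interval`;
the grid restarts at each segment's first point (a global grid would
introduce phantom phase offsets after breaks). Values at non-observed grid
points are linear interpolations of the bracketing observations; observed
points on the grid pass through exactly; off-grid interior observations are
dropped — the output *is* the regularized series — but segment endpoints are
always retained so no data range is truncated. Interpolation never crosses
a break or extrapolates beyond the series ends, and the operation is
idempotent (interpolated points stay flagged interpolated on a re-run).

The origin and automatic thickness are always computed from the
pre-interpolation observed values (the pipeline passes the raw series as the
calibration for `build_horizon()`), so interpolation density cannot shift
the median or the scale.

## Rendering

`assemble_panels()` enforces one band count across panels (a readable
figure has one legend), derives axis breaks from segment boundaries, and
sizes the two color ramps to `n_bands`. SVG output comes from a small
deterministic writer inside the package: fixed layout, fixed number
formatting, one `<g class="facet">` per panel, a dashed marker in each gap,
and a legend of `n_bands` blue plus `n_bands` red swatches — so repeated
renders are byte-identical and tests can parse the file instead of
inspecting pixels. The band geometry itself is exported as a tidy TSV
(`write_geometry()`), the machine-readable surface the CLI exposes via
`--geometry-out`. PNG and PDF output render the equivalent `ggplot2`
figure through the standard graphics devices; exact fonts, margins, and
palette hex values are explicitly not part of the package's contract, only
the color *ordering* semantics (light to dark with band depth, blue
positive, red negative).

Where the deviation changes sign between two adjacent points, the drawn
polygons are split at the linear zero crossing so positive and negative
areas close exactly at the origin.

## The synthetic generator

No external dataset is required: `generate_dataset()` produces an OTU
table, metadata, and taxonomy with the temporal structure the tool is meant
to reveal. Per taxon and subject, a latent log-abundance follows an AR(1)
walk \(x_t = \rho x_{t-1} + \varepsilon\) (Gaussian innovations, stationary
start) around a fixed baseline, optionally plus a sinusoid; latent vectors
are softmax-normalized per sample and scaled by a library size (default
10,000 reads) to give counts. Two schedules mirror the two study designs
the tool targets: `schedule_regular()` (set time points, as in intervention
studies) and `schedule_irregular()` (variable spacing with occasional long
collection gaps, as in observational wildlife sampling). Defaults —
\(\rho = 0.8\), innovation SD 0.4 on the log scale, 8 taxa with baselines
spanning four log-units, 20 samples per subject — were chosen once as
typical of moderately autocorrelated gut communities.

The generator is deliberately minimal: it produces no interaction networks,
no compositional zero-inflation, no overdispersed counting noise. Passing
tests therefore demonstrate the correctness of the transform and plumbing
on data with realistic temporal structure, not robustness to every artifact
of real sequencing data. Seeding is mandatory; identical seeds give
byte-identical tables.

`generate_worked_example()` is a fixed 1-subject, 3-taxa, 5-sample percent
bundle whose horizon output is hand-computable (one taxon runs 10–50% in
steps of 10, one is constant, one takes the compositional remainder — a
third taxon is needed because two percent-valued taxa cannot be "one
varying, one constant" and still close to 100%). Its expected geometry is
shipped under `inst/extdata/` and re-derived in the tests.

## Numerical choices and testing scale

Tolerances: percent-column closure is checked at \(10^{-6}\) relative on
input and \(10^{-9}\) after normalization; fill conservation and
monotonicity at \(10^{-12}\); band-edge ties at \(10^{-9}\). The property
suites run 10,000 random (deviation, thickness, band-count) triples against
an interval-intersection oracle, 1,000 random irregular series against an
independent two-point line evaluator, and 100 random tables for filtering
monotonicity — desk-scale sizes that complete in well under two minutes
while exercising the full parameter ranges.

## Known limitations

* Linear interpolation only; no splines, LOESS, or model-based imputation.
* Percent scale end-to-end; no log or CLR transform of the deviations.
* Day resolution; no time zones or sub-day sampling.
* Origin modes are median and fixed; mean or trimmed variants are easy
  extensions but not provided.
* The renderer exposes a minimal option set, not a full grammar
  passthrough; for bespoke aesthetics, take `horizon_ggplot()` output and
  restyle it, or post-process the geometry TSV.
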