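---
title: "Methods: 3D waterfall visualization of qHTS concentration-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D waterfall visualization of qHTS concentration-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtsviz)
```

## The problem

Quantitative high-throughput screening (qHTS) tests every compound of a
chemical library at a titration of concentrations — typically 7 to 15
points spanning 4-5 orders of magnitude — instead of a single dose. The
result is one concentration-response curve (CRC) per compound per
readout, for libraries of 10^4 to 10^5 compounds. Two-axis plots
(activity vs. compound) cannot show the shape of those curves; a 3-axis
*waterfall* rendering — compounds along one axis, log concentration
along the second, response on the third — lets thousands of CRCs be
inspected at once, revealing potency gradients, gain- vs. loss-of-signal
structure, and reporter artifacts at a glance.

qhtsviz reads a simple tabular exchange format for fitted qHTS results,
orders and groups the records, and builds that waterfall scene, exported
to a self-contained interactive HTML page or a static PNG snapshot.

## The response model

Each fitted record carries the four parameters of the Hill (four-parameter
logistic) concentration-response model. With $x$ the log10 molar
concentration, the response in % activity is

$$ y(x) = S_0 + \frac{S_\infty - S_0}{1 + 10^{\,h\,(\log AC_{50} - x)}} $$

where $S_0$ and $S_\infty$ are the zero- and infinite-concentration
asymptotes, $\log AC_{50}$ the log10 molar midpoint concentration and $h$
the Hill coefficient. Sign conventions for $h$ vary between curve-fitting
programs; qhtsviz fixes the parameterization above, which makes $S_0$ the
low-concentration asymptote whenever $h > 0$. Useful identities (all
verified as properties in the test suite): $y(\log AC_{50}) =
(S_0 + S_\infty)/2$; reflection symmetry $y(\log AC_{50} + d) +
y(\log AC_{50} - d) = S_0 + S_\infty$; monotonicity between the two
asymptotes; and the signed span $S_\infty - S_0$ (the *efficacy*), whose
sign separates gain-of-signal from loss-of-signal responses.

Numerically, the exponent $h(\log AC_{50} - x)$ is clamped at $\pm 300$
before exponentiation so that extreme inputs return the correct asymptote
rather than overflowing; curves are *sampled*, never extrapolated: the
drawn polyline spans exactly the tested concentration range, by default
with 64 evenly spaced points (smooth at screen resolution without
bloating a 50,000-curve scene). The package never fits curves for
plotting — input files already carry fitted parameters; the only fitting
code, `fit_hill()`, is a Levenberg-Marquardt least-squares oracle used to
check that the synthetic generator's ground truth is recoverable.

## The input format

Files are `.csv` or `.xlsx` with one shared layout: a `Format` keyword and
dialect tag (`generic_qhts`) in the first two cells; a header row with
`Fit_Output`, `Comp_ID`, `Readout`, optional free annotation columns
(compound name, SMILES — carried as opaque text), the four parameter
columns `Log_AC50_M`, `S_0`, `S_Inf`, `Hill_Slope`, and a contiguous
block of `Data0..DataN` response columns whose log10 molar concentrations
sit in the row above, flagged by a `Log_Conc_M` tag in the preceding
column. `Fit_Output` is 1 to draw the fitted curve, 0 for points only.
Compound IDs may repeat — one row per readout, as in coincidence-reporter
assays with paired firefly (FLuc) and NanoLuc (NLuc) channels.

Deliberate reader policies:

* **Order is sacred.** Rows and columns are never re-sorted; users encode
  grouping by pre-sorting their file, and the plot honors it.
* Header matching is case-insensitive and whitespace-trimmed (hand-edited
  files are common); canonical names are written back on output.
* Blank cells, `NA` and `NaN` denote missing responses; they are dropped
  pointwise when plotting, never imputed — imputation would fabricate
  data. Only the empty string is written back.
* Responses are assumed to be already-normalized % activity; no
  normalization is applied. Scales outside [-200, 200] % raise a
  validation warning, not an error.
* A non-monotonic concentration grid is legal (it is plotted as given)
  but flagged as a warning; grid/record length mismatches always fail
  construction rather than truncate or pad.
* The NCATS-internal `ncats_qhts` dialect tag is recognized and rejected
  with a pointer to the generic layout; its structure is undocumented and
  guessing it would be worse than refusing.

The xlsx writer is deliberately minimal — one worksheet of numeric and
inline-string cells, member timestamps pinned so identical datasets give
byte-identical archives — and is paired with readxl for reading. Numbers
are written at full double precision (`%.17g`), so round-trips are exact
well beyond the 12 significant digits the tests require.

## Ordering and the simplified curve classes

`order_records()` applies a list of sort keys (curve class, AC50,
efficacy, readout, compound ID, or any annotation column), each
ascending or descending, as a *stable* sort: ties and the empty key list
preserve file order. AC50 sorting uses `Log_AC50_M` directly (monotone in
AC50); records lacking parameters always sort last, whatever the
direction, since "no potency" has no meaningful rank.

Full criteria-based curve classification systems take fit quality and
response shape into account; qhtsviz implements a deliberately small,
fully documented surrogate with three knobs
(`curve_class_thresholds()`): a record is **inactive** when it has no
complete parameters or |efficacy| < `min_efficacy` (default 25%);
**complete** when |efficacy| ≥ `low_efficacy_cap` (default 50%) and the
AC50 lies at least `plateau_margin` (default 1) log unit inside both ends
of the tested range, so both plateaus are bracketed by the data;
**partial** when the span is full but a plateau extends beyond the tested
range; and **low_efficacy** otherwise (spans between the two efficacy
thresholds). The rules are evaluated in that precedence order and are
total — every record gets exactly one label. The defaults are exposed
knobs chosen to be pharmacologically conventional (a quarter of full
response as the activity floor, half as the full-efficacy bar, one log
unit as "plateau reached"), not a claim of fidelity to any particular
published classification scheme.

Colors follow the field's conventions: complete red, partial yellow,
low-efficacy green, inactive gray; gain-of-signal blue vs. loss-of-signal
red when coloring by polarity; green/blue for the first two readouts in
coincidence-reporter data. Every label not covered draws
deterministically from a fixed fallback sequence, and user overrides
always win.

## The scene and its renderers

`build_scene()` produces a renderer-independent scene with axis
convention x = compound position, y = log10 molar concentration, z = %
response. Each visible record contributes at most one markers trace and,
if fitted, one line trace — exact bookkeeping that the tests check
against `partition_records()`. Compound positions are consecutive
integers over the plotted compound slots in layout order; by default
records sharing a `Comp_ID` collapse onto one slot so multi-readout
responses overlay (the coincidence-reporter reading), with
`collapse_by_compound = FALSE` giving one slot per row instead. Hidden
readouts contribute nothing; `show_inactive = FALSE` drops points-only
records entirely.

Above 20,000 records (configurable) the markers of points-only records
are thinned to every k-th point, k = ceiling(records / threshold), to
keep interactive files tractable at the 10^4-10^5-compound scale; fitted
records are never decimated, so no curve loses shape.

The HTML exporter embeds the plotly.js runtime and the merged trace data
in a single self-contained page (rotate / zoom / pan; the in-page
toolbar saves PNG snapshots). For rendering performance the exporter
merges scene traces that share a style into one plotly trace, separating
line segments with null coordinates — a pure rendering optimization that
does not alter the scene contract. The static PNG renderer projects the
same scene through a fixed-angle 3D projection onto a raster device
(default 1600 x 1200), drawing far compound slots first so near rows
overdraw them.

## The synthetic-data generator

`generate_dataset()` produces schema-valid datasets with known ground
truth, which is how the whole pipeline is tested without any downloads.
Its defaults emulate the sample data the format was designed around: an
11-point titration from 1 nM to 100 uM (log10 -9 to -4), paired
FLuc/NLuc readouts sharing each compound's true curve with independent
noise, 30% active compounds split evenly between gain and loss of
signal, and additive Gaussian response noise with a 5% activity standard
deviation. Actives draw log AC50 uniformly over the titration range
shrunk by half a log unit (so midpoints are tested), Hill slopes from
U(0.5, 3), baselines near zero (responses are normalized) and |span|
from U(50, 100)%. One seed controls every draw: equal specs give
byte-identical written files.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: plate-position artifacts and edge effects,
heteroscedastic or correlated noise, partially-fit curves whose reported
parameters disagree with their points, and structure-activity
correlation between compounds. The generator validates the pipeline's
bookkeeping and numerics, not assay realism.

The recovery oracle refits every generated titration by
Levenberg-Marquardt least squares. Noiseless draws recover the generating
parameters to 1e-6 relative; at the default 5% noise over 11 points the
median absolute log AC50 error across 200 actives is about 0.06 log
units, comfortably under the 0.25-log-unit bar the acceptance suite
asserts (a threshold frozen from a recorded pilot run of the generator
itself).

## Problem sizes and limitations

The test and acceptance workloads are sized for routine re-runs: 200-400
record datasets for format fidelity, 1000 random draws for the Hill
identities, a 1000-record mixed library for scene bookkeeping, and one
51,441-record single-readout library — a realistic large-campaign size —
for the scale contract, which builds and renders to HTML in well under a
minute on one CPU with decimation engaged.

Known limitations: no 5-parameter or biphasic models; no curve fitting in
the plotting path; no streaming parser (files are read whole); Excel
output is a minimal single-sheet writer without styling; PNG export is a
fixed-camera snapshot rather than a captured interactive view; and the
simplified curve classes are a documented surrogate, not a reimplementation
of any published multi-class criteria system.
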