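# qhtsviz

3D waterfall visualization of quantitative high-throughput screening
(qHTS) concentration–response data.

## What this is for

qHTS tests every compound of a chemical library at a titration of
concentrations (typically 7–15 points over 4–5 log units), yielding one
concentration–response curve (CRC) per compound per readout for
libraries of tens of thousands of compounds. Two-axis activity plots
cannot show curve shape at that scale. qhtsviz builds the 3-axis
*waterfall* view — compounds along one axis, log10 molar concentration
along the second, % response on the third — so thousands of CRCs can be
inspected at once: potency gradients, gain- vs. loss-of-signal
structure, reporter-specific artifacts in coincidence assays.

It is aimed at screening scientists and cheminformaticians who have
*fitted* qHTS results (the tool never fits curves itself) and want an
interactive or static overview plot, from R or from the shell.

Each fitted record carries the four-parameter Hill model

    y(x) = S0 + (Sinf − S0) / (1 + 10^( h · (logAC50 − x) ))

with `x` in log10 molar units, asymptotes `S0`/`Sinf` in % activity,
midpoint `logAC50`, and Hill coefficient `h`. The signed span
`Sinf − S0` (efficacy) separates gain- from loss-of-signal responses.

The package covers:

* **I/O** — read/write/validate the `generic_qhts` tabular layout in
  `.csv` and `.xlsx`: a `Format` tag, `Fit_Output`/`Comp_ID`/`Readout`
  columns, free annotation columns (name, SMILES), the four Hill
  parameter columns, and a contiguous `Data0..DataN` response block with
  log10 molar concentrations in the header row. Row order is never
  changed: pre-sorting the file is how you group the plot.
* **Curves** — evaluate and sample the Hill model, partition fitted vs.
  points-only records, label gain/loss polarity.
* **Layout** — stable multi-key ordering (curve class, AC50, efficacy,
  readout, annotations) and a simplified, fully documented curve-class
  surrogate (complete / partial / low_efficacy / inactive) with exposed
  thresholds.
* **Scene + rendering** — a backend-agnostic 3D scene with exact
  per-record trace bookkeeping, exported to self-contained interactive
  HTML (embedded plotly.js), a static PNG snapshot, or JSON.
* **Synthetic data** — a seeded generator with ground-truth ledger
  (active fraction, gain/loss mix, paired FLuc/NLuc readouts, additive
  noise) plus a least-squares Hill-fit oracle for recovery checks.

## Worked example

```r
library(qhtsviz)

# a 200-compound synthetic library, two coincidence readouts, seeded
out <- generate_dataset(generator_spec(n_compounds = 200, seed = 42))
ds  <- out$dataset
ds
#> <qhts_dataset> 400 records (112 fitted), 11-point grid [-9 .. -4] log10 M
#>   format: generic_qhts | source: synthetic

validate_qhts(ds)
#> <qhts_validation> ok = TRUE (0 error(s), 0 warning(s))

table(curve_classes(ds))
#>     complete     inactive low_efficacy      partial
#>           84          288            6           22

# order by curve class, then decreasing potency within each class,
# color by class, drop the inactive gray dots
perm  <- order_records(ds, ordering_spec("curve_class", "ac50:desc"))
scene <- build_scene(ds, perm, plot_config(show_inactive = FALSE),
                     groups = curve_classes(ds))
scene
#> <qhts_scene> 224 traces (112 markers, 112 lines), 56 compound slots

render_scene(scene, "waterfall.html")   # interactive; rotate/zoom/pan
render_scene(scene, "waterfall.png")    # static snapshot
```

Reading the numbers: 200 compounds × 2 readouts = 400 records; 56
active compounds (112 fitted records — both readouts of each active
compound share one compound slot, hence 56 slots) each contribute one
markers trace and one fitted-curve trace; the 288 inactive records are
hidden. The class table is the simplified classification at its default
thresholds: full-span curves with both plateaus inside the tested range
are `complete`, full-span curves running off the titration edge are
`partial`, 25–50% spans are `low_efficacy`, everything weaker is
`inactive`.

The same pipeline from the shell:

```sh
Rscript inst/scripts/qhtsviz example --output demo.csv --n-compounds 200 --seed 42
Rscript inst/scripts/qhtsviz validate --input demo.csv
Rscript inst/scripts/qhtsviz plot --input demo.csv --output demo.html \
    --sort-by curve_class --sort-by ac50:desc --color-by curve_class --hide-inactive
```

(After installation the script is also at
`system.file("scripts", "qhtsviz", package = "qhtsviz")`.)

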