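Package: qhtsviz
Title: 3D Waterfall Visualization of Quantitative High-Throughput
    Screening Concentration-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads and writes the generic qHTS tabular file format for
    concentration-response screening data (csv and xlsx), evaluates and
    samples four-parameter Hill curves, orders and groups thousands of
    compound responses by curve class, potency, efficacy or readout, and
    builds a 3-axis (compound x log-concentration x response) waterfall
    scene exportable to self-contained interactive HTML or a static PNG
    snapshot. Includes a synthetic-data generator with known ground truth
    (mixtures of active/inactive compounds, gain- and loss-of-signal
    responses, paired coincidence-reporter readouts, additive noise) and a
    Hill-fit recovery oracle, plus a command-line interface over the plot,
    validate and example workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    readxl,
    stats,
    tools,
    utils,
    zip
Suggests:
    plotly,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
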