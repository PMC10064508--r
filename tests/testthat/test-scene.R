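all_fitted_ds <- function() {
  grid <- seq(-8, -4, length.out = 5)
  qhts_dataset(list(
    response_record(1, "A", "FLuc", c(1, 5, 50, 95, 99),
                    params = make_params(-6, 0, 100, 1)),
    response_record(1, "A", "NLuc", c(2, 6, 48, 93, 97),
                    params = make_params(-6, 0, 95, 1)),
    response_record(1, "B", "FLuc", c(99, 95, 50, 5, 1),
                    params = make_params(-6, 100, 0, 1))), grid)
}

test_that("every visible fitted record contributes one markers and one line trace", {
  sc <- build_scene(all_fitted_ds())
  expect_identical(unname(scene_counts(sc)), c(3L, 3L))
  # hiding a readout that covers one record drops exactly its two traces
  sc2 <- build_scene(all_fitted_ds(),
                     config = plot_config(hidden_readouts = "NLuc"))
  expect_identical(unname(scene_counts(sc2)), c(2L, 2L))
  expect_false("NLuc" %in% vapply(sc2$traces, `[[`, "", "readout"))
})

test_that("trace order follows layout order and slots are consecutive", {
  ds <- all_fitted_ds()
  sc <- build_scene(ds, config = plot_config(collapse_by_compound = FALSE))
  idx <- vapply(sc$traces, `[[`, 0L, "record_index")
  expect_identical(unique(idx), 1:3)          # file order preserved
  xs <- vapply(sc$traces, `[[`, 0, "x")
  expect_identical(sort(unique(xs)), c(0, 1, 2))
  # reversing the order reverses the slots
  sc_rev <- build_scene(ds, order = 3:1,
                        config = plot_config(collapse_by_compound = FALSE))
  first <- sc_rev$traces[[1]]
  expect_identical(first$record_index, 3L)
  expect_identical(first$x, 0L)
})

test_that("records sharing a compound id share one slot by default", {
  sc <- build_scene(all_fitted_ds())
  xs <- tapply(vapply(sc$traces, `[[`, 0, "x"),
               vapply(sc$traces, `[[`, "", "comp_id"), unique)
  expect_identical(xs[["A"]], 0)
  expect_identical(xs[["B"]], 1)
})

test_that("hiding inactives keeps exactly the fitted bookkeeping", {
  out <- generate_dataset(generator_spec(n_compounds = 500,
                                         active_fraction = 0.3, seed = 4))
  ds <- out$dataset   # 1000 records over two readouts
  part <- partition_records(ds)
  sc <- build_scene(ds, config = plot_config(show_inactive = FALSE))
  cnt <- scene_counts(sc)
  expect_identical(unname(cnt["markers"]), length(part$fitted))
  expect_identical(unname(cnt["lines"]), length(part$fitted))
  # line traces only ever come from fitted records with complete params
  for (tr in sc$traces[trace_kinds(sc) == "line"]) {
    r <- ds$records[[tr$record_index]]
    expect_identical(r$fit_output, 1L)
    expect_false(is.null(r$params))
  }
})

test_that("missing cells are dropped pointwise and no coordinate is non-finite", {
  ds <- tiny_dataset()   # record 3 has one NA response
  sc <- build_scene(ds)
  tr3 <- Filter(function(t) t$record_index == 3L, sc$traces)[[1]]
  expect_length(tr3$y, 4L)
  for (tr in sc$traces) {
    expect_true(all(is.finite(tr$x)))
    expect_true(all(is.finite(tr$y)))
    expect_true(all(is.finite(tr$z)))
  }
})

test_that("scene construction is deterministic and rejects bad permutations", {
  ds <- tiny_dataset()
  expect_identical(build_scene(ds), build_scene(ds))
  expect_error(build_scene(ds, order = c(1L, 1L, 2L, 3L)), "permutation")
  expect_error(build_scene(ds, order = 1:3), "permutation")
})

test_that("point decimation engages above the threshold, fitted rows untouched", {
  out <- generate_dataset(generator_spec(n_compounds = 60,
                                         active_fraction = 0.2, seed = 9))
  ds <- out$dataset   # 120 records
  cfg <- plot_config(decimation_threshold = 40L)   # stride = ceiling(120/40) = 3
  sc <- build_scene(ds, config = cfg)
  part <- partition_records(ds)
  for (tr in sc$traces[trace_kinds(sc) == "markers"]) {
    n_pts <- length(ds$records[[tr$record_index]]$responses)
    if (tr$record_index %in% part$fitted)
      expect_length(tr$y, n_pts)
    else
      expect_length(tr$y, ceiling(n_pts / 3))
  }
  # below the threshold nothing is thinned
  sc_full <- build_scene(ds)
  for (tr in sc_full$traces[trace_kinds(sc_full) == "markers"])
    expect_length(tr$y, 11L)
})

test_that("group labels and overrides drive the colors", {
  ds <- all_fitted_ds()
  pol <- vapply(ds$records, function(r) polarity(r$params), "")
  sc <- build_scene(ds, groups = pol)
  cols <- vapply(sc$traces, `[[`, "", "color")
  grps <- vapply(sc$traces, `[[`, "", "group")
  expect_true(all(cols[grps == "gain"] == "blue"))
  expect_true(all(cols[grps == "loss"] == "red"))
  sc2 <- build_scene(ds, groups = pol,
                     config = plot_config(line_color = c(gain = "black")))
  line_cols <- vapply(sc2$traces[trace_kinds(sc2) == "line"], `[[`, "", "color")
  line_grps <- vapply(sc2$traces[trace_kinds(sc2) == "line"], `[[`, "", "group")
  expect_true(all(line_cols[line_grps == "gain"] == "black"))
})

test_that("scenes serialize to parseable JSON and render to non-empty files", {
  sc <- build_scene(tiny_dataset())
  js <- scene_to_json(sc)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed$traces, length(sc$traces))
  expect_identical(parsed$traces[[1]]$kind, "markers")

  h <- tempfile(fileext = ".html")
  render_scene(sc, h)
  expect_gt(file.size(h), 1000)
  expect_match(readLines(h, n = 3, warn = FALSE)[1], "<!DOCTYPE html>")
  p <- tempfile(fileext = ".png")
  render_scene(sc, p)
  expect_gt(file.size(p), 1000)
  # rendering twice loads/parses both times
  render_scene(sc, h)
  expect_gt(file.size(h), 1000)
})

test_that("an empty scene still renders valid axes-only files", {
  ds <- qhts_dataset(list(response_record(0, "A", "FLuc", c(1, 2, 3))),
                     c(-8, -7, -6))
  sc <- build_scene(ds, config = plot_config(show_inactive = FALSE))
  expect_length(sc$traces, 0L)
  h <- tempfile(fileext = ".html"); p <- tempfile(fileext = ".png")
  render_scene(sc, h); render_scene(sc, p)
  expect_gt(file.size(h), 100)
  expect_gt(file.size(p), 100)
  expect_error(render_scene(sc, tempfile(fileext = ".svg")), "unsupported")
  expect_error(render_scene(sc, file.path(tempfile(), "x", "y.html")),
               "directory")
})
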