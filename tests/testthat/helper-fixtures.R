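# Shared fixture builders: everything is constructed in code, no stored
# binary fixtures.

make_params <- function(log_ac50_m = -6, s0 = 0, s_inf = 100, hill_slope = 1) {
  curve_fit_params(log_ac50_m, s0, s_inf, hill_slope)
}

# 4 records over a 5-point grid: two fitted (gain FLuc / loss NLuc), two
# points-only, with annotations and one missing response cell
tiny_dataset <- function() {
  grid <- seq(-8, -4, length.out = 5)
  ann <- c(Sample_Name = "thing one", SMILES = "CCO")
  qhts_dataset(list(
    response_record(1, "A", "FLuc", responses = c(1, 5, 50, 95, 99),
                    params = make_params(-6, 0, 100, 1), annotations = ann),
    response_record(1, "A", "NLuc", responses = c(98, 96, 52, 6, 2),
                    params = make_params(-6, 100, 0, 1), annotations = ann),
    response_record(0, "B", "FLuc", responses = c(0, NA, 2, -1, 1),
                    annotations = c(Sample_Name = "thing two", SMILES = "CCO")),
    response_record(0, "B", "NLuc", responses = c(1, 0, -2, 2, 0),
                    annotations = c(Sample_Name = "thing two", SMILES = "CCO"))
  ), grid, source = "synthetic")
}

params_equal <- function(a, b, tol = 1e-12) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = tol))
}

record_equal <- function(a, b, tol = 1e-12) {
  identical(a$comp_id, b$comp_id) &&
    identical(a$readout, b$readout) &&
    a$fit_output == b$fit_output &&
    identical(names(a$annotations), names(b$annotations)) &&
    identical(unname(a$annotations), unname(b$annotations)) &&
    isTRUE(all.equal(a$responses, b$responses, tolerance = tol)) &&
    params_equal(a$params, b$params, tol)
}

dataset_equal <- function(a, b, tol = 1e-12) {
  length(a$records) == length(b$records) &&
    isTRUE(all.equal(a$log_conc_m, b$log_conc_m, tolerance = tol)) &&
    all(vapply(seq_along(a$records), function(i)
      record_equal(a$records[[i]], b$records[[i]], tol), TRUE))
}

# write a raw csv from a list of line strings
write_raw_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# a hand-written minimal 2-record csv in the canonical layout
minimal_csv <- function() {
  write_raw_csv(c(
    "Format,generic_qhts,,,,,Log_Conc_M,-8,-7,-6",
    "Fit_Output,Comp_ID,Readout,Log_AC50_M,S_0,S_Inf,Hill_Slope,Data0,Data1,Data2",
    "1,cmpd-1,FLuc,-7,0,100,1,5,50,95",
    "0,cmpd-2,FLuc,,,,,1,-2,0"))
}

trace_kinds <- function(scene) vapply(scene$traces, `[[`, "", "kind")

scene_counts <- function(scene) {
  k <- trace_kinds(scene)
  c(markers = sum(k == "markers"), lines = sum(k == "line"))
}
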