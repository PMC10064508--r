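#' @keywords internal
"_PACKAGE"

## usethis namespace: start
## usethis namespace: end
NULL

#' Four-parameter Hill curve-fit parameters
#'
#' Bundles the four parameters of a sigmoidal concentration-response fit:
#' the log10-molar half-maximal concentration, the two response asymptotes
#' (in % activity), and the Hill coefficient.
#'
#' @param log_ac50_m log10 of the AC50 in molar units (dimensionless
#'   exponent, e.g. `-6` for 1 uM).
#' @param s0 response at the zero-concentration asymptote (% activity).
#' @param s_inf response at the infinite-concentration asymptote (% activity).
#' @param hill_slope Hill coefficient (dimensionless). Must be non-zero for
#'   a record rendered as a curve; values much greater than 1 indicate
#'   switch-like responses.
#'
#' @return An object of class `curve_fit_params`.
#' @examples
#' p <- curve_fit_params(log_ac50_m = -6, s0 = 0, s_inf = 100, hill_slope = 1.2)
#' efficacy(p)
#' @export
curve_fit_params <- function(log_ac50_m, s0, s_inf, hill_slope) {
  p <- list(log_ac50_m = log_ac50_m, s0 = s0, s_inf = s_inf,
            hill_slope = hill_slope)
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("curve_fit_params: field '", f, "' must be a single finite number",
           call. = FALSE)
  }
  structure(p, class = "curve_fit_params")
}

#' @export
print.curve_fit_params <- function(x, ...) {
  cat(sprintf("<curve_fit_params> logAC50 = %g, S0 = %g, Sinf = %g, slope = %g\n",
              x$log_ac50_m, x$s0, x$s_inf, x$hill_slope))
  invisible(x)
}

#' Signed response span (efficacy) of a fitted curve
#'
#' Efficacy is `s_inf - s0`: positive spans are gain-of-signal responses,
#' negative spans loss-of-signal, zero spans flat (degenerate) curves.
#'
#' @param params a [curve_fit_params()] object.
#' @return A single number, the signed span in % activity.
#' @seealso [polarity()] for the gain/loss/flat label.
#' @export
efficacy <- function(params) {
  if (!inherits(params, "curve_fit_params"))
    stop("efficacy: 'params' must be a curve_fit_params object", call. = FALSE)
  for (f in c("s0", "s_inf")) {
    v <- params[[f]]
    if (is.null(v) || !is.finite(v))
      stop("efficacy: missing parameter '", f, "'", call. = FALSE)
  }
  params$s_inf - params$s0
}

#' One compound-response row of a qHTS dataset
#'
#' A record couples one compound/readout pair with its titration responses,
#' an optional curve fit, and free-form annotation columns carried through
#' from the input file (compound name, SMILES, ...). Compound IDs need not
#' be unique: a compound appears once per readout.
#'
#' @param fit_output 0 or 1. 1 = render the fitted curve, 0 = points only.
#' @param comp_id compound identifier (character scalar; duplicates allowed).
#' @param readout readout name, e.g. `"FLuc"` or `"NLuc"`; must be non-empty.
#' @param responses numeric vector of % activity values, one per grid
#'   concentration; `NA` marks a masked/missing well.
#' @param params optional [curve_fit_params()]; required when
#'   `fit_output == 1`.
#' @param annotations named character vector (possibly empty) of extra
#'   columns, order preserved.
#' @return An object of class `response_record`.
#' @export
response_record <- function(fit_output, comp_id, readout, responses,
                            params = NULL, annotations = character(0)) {
  if (!(length(fit_output) == 1L && fit_output %in% c(0, 1)))
    stop("response_record: fit_output must be 0 or 1", call. = FALSE)
  comp_id <- as.character(comp_id)
  readout <- as.character(readout)
  if (length(readout) != 1L || is.na(readout) || !nzchar(trimws(readout)))
    stop("response_record: readout must be non-empty", call. = FALSE)
  if (!is.null(params) && !inherits(params, "curve_fit_params"))
    stop("response_record: params must be NULL or curve_fit_params", call. = FALSE)
  if (fit_output == 1 && is.null(params))
    stop("response_record: fit_output = 1 requires complete curve parameters",
         call. = FALSE)
  if (length(annotations) && is.null(names(annotations)))
    stop("response_record: annotations must be named", call. = FALSE)
  structure(list(fit_output = as.integer(fit_output), comp_id = comp_id,
                 readout = readout, annotations = annotations,
                 params = params, responses = as.numeric(responses)),
            class = "response_record")
}

#' An ordered qHTS concentration-response dataset
#'
#' Holds a shared log10-molar concentration grid (one header row per file),
#' the records in exactly their input-row order, the format tag and a
#' provenance string. Record order is sacred: the waterfall plot is drawn
#' in this order, so pre-sorting the file is how users group compounds.
#'
#' @param records list of [response_record()] objects, input order.
#' @param log_conc_m numeric vector of log10-molar concentrations, one per
#'   data column, in file column order (not resorted).
#' @param format_tag dialect token; the generic reader always produces
#'   `"generic_qhts"`.
#' @param source provenance text: a file path or `"synthetic"`.
#' @return An object of class `qhts_dataset`.
#' @details Construction fails (never truncates or pads) when any record's
#'   response vector disagrees in length with the grid.
#' @export
qhts_dataset <- function(records, log_conc_m, format_tag = "generic_qhts",
                         source = "synthetic") {
  log_conc_m <- as.numeric(log_conc_m)
  if (length(log_conc_m) < 1L || any(!is.finite(log_conc_m)))
    stop("qhts_dataset: log_conc_m must be finite", call. = FALSE)
  if (!is.list(records) || !all(vapply(records, inherits, TRUE, "response_record")))
    stop("qhts_dataset: records must be a list of response_record objects",
         call. = FALSE)
  for (i in seq_along(records)) {
    if (length(records[[i]]$responses) != length(log_conc_m))
      stop(sprintf(paste0("qhts_dataset: record %d has %d responses but the ",
                          "concentration grid has %d points"),
                   i, length(records[[i]]$responses), length(log_conc_m)),
           call. = FALSE)
  }
  structure(list(format_tag = format_tag, log_conc_m = log_conc_m,
                 records = records, source = source),
            class = "qhts_dataset")
}

#' @export
length.qhts_dataset <- function(x) length(x$records)

#' @export
print.qhts_dataset <- function(x, ...) {
  n_fit <- sum(vapply(x$records, function(r) r$fit_output == 1L, TRUE))
  cat(sprintf("<qhts_dataset> %d records (%d fitted), %d-point grid [%g .. %g] log10 M\n",
              length(x$records), n_fit, length(x$log_conc_m),
              min(x$log_conc_m), max(x$log_conc_m)))
  cat(sprintf("  format: %s | source: %s\n", x$format_tag, x$source))
  invisible(x)
}

# internal: TRUE when a record carries a complete, usable fit
has_complete_params <- function(rec) {
  !is.null(rec$params) &&
    all(vapply(rec$params[c("log_ac50_m", "s0", "s_inf", "hill_slope")],
               function(v) length(v) == 1L && is.finite(v), TRUE))
}
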