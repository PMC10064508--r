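#' Evaluate the four-parameter Hill concentration-response model
#'
#' Computes `s0 + (s_inf - s0) / (1 + 10^(hill_slope * (log_ac50_m - x)))`
#' at log10-molar concentration(s) `x`. With a positive Hill slope the
#' response tends to `s0` as `x -> -Inf` and to `s_inf` as `x -> +Inf`;
#' at `x = log_ac50_m` it is the midpoint `(s0 + s_inf)/2`.
#'
#' @param x numeric vector of log10-molar concentrations (finite).
#' @param params a [curve_fit_params()] object with `hill_slope != 0`.
#' @return Numeric vector of responses (% activity), same length as `x`.
#' @details The power-term exponent is clamped at +/-300 before
#'   exponentiation, so extreme concentrations return the appropriate
#'   asymptote instead of overflowing to non-finite values.
#' @examples
#' p <- curve_fit_params(-6, 0, 100, 1)
#' hill_response(-6, p)       # 50, the midpoint
#' hill_response(-5, p)       # 100/1.1, one log unit above the AC50
#' @export
hill_response <- function(x, params) {
  if (!inherits(params, "curve_fit_params"))
    stop("hill_response: 'params' must be a curve_fit_params object", call. = FALSE)
  if (params$hill_slope == 0)
    stop("hill_response: hill_slope must be non-zero", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("hill_response: 'x' must be finite log10-molar concentrations",
         call. = FALSE)
  e <- params$hill_slope * (params$log_ac50_m - x)
  e <- pmin(pmax(e, -300), 300)
  params$s0 + (params$s_inf - params$s0) / (1 + 10^e)
}

#' Sample a Hill curve over a concentration range
#'
#' Evaluates the fitted curve on an evenly spaced grid spanning the tested
#' concentration range (no extrapolation beyond it), producing the polyline
#' drawn for each fitted record in the waterfall plot.
#'
#' @param params a [curve_fit_params()] object.
#' @param grid numeric vector (>= 2 distinct finite values) of tested
#'   log10-molar concentrations; only its range is used.
#' @param points_per_curve number of evenly spaced sample points (>= 2;
#'   default 64, smooth at plot resolution without bloating large scenes).
#' @param record_index index of the source record, carried for bookkeeping.
#' @return A list of class `sampled_curve` with fields `x` (strictly
#'   increasing), `y`, and `record_index`.
#' @export
sample_curve <- function(params, grid, points_per_curve = 64L,
                         record_index = NA_integer_) {
  grid <- as.numeric(grid)
  if (any(!is.finite(grid)))
    stop("sample_curve: grid concentrations must be finite", call. = FALSE)
  lo <- min(grid); hi <- max(grid)
  if (length(grid) < 2L || lo == hi)
    stop("sample_curve: need at least two distinct concentrations to draw a curve",
         call. = FALSE)
  if (points_per_curve < 2L)
    stop("sample_curve: points_per_curve must be >= 2", call. = FALSE)
  x <- seq(lo, hi, length.out = points_per_curve)
  structure(list(x = x, y = hill_response(x, params),
                 record_index = as.integer(record_index)),
            class = "sampled_curve")
}

#' Partition records into fitted and points-only sets
#'
#' A record is rendered as a curve fit only when its `Fit_Output` flag is 1
#' and all four Hill parameters are present and finite; every other record
#' is drawn as data points only.
#'
#' @param ds a [qhts_dataset()].
#' @return A list with integer index vectors `fitted` and `points_only`,
#'   disjoint, covering all records, each in dataset order.
#' @export
partition_records <- function(ds) {
  stopifnot(inherits(ds, "qhts_dataset"))
  is_fit <- vapply(ds$records,
                   function(r) r$fit_output == 1L && has_complete_params(r),
                   TRUE)
  list(fitted = which(is_fit), points_only = which(!is_fit))
}

#' Gain/loss/flat polarity of a fitted curve
#'
#' The sign of the efficacy (`s_inf - s0`) distinguishes gain-of-signal
#' responses (positive span) from loss-of-signal (negative span); a zero
#' span is a flat, degenerate curve classified as neither.
#'
#' @param params a [curve_fit_params()] object.
#' @return `"gain"`, `"loss"`, or `"flat"`.
#' @export
polarity <- function(params) {
  e <- efficacy(params)
  if (e > 0) "gain" else if (e < 0) "loss" else "flat"
}
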