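# Synthetic qHTS datasets with known ground truth. The generator emulates
# the generic-format sample data: an 11-point titration over ~5 log units,
# a mixture of active and inactive compounds, gain- and loss-of-signal
# responses, paired coincidence-reporter readouts (one record per
# compound x readout sharing the compound's true curve, independent
# noise), and additive Gaussian noise on % activity.

#' Specification for the synthetic qHTS generator
#'
#' @param n_compounds number of compounds.
#' @param n_concs titration points (default 11).
#' @param conc_range length-2 `c(low, high)` log10-molar range of the
#'   titration (default -9 to -4, i.e. 1 nM to 100 uM).
#' @param active_fraction probability a compound is active (default 0.3).
#' @param gain_fraction among actives, probability of a gain-of-signal
#'   response (default 0.5); the rest are loss-of-signal.
#' @param readouts readout names; each compound gets one record per
#'   readout (default the coincidence-reporter pair `c("FLuc", "NLuc")`).
#' @param noise_sd standard deviation of additive response noise
#'   (% activity; default 5).
#' @param seed integer seed; the single source of randomness, so equal
#'   specs give byte-identical written files.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_compounds = 100L, n_concs = 11L,
                           conc_range = c(-9, -4), active_fraction = 0.3,
                           gain_fraction = 0.5,
                           readouts = c("FLuc", "NLuc"),
                           noise_sd = 5, seed = 1L) {
  if (!(n_compounds >= 1L)) stop("generator_spec: n_compounds must be >= 1",
                                 call. = FALSE)
  if (!(n_concs >= 2L)) stop("generator_spec: n_concs must be >= 2", call. = FALSE)
  if (!(length(conc_range) == 2L && conc_range[1L] < conc_range[2L]))
    stop("generator_spec: conc_range must be c(low, high) with low < high",
         call. = FALSE)
  if (active_fraction < 0 || active_fraction > 1)
    stop("generator_spec: active_fraction must be in [0, 1]", call. = FALSE)
  if (gain_fraction < 0 || gain_fraction > 1)
    stop("generator_spec: gain_fraction must be in [0, 1]", call. = FALSE)
  if (!length(readouts) || any(!nzchar(readouts)))
    stop("generator_spec: readouts must be non-empty names", call. = FALSE)
  if (noise_sd < 0) stop("generator_spec: noise_sd must be >= 0", call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_concs = as.integer(n_concs),
                 conc_range = as.numeric(conc_range),
                 active_fraction = active_fraction,
                 gain_fraction = gain_fraction,
                 readouts = as.character(readouts),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_spec")
}

# a few valid opaque structure strings cycled through the annotation column
SMILES_POOL <- c("c1ccccc1", "CCO", "CC(=O)Oc1ccccc1C(=O)O", "C1CCCCC1",
                 "c1ccc2ccccc2c1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O")

#' Generate a synthetic qHTS dataset with ground truth
#'
#' Active compounds draw `Log_AC50_M ~ U(low + 0.5, high - 0.5)` (so the
#' midpoint sits inside the tested range), `Hill_Slope ~ U(0.5, 3)`,
#' `S_0 ~ U(-5, 5)` (responses are normalized, so the baseline sits near
#' zero) and `|S_Inf| ~ U(50, 100)` signed by the gain/loss draw; their
#' responses are the Hill curve plus `N(0, noise_sd)` noise and their
#' records carry the true parameters with `Fit_Output = 1`. Inactive
#' compounds get pure-noise responses, `Fit_Output = 0` and no
#' parameters. Each compound yields one record per readout, sharing the
#' true curve with independent noise.
#'
#' @param spec a [generator_spec()].
#' @return A list with `dataset` (a [qhts_dataset()]) and `ledger`, a data
#'   frame of per-compound ground truth: `comp_id`, `active`, `polarity`,
#'   the four true parameters, and the true `curve_class` under default
#'   [curve_class_thresholds()].
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  lo <- spec$conc_range[1L]; hi <- spec$conc_range[2L]
  grid <- seq(lo, hi, length.out = spec$n_concs)

  active <- stats::runif(n) < spec$active_fraction
  gain <- stats::runif(n) < spec$gain_fraction
  log_ac50 <- stats::runif(n, lo + 0.5, hi - 0.5)
  hill <- stats::runif(n, 0.5, 3)
  s0 <- stats::runif(n, -5, 5)
  s_inf <- ifelse(gain, 1, -1) * stats::runif(n, 50, 100)

  comp_id <- sprintf("CMPD_%05d", seq_len(n))
  records <- vector("list", n * length(spec$readouts))
  ledger <- data.frame(comp_id = comp_id, active = active,
                       polarity = NA_character_,
                       log_ac50_m = NA_real_, s0 = NA_real_,
                       s_inf = NA_real_, hill_slope = NA_real_,
                       curve_class = "inactive", stringsAsFactors = FALSE)

  k <- 0L
  for (i in seq_len(n)) {
    ann <- c(Sample_Name = sprintf("Compound %d", i),
             SMILES = SMILES_POOL[((i - 1L) %% length(SMILES_POOL)) + 1L])
    if (active[i]) {
      p <- curve_fit_params(log_ac50[i], s0[i], s_inf[i], hill[i])
      mu <- hill_response(grid, p)
      ledger$polarity[i] <- polarity(p)
      ledger$log_ac50_m[i] <- p$log_ac50_m; ledger$s0[i] <- p$s0
      ledger$s_inf[i] <- p$s_inf; ledger$hill_slope[i] <- p$hill_slope
      ledger$curve_class[i] <- assign_curve_class(
        response_record(1, comp_id[i], spec$readouts[1L],
                        responses = mu, params = p),
        grid)
      for (ro in spec$readouts) {
        k <- k + 1L
        records[[k]] <- response_record(
          1, comp_id[i], ro,
          responses = mu + stats::rnorm(spec$n_concs, 0, spec$noise_sd),
          params = p, annotations = ann)
      }
    } else {
      for (ro in spec$readouts) {
        k <- k + 1L
        records[[k]] <- response_record(
          0, comp_id[i], ro,
          responses = stats::rnorm(spec$n_concs, 0, spec$noise_sd),
          annotations = ann)
      }
    }
  }

  list(dataset = qhts_dataset(records, grid, source = "synthetic"),
       ledger = ledger)
}

#' Write a ready-to-plot synthetic example file
#'
#' Generates a dataset with [generate_dataset()] and writes it in the
#' generic qHTS layout (`.csv` or `.xlsx` by extension). Equal specs give
#' byte-identical files.
#'
#' @param path output path.
#' @param spec a [generator_spec()].
#' @return The generator output (dataset + ledger), invisibly.
#' @export
generate_example_file <- function(path, spec = generator_spec()) {
  out <- generate_dataset(spec)
  write_generic_qhts(out$dataset, path)
  invisible(out)
}

#' Least-squares Hill fit (generator recovery oracle)
#'
#' Fits the four-parameter Hill model to one titration by
#' Levenberg-Marquardt least squares. The plotting pipeline never fits —
#' input files already carry fitted parameters — this exists to verify
#' that the generator's ground truth is recoverable from its own noisy
#' responses.
#'
#' @param responses numeric responses (% activity), `NA` allowed.
#' @param grid log10-molar concentrations, same length.
#' @return A list of class `hill_fit`: `params` (a [curve_fit_params()],
#'   or `NULL` when the fit failed) and `converged` (logical flag).
#' @export
fit_hill <- function(responses, grid) {
  stopifnot(length(responses) == length(grid))
  ok <- is.finite(responses) & is.finite(grid)
  if (sum(ok) < 5L)
    stop("fit_hill: need at least 5 non-missing points", call. = FALSE)
  y <- responses[ok]; x <- grid[ok]
  o <- order(x); x <- x[o]; y <- y[o]
  nlow <- max(2L, min(3L, length(y) %/% 3L))
  start <- list(s0 = mean(y[seq_len(nlow)]),
                s_inf = mean(y[seq.int(length(y) - nlow + 1L, length(y))]),
                ac50 = x[which.min(abs(y - mean(range(y))))],
                h = 1.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ s0 + (s_inf - s0) / (1 + 10^(h * (ac50 - x))),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(params = NULL, converged = FALSE),
                     class = "hill_fit"))
  cf <- stats::coef(fit)
  params <- tryCatch(
    curve_fit_params(cf[["ac50"]], cf[["s0"]], cf[["s_inf"]], cf[["h"]]),
    error = function(e) NULL)
  structure(list(params = params, converged = !is.null(params)),
            class = "hill_fit")
}
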