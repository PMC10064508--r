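# Ordering, grouping and curve-classification of records ahead of scene
# construction. The cardinal rule is order preservation: with no sorting
# keys the plot is drawn in exact file row order, and all sorts are stable
# so ties never reshuffle rows.

ORDER_CRITERIA <- c("file_order", "curve_class", "ac50", "efficacy",
                    "readout", "comp_id")

#' Specify how records are ordered in the waterfall
#'
#' Keys are applied left to right; an empty spec means file order (the
#' identity). Each key is a criterion name, optionally suffixed `:asc` or
#' `:desc` (default ascending). Criteria: `file_order`, `curve_class`
#' (class rank: complete, partial, low_efficacy, inactive), `ac50` (sorts
#' on `Log_AC50_M`; records without parameters always sort last),
#' `efficacy`, `readout`, `comp_id`, or `annotation:<name>` for any
#' annotation column.
#'
#' @param ... character keys, e.g. `ordering_spec("curve_class", "ac50:desc")`.
#' @return An object of class `ordering_spec`.
#' @export
ordering_spec <- function(...) {
  keys <- as.character(unlist(list(...), use.names = FALSE))
  parsed <- lapply(keys, function(k) {
    k <- trimws(k)
    dir <- "asc"
    if (grepl(":(asc|desc)$", k)) {
      dir <- sub("^.*:", "", k)
      k <- sub(":(asc|desc)$", "", k)
    }
    crit <- if (grepl("^annotation:", k, ignore.case = TRUE)) {
      paste0("annotation:", sub("^[Aa]nnotation:", "", k))  # name keeps its case
    } else {
      tolower(k)
    }
    if (!(crit %in% ORDER_CRITERIA || startsWith(crit, "annotation:")))
      stop("ordering_spec: unknown criterion '", k, "' (expected one of ",
           paste(ORDER_CRITERIA, collapse = ", "), " or annotation:<name>)",
           call. = FALSE)
    list(criterion = crit, direction = dir)
  })
  structure(parsed, class = "ordering_spec")
}

#' @export
print.ordering_spec <- function(x, ...) {
  if (!length(x)) cat("<ordering_spec> file order (identity)\n")
  else cat("<ordering_spec>",
           paste(vapply(x, function(k) paste0(k$criterion, ":", k$direction), ""),
                 collapse = ", "), "\n")
  invisible(x)
}

CLASS_LEVELS <- c("complete", "partial", "low_efficacy", "inactive")

#' Curve-class thresholds
#'
#' Tunable parameters of the simplified curve classification:
#' `min_efficacy` (% activity; spans below it are inactive),
#' `low_efficacy_cap` (% activity; spans below it but above `min_efficacy`
#' are low-efficacy), and `plateau_margin` (log10 units the AC50 must sit
#' inside both grid extremes for the curve to count as complete, i.e. both
#' plateaus reached within the tested range).
#'
#' @param min_efficacy minimum absolute span to call a record active (default 25).
#' @param low_efficacy_cap span below which an active response is
#'   low-efficacy (default 50).
#' @param plateau_margin bracketing margin in log10 units (default 1).
#' @return A named list of class `curve_class_thresholds`.
#' @export
curve_class_thresholds <- function(min_efficacy = 25, low_efficacy_cap = 50,
                                   plateau_margin = 1) {
  stopifnot(min_efficacy >= 0, low_efficacy_cap >= min_efficacy,
            plateau_margin >= 0)
  structure(list(min_efficacy = min_efficacy,
                 low_efficacy_cap = low_efficacy_cap,
                 plateau_margin = plateau_margin),
            class = "curve_class_thresholds")
}

#' Assign a simplified curve class to one record
#'
#' A deterministic surrogate for criteria-based response-curve
#' classification, on four levels. In precedence order: `inactive` (no
#' complete parameters, or |efficacy| < `min_efficacy`); `complete`
#' (|efficacy| >= `low_efficacy_cap` and the AC50 at least
#' `plateau_margin` log units inside both grid extremes, so both
#' asymptotes are bracketed by the tested range); `partial` (full-span
#' response whose AC50 is tested but a plateau extends beyond the range);
#' `low_efficacy` (the rest: responses with `min_efficacy` <= |efficacy| <
#' `low_efficacy_cap`).
#'
#' @param rec a [response_record()].
#' @param grid the dataset's log10-molar concentration grid.
#' @param thresholds a [curve_class_thresholds()] object.
#' @return One of `"complete"`, `"partial"`, `"low_efficacy"`, `"inactive"`.
#' @export
assign_curve_class <- function(rec, grid, thresholds = curve_class_thresholds()) {
  stopifnot(inherits(rec, "response_record"),
            inherits(thresholds, "curve_class_thresholds"))
  if (!has_complete_params(rec)) return("inactive")
  eff <- abs(efficacy(rec$params))
  if (eff < thresholds$min_efficacy) return("inactive")
  lo <- min(grid); hi <- max(grid)
  ac50 <- rec$params$log_ac50_m
  bracketed <- ac50 >= lo + thresholds$plateau_margin &&
               ac50 <= hi - thresholds$plateau_margin
  if (eff >= thresholds$low_efficacy_cap && bracketed) return("complete")
  if (eff >= thresholds$low_efficacy_cap) return("partial")
  "low_efficacy"
}

#' Curve classes for every record of a dataset
#'
#' @param ds a [qhts_dataset()].
#' @param thresholds a [curve_class_thresholds()] object.
#' @return Character vector of class labels, one per record, dataset order.
#' @export
curve_classes <- function(ds, thresholds = curve_class_thresholds()) {
  stopifnot(inherits(ds, "qhts_dataset"))
  vapply(ds$records, assign_curve_class, "", grid = ds$log_conc_m,
         thresholds = thresholds)
}

#' Order records for plotting
#'
#' Produces a permutation of record indices under an [ordering_spec()].
#' The sort is stable: ties — and the empty spec — preserve input file
#' order, honoring the contract that compound order in the file is the
#' order in the plot. `ac50` sorts on `Log_AC50_M` (monotone in AC50);
#' records without complete parameters sort last regardless of direction.
#'
#' @param ds a [qhts_dataset()].
#' @param spec an [ordering_spec()] (default: empty, i.e. file order).
#' @param thresholds thresholds used when a `curve_class` key is present.
#' @return An integer permutation of `seq_along(ds$records)`.
#' @export
order_records <- function(ds, spec = ordering_spec(),
                          thresholds = curve_class_thresholds()) {
  stopifnot(inherits(ds, "qhts_dataset"), inherits(spec, "ordering_spec"))
  n <- length(ds$records)
  if (!length(spec)) return(seq_len(n))

  cols <- list()
  dirs <- logical(0)   # TRUE = decreasing
  push <- function(v, desc) {
    cols[[length(cols) + 1L]] <<- v
    dirs <<- c(dirs, desc)
  }
  param_num <- function(field) {
    vapply(ds$records, function(r)
      if (has_complete_params(r)) r$params[[field]] else NA_real_, 0)
  }

  for (k in spec) {
    desc <- identical(k$direction, "desc")
    if (k$criterion == "file_order") {
      push(seq_len(n), desc)
    } else if (k$criterion == "curve_class") {
      cls <- curve_classes(ds, thresholds)
      push(match(cls, CLASS_LEVELS), desc)
    } else if (k$criterion == "ac50") {
      v <- param_num("log_ac50_m")
      push(is.na(v), FALSE)                  # missing params last, always
      push(ifelse(is.na(v), 0, v), desc)
    } else if (k$criterion == "efficacy") {
      v <- vapply(ds$records, function(r)
        if (has_complete_params(r)) efficacy(r$params) else NA_real_, 0)
      push(is.na(v), FALSE)
      push(ifelse(is.na(v), 0, v), desc)
    } else if (k$criterion == "readout") {
      push(vapply(ds$records, function(r) r$readout, ""), desc)
    } else if (k$criterion == "comp_id") {
      push(vapply(ds$records, function(r) r$comp_id, ""), desc)
    } else {  # annotation:<name>
      nm <- sub("^annotation:", "", k$criterion)
      v <- vapply(ds$records, function(r) {
        a <- r$annotations[names(r$annotations) == nm]
        if (!length(a)) NA_character_ else as.character(a[[1L]])
      }, "")
      if (anyNA(v))
        stop("order_records: annotation '", nm, "' is missing from record ",
             which(is.na(v))[1L], call. = FALSE)
      push(v, desc)
    }
  }
  cols$decreasing <- dirs
  cols$method <- "radix"    # stable, supports per-key direction
  do.call(order, cols)
}

#' Default deterministic color palette for plot groups
#'
#' Built-in conventions: curve classes run from red (fully efficacious
#' complete sigmoids) through yellow (partial) and green (low efficacy),
#' with inactive gray; polarity colors are blue for gain-of-signal and red
#' for loss-of-signal; the first two readouts get green and blue (the
#' coincidence-reporter pairing). Unknown labels draw from a fixed
#' fallback sequence by position, so the mapping is deterministic. User
#' overrides always win.
#'
#' @param groups character vector of group labels (order matters for
#'   fallback assignment; duplicates allowed).
#' @param overrides optional named character vector label -> color.
#' @return Named character vector mapping each distinct label to a color.
#' @export
default_palette <- function(groups, overrides = NULL) {
  labs <- unique(as.character(groups))
  builtin <- c(complete = "red", partial = "yellow", low_efficacy = "green",
               inactive = "gray", gain = "blue", loss = "red",
               flat = "gray", FLuc = "green", NLuc = "blue")
  fallback <- c("forestgreen", "blue", "purple", "orange", "deepskyblue",
                "magenta", "brown", "darkcyan")
  out <- character(length(labs)); names(out) <- labs
  k <- 0L
  for (l in labs) {
    if (l %in% names(builtin)) out[l] <- builtin[[l]]
    else { k <- k + 1L; out[l] <- fallback[[((k - 1L) %% length(fallback)) + 1L]] }
  }
  if (length(overrides)) {
    hit <- intersect(names(overrides), labs)
    out[hit] <- overrides[hit]
  }
  out
}
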