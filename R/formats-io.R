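# Reading, validating and writing the generic qHTS tabular layout.
#
# Layout contract (csv and xlsx share one cell model):
#   row 1: Format, <tag>, ..., Log_Conc_M, conc_0 .. conc_N
#   row 2: Fit_Output, Comp_ID, Readout, <annotations...>,
#          Log_AC50_M, S_0, S_Inf, Hill_Slope, Data0 .. DataN
#   rows 3+: one record per row
# Header matching is case-insensitive and whitespace-trimmed; canonical
# names are written on output. The Data block must be contiguous and its
# headers consecutively numbered from Data0; annotation columns may sit
# anywhere outside it. Rows and columns are never reordered.

FIXED_COLS  <- c("fit_output", "comp_id", "readout")
PARAM_COLS  <- c("log_ac50_m", "s_0", "s_inf", "hill_slope")
PARAM_CANON <- c("Log_AC50_M", "S_0", "S_Inf", "Hill_Slope")

norm_header <- function(x) tolower(trimws(x))

is_missing_token <- function(x) {
  is.na(x) | norm_header(x) %in% c("", "na", "nan")
}

# strict numeric parse: scientific notation ok, thousands separators are not
parse_number <- function(x) {
  suppressWarnings(as.numeric(trimws(x)))
}

read_cells <- function(path) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                          check.names = FALSE, na.strings = character(0),
                          blank.lines.skip = FALSE, fill = TRUE)
    as.matrix(df)
  } else if (ext %in% c("xlsx", "xls")) {
    df <- suppressMessages(
      readxl::read_excel(path, sheet = 1, col_names = FALSE,
                         col_types = "text", .name_repair = "minimal"))
    m <- as.matrix(df)
    m[is.na(m)] <- ""
    m
  } else {
    stop("unsupported file extension '.", ext, "' (expected .csv or .xlsx)",
         call. = FALSE)
  }
}

#' Detect the dialect tag of a qHTS input file
#'
#' Reads the Format keyword cell (first cell of the first row) and returns
#' the adjacent format value, lower-cased and trimmed — typically
#' `"generic_qhts"`, or `"ncats_qhts"` for the NCATS export dialect.
#'
#' @param path path to a `.csv` or `.xlsx` file.
#' @return The format token as a character scalar.
#' @export
detect_format <- function(path) {
  detect_format_cells(read_cells(path))
}

detect_format_cells <- function(cells) {
  if (nrow(cells) < 1L || ncol(cells) < 2L || norm_header(cells[1L, 1L]) != "format")
    stop("no Format tag: first cell of the first row must be the keyword 'Format'",
         call. = FALSE)
  unname(norm_header(cells[1L, 2L]))
}

# locate the fixed columns, parameter columns, data block and annotations
parse_layout <- function(cells, path = "<cells>") {
  if (nrow(cells) < 2L)
    stop("format error in '", path, "': need a Format row and a header row",
         call. = FALSE)
  hdr <- norm_header(cells[2L, ])

  data_cols <- grep("^data[0-9]+$", hdr)
  if (!length(data_cols))
    stop("format error in '", path, "': no Data0..DataN response columns found",
         call. = FALSE)
  idx <- as.integer(sub("^data", "", hdr[data_cols]))
  if (any(diff(data_cols) != 1L))
    stop("format error in '", path, "': Data block is not contiguous near column ",
         data_cols[which(diff(data_cols) != 1L)[1L] + 1L], call. = FALSE)
  if (!identical(idx, seq_along(idx) - 1L))
    stop("format error in '", path, "': Data headers must be consecutively ",
         "numbered from Data0; found '", cells[2L, data_cols[which(idx != seq_along(idx) - 1L)[1L]]],
         "' out of sequence", call. = FALSE)

  tag_col <- data_cols[1L] - 1L
  if (tag_col < 1L || norm_header(cells[1L, tag_col]) != "log_conc_m")
    stop("format error in '", path, "': expected the Log_Conc_M tag in row 1 ",
         "immediately before the Data block (column ", max(tag_col, 1L), ")",
         call. = FALSE)

  conc <- parse_number(cells[1L, data_cols])
  if (any(!is.finite(conc))) {
    bad <- data_cols[which(!is.finite(conc))[1L]]
    stop("format error in '", path, "': unparseable concentration above data ",
         "header '", cells[2L, bad], "' (column ", bad, ")", call. = FALSE)
  }

  fixed <- match(FIXED_COLS, hdr)
  if (anyNA(fixed))
    stop("format error in '", path, "': missing required column(s): ",
         paste(c("Fit_Output", "Comp_ID", "Readout")[is.na(fixed)], collapse = ", "),
         call. = FALSE)
  params <- match(PARAM_COLS, hdr)

  known <- c(fixed, params[!is.na(params)], data_cols)
  ann_cols <- setdiff(which(nzchar(trimws(cells[2L, ]))), known)
  ann_cols <- ann_cols[order(ann_cols)]

  list(fit_output = fixed[1L], comp_id = fixed[2L], readout = fixed[3L],
       params = params, has_params = !anyNA(params),
       data_cols = data_cols, log_conc_m = conc,
       ann_cols = ann_cols, ann_names = trimws(cells[2L, ann_cols]))
}

#' Read a generic qHTS concentration-response file
#'
#' Parses a `.csv` or `.xlsx` file in the generic qHTS layout into a
#' [qhts_dataset()], preserving record order, column order of annotations,
#' and the concentration grid exactly as given. Blank cells, `NA` and
#' `NaN` (case-insensitive) denote missing responses.
#'
#' @param path path to a `.csv` or `.xlsx` file whose format tag is
#'   `generic_qhts`.
#' @return A [qhts_dataset()] with `source = path`.
#' @details Files tagged `ncats_qhts` (the NCATS-internal export dialect)
#'   are recognized and rejected with a pointer to the generic format. A
#'   row flagged `Fit_Output = 1` must carry all four curve parameters;
#'   otherwise reading fails with the offending row named.
#' @seealso [write_generic_qhts()], [validate_qhts()], [detect_format()]
#' @export
read_generic_qhts <- function(path) {
  cells <- read_cells(path)
  tag <- detect_format_cells(cells)
  if (tag == "ncats_qhts")
    stop("unsupported dialect 'ncats_qhts': this reader handles the generic ",
         "format only; export or convert your data to the 'generic_qhts' layout",
         call. = FALSE)
  if (tag != "generic_qhts")
    stop("unknown format tag '", tag, "' (expected 'generic_qhts')", call. = FALSE)

  lay <- parse_layout(cells, path)
  nconc <- length(lay$data_cols)

  records <- list()
  for (i in seq_len(nrow(cells))[-(1:2)]) {
    row <- cells[i, ]
    if (all(is_missing_token(row))) next   # skip fully blank rows

    fo_raw <- parse_number(row[lay$fit_output])
    if (!isTRUE(fo_raw %in% c(0, 1)))
      stop("validation error in '", path, "' row ", i,
           ": Fit_Output must be 0 or 1, got '", row[lay$fit_output], "'",
           call. = FALSE)

    params <- NULL
    if (lay$has_params) {
      raw <- row[lay$params]
      miss <- is_missing_token(raw)
      if (!all(miss)) {
        vals <- parse_number(raw)
        bad <- !miss & !is.finite(vals)
        if (any(bad))
          stop("validation error in '", path, "' row ", i, ": unparseable ",
               PARAM_CANON[which(bad)[1L]], " value '", raw[which(bad)[1L]], "'",
               call. = FALSE)
        if (any(miss)) {
          if (fo_raw == 1)
            stop("validation error in '", path, "' row ", i,
                 ": Fit_Output = 1 but ", PARAM_CANON[which(miss)[1L]],
                 " is missing", call. = FALSE)
          # incomplete fit on a points-only row: carry no parameters
        } else {
          params <- curve_fit_params(vals[1L], vals[2L], vals[3L], vals[4L])
        }
      }
    }
    if (fo_raw == 1 && is.null(params))
      stop("validation error in '", path, "' row ", i,
           ": Fit_Output = 1 but the curve parameters are missing", call. = FALSE)

    raw_resp <- row[lay$data_cols]
    resp <- rep(NA_real_, nconc)
    present <- !is_missing_token(raw_resp)
    vals <- parse_number(raw_resp[present])
    if (any(!is.finite(vals))) {
      bad <- which(present)[which(!is.finite(vals))[1L]]
      stop("validation error in '", path, "' row ", i, ": unparseable response '",
           raw_resp[bad], "' under '", cells[2L, lay$data_cols[bad]], "'",
           call. = FALSE)
    }
    resp[present] <- vals

    ann <- character(0)
    if (length(lay$ann_cols)) {
      ann <- as.character(row[lay$ann_cols])
      ann[is.na(ann)] <- ""
      names(ann) <- lay$ann_names
    }

    records[[length(records) + 1L]] <-
      response_record(fit_output = fo_raw, comp_id = trimws(row[lay$comp_id]),
                      readout = trimws(row[lay$readout]), responses = resp,
                      params = params, annotations = ann)
  }

  qhts_dataset(records, lay$log_conc_m, format_tag = "generic_qhts",
               source = path)
}

#' Validate a qHTS dataset
#'
#' Checks structural and semantic consistency and returns a report rather
#' than raising: errors void the dataset for writing/plotting, warnings
#' flag suspicious but legal content.
#'
#' @param ds a [qhts_dataset()].
#' @return A list of class `qhts_validation` with `ok` (TRUE iff no issue
#'   of severity `"error"`) and `issues`, a data frame with columns
#'   `severity`, `locator`, `message`.
#' @details Errors: a record/grid length mismatch, non-finite grid
#'   concentrations, a `Fit_Output = 1` record with incomplete parameters,
#'   or a fitted record with `Hill_Slope = 0`. Warnings: a non-monotonic
#'   concentration grid, duplicate (Comp_ID, Readout) pairs, and responses
#'   outside \[-200, 200\] % (suspicious scale for normalized activity).
#' @export
validate_qhts <- function(ds) {
  stopifnot(inherits(ds, "qhts_dataset"))
  sev <- character(0); loc <- character(0); msg <- character(0)
  add <- function(s, l, m) {
    sev <<- c(sev, s); loc <<- c(loc, l); msg <<- c(msg, m)
  }

  g <- ds$log_conc_m
  if (any(!is.finite(g)))
    add("error", "grid", "concentration grid contains non-finite values")
  else if (length(g) > 1L) {
    d <- diff(g)
    if (!(all(d > 0) || all(d < 0)))
      add("warning", "grid",
          "concentration grid is not strictly monotonic; columns are plotted as given")
  }

  keys <- character(length(ds$records))
  for (i in seq_along(ds$records)) {
    r <- ds$records[[i]]
    locator <- sprintf("record %d", i)
    if (length(r$responses) != length(g))
      add("error", locator, "response length disagrees with the concentration grid")
    if (r$fit_output == 1L && !has_complete_params(r))
      add("error", locator, "Fit_Output = 1 but curve parameters are incomplete")
    if (r$fit_output == 1L && has_complete_params(r) && r$params$hill_slope == 0)
      add("error", locator, "fitted record has Hill_Slope = 0")
    out <- r$responses[is.finite(r$responses)]
    if (length(out) && any(out < -200 | out > 200))
      add("warning", locator,
          "responses outside [-200, 200] %: check the normalization scale")
    keys[i] <- paste0(r$comp_id, "\r", r$readout)
  }
  dup <- duplicated(keys)
  if (any(dup))
    add("warning", sprintf("record %d", which(dup)[1L]),
        sprintf("%d duplicate (Comp_ID, Readout) pair(s)", sum(dup)))

  issues <- data.frame(severity = sev, locator = loc, message = msg,
                       stringsAsFactors = FALSE)
  structure(list(ok = !any(sev == "error"), issues = issues),
            class = "qhts_validation")
}

#' @export
print.qhts_validation <- function(x, ...) {
  cat(sprintf("<qhts_validation> ok = %s (%d error(s), %d warning(s))\n",
              x$ok, sum(x$issues$severity == "error"),
              sum(x$issues$severity == "warning")))
  for (i in seq_len(nrow(x$issues)))
    cat(sprintf("  [%s] %s: %s\n", x$issues$severity[i], x$issues$locator[i],
                x$issues$message[i]))
  invisible(x)
}

fmt_num <- function(v) {
  out <- character(length(v))
  ok <- is.finite(v)
  out[ok] <- sprintf("%.17g", v[ok])
  out
}

csv_escape <- function(x) {
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Write a dataset in the generic qHTS layout
#'
#' Emits the canonical layout — Format tag row, `Log_Conc_M` tag with the
#' concentration grid above the `Data0..DataN` headers, fixed columns,
#' annotation columns, curve parameters — to `.csv` (RFC 4180 quoting) or
#' `.xlsx`, chosen by the file extension. Missing responses are written as
#' empty cells; numeric values keep full double precision.
#'
#' @param ds a [qhts_dataset()] that passes [validate_qhts()] with no errors.
#' @param path output path ending in `.csv` or `.xlsx`.
#' @return `path`, invisibly.
#' @export
write_generic_qhts <- function(ds, path) {
  rep <- validate_qhts(ds)
  if (!rep$ok) {
    errs <- rep$issues[rep$issues$severity == "error", , drop = FALSE]
    stop("refusing to write an invalid dataset: ",
         paste(sprintf("%s: %s", errs$locator, errs$message), collapse = "; "),
         call. = FALSE)
  }

  ann_names <- character(0)
  for (r in ds$records)
    ann_names <- union(ann_names, names(r$annotations))

  nann <- length(ann_names)
  nconc <- length(ds$log_conc_m)
  nc <- 3L + nann + 4L + nconc
  nr <- 2L + length(ds$records)
  txt <- matrix("", nr, nc)
  isnum <- matrix(FALSE, nr, nc)

  p_cols <- 3L + nann + seq_len(4L)
  d_cols <- 3L + nann + 4L + seq_len(nconc)

  txt[1L, 1:2] <- c("Format", "generic_qhts")
  txt[1L, d_cols[1L] - 1L] <- "Log_Conc_M"
  txt[1L, d_cols] <- fmt_num(ds$log_conc_m)
  isnum[1L, d_cols] <- TRUE
  txt[2L, ] <- c("Fit_Output", "Comp_ID", "Readout", ann_names, PARAM_CANON,
                 paste0("Data", seq_len(nconc) - 1L))

  for (i in seq_along(ds$records)) {
    r <- ds$records[[i]]
    row <- 2L + i
    txt[row, 1L] <- as.character(r$fit_output); isnum[row, 1L] <- TRUE
    txt[row, 2L] <- r$comp_id
    txt[row, 3L] <- r$readout
    if (nann) {
      m <- match(ann_names, names(r$annotations))
      vals <- ifelse(is.na(m), "", r$annotations[m])
      txt[row, 3L + seq_len(nann)] <- vals
    }
    if (!is.null(r$params)) {
      txt[row, p_cols] <- fmt_num(unlist(r$params[c("log_ac50_m", "s0", "s_inf",
                                                    "hill_slope")]))
      isnum[row, p_cols] <- TRUE
    }
    txt[row, d_cols] <- fmt_num(r$responses)
    isnum[row, d_cols] <- is.finite(r$responses)
  }

  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    lines <- apply(txt, 1L, function(r) paste(csv_escape(r), collapse = ","))
    con <- file(path, open = "wb")   # fixed \n eol for reproducible bytes
    writeLines(lines, con, sep = "\n")
    close(con)
  } else if (ext == "xlsx") {
    write_cells_xlsx(txt, isnum, path)
  } else {
    stop("unsupported output extension '.", ext, "' (expected .csv or .xlsx)",
         call. = FALSE)
  }
  invisible(path)
}
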