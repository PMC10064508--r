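# Backend-agnostic 3D waterfall scene. Axis convention: x = compound
# position (layout order), y = log10 molar concentration, z = % response.
# The scene keeps one markers trace and (for fitted records) one line
# trace per record so visibility bookkeeping is exact; renderers are free
# to merge traces of identical style.

#' Styling and visibility options for the waterfall plot
#'
#' Mirrors the interactive app controls: per-readout show/hide, point and
#' line colors, marker size, line weight, aspect ratio, background, and
#' inactive-record visibility.
#'
#' @param hidden_readouts character vector of readout names to hide.
#' @param point_color,line_color optional named character vectors mapping a
#'   group label (readout, curve class, or polarity) to a color; they
#'   override the built-in palette.
#' @param point_size marker size in display units (> 0).
#' @param line_weight curve width in display units (> 0).
#' @param aspect_ratio length-3 positive vector scaling the compound,
#'   concentration and response axes; the default stretches the compound
#'   axis, the natural reading for thousands of rows.
#' @param background_color plot background color.
#' @param show_inactive draw points-only records (gray-dot rows)? Setting
#'   `FALSE` drops them entirely.
#' @param axis_labels length-3 character vector: compound, log
#'   concentration and response axis titles.
#' @param points_per_curve samples per fitted curve polyline (>= 2).
#' @param collapse_by_compound if `TRUE` (default) records sharing a
#'   `Comp_ID` share one compound slot so multi-readout responses overlay;
#'   if `FALSE` every record gets its own slot.
#' @param decimation_threshold record count above which points-only
#'   markers are thinned (every k-th point kept, k scaling with dataset
#'   size) to keep interactive files tractable; fitted records are never
#'   decimated.
#' @return An object of class `qhts_plot_config`.
#' @export
plot_config <- function(hidden_readouts = character(0),
                        point_color = NULL, line_color = NULL,
                        point_size = 3, line_weight = 3,
                        aspect_ratio = c(3, 1, 1),
                        background_color = "white",
                        show_inactive = TRUE,
                        axis_labels = c("Compound", "log10 Concentration (M)",
                                        "Response (%)"),
                        points_per_curve = 64L,
                        collapse_by_compound = TRUE,
                        decimation_threshold = 20000L) {
  stopifnot(point_size > 0, line_weight > 0,
            length(aspect_ratio) == 3L, all(aspect_ratio > 0),
            length(axis_labels) == 3L, points_per_curve >= 2L,
            decimation_threshold >= 1L)
  structure(list(hidden_readouts = as.character(hidden_readouts),
                 point_color = point_color, line_color = line_color,
                 point_size = point_size, line_weight = line_weight,
                 aspect_ratio = as.numeric(aspect_ratio),
                 background_color = background_color,
                 show_inactive = isTRUE(show_inactive),
                 axis_labels = as.character(axis_labels),
                 points_per_curve = as.integer(points_per_curve),
                 collapse_by_compound = isTRUE(collapse_by_compound),
                 decimation_threshold = as.integer(decimation_threshold)),
            class = "qhts_plot_config")
}

#' Build the 3D waterfall scene
#'
#' Turns an ordered dataset into a renderer-independent scene: one markers
#' trace per visible record (missing response cells dropped pointwise) and
#' one line trace per visible fitted record, sampled with [sample_curve()].
#' Records of hidden readouts emit no traces; with `show_inactive = FALSE`
#' points-only records are dropped entirely. Compound positions are
#' consecutive integers `0..K-1` over the distinct plotted compound slots
#' in layout order.
#'
#' @param ds a [qhts_dataset()].
#' @param order integer permutation of record indices (from
#'   [order_records()]); default file order.
#' @param config a [plot_config()].
#' @param groups optional character vector, one label per record (e.g.
#'   curve classes or polarities), used for coloring; default groups by
#'   readout.
#' @return An object of class `qhts_scene` with `traces`, `axes`, `camera`,
#'   `aspect` and `background` fields.
#' @export
build_scene <- function(ds, order = seq_along(ds$records),
                        config = plot_config(), groups = NULL) {
  stopifnot(inherits(ds, "qhts_dataset"), inherits(config, "qhts_plot_config"))
  n <- length(ds$records)
  order <- as.integer(order)
  if (length(order) != n || !identical(sort(order), seq_len(n)))
    stop("build_scene: 'order' is not a permutation of the record indices",
         call. = FALSE)
  if (!is.null(groups) && length(groups) != n)
    stop("build_scene: 'groups' must have one label per record", call. = FALSE)

  part <- partition_records(ds)
  fitted <- logical(n); fitted[part$fitted] <- TRUE

  # visibility, evaluated in layout order
  visible <- integer(0)
  for (i in order) {
    r <- ds$records[[i]]
    if (r$readout %in% config$hidden_readouts) next
    if (!config$show_inactive && !fitted[i]) next
    visible <- c(visible, i)
  }

  # compound slots over plotted records, consecutive 0..K-1 in layout order
  slot_key <- if (config$collapse_by_compound) {
    vapply(ds$records, function(r) r$comp_id, "")
  } else {
    as.character(seq_len(n))
  }
  slot_of <- match(slot_key[visible], unique(slot_key[visible])) - 1L
  names(slot_of) <- NULL

  labels <- if (is.null(groups)) {
    vapply(ds$records, function(r) r$readout, "")
  } else {
    as.character(groups)
  }
  pal <- default_palette(labels[visible])
  pcol <- function(l) {
    if (!is.null(config$point_color) && l %in% names(config$point_color))
      config$point_color[[l]] else pal[[l]]
  }
  lcol <- function(l) {
    if (!is.null(config$line_color) && l %in% names(config$line_color))
      config$line_color[[l]] else pal[[l]]
  }

  stride <- if (n > config$decimation_threshold)
    as.integer(ceiling(n / config$decimation_threshold)) else 1L

  grid <- ds$log_conc_m
  traces <- vector("list", 2L * length(visible))
  nt <- 0L
  zmin <- Inf; zmax <- -Inf
  for (k in seq_along(visible)) {
    i <- visible[k]
    r <- ds$records[[i]]
    lab <- labels[i]
    keep <- which(is.finite(r$responses))
    if (stride > 1L && !fitted[i] && length(keep))
      keep <- keep[seq(1L, length(keep), by = stride)]
    if (length(keep)) {
      z <- r$responses[keep]
      zmin <- min(zmin, z); zmax <- max(zmax, z)
      nt <- nt + 1L
      traces[[nt]] <- list(kind = "markers", record_index = i,
                           comp_id = r$comp_id, readout = r$readout,
                           group = lab, x = slot_of[k], y = grid[keep], z = z,
                           color = pcol(lab), size = config$point_size)
    }
    if (fitted[i]) {
      sc <- sample_curve(r$params, grid, config$points_per_curve,
                         record_index = i)
      zmin <- min(zmin, sc$y); zmax <- max(zmax, sc$y)
      nt <- nt + 1L
      traces[[nt]] <- list(kind = "line", record_index = i,
                           comp_id = r$comp_id, readout = r$readout,
                           group = lab, x = slot_of[k], y = sc$x, z = sc$y,
                           color = lcol(lab), width = config$line_weight)
    }
  }
  traces <- traces[seq_len(nt)]

  nslots <- length(unique(slot_key[visible]))
  if (!is.finite(zmin)) { zmin <- 0; zmax <- 1 }
  structure(list(
    traces = traces,
    axes = list(labels = config$axis_labels,
                ranges = list(x = c(0, max(nslots - 1L, 1L)),
                              y = range(grid), z = c(zmin, zmax))),
    camera = list(eye = list(x = 1.9, y = -1.9, z = 0.9)),
    aspect = config$aspect_ratio,
    background = config$background_color),
    class = "qhts_scene")
}

#' @export
print.qhts_scene <- function(x, ...) {
  kinds <- vapply(x$traces, `[[`, "", "kind")
  cat(sprintf("<qhts_scene> %d traces (%d markers, %d lines), %d compound slots\n",
              length(x$traces), sum(kinds == "markers"), sum(kinds == "line"),
              x$axes$ranges$x[2] + 1))
  invisible(x)
}

#' Serialize a scene to JSON
#'
#' Writes the documented trace/axes/camera structure, so scenes can be
#' inspected and compared without a graphics stack.
#'
#' @param scene a `qhts_scene` from [build_scene()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return The JSON as a character scalar (invisibly when `path` is given).
#' @export
scene_to_json <- function(scene, path = NULL) {
  stopifnot(inherits(scene, "qhts_scene"))
  js <- jsonlite::toJSON(unclass(scene), auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
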