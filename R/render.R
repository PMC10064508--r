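# Rendering a qhts_scene to interactive HTML, a static PNG snapshot, or
# the scene's own JSON. The HTML export embeds the plotly.js runtime in a
# single self-contained file; for performance, scene traces sharing one
# style are merged into a single plotly trace (lines are separated with
# null coordinates), which leaves the rendered picture identical.

# merge per-record traces into one plotly trace per (kind, style, group)
scene_to_plotly_spec <- function(scene) {
  stopifnot(inherits(scene, "qhts_scene"))
  keys <- vapply(scene$traces, function(tr)
    paste(tr$kind, tr$group, tr$color,
          if (tr$kind == "markers") tr$size else tr$width, sep = "\r"), "")
  data <- list()
  for (key in unique(keys)) {
    trs <- scene$traces[keys == key]
    kind <- trs[[1L]]$kind
    if (kind == "markers") {
      x <- unlist(lapply(trs, function(t) rep(t$x, length(t$y))))
      y <- unlist(lapply(trs, function(t) t$y))
      z <- unlist(lapply(trs, function(t) t$z))
      data[[length(data) + 1L]] <- list(
        type = "scatter3d", mode = "markers", name = trs[[1L]]$group,
        x = x, y = y, z = z,
        marker = list(size = trs[[1L]]$size, color = trs[[1L]]$color))
    } else {
      x <- unlist(lapply(trs, function(t) c(rep(t$x, length(t$y)), NA)))
      y <- unlist(lapply(trs, function(t) c(t$y, NA)))
      z <- unlist(lapply(trs, function(t) c(t$z, NA)))
      data[[length(data) + 1L]] <- list(
        type = "scatter3d", mode = "lines", name = trs[[1L]]$group,
        x = x, y = y, z = z, connectgaps = FALSE,
        line = list(width = trs[[1L]]$width, color = trs[[1L]]$color))
    }
  }
  asp <- scene$aspect / max(scene$aspect)
  layout <- list(
    scene = list(
      xaxis = list(title = scene$axes$labels[1L]),
      yaxis = list(title = scene$axes$labels[2L]),
      zaxis = list(title = scene$axes$labels[3L]),
      aspectmode = "manual",
      aspectratio = list(x = asp[1L], y = asp[2L], z = asp[3L]),
      camera = scene$camera),
    paper_bgcolor = scene$background,
    margin = list(l = 0, r = 0, t = 30, b = 0),
    showlegend = TRUE)
  list(data = data, layout = layout)
}

plotlyjs_path <- function() {
  p <- system.file("htmlwidgets", "lib", "plotlyjs", "plotly-latest.min.js",
                   package = "plotly")
  if (!nzchar(p) || !file.exists(p))
    stop("HTML export needs the 'plotly' package (for its bundled plotly.js); ",
         "it does not appear to be installed", call. = FALSE)
  p
}

render_html <- function(scene, path) {
  spec <- scene_to_plotly_spec(scene)
  js <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = 7, na = "null",
                         null = "null")
  lib <- readChar(plotlyjs_path(), file.size(plotlyjs_path()), useBytes = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>qHTS waterfall</title>",
    "<style>html,body,#waterfall{margin:0;height:100%;width:100%;}</style>",
    "<script>", lib, "</script>",
    "</head><body>",
    "<div id=\"waterfall\"></div>",
    "<script>",
    paste0("var spec = ", js, ";"),
    "Plotly.newPlot(\"waterfall\", spec.data, spec.layout, {responsive: true});",
    "</script>",
    "</body></html>"), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

render_png <- function(scene, path, width = 1600, height = 1200) {
  rng <- scene$axes$ranges
  span <- function(r) if (diff(r) > 0) diff(r) else 1
  asp <- scene$aspect / max(scene$aspect)
  nx <- function(v) (v - rng$x[1L]) / span(rng$x) * asp[1L]
  ny <- function(v) (v - rng$y[1L]) / span(rng$y) * asp[2L]
  nz <- function(v) (v - rng$z[1L]) / span(rng$z) * asp[3L]

  grDevices::png(path, width = width, height = height, res = 150,
                 type = "cairo")
  on.exit(grDevices::dev.off())
  op <- graphics::par(bg = scene$background, mar = c(1, 1, 1, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  pmat <- graphics::persp(x = c(0, asp[1L]), y = c(0, asp[2L]),
                          z = matrix(NA_real_, 2, 2), zlim = c(0, asp[3L]),
                          theta = -50, phi = 20, expand = 1, scale = FALSE,
                          border = NA, box = TRUE, axes = TRUE,
                          xlab = scene$axes$labels[1L],
                          ylab = scene$axes$labels[2L],
                          zlab = scene$axes$labels[3L])
  # painter order: far compound slots first so near rows overdraw them
  ord <- order(vapply(scene$traces, `[[`, 0, "x"), decreasing = TRUE)
  for (tr in scene$traces[ord]) {
    pt <- grDevices::trans3d(nx(rep(tr$x, length(tr$y))), ny(tr$y), nz(tr$z),
                             pmat)
    if (tr$kind == "markers") {
      graphics::points(pt, pch = 16, col = tr$color,
                       cex = tr$size / 6)
    } else {
      graphics::lines(pt, col = tr$color, lwd = tr$width / 2)
    }
  }
  invisible(path)
}

#' Render a waterfall scene to a file
#'
#' `"html"` writes a self-contained interactive page (rotate, zoom, pan;
#' the in-page toolbar can capture a PNG snapshot). `"png"` writes a
#' static raster projection of the same scene (default 1600 x 1200).
#' `"json"` writes the scene's documented JSON structure. When `format`
#' is omitted it is inferred from the file extension.
#'
#' @param scene a `qhts_scene` from [build_scene()].
#' @param path output file path.
#' @param format `"html"`, `"png"`, or `"json"`.
#' @param width,height raster size in pixels (png only).
#' @return `path`, invisibly.
#' @export
render_scene <- function(scene, path, format = NULL, width = 1600,
                         height = 1200) {
  stopifnot(inherits(scene, "qhts_scene"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("html", "png", "json"))
    stop("render_scene: unsupported format '", format,
         "' (expected html, png or json)", call. = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("render_scene: cannot write to '", path, "': directory does not exist",
         call. = FALSE)
  switch(format,
         html = render_html(scene, path),
         png = render_png(scene, path, width, height),
         json = { scene_to_json(scene, path); invisible(path) })
}
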