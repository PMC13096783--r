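# render: turn layout geometry into a static SVG or a self-contained
# interactive HTML document. Both renderers consume the same geometry, so
# element counts always agree; rendering is fully deterministic (fixed
# coordinate formatting, no randomness, no timestamps in the output).

.THEMES <- list(
  light = list(bg = "#FFFFFF", fg = "#222222", axis = "#555555",
               grid = "#DDDDDD", background_line = "#9C9C9C"),
  dark  = list(bg = "#1B1B1B", fg = "#EEEEEE", axis = "#AAAAAA",
               grid = "#444444", background_line = "#777777"))

#' Rendering options
#'
#' @param width,height Canvas size in pixels.
#' @param theme `"light"` or `"dark"`.
#' @param tooltip_columns Columns whose values appear in HTML tooltips
#'   (must exist in the source table passed to [render_html()]).
#' @param background_opacity Stroke opacity of non-highlighted PCP lines.
#' @param highlight_colour Stroke colour of highlighted PCP lines.
#' @return A `render_options` list.
#' @export
render_options <- function(width = 900, height = 600,
                           theme = c("light", "dark"),
                           tooltip_columns = character(),
                           background_opacity = 0.15,
                           highlight_colour = "#D62728") {
  theme <- match.arg(theme)
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop_config("render dimensions must be positive")
  if (background_opacity < 0 || background_opacity > 1)
    stop_config("background_opacity must lie in [0,1]")
  structure(list(width = width, height = height, theme = theme,
                 tooltip_columns = as.character(tooltip_columns),
                 background_opacity = background_opacity,
                 highlight_colour = highlight_colour),
            class = "render_options")
}

.fmt <- function(x) sprintf("%.2f", x)

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.attr_str <- function(attrs) {
  if (length(attrs) == 0L) return("")
  paste0(" ", paste(sprintf('%s="%s"', names(attrs),
                            vapply(attrs, .xml_escape, character(1))),
                    collapse = " "))
}

# --- PCP body -------------------------------------------------------------

.svg_body_pcp <- function(layout, options, tips = NULL) {
  th <- .THEMES[[options$theme]]
  w <- options$width
  h <- options$height
  mar <- c(top = 30, right = 40, bottom = 40, left = 40)
  k <- nrow(layout$axes)
  if (k == 0L) stop_contract("render: layout has zero axes")
  xpos <- if (k == 1L) (w - mar["left"] - mar["right"]) / 2 + mar["left"]
          else mar["left"] + (seq_len(k) - 1L) / (k - 1L) *
               (w - mar["left"] - mar["right"])
  y_of <- function(v) mar["top"] + (1 - v) * (h - mar["top"] - mar["bottom"])

  out <- character()
  for (i in seq_len(k))
    out <- c(out,
      sprintf('<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
              .fmt(xpos[i]), .fmt(y_of(1)), .fmt(xpos[i]), .fmt(y_of(0)),
              th$axis),
      sprintf('<text class="axis-label" x="%s" y="%s" text-anchor="middle" font-size="12" fill="%s">%s</text>',
              .fmt(xpos[i]), .fmt(h - mar["bottom"] / 3), th$fg,
              .xml_escape(layout$axes$column[i])))

  n <- nrow(layout$polylines)
  if (n == 0L)
    log_msg("warn", "all rows were dropped; rendering axes with no polylines")
  # background lines first, foreground after: document order = z-order
  draw_order <- c(which(!layout$foreground), which(layout$foreground))
  for (i in draw_order) {
    v <- layout$polylines[i, ]
    d <- paste0("M ", paste(sprintf("%s,%s", .fmt(xpos), .fmt(y_of(v))),
                            collapse = " L "))
    fg <- layout$foreground[i]
    stroke <- if (!is.null(layout$highlight_level) && fg)
      options$highlight_colour
    else if (!is.null(layout$highlight_level)) th$background_line
    else .BAR_FILL
    opacity <- if (!is.null(layout$highlight_level) && !fg)
      options$background_opacity else 0.8
    extra <- if (!is.null(tips))
      c("data-row" = as.character(layout$row_index[i]),
        "data-tip" = tips[i]) else NULL
    out <- c(out, sprintf(
      '<path class="pcp-line" d="%s" fill="none" stroke="%s" stroke-opacity="%s"%s/>',
      d, stroke, .fmt(opacity), .attr_str(extra)))
  }
  out
}

# --- tiled body -----------------------------------------------------------

.svg_body_tiled <- function(layout, options, tips = NULL) {
  th <- .THEMES[[options$theme]]
  w <- options$width
  h <- options$height
  mar <- c(top = 20, right = 20, bottom = 20, left = 110)
  n_tracks <- length(layout$tracks)
  if (n_tracks == 0L) stop_contract("render: layout has zero tracks")
  n <- layout$n_rows
  plot_w <- w - mar["left"] - mar["right"]
  plot_h <- h - mar["top"] - mar["bottom"]
  track_h <- plot_h / n_tracks
  cell_w <- if (n > 0L) plot_w / n else plot_w
  glyph_key <- paste(layout$glyphs$row, layout$glyphs$track)

  out <- character()
  for (t in seq_len(n_tracks)) {
    spec <- layout$tracks[[t]]
    y0 <- mar["top"] + (t - 1L) * track_h
    out <- c(out, sprintf(
      '<text class="track-label" x="%s" y="%s" text-anchor="end" font-size="11" fill="%s">%s</text>',
      .fmt(mar["left"] - 6), .fmt(y0 + track_h / 2 + 4), th$fg,
      .xml_escape(spec$column)))
    cellv <- layout$cells[[spec$column]]
    for (s in seq_len(n)) {
      row <- layout$sample_order[s]       # original row drawn at position s
      x0 <- mar["left"] + (s - 1L) * cell_w
      val <- cellv[row]
      missing_here <- is.na(val)
      extra <- if (!is.null(tips))
        c("data-row" = as.character(row), "data-tip" = tips[row]) else NULL
      if (missing_here) {
        out <- c(out, sprintf(
          '<rect class="cell cell-missing" x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          .fmt(x0), .fmt(y0 + 1), .fmt(cell_w), .fmt(track_h - 2),
          .MISSING_FILL, .attr_str(extra)))
      } else if (spec$kind == "bar") {
        bar_h <- val * (track_h - 2)
        out <- c(out, sprintf(
          '<rect class="cell cell-bar" x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          .fmt(x0), .fmt(y0 + 1 + (track_h - 2) - bar_h), .fmt(cell_w),
          .fmt(bar_h), spec$palette[[1L]], .attr_str(extra)))
      } else {
        fill <- unname(spec$palette[val])
        if (length(fill) != 1L || is.na(fill)) fill <- .MISSING_FILL
        out <- c(out, sprintf(
          '<rect class="cell cell-tile" x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          .fmt(x0), .fmt(y0 + 1), .fmt(cell_w), .fmt(track_h - 2), fill,
          .attr_str(extra)))
      }
      if (paste(row, spec$column) %in% glyph_key) {
        out <- c(out, sprintf(
          '<text class="glyph" x="%s" y="%s" text-anchor="middle" font-size="%s" font-weight="bold" fill="%s">!</text>',
          .fmt(x0 + cell_w / 2), .fmt(y0 + track_h / 2 + 4),
          .fmt(min(track_h * 0.6, 14)), th$fg))
      }
    }
  }
  out
}

.svg_document <- function(body, options) {
  th <- .THEMES[[options$theme]]
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">\n',
            .fmt(options$width), .fmt(options$height),
            .fmt(options$width), .fmt(options$height)),
    sprintf('<rect class="canvas" x="0" y="0" width="%s" height="%s" fill="%s"/>\n',
            .fmt(options$width), .fmt(options$height), th$bg),
    paste(body, collapse = "\n"),
    "\n</svg>\n")
}

.render_body <- function(layout, options, tips = NULL) {
  if (inherits(layout, "pcp_layout")) .svg_body_pcp(layout, options, tips)
  else if (inherits(layout, "tiled_layout")) .svg_body_tiled(layout, options, tips)
  else stop_contract("render: expected a pcp_layout or tiled_layout")
}

#' Render a layout as an SVG document
#'
#' One `<path class="pcp-line">` per polyline for PCP layouts; one
#' `<rect class="cell ...">` per cell plus one `<text class="glyph">`
#' per missing cell for tiled layouts. Element counts are exactly
#' determined by the layout, and identical inputs produce byte-identical
#' output.
#'
#' @param layout A `pcp_layout` or `tiled_layout`.
#' @param options A [render_options()] object.
#' @return SVG document text (a single string).
#' @export
render_svg <- function(layout, options = render_options()) {
  .svg_document(.render_body(layout, options), options)
}

.tooltip_strings <- function(layout, options, source) {
  n <- source$n_rows
  cols <- options$tooltip_columns
  missing_cols <- setdiff(cols, .table_cols(source))
  if (length(missing_cols) > 0L)
    stop_config("tooltip column(s) not in source table: %s",
                paste(missing_cols, collapse = ", "))
  vapply(seq_len(n), function(i) {
    base <- sprintf("row %d", i)
    if (length(cols) == 0L) return(base)
    parts <- vapply(cols, function(cl) {
      v <- source$values[[cl]][i]
      sprintf("%s: %s", cl, if (is.na(v)) "(missing)" else as.character(v))
    }, character(1))
    paste(c(base, parts), collapse = " | ")
  }, character(1))
}

#' Render a layout as a self-contained interactive HTML document
#'
#' Embeds the same SVG geometry as [render_svg()] (element counts always
#' agree) plus a small dependency-free script: hovering a line or cell
#' shows a tooltip with the sample's `tooltip_columns` values, or just the
#' row index when no tooltip columns are configured. No network fetches;
#' the data never leaves the file.
#'
#' @param layout A `pcp_layout` or `tiled_layout`.
#' @param options A [render_options()] object.
#' @param source The `typed_table` the layout was built from (tooltip
#'   values are read from it).
#' @return HTML document text (a single string).
#' @export
render_html <- function(layout, options = render_options(), source) {
  stopifnot(inherits(source, "typed_table"))
  tips_by_row <- .tooltip_strings(layout, options, source)
  tips <- if (inherits(layout, "pcp_layout"))
    tips_by_row[layout$row_index] else tips_by_row
  svg <- .svg_document(.render_body(layout, options, tips), options)
  svg <- sub('^<\\?xml[^>]*\\?>\n', "", svg)
  th <- .THEMES[[options$theme]]
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>pcptiles</title>\n<style>\n",
    sprintf("body{margin:0;background:%s;color:%s;font-family:sans-serif}\n",
            th$bg, th$fg),
    "#tip{position:fixed;display:none;pointer-events:none;background:#000c;",
    "color:#fff;padding:4px 8px;border-radius:4px;font-size:12px;z-index:10}\n",
    ".pcp-line:hover{stroke-width:2.5}\n.cell:hover{stroke:#000;stroke-width:1}\n",
    "</style>\n</head>\n<body>\n<div id=\"tip\"></div>\n",
    svg,
    "<script>\n",
    "var tip=document.getElementById('tip');\n",
    "document.querySelectorAll('[data-tip]').forEach(function(el){\n",
    " el.addEventListener('mousemove',function(ev){\n",
    "  tip.style.display='block';tip.style.left=(ev.clientX+12)+'px';\n",
    "  tip.style.top=(ev.clientY+12)+'px';tip.textContent=el.getAttribute('data-tip');});\n",
    " el.addEventListener('mouseleave',function(){tip.style.display='none';});\n",
    "});\n</script>\n</body>\n</html>\n")
}
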