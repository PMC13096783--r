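# tile_engine: tiled one-dimensional stacked graphics.
#
# One vertically aligned track per feature (colour tiles for categorical /
# boolean, bars for numeric), a single sample order shared by all tracks so
# cross-feature patterns read as vertical alignment, and an explicit "!"
# glyph on every missing cell.

# Colour-blind-safe qualitative cycle (Okabe-Ito extended to 12); levels
# beyond 12 recycle the cycle.
.QUALITATIVE_CYCLE <- c(
  "#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2", "#D55E00",
  "#CC79A7", "#999999", "#882255", "#44AA99", "#DDCC77", "#332288")
.MISSING_FILL <- "#EEEEEE"  # neutral background tile under the "!" glyph
.BAR_FILL <- "#4477AA"

#' Select a track type for a column
#'
#' Numeric columns become bar tracks; categorical and boolean columns
#' become tile tracks. Identifier/tooltip columns are not plottable.
#'
#' @param spec A [column_spec()].
#' @return `"bar"` or `"tile"`.
#' @export
select_track_type <- function(spec) {
  stopifnot(inherits(spec, "column_spec"))
  switch(spec$role,
    numeric = "bar",
    categorical = "tile",
    boolean = "tile",
    stop_contract("column '%s' (role '%s') is not plottable as a track",
                  spec$name, spec$role))
}

# Parse sort keys given either as "col", "col:asc", "col:desc" strings or
# as a list of c(column, direction) pairs.
.parse_sort_keys <- function(sort_keys) {
  if (is.null(sort_keys) || length(sort_keys) == 0L)
    return(list())
  if (is.character(sort_keys)) sort_keys <- as.list(sort_keys)
  lapply(sort_keys, function(key) {
    if (is.character(key) && length(key) == 1L) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
      col <- parts[1L]
      dir <- if (length(parts) > 1L) parts[2L] else "asc"
    } else {
      col <- key[[1L]]
      dir <- if (length(key) > 1L) key[[2L]] else "asc"
    }
    if (!dir %in% c("asc", "desc"))
      stop_config("sort direction must be 'asc' or 'desc' (got '%s' for '%s')",
                  dir, col)
    list(column = col, direction = dir)
  })
}

#' Order samples by multiple sort keys
#'
#' Stable lexicographic multi-key sort: categorical/boolean keys sort by
#' level order, numeric keys by value, identifier/tooltip keys
#' lexicographically; missing values go last within each key regardless of
#' direction. An empty key list returns the identity permutation.
#'
#' @param table A `typed_table`.
#' @param sort_keys Character vector of `"column"` / `"column:desc"` keys,
#'   or a list of `(column, direction)` pairs.
#' @return Integer permutation of `1:n_rows`.
#' @export
order_samples <- function(table, sort_keys = NULL) {
  stopifnot(inherits(table, "typed_table"))
  keys <- .parse_sort_keys(sort_keys)
  n <- table$n_rows
  if (length(keys) == 0L) return(seq_len(n))
  args <- list()
  decreasing <- logical(0)
  for (key in keys) {
    cs <- .col_spec(table, key$column)  # errors on unknown column
    v <- table$values[[key$column]]
    kv <- switch(cs$role,
      numeric = v,
      categorical = as.numeric(match(v, cs$levels)),
      boolean = as.numeric(match(as.character(v), cs$levels)),
      xtfrm(v))
    miss <- table$missing_mask[, key$column]
    # missing-last is encoded as a leading ascending is-missing key
    args <- c(args, list(miss), list(kv))
    decreasing <- c(decreasing, FALSE, key$direction == "desc")
  }
  do.call(order, c(args, list(decreasing = decreasing, method = "radix",
                              na.last = TRUE)))
}

#' Build tiled stacked-plot geometry
#'
#' Applies [order_samples()], builds one track per plottable column (bars
#' for numeric, tiles for categorical/boolean), minmax-normalises bar cells
#' per track (a constant track maps to 0.5), attaches a palette per tile
#' track, and emits one glyph mark per missing cell. Designed for small
#' datasets; at `max_rows_warn` rows and above a warning string is recorded
#' (and surfaced by the CLI) but the layout is still produced.
#'
#' @param table A `typed_table`.
#' @param tracks Columns to plot; default all plottable columns in table
#'   order (identifier/tooltip columns are skipped).
#' @param sort_keys Passed to [order_samples()].
#' @param palettes Optional named list: column -> named character vector of
#'   level colours, overriding the default qualitative cycle.
#' @param max_rows_warn Row count at which the size-guidance warning is
#'   emitted (default 1000).
#' @return A `tiled_layout`: `sample_order` permutation, `tracks` (specs),
#'   `cells` (per-track vectors indexed by *original* row; renderers apply
#'   `sample_order`), `glyphs` (row/track marks), and `warnings`.
#' @export
build_tiled_layout <- function(table, tracks = NULL, sort_keys = NULL,
                               palettes = NULL, max_rows_warn = 1000L) {
  stopifnot(inherits(table, "typed_table"))
  nm <- .table_cols(table)
  roles <- vapply(table$columns, `[[`, character(1), "role")
  if (is.null(tracks)) {
    tracks <- nm[roles %in% c("numeric", "categorical", "boolean")]
  } else {
    for (tr in tracks) .col_spec(table, tr)
  }
  if (length(tracks) == 0L)
    stop_input("no plottable columns (need at least one numeric, categorical or boolean track)")

  sample_order <- order_samples(table, sort_keys)
  warnings <- character()
  if (table$n_rows >= max_rows_warn)
    warnings <- c(warnings, sprintf(
      "dataset has %d rows (>= %d): tiled one-dimensional graphics are designed for small datasets (n < 1000); consider the parallel coordinate view",
      table$n_rows, max_rows_warn))

  track_specs <- list()
  cells <- list()
  glyph_rows <- integer()
  glyph_tracks <- character()
  for (tr in tracks) {
    cs <- .col_spec(table, tr)
    kind <- select_track_type(cs)
    v <- table$values[[tr]]
    if (kind == "bar") {
      cells[[tr]] <- normalise_axis(v, "minmax")
      obs <- v[!is.na(v)]
      track_specs[[tr]] <- list(
        column = tr, kind = "bar", palette = .BAR_FILL,
        height_scale = if (length(obs))
          c(min = min(obs), max = max(obs)) else c(min = NA_real_, max = NA_real_))
    } else {
      lev <- cs$levels
      pal <- if (!is.null(palettes[[tr]])) palettes[[tr]]
             else stats::setNames(
               rep_len(.QUALITATIVE_CYCLE, max(length(lev), 1L))[seq_along(lev)],
               lev)
      cells[[tr]] <- as.character(v)
      track_specs[[tr]] <- list(column = tr, kind = "tile", palette = pal,
                                height_scale = NULL)
    }
    miss <- which(table$missing_mask[, tr])
    glyph_rows <- c(glyph_rows, miss)
    glyph_tracks <- c(glyph_tracks, rep(tr, length(miss)))
  }

  structure(list(
    sample_order = sample_order,
    tracks = track_specs,
    cells = cells,
    glyphs = data.frame(row = glyph_rows, track = glyph_tracks,
                        glyph = rep("!", length(glyph_rows)),
                        stringsAsFactors = FALSE),
    warnings = warnings,
    n_rows = table$n_rows
  ), class = "tiled_layout")
}

#' Serialise a tiled layout to JSON
#'
#' Documented shape: `sample_order`, `tracks` (column/kind/palette),
#' `cells` keyed by track, `glyphs` (row/track records), `warnings`.
#'
#' @param layout A `tiled_layout`.
#' @return A JSON string.
#' @export
tiled_layout_json <- function(layout) {
  stopifnot(inherits(layout, "tiled_layout"))
  jsonlite::toJSON(list(
    sample_order = layout$sample_order,
    tracks = lapply(unname(layout$tracks), function(t)
      list(column = t$column, kind = t$kind, palette = as.list(t$palette))),
    cells = layout$cells,
    glyphs = layout$glyphs,
    warnings = layout$warnings,
    n_rows = layout$n_rows
  ), auto_unbox = TRUE, digits = NA, null = "null")
}
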