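# pcp_engine: parallel-coordinate-plot geometry.
#
# Axes are normalised to a shared [0,1] vertical scale, ordered either by
# polyline crossing minimisation or by mutual information with a categorical
# feature, and each retained sample becomes a polyline with one vertex per
# axis. No randomness anywhere in this module; all ties resolve by
# documented deterministic rules.

.NORMALISATIONS <- c("minmax", "rank", "zscore")

#' Normalise one numeric axis to the unit interval
#'
#' Methods: `minmax` maps the observed minimum to 0 and maximum to 1
#' linearly; `rank` maps ascending ranks (average ranks for ties) to
#' equally spaced points in `[0,1]`, making the axis robust to monotone
#' transforms; `zscore` standardises, clips at +/-3 standard deviations,
#' and rescales the clipped range to `[0,1]`. A constant column maps every
#' observed value to 0.5 under all methods. Missing stays missing.
#'
#' @param values Numeric vector, `NA` allowed.
#' @param method One of `"minmax"`, `"rank"`, `"zscore"`.
#' @return Numeric vector of the same length with all observed entries in
#'   `[0,1]`.
#' @export
normalise_axis <- function(values, method = c("minmax", "rank", "zscore")) {
  method <- match.arg(method)
  if (!is.numeric(values))
    stop_contract("normalise_axis: input must be numeric")
  obs <- !is.na(values)
  x <- values[obs]
  out <- rep(NA_real_, length(values))
  if (length(x) == 0L) return(out)
  if (length(unique(x)) == 1L) {  # constant-column rule, all methods
    out[obs] <- 0.5
    return(out)
  }
  out[obs] <- switch(method,
    minmax = (x - min(x)) / (max(x) - min(x)),
    rank = (rank(x, ties.method = "average") - 1) / (length(x) - 1),
    zscore = {
      z <- (x - mean(x)) / stats::sd(x)
      (pmin(pmax(z, -3), 3) + 3) / 6
    })
  out
}

# Strict inversion count of a numeric sequence (pairs i<j with x_i > x_j),
# bottom-up merge counting: O(n log n) up to the vectorised merges.
.count_inversions <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  total <- 0
  blocks <- lapply(seq_len(n), function(i) x[i])
  while (length(blocks) > 1L) {
    nxt <- vector("list", ceiling(length(blocks) / 2))
    for (k in seq_along(nxt)) {
      i <- 2L * k - 1L
      if (i + 1L <= length(blocks)) {
        L <- blocks[[i]]
        R <- blocks[[i + 1L]]
        # findInterval(r, L) = #(L <= r); strictly-greater count per r
        total <- total + sum(length(L) - findInterval(R, L))
        nxt[[k]] <- sort(c(L, R))
      } else {
        nxt[[k]] <- blocks[[i]]
      }
    }
    blocks <- nxt
  }
  total
}

#' Count polyline crossings between two adjacent axes
#'
#' The number of sample pairs whose vertical order reverses between axis
#' `a` and axis `b`, i.e. the inversion count
#' `|{(i,j): i<j, (a_i-a_j)(b_i-b_j) < 0}|`. Ties contribute nothing.
#' Pairs with a missing value on either axis are excluded before counting.
#' Computed in O(n log n) by merge counting but contractually identical to
#' the quadratic pairwise definition.
#'
#' @param a,b Numeric vectors of equal length (typically normalised axis
#'   heights).
#' @return Non-negative crossing count.
#' @export
count_crossings <- function(a, b) {
  if (length(a) != length(b))
    stop_contract("count_crossings: length mismatch (%d vs %d)",
                  length(a), length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 2L) return(0)
  # Sort by a ascending, ties by b ascending: pairs tied on a then appear in
  # non-decreasing b order and contribute no strict inversion, matching the
  # product-rule definition. Ties on b are not counted by the strict count.
  o <- order(a, b)
  .count_inversions(b[o])
}

#' Pairwise crossing-count matrix over candidate axes
#'
#' For every pair of numeric columns, normalises both and counts crossings
#' over their pairwise-complete rows (listwise deletion across all axes is
#' deliberately not used, so the ordering exploits maximal information).
#'
#' @param table A `typed_table`.
#' @param axes Column names; default all numeric columns.
#' @param normalisation Axis normalisation method (crossing counts are
#'   invariant under any monotone normalisation; kept for symmetry with the
#'   layout builder).
#' @return A `crossing_matrix`: list with `axes` and the symmetric integer
#'   `counts` matrix (zero diagonal).
#' @export
crossing_matrix <- function(table, axes = NULL, normalisation = "minmax") {
  stopifnot(inherits(table, "typed_table"))
  nm <- .table_cols(table)
  roles <- vapply(table$columns, `[[`, character(1), "role")
  if (is.null(axes)) axes <- nm[roles == "numeric"]
  for (ax in axes) {
    if (.col_spec(table, ax)$role != "numeric")
      stop_contract("crossing_matrix: column '%s' is not numeric", ax)
  }
  k <- length(axes)
  norm <- lapply(axes, function(ax)
    normalise_axis(table$values[[ax]], normalisation))
  counts <- matrix(0, k, k, dimnames = list(axes, axes))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        c_ij <- count_crossings(norm[[i]], norm[[j]])
        counts[i, j] <- c_ij
        counts[j, i] <- c_ij
      }
    }
  }
  structure(list(axes = axes, counts = counts), class = "crossing_matrix")
}

.validate_crossing_matrix <- function(cm) {
  if (!inherits(cm, "crossing_matrix"))
    stop_contract("expected a crossing_matrix")
  m <- cm$counts
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      nrow(m) != length(cm$axes) ||
      any(m < 0) || any(diag(m) != 0) || !isTRUE(all.equal(m, t(m))))
    stop_contract("invalid crossing_matrix: counts must be a symmetric non-negative matrix with zero diagonal")
  invisible(cm)
}

.path_cost <- function(m, ord) {
  k <- length(ord)
  if (k < 2L) return(0)
  sum(m[cbind(ord[-k], ord[-1L])])
}

# All permutations of 1..k, rows in lexicographic order.
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[c(sub)], nrow(sub)))
  }))
}

# 2-opt for an open path: reverse segments while any reversal lowers the
# adjacent-pair cost; first-improvement scan, deterministic.
.two_opt <- function(m, ord) {
  k <- length(ord)
  repeat {
    improved <- FALSE
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        if (.path_cost(m, cand) < .path_cost(m, ord)) {
          ord <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) return(ord)
  }
}

#' Order axes to minimise adjacent crossings
#'
#' Finds an ordering of the axes minimising the sum of crossing counts over
#' adjacent pairs (an open-path objective). Exact by exhaustive enumeration
#' for up to 8 axes; above that, greedy nearest-neighbour from every start
#' followed by 2-opt, always at least as good as the input order.
#' Tie-breaks are deterministic: among equal-cost orderings the
#' lexicographically smallest by original axis position is returned, and of
#' an ordering and its (equal-cost) reversal, the one starting at the
#' smaller original position.
#'
#' @param cm A `crossing_matrix`.
#' @return Character vector of axis names in plotting order.
#' @export
order_axes_min_crossings <- function(cm) {
  .validate_crossing_matrix(cm)
  m <- cm$counts
  k <- length(cm$axes)
  if (k == 1L) return(cm$axes)
  if (k <= 8L) {
    perms <- .permutations(k)
    best <- perms[1L, ]
    best_cost <- .path_cost(m, best)
    for (r in seq_len(nrow(perms))[-1L]) {
      cost <- .path_cost(m, perms[r, ])
      if (cost < best_cost) {  # strict: first (lex-smallest) minimum kept
        best <- perms[r, ]
        best_cost <- cost
      }
    }
    return(cm$axes[best])
  }
  # Heuristic regime: best greedy nearest-neighbour start, then 2-opt;
  # the identity (input) order competes so the result is never worse.
  best <- seq_len(k)
  best_cost <- .path_cost(m, best)
  for (start in seq_len(k)) {
    ord <- start
    left <- setdiff(seq_len(k), start)
    while (length(left) > 0L) {
      nxt <- left[which.min(m[ord[length(ord)], left])]
      ord <- c(ord, nxt)
      left <- setdiff(left, nxt)
    }
    if (.path_cost(m, ord) < best_cost) {
      best <- ord
      best_cost <- .path_cost(m, ord)
    }
  }
  best <- .two_opt(m, best)
  if (best[1L] > best[length(best)]) best <- rev(best)
  cm$axes[best]
}

#' Mutual information between a numeric feature and categorical labels
#'
#' Discretises the feature into `n_bins` equal-frequency bins (duplicate
#' quantile edges are merged, so the effective bin count may be lower),
#' builds the bin-by-label contingency table, and returns the plug-in
#' mutual information in bits:
#' `sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`.
#' Rows missing in either input are excluded pairwise. Degenerate inputs
#' (fewer than 2 usable rows, or a single label level) return 0 with a
#' warning.
#'
#' @param feature Numeric vector (`NA` allowed).
#' @param labels Categorical vector of the same length.
#' @param n_bins Number of equal-frequency bins.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(feature, labels, n_bins = 4L) {
  if (length(feature) != length(labels))
    stop_contract("mutual_information: length mismatch")
  if (!is.numeric(feature))
    stop_contract("mutual_information: 'feature' must be numeric")
  if (!is.numeric(n_bins) || n_bins < 1)
    stop_contract("mutual_information: 'n_bins' must be positive")
  keep <- !is.na(feature) & !is.na(labels)
  x <- feature[keep]
  y <- as.character(labels[keep])
  n <- length(x)
  if (n < 2L || length(unique(y)) < 2L) {
    warning("mutual_information: degenerate input (<2 usable rows or a single label level); returning 0",
            call. = FALSE)
    return(0)
  }
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) return(0)  # constant feature: zero-entropy marginal
  bins <- cut(x, breaks = edges, include.lowest = TRUE)
  tab <- table(bins, y)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  pos <- p > 0
  expected <- outer(px, py)
  max(0, sum(p[pos] * log2(p[pos] / expected[pos])))
}

#' Rank axes by mutual information with a class column
#'
#' @param table A `typed_table`.
#' @param axes Numeric column names; default all numeric columns.
#' @param class_column A categorical or boolean column.
#' @param n_bins Bins for [mutual_information()]; default
#'   `min(10, ceiling(sqrt(n_rows)))`.
#' @return Data.frame with columns `column` and `mi_bits`, sorted by MI
#'   descending; ties broken by original column order.
#' @export
order_axes_by_mi <- function(table, axes = NULL, class_column, n_bins = NULL) {
  stopifnot(inherits(table, "typed_table"))
  cls <- .col_spec(table, class_column)
  if (!cls$role %in% c("categorical", "boolean"))
    stop_contract("order_axes_by_mi: class column '%s' must be categorical or boolean (got '%s')",
                  class_column, cls$role)
  nm <- .table_cols(table)
  roles <- vapply(table$columns, `[[`, character(1), "role")
  if (is.null(axes)) axes <- setdiff(nm[roles == "numeric"], class_column)
  for (ax in axes) {
    if (.col_spec(table, ax)$role != "numeric")
      stop_contract("order_axes_by_mi: axis '%s' is not numeric", ax)
  }
  if (is.null(n_bins)) n_bins <- min(10L, ceiling(sqrt(max(table$n_rows, 1L))))
  labels <- as.character(table$values[[class_column]])
  mi <- vapply(axes, function(ax)
    mutual_information(table$values[[ax]], labels, n_bins = n_bins),
    numeric(1))
  ord <- order(-mi)  # stable: ties keep original axis order
  data.frame(column = axes[ord], mi_bits = unname(mi[ord]),
             stringsAsFactors = FALSE)
}

#' Build parallel-coordinate-plot geometry
#'
#' Normalises the chosen axes, orders them by the requested strategy, and
#' emits one polyline per retained sample. Rows with any missing value on a
#' plotted axis are excluded and listed in `dropped_rows` - never silently
#' dropped; the tiled layout, not the PCP, is this package's missingness
#' instrument. With `missing_policy = "drop_and_report"` a per-axis missing
#' count summary is additionally logged.
#'
#' @param table A `typed_table`.
#' @param axes Numeric columns to plot; default all numeric columns
#'   (at least 2 required).
#' @param colour_feature Optional categorical/boolean column used for
#'   colouring and (for `ordering = "mi"`) as the MI class.
#' @param highlight_level Optional single level of `colour_feature`;
#'   matching samples are foreground-styled, the rest become background
#'   context.
#' @param ordering `"given"` (axes as supplied), `"crossings"` (crossing
#'   minimisation) or `"mi"` (mutual information, requires
#'   `colour_feature`).
#' @param normalisation Axis normalisation method.
#' @param n_bins Bins for MI ordering.
#' @param missing_policy `"drop_rows"` or `"drop_and_report"`.
#' @return A `pcp_layout`: ordered axes, a polyline matrix (one row per
#'   retained sample, one column per axis, heights in `[0,1]`), colour and
#'   highlight metadata, and `dropped_rows`.
#' @export
build_pcp_layout <- function(table, axes = NULL, colour_feature = NULL,
                             highlight_level = NULL,
                             ordering = c("given", "crossings", "mi"),
                             normalisation = "minmax", n_bins = NULL,
                             missing_policy = c("drop_rows", "drop_and_report")) {
  stopifnot(inherits(table, "typed_table"))
  ordering <- match.arg(ordering)
  missing_policy <- match.arg(missing_policy)
  normalisation <- match.arg(normalisation, .NORMALISATIONS)
  nm <- .table_cols(table)
  roles <- vapply(table$columns, `[[`, character(1), "role")
  if (is.null(axes)) axes <- nm[roles == "numeric"]
  for (ax in axes) {
    if (.col_spec(table, ax)$role != "numeric")
      stop_input("axis '%s' is not numeric", ax)
  }
  if (length(axes) < 2L)
    stop_input("a parallel coordinate plot needs at least 2 numeric axes (got %d)",
               length(axes))
  if (!is.null(highlight_level) && is.null(colour_feature))
    stop_config("highlight_level requires colour_feature")
  if (!is.null(colour_feature)) {
    cs <- .col_spec(table, colour_feature)
    if (!cs$role %in% c("categorical", "boolean"))
      stop_config("colour feature '%s' must be categorical or boolean (got '%s')",
                  colour_feature, cs$role)
    if (!is.null(highlight_level) && !highlight_level %in% cs$levels)
      stop_config("highlight level '%s' not found in '%s'; available levels: %s",
                  highlight_level, colour_feature,
                  paste(cs$levels, collapse = ", "))
  }
  if (ordering == "mi" && is.null(colour_feature))
    stop_config("ordering = 'mi' requires a colour_feature to rank against")

  axes_ordered <- switch(ordering,
    given = axes,
    crossings = order_axes_min_crossings(
      crossing_matrix(table, axes, normalisation)),
    mi = order_axes_by_mi(table, axes, colour_feature, n_bins)$column)

  miss <- table$missing_mask[, axes_ordered, drop = FALSE]
  dropped <- which(rowSums(miss) > 0)
  kept <- setdiff(seq_len(table$n_rows), dropped)
  if (missing_policy == "drop_and_report") {
    for (ax in axes_ordered)
      log_msg("info", "axis '%s': %d missing value(s)", ax, sum(miss[, ax]))
  }

  # Normalisation uses each axis's full observed column, then subsets, so a
  # value's height does not depend on other axes' missingness.
  poly <- vapply(axes_ordered, function(ax)
    normalise_axis(table$values[[ax]], normalisation)[kept],
    numeric(length(kept)))
  poly <- matrix(poly, nrow = length(kept), ncol = length(axes_ordered),
                 dimnames = list(NULL, axes_ordered))

  colour_values <- if (!is.null(colour_feature))
    as.character(table$values[[colour_feature]])[kept] else NULL
  foreground <- if (!is.null(highlight_level))
    !is.na(colour_values) & colour_values == highlight_level
  else rep(TRUE, length(kept))

  structure(list(
    axes = data.frame(column = axes_ordered,
                      position = seq_along(axes_ordered) - 1L,
                      normalisation = normalisation,
                      stringsAsFactors = FALSE),
    polylines = poly,
    row_index = kept,
    colour_feature = colour_feature,
    colour_values = colour_values,
    highlight_level = highlight_level,
    foreground = foreground,
    dropped_rows = dropped
  ), class = "pcp_layout")
}

#' Serialise a PCP layout to JSON
#'
#' Documented shape: `axes` (column/position/normalisation records),
#' `polylines` (per-sample arrays of heights), `row_index`, colour and
#' highlight metadata, `foreground` flags, `dropped_rows`.
#'
#' @param layout A `pcp_layout`.
#' @return A JSON string.
#' @export
pcp_layout_json <- function(layout) {
  stopifnot(inherits(layout, "pcp_layout"))
  jsonlite::toJSON(list(
    axes = layout$axes,
    polylines = unname(split(layout$polylines, seq_len(nrow(layout$polylines)))),
    row_index = layout$row_index,
    colour_feature = layout$colour_feature,
    colour_values = layout$colour_values,
    highlight_level = layout$highlight_level,
    foreground = layout$foreground,
    dropped_rows = layout$dropped_rows
  ), auto_unbox = TRUE, digits = NA, null = "null")
}
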