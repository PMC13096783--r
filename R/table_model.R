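# table_model: read, type and validate rectangular data into a typed_table
# that both layout engines consume.

#' Column specification
#'
#' Describes one column of a [typed_table()]: its name, its role, the level
#' order for categorical/boolean columns, and whether the role was declared
#' by the user or inferred.
#'
#' @param name Column name (unique within a table).
#' @param role One of `"numeric"`, `"categorical"`, `"boolean"`,
#'   `"identifier"`, `"tooltip"`. Identifier and tooltip roles are never
#'   inferred, only declared; they are carried along for tooltips but are
#'   not plottable as axes or tracks.
#' @param levels Character vector of levels in display order
#'   (categorical/boolean only; must be empty for numeric columns).
#' @param declared `TRUE` if the role was set by a user override.
#' @return An object of class `column_spec`.
#' @export
column_spec <- function(name, role, levels = character(), declared = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_contract("column_spec: 'name' must be a single non-empty string")
  role <- match.arg(role, .ROLES)
  levels <- as.character(levels)
  if (role %in% c("categorical", "boolean")) {
    if (anyDuplicated(levels))
      stop_contract("column_spec '%s': duplicate levels", name)
  } else if (length(levels) > 0L) {
    stop_contract("column_spec '%s': role '%s' cannot carry levels", name, role)
  }
  structure(list(name = name, role = role, levels = levels,
                 declared = isTRUE(declared)),
            class = "column_spec")
}

#' Infer the role of a raw column
#'
#' Decision rule: entries matching `na_tokens` are treated as missing and
#' set aside. A column whose non-missing entries are all boolean synonyms
#' (`TRUE/True/true/T` and the `FALSE` counterparts) is `boolean`. A column
#' whose non-missing entries all parse as finite numbers is `numeric`
#' unless every value is integer-valued *and* there are at most
#' `max_levels` distinct values, in which case it is treated as a
#' categorical code. Everything else - including all-missing columns -
#' is `categorical`. The result is deterministic and does not depend on
#' row order.
#'
#' @param values Character vector of raw cell contents.
#' @param max_levels Distinct-value threshold below which integer-valued
#'   columns are read as categorical codes (default 5).
#' @param na_tokens Strings treated as missing.
#' @return `"numeric"`, `"boolean"` or `"categorical"`.
#' @export
infer_role <- function(values, max_levels = .DEFAULT_MAX_LEVELS,
                       na_tokens = .DEFAULT_NA_TOKENS) {
  if (length(values) == 0L)
    stop_contract("infer_role: 'values' must be non-empty")
  if (!is.numeric(max_levels) || length(max_levels) != 1L || max_levels < 1)
    stop_contract("infer_role: 'max_levels' must be a positive integer")
  values <- as.character(values)
  obs <- values[!is.na(values) & !(values %in% na_tokens)]
  if (length(obs) == 0L) return("categorical")
  if (all(obs %in% c(.TRUE_TOKENS, .FALSE_TOKENS))) return("boolean")
  num <- suppressWarnings(as.numeric(obs))
  if (!anyNA(num) && all(is.finite(num))) {
    all_integer <- all(num == trunc(num))
    n_distinct <- length(unique(num))
    if (all_integer && n_distinct <= max_levels) return("categorical")
    return("numeric")
  }
  "categorical"
}

.parse_boolean <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% .TRUE_TOKENS] <- TRUE
  out[x %in% .FALSE_TOKENS] <- FALSE
  out
}

#' Coerce a raw character table into a typed table
#'
#' Applies user role overrides first and [infer_role()] everywhere else,
#' builds the missingness mask from the configured NA tokens, and orders
#' categorical levels by first appearance (boolean levels are always
#' `FALSE < TRUE`).
#'
#' @param raw A data.frame of character columns (as parsed from CSV/TSV).
#' @param overrides Named list/character vector mapping column names to
#'   roles; overrides always win over inference.
#' @param na_tokens Strings treated as missing cells.
#' @param max_levels Passed to [infer_role()].
#' @return A [typed_table()] object.
#' @export
coerce_table <- function(raw, overrides = list(),
                         na_tokens = .DEFAULT_NA_TOKENS,
                         max_levels = .DEFAULT_MAX_LEVELS) {
  if (!is.data.frame(raw))
    stop_contract("coerce_table: 'raw' must be a data.frame")
  nm <- names(raw)
  if (anyDuplicated(nm))
    stop_input("duplicate header name(s): %s",
               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  overrides <- as.list(overrides)
  bad <- setdiff(names(overrides), nm)
  if (length(bad) > 0L)
    stop_config("override(s) refer to unknown column(s): %s",
                paste(bad, collapse = ", "))
  n <- nrow(raw)
  cols <- vector("list", length(nm))
  vals <- vector("list", length(nm))
  mask <- matrix(FALSE, nrow = n, ncol = length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    x <- as.character(raw[[j]])
    miss <- is.na(x) | x %in% na_tokens
    declared <- nm[j] %in% names(overrides)
    role <- if (declared) match.arg(overrides[[nm[j]]], .ROLES)
            else infer_role(if (n == 0L) NA_character_ else x,
                            max_levels = max_levels, na_tokens = na_tokens)
    obs <- x[!miss]
    if (role == "numeric") {
      v <- rep(NA_real_, n)
      parsed <- suppressWarnings(as.numeric(obs))
      if (anyNA(parsed) || any(!is.finite(parsed))) {
        offender <- which(!miss)[which(is.na(parsed) | !is.finite(parsed))[1L]]
        stop_input("column '%s' cannot be coerced to numeric (first offending row: %d, value '%s')",
                   nm[j], offender, x[offender])
      }
      v[!miss] <- parsed
      cols[[j]] <- column_spec(nm[j], "numeric", declared = declared)
    } else if (role == "boolean") {
      parsed <- .parse_boolean(obs)
      if (anyNA(parsed)) {
        offender <- which(!miss)[which(is.na(parsed))[1L]]
        stop_input("column '%s' cannot be coerced to boolean (first offending row: %d, value '%s')",
                   nm[j], offender, x[offender])
      }
      v <- rep(NA, n)
      v[!miss] <- parsed
      cols[[j]] <- column_spec(nm[j], "boolean", levels = c("FALSE", "TRUE"),
                               declared = declared)
    } else if (role == "categorical") {
      v <- rep(NA_character_, n)
      v[!miss] <- obs
      lev <- unique(obs)  # first-appearance order
      cols[[j]] <- column_spec(nm[j], "categorical", levels = lev,
                               declared = declared)
    } else {  # identifier / tooltip: carried as character, no levels
      v <- rep(NA_character_, n)
      v[!miss] <- obs
      cols[[j]] <- column_spec(nm[j], role, declared = TRUE)
    }
    vals[[j]] <- v
    mask[, j] <- miss
  }
  names(vals) <- nm
  new_typed_table(cols, vals, mask)
}

#' Construct a typed table from parsed pieces
#'
#' Low-level constructor; most users will call [read_typed_table()] or
#' [as_typed_table()] instead. Validates the container invariants: equal
#' column lengths, mask/value agreement, and categorical values being
#' members of their level sets.
#'
#' @param columns List of [column_spec()] objects.
#' @param values Named list of column vectors.
#' @param missing_mask Logical matrix, `n_rows x n_columns`.
#' @return An object of class `typed_table`.
#' @export
new_typed_table <- function(columns, values, missing_mask) {
  nm <- vapply(columns, function(cs) cs$name, character(1))
  if (anyDuplicated(nm))
    stop_contract("typed_table: duplicate column names")
  if (!identical(names(values), nm))
    stop_contract("typed_table: values must be named to match columns")
  n <- if (length(values) > 0L) length(values[[1L]]) else 0L
  if (!all(lengths(values) == n))
    stop_contract("typed_table: ragged columns")
  if (!is.matrix(missing_mask) || !is.logical(missing_mask) ||
      nrow(missing_mask) != n || ncol(missing_mask) != length(nm))
    stop_contract("typed_table: missing_mask must be an n_rows x n_columns logical matrix")
  colnames(missing_mask) <- nm
  for (j in seq_along(nm)) {
    if (!identical(unname(is.na(values[[j]])), unname(missing_mask[, j])))
      stop_contract("typed_table: missing_mask disagrees with NA pattern in column '%s'", nm[j])
    cs <- columns[[j]]
    if (cs$role == "categorical") {
      obs <- values[[j]][!missing_mask[, j]]
      if (!all(obs %in% cs$levels))
        stop_contract("typed_table: column '%s' has values outside its level set", nm[j])
    }
  }
  structure(list(columns = columns, n_rows = n, values = values,
                 missing_mask = missing_mask),
            class = "typed_table")
}

#' Convert a data.frame to a typed table
#'
#' Convenience wrapper: every cell is rendered to its character form and
#' passed through [coerce_table()], so inference and overrides behave
#' exactly as they do for file input.
#'
#' @inheritParams coerce_table
#' @param df A data.frame.
#' @return A `typed_table`.
#' @export
as_typed_table <- function(df, overrides = list(),
                           na_tokens = .DEFAULT_NA_TOKENS,
                           max_levels = .DEFAULT_MAX_LEVELS) {
  raw <- as.data.frame(lapply(df, function(x) {
    out <- as.character(x)
    out[is.na(x)] <- NA_character_
    out
  }), optional = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- names(df)
  coerce_table(raw, overrides = overrides, na_tokens = na_tokens,
               max_levels = max_levels)
}

.table_cols <- function(table) vapply(table$columns, `[[`, character(1), "name")

.col_spec <- function(table, name) {
  idx <- match(name, .table_cols(table))
  if (is.na(idx)) stop_config("unknown column: '%s'", name)
  table$columns[[idx]]
}

#' Read a delimited file into a typed table
#'
#' Reads RFC-4180-style CSV or tab-separated TSV (UTF-8, first row =
#' header). The delimiter is auto-detected from the file extension
#' (`.tsv`/`.tab` = tab, anything else = comma) unless given explicitly.
#'
#' @inheritParams coerce_table
#' @param path File path.
#' @param delim `","` or `"\t"`; `NULL` auto-detects from the extension.
#' @return A `typed_table`.
#' @export
read_typed_table <- function(path, overrides = list(),
                             na_tokens = .DEFAULT_NA_TOKENS,
                             max_levels = .DEFAULT_MAX_LEVELS,
                             delim = NULL) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  if (is.null(delim))
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                      colClasses = "character", check.names = FALSE,
                      na.strings = character(), comment.char = "",
                      fileEncoding = "UTF-8", stringsAsFactors = FALSE),
    error = function(e) stop_input("failed to parse '%s': %s", path,
                                   conditionMessage(e)))
  coerce_table(raw, overrides = overrides, na_tokens = na_tokens,
               max_levels = max_levels)
}

#' Write a typed table back to CSV/TSV
#'
#' Missing cells are written as empty fields, so re-reading with the same
#' overrides reproduces roles, levels and the missingness mask exactly.
#'
#' @param table A `typed_table`.
#' @param path Output path; `.tsv`/`.tab` extensions write tab-separated.
#' @param delim Optional explicit delimiter.
#' @export
write_typed_table <- function(table, path, delim = NULL) {
  stopifnot(inherits(table, "typed_table"))
  if (is.null(delim))
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(lapply(table$values, function(v) {
    out <- as.character(v)
    out[is.na(out)] <- ""
    out
  }), optional = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- .table_cols(table)
  utils::write.table(df, path, sep = delim, quote = TRUE, qmethod = "double",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-column summary of a typed table
#'
#' @param table A `typed_table`.
#' @return A data.frame with one row per column: role, number of missing
#'   cells, number of distinct observed values, and min/max for numeric
#'   columns.
#' @export
summarise_table <- function(table) {
  stopifnot(inherits(table, "typed_table"))
  nm <- .table_cols(table)
  recs <- lapply(seq_along(nm), function(j) {
    v <- table$values[[j]]
    obs <- v[!table$missing_mask[, j]]
    num <- table$columns[[j]]$role == "numeric"
    data.frame(
      column = nm[j],
      role = table$columns[[j]]$role,
      n_missing = sum(table$missing_mask[, j]),
      n_distinct = length(unique(obs)),
      min = if (num && length(obs)) min(obs) else NA_real_,
      max = if (num && length(obs)) max(obs) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' @export
print.typed_table <- function(x, ...) {
  cat(sprintf("<typed_table> %d rows x %d columns\n", x$n_rows,
              length(x$columns)))
  print(summarise_table(x))
  invisible(x)
}

#' @export
summary.typed_table <- function(object, ...) summarise_table(object)
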