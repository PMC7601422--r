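#' Iteration modes of the mapping dialect
#'
#' The three first-class strategies for walking a workbook: `ROW_SINGLE`
#' (each table row is one substance record; the row is discovered during
#' iteration, so a data location needs only a column), `ABSOLUTE_LOCATION`
#' (a fixed row and column), and `JSON_VALUE` (the value is a literal taken
#' from the configuration itself, no cell is read). The registry is
#' extensible so further modes can be added without changing the engine
#' contract.
#'
#' @export
ITERATION_MODES <- c("ROW_SINGLE", "ABSOLUTE_LOCATION", "JSON_VALUE")

.iteration_registry <- new.env(parent = emptyenv())

#' Register an additional iteration mode keyword
#'
#' @param mode Upper-case keyword.
#' @param reader Function `(workbook, edl, cursor) -> value` implementing it.
#' @export
register_iteration_mode <- function(mode, reader) {
  assign(mode, reader, envir = .iteration_registry)
  invisible(mode)
}

known_iteration_modes <- function() {
  c(ITERATION_MODES, ls(.iteration_registry))
}

# ---- problem collector -----------------------------------------------------

new_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$problems <- list()
  env
}

add_problem <- function(col, severity, path, message,
                        expected = NA_character_, found = NA_character_) {
  col$problems[[length(col$problems) + 1L]] <-
    list(severity = severity, path = path, message = message,
         expected = expected, found = found)
  invisible(NULL)
}

problems_tibble <- function(col) {
  if (!length(col$problems)) {
    return(tibble::tibble(severity = character(), path = character(),
                          message = character(), expected = character(),
                          found = character()))
  }
  tibble::tibble(
    severity = vapply(col$problems, `[[`, character(1), "severity"),
    path = vapply(col$problems, `[[`, character(1), "path"),
    message = vapply(col$problems, `[[`, character(1), "message"),
    expected = vapply(col$problems, `[[`, character(1), "expected"),
    found = vapply(col$problems, `[[`, character(1), "found"))
}

json_kind <- function(x) {
  if (is.null(x)) "null"
  else if (is.list(x)) { if (!is.null(names(x)) && any(nzchar(names(x)))) "object" else "array" }
  else if (is.character(x)) "string"
  else if (is.logical(x)) "boolean"
  else if (is.numeric(x)) "number"
  else class(x)[1]
}

check_integer <- function(col, x, path, key, required = FALSE, min = NULL) {
  v <- x[[key]]
  p <- paste0(path, ".", key)
  if (is.null(v)) {
    if (required) add_problem(col, "error", p,
                              sprintf("%s required", key), "integer", "missing")
    return(NULL)
  }
  if (!is.numeric(v) || length(v) != 1L || v != floor(v)) {
    add_problem(col, "error", p, sprintf("%s must be an integer", key),
                "integer", json_kind(v))
    return(NULL)
  }
  v <- as.integer(v)
  if (!is.null(min) && v < min) {
    add_problem(col, "error", p, sprintf("%s must be >= %d", key, min),
                sprintf(">= %d", min), format(v))
    return(NULL)
  }
  v
}

check_string <- function(col, x, path, key, required = FALSE) {
  v <- x[[key]]
  p <- paste0(path, ".", key)
  if (is.null(v)) {
    if (required) add_problem(col, "error", p,
                              sprintf("%s required", key), "string", "missing")
    return(NULL)
  }
  if (!is.character(v) || length(v) != 1L) {
    add_problem(col, "error", p, sprintf("%s must be a string", key),
                "string", json_kind(v))
    return(NULL)
  }
  v
}

warn_unknown_keys <- function(col, x, path, known) {
  unknown <- setdiff(names(x), known)
  for (k in unknown) {
    add_problem(col, "warning", paste0(path, ".", k),
                sprintf("unknown key %s ignored", k))
  }
}

# ---- Excel Data Locations --------------------------------------------------

#' Construct an Excel Data Location
#'
#' An EDL is the coordinate object of the mapping dialect: it says where
#' and how one datum is read from the workbook. Row and column indices are
#' 0-based throughout the dialect; column letters (`"A"`, `"B"`, ...) are
#' accepted and converted.
#'
#' @param iteration One of the registered iteration modes.
#' @param sheet_index 0-based sheet index, or NULL.
#' @param sheet_name Exact sheet name; wins over `sheet_index` if both set.
#' @param row_index 0-based row, or NULL.
#' @param column_index 0-based column index or column letter, or NULL.
#' @param json_value Literal value (for `JSON_VALUE` mode).
#' @param unit Optional unit attached to values read through this location.
#' @return An object of class `fs_edl`.
#' @export
edl <- function(iteration = NULL, sheet_index = NULL, sheet_name = NULL,
                row_index = NULL, column_index = NULL, json_value = NULL,
                unit = NULL) {
  if (is.character(column_index)) {
    column_index <- col_letter_to_index(column_index)
  }
  structure(list(iteration = iteration,
                 sheet_index = if (!is.null(sheet_index)) as.integer(sheet_index),
                 sheet_name = sheet_name,
                 row_index = if (!is.null(row_index)) as.integer(row_index),
                 column_index = if (!is.null(column_index)) as.integer(column_index),
                 json_value = json_value,
                 unit = unit),
            class = "fs_edl")
}

EDL_KEYS <- c("ITERATION", "SHEET_INDEX", "SHEET_NAME", "ROW_INDEX",
              "COLUMN_INDEX", "JSON_VALUE", "UNIT")

# raw JSON EDL (object or bare-scalar shorthand) -> unresolved fs_edl
parse_edl <- function(col, x, path) {
  if (!is.list(x)) {
    # bare scalar shorthand: a column reference under the default iteration
    if (is.character(x) && length(x) == 1L &&
        grepl("^[A-Za-z]{1,3}$", x)) {
      return(edl(column_index = col_letter_to_index(x)))
    }
    if (is.numeric(x) && length(x) == 1L && x == floor(x)) {
      return(edl(column_index = as.integer(x)))
    }
    add_problem(col, "error", path,
                "EDL must be an object or a bare column reference",
                "object", json_kind(x))
    return(NULL)
  }
  warn_unknown_keys(col, x, path, EDL_KEYS)
  iteration <- check_string(col, x, path, "ITERATION")
  if (!is.null(iteration) && !iteration %in% known_iteration_modes()) {
    add_problem(col, "error", paste0(path, ".ITERATION"),
                sprintf("unknown iteration mode \"%s\"", iteration),
                paste(known_iteration_modes(), collapse = "|"), iteration)
    iteration <- NULL
  }
  column_index <- x[["COLUMN_INDEX"]]
  if (!is.null(column_index)) {
    if (is.character(column_index) && length(column_index) == 1L &&
        grepl("^[A-Za-z]{1,3}$", column_index)) {
      column_index <- col_letter_to_index(column_index)
    } else if (is.numeric(column_index) && length(column_index) == 1L &&
               column_index == floor(column_index) && column_index >= 0) {
      column_index <- as.integer(column_index)
    } else {
      add_problem(col, "error", paste0(path, ".COLUMN_INDEX"),
                  "COLUMN_INDEX must be a non-negative integer or a column letter",
                  "integer|letter", json_kind(x[["COLUMN_INDEX"]]))
      column_index <- NULL
    }
  }
  row_index <- check_integer(col, x, path, "ROW_INDEX", min = 0L)
  sheet_index <- check_integer(col, x, path, "SHEET_INDEX", min = 0L)
  sheet_name <- check_string(col, x, path, "SHEET_NAME")
  unit <- check_string(col, x, path, "UNIT")
  json_value <- x[["JSON_VALUE"]]
  if (!is.null(json_value) && is.list(json_value)) {
    add_problem(col, "error", paste0(path, ".JSON_VALUE"),
                "JSON_VALUE must be a scalar", "scalar", json_kind(json_value))
    json_value <- NULL
  }
  e <- edl(iteration = iteration, sheet_index = sheet_index,
           sheet_name = sheet_name, row_index = row_index,
           column_index = column_index, json_value = json_value, unit = unit)
  attr(e, "path") <- path
  e
}

#' Expand a partially specified data location against the access defaults
#'
#' Short-syntax configurations omit attributes that the `DATA_ACCESS`
#' section defines globally; this fills them in (defaults never override an
#' explicitly set attribute) and re-checks the iteration-mode invariants on
#' the completed location. The operation is idempotent.
#'
#' @param raw_edl An [edl()] (possibly with missing attributes).
#' @param defaults A data-access configuration (see [load_config()]).
#' @param collector Optional internal problem collector; when absent,
#'   violations abort.
#' @param path Dialect path used in error messages.
#' @return A fully resolved `fs_edl`.
#' @export
resolve_edl <- function(raw_edl, defaults, collector = NULL, path = "EDL") {
  col <- collector %||% new_collector()
  e <- raw_edl
  path <- attr(raw_edl, "path") %||% path
  if (is.null(e$iteration)) {
    e["iteration"] <- list(if (!is.null(e$json_value)) "JSON_VALUE"
                           else defaults$iteration)
  }
  if (!identical(e$iteration, "JSON_VALUE") && is.null(e$sheet_name) &&
      is.null(e$sheet_index)) {
    e["sheet_name"] <- list(defaults$sheet_name)
    e["sheet_index"] <- list(defaults$sheet_index)
  }
  if (identical(e$iteration, "ROW_SINGLE")) {
    if (is.null(e$column_index)) {
      add_problem(col, "error", path, "COLUMN_INDEX required",
                  "integer|letter", "missing")
    }
    if (!is.null(e$row_index)) {
      add_problem(col, "error", paste0(path, ".ROW_INDEX"),
                  "ROW_INDEX is not allowed in ROW_SINGLE mode (the row is obtained during iteration)",
                  "absent", format(e$row_index))
    }
  } else if (identical(e$iteration, "ABSOLUTE_LOCATION")) {
    if (is.null(e$column_index)) {
      add_problem(col, "error", path, "COLUMN_INDEX required",
                  "integer|letter", "missing")
    }
    if (is.null(e$row_index)) {
      add_problem(col, "error", path, "ROW_INDEX required",
                  "integer", "missing")
    }
  } else if (identical(e$iteration, "JSON_VALUE")) {
    if (is.null(e$json_value)) {
      add_problem(col, "error", path, "JSON_VALUE required",
                  "scalar", "missing")
    }
    if (!is.null(e$row_index) || !is.null(e$column_index) ||
        !is.null(raw_edl$sheet_name) || !is.null(raw_edl$sheet_index)) {
      add_problem(col, "error", path,
                  "JSON_VALUE mode takes no sheet/row/column attributes",
                  "absent", "present")
    }
    e["sheet_name"] <- list(NULL)
    e["sheet_index"] <- list(NULL)
  }
  if (is.null(collector)) raise_problems(col, "Invalid data location")
  # rebuild canonically so field order never depends on the input syntax
  out <- edl(iteration = e$iteration, sheet_index = e$sheet_index,
             sheet_name = e$sheet_name, row_index = e$row_index,
             column_index = e$column_index, json_value = e$json_value,
             unit = e$unit)
  attr(out, "path") <- attr(raw_edl, "path")
  out
}

raise_problems <- function(col, headline) {
  tb <- problems_tibble(col)
  errs <- tb[tb$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    msg <- paste0(headline, ":\n", paste0(
      "  - ", errs$path, ": ", errs$message,
      ifelse(is.na(errs$expected), "",
             paste0(" (expected ", errs$expected, ", found ", errs$found, ")")),
      collapse = "\n"))
    rlang::abort(msg, class = "fairsheet_config_error", problems = tb)
  }
  invisible(tb)
}

# ---- sections --------------------------------------------------------------

DATA_ACCESS_KEYS <- c("ITERATION", "SHEET_INDEX", "SHEET_NAME", "ROW_START",
                      "ROW_END", "STOP_ON_BLANK_ROWS", "NA_MARKERS")

#' Default markers treated as "value not reported"
#' @export
DEFAULT_NA_MARKERS <- c("", "n/a", "N/A", "-", "–")

parse_data_access <- function(col, x, path = "DATA_ACCESS") {
  if (is.null(x)) {
    add_problem(col, "error", path, "DATA_ACCESS section required",
                "object", "missing")
    x <- list()
  } else if (!is.list(x)) {
    add_problem(col, "error", path, "DATA_ACCESS must be an object",
                "object", json_kind(x))
    x <- list()
  }
  warn_unknown_keys(col, x, path, DATA_ACCESS_KEYS)
  iteration <- check_string(col, x, path, "ITERATION", required = TRUE)
  if (!is.null(iteration) && !iteration %in% known_iteration_modes()) {
    add_problem(col, "error", paste0(path, ".ITERATION"),
                sprintf("unknown iteration mode \"%s\"", iteration),
                paste(known_iteration_modes(), collapse = "|"), iteration)
    iteration <- NULL
  }
  row_start <- check_integer(col, x, path, "ROW_START", min = 0L)
  row_end <- check_integer(col, x, path, "ROW_END", min = 0L)
  if (!is.null(row_start) && !is.null(row_end) && row_end < row_start) {
    add_problem(col, "error", paste0(path, ".ROW_END"),
                "ROW_END must be >= ROW_START",
                sprintf(">= %d", row_start), format(row_end))
  }
  stop_blank <- check_integer(col, x, path, "STOP_ON_BLANK_ROWS", min = 1L)
  na_markers <- x[["NA_MARKERS"]]
  if (!is.null(na_markers)) {
    na_markers <- tryCatch(vapply(na_markers, as.character, character(1)),
                           error = function(e) {
                             add_problem(col, "error", paste0(path, ".NA_MARKERS"),
                                         "NA_MARKERS must be an array of strings",
                                         "array", json_kind(na_markers))
                             NULL
                           })
  }
  list(iteration = iteration %||% "ROW_SINGLE",
       sheet_index = check_integer(col, x, path, "SHEET_INDEX", min = 0L),
       sheet_name = check_string(col, x, path, "SHEET_NAME"),
       row_start = row_start %||% 1L,
       row_end = row_end,
       stop_on_blank_rows = stop_blank %||% 2L,
       na_markers = na_markers %||% DEFAULT_NA_MARKERS)
}

SUBSTANCE_RECORD_KEYS <- c("SUBSTANCE_NAME", "PUBLIC_NAME", "OWNER_NAME",
                           "OWNER_UUID", "SUBSTANCE_UUID", "SUBSTANCE_TYPE",
                           "EXTERNAL_IDENTIFIERS", "COMPOSITION")

parse_substance_record <- function(col, x, da, path = "SUBSTANCE_RECORD") {
  if (is.null(x)) {
    add_problem(col, "error", path, "SUBSTANCE_RECORD section required",
                "object", "missing")
    return(list())
  }
  if (!is.list(x)) {
    add_problem(col, "error", path, "SUBSTANCE_RECORD must be an object",
                "object", json_kind(x))
    return(list())
  }
  warn_unknown_keys(col, x, path, SUBSTANCE_RECORD_KEYS)
  out <- list()
  for (key in c("SUBSTANCE_NAME", "PUBLIC_NAME", "OWNER_NAME", "OWNER_UUID",
                "SUBSTANCE_UUID", "SUBSTANCE_TYPE")) {
    if (!is.null(x[[key]])) {
      e <- parse_edl(col, x[[key]], paste0(path, ".", key))
      if (!is.null(e)) out[[tolower(key)]] <- resolve_edl(e, da, col)
    }
  }
  if (is.null(x[["SUBSTANCE_NAME"]]) && is.null(x[["SUBSTANCE_UUID"]])) {
    add_problem(col, "error", paste0(path, ".SUBSTANCE_NAME"),
                "SUBSTANCE_NAME required (or an explicit SUBSTANCE_UUID)",
                "EDL", "missing")
  }
  ids <- x[["EXTERNAL_IDENTIFIERS"]]
  if (!is.null(ids)) {
    if (!is.list(ids) || (!is.null(names(ids)) && any(nzchar(names(ids))))) {
      add_problem(col, "error", paste0(path, ".EXTERNAL_IDENTIFIERS"),
                  "EXTERNAL_IDENTIFIERS must be an array",
                  "array", json_kind(ids))
    } else {
      out$external_identifiers <- lapply(seq_along(ids), function(i) {
        p <- sprintf("%s.EXTERNAL_IDENTIFIERS[%d]", path, i - 1L)
        entry <- ids[[i]]
        warn_unknown_keys(col, entry, p, c("SYSTEM", "VALUE"))
        sys_e <- if (!is.null(entry[["SYSTEM"]]))
          resolve_edl(parse_edl(col, entry[["SYSTEM"]], paste0(p, ".SYSTEM")), da, col)
        else {
          add_problem(col, "error", paste0(p, ".SYSTEM"), "SYSTEM required",
                      "EDL", "missing"); NULL
        }
        val_e <- if (!is.null(entry[["VALUE"]]))
          resolve_edl(parse_edl(col, entry[["VALUE"]], paste0(p, ".VALUE")), da, col)
        else {
          add_problem(col, "error", paste0(p, ".VALUE"), "VALUE required",
                      "EDL", "missing"); NULL
        }
        list(system = sys_e, value = val_e)
      })
    }
  }
  comp <- x[["COMPOSITION"]]
  if (!is.null(comp)) {
    out$composition <- lapply(seq_along(comp), function(i) {
      p <- sprintf("%s.COMPOSITION[%d]", path, i - 1L)
      entry <- comp[[i]]
      warn_unknown_keys(col, entry, p, "COMPONENTS")
      comps <- entry[["COMPONENTS"]]
      if (is.null(comps) || !is.list(comps)) {
        add_problem(col, "error", paste0(p, ".COMPONENTS"),
                    "COMPONENTS array required", "array", json_kind(comps))
        return(list(components = list()))
      }
      list(components = lapply(seq_along(comps), function(k) {
        pk <- sprintf("%s.COMPONENTS[%d]", p, k - 1L)
        ce <- comps[[k]]
        warn_unknown_keys(col, ce, pk, c("ROLE", "NAME", "STRUCTURE"))
        role <- check_string(col, ce, pk, "ROLE", required = TRUE)
        if (!is.null(role) && !role %in% COMPONENT_ROLES) {
          add_problem(col, "error", paste0(pk, ".ROLE"),
                      sprintf("unknown component role \"%s\"", role),
                      paste(COMPONENT_ROLES, collapse = "|"), role)
        }
        list(role = role,
             name = if (!is.null(ce[["NAME"]]))
               resolve_edl(parse_edl(col, ce[["NAME"]], paste0(pk, ".NAME")), da, col),
             structure = if (!is.null(ce[["STRUCTURE"]]))
               resolve_edl(parse_edl(col, ce[["STRUCTURE"]], paste0(pk, ".STRUCTURE")), da, col))
      }))
    })
  }
  out
}

PA_KEYS <- c("CITATION_TITLE", "CITATION_YEAR", "CITATION_OWNER",
             "INTERPRETATION_RESULT", "INTERPRETATION_CRITERIA",
             "PROTOCOL_GUIDELINE", "INVESTIGATION_UUID", "ASSAY_UUID",
             "RELIABILITY_FLAG", "PARAMETERS", "EFFECTS", "EFFECT_BLOCKS")

EFFECT_KEYS <- c("SAMPLE_ID", "ENDPOINT", "ENDPOINT_TYPE", "VALUE",
                 "LO_VALUE", "UP_VALUE", "LO_QUALIFIER", "UP_QUALIFIER",
                 "ERR_VALUE", "ERR_QUALIFIER", "TEXT_VALUE", "UNIT",
                 "CONDITIONS")

parse_named_edls <- function(col, x, da, path) {
  # a PARAMETERS / CONDITIONS map: ordered name -> EDL
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    add_problem(col, "error", path,
                "must be an object mapping names to EDLs",
                "object", json_kind(x))
    return(list())
  }
  out <- list()
  for (nm in names(x)) {
    e <- parse_edl(col, x[[nm]], paste0(path, ".", nm))
    if (!is.null(e)) out[[nm]] <- resolve_edl(e, da, col)
  }
  out
}

parse_effect <- function(col, x, da, path) {
  if (!is.list(x)) {
    add_problem(col, "error", path, "EFFECTS entry must be an object",
                "object", json_kind(x))
    return(NULL)
  }
  warn_unknown_keys(col, x, path, EFFECT_KEYS)
  out <- list()
  if (is.null(x[["ENDPOINT"]])) {
    add_problem(col, "error", paste0(path, ".ENDPOINT"), "ENDPOINT required",
                "EDL", "missing")
  }
  for (key in setdiff(EFFECT_KEYS, "CONDITIONS")) {
    if (!is.null(x[[key]])) {
      e <- parse_edl(col, x[[key]], paste0(path, ".", key))
      if (!is.null(e)) out[[tolower(key)]] <- resolve_edl(e, da, col)
    }
  }
  if (!is.null(x[["CONDITIONS"]])) {
    out$conditions <- parse_named_edls(col, x[["CONDITIONS"]], da,
                                       paste0(path, ".CONDITIONS"))
  }
  out
}

BLOCK_KEYS <- c("BLOCK_ORIGIN", "SUB_BLOCK_GRID", "SUB_BLOCK_SIZE",
                "SHEET_INDEX", "SHEET_NAME", "ENDPOINT", "ENDPOINT_TYPE",
                "UNIT", "SAMPLE_ID", "VALUE_GROUPS")

PARAM_SOURCES <- c("JSON_VALUE", "COLUMN_HEADER", "ROW_HEADER",
                   "SUB_BLOCK_ROW", "SUB_BLOCK_COL", "ABSOLUTE_LOCATION")

parse_rowcol_pair <- function(col, x, path, rkey = "ROWS", ckey = "COLUMNS",
                              min = 1L) {
  if (!is.list(x)) {
    add_problem(col, "error", path, "must be an object", "object",
                json_kind(x))
    return(NULL)
  }
  warn_unknown_keys(col, x, path, c(rkey, ckey))
  r <- check_integer(col, x, path, rkey, required = TRUE, min = min)
  c_ <- check_integer(col, x, path, ckey, required = TRUE, min = min)
  if (is.null(r) || is.null(c_)) return(NULL)
  c(r, c_)
}

parse_effect_block <- function(col, x, da, path) {
  if (!is.list(x)) {
    add_problem(col, "error", path, "EFFECT_BLOCKS entry must be an object",
                "object", json_kind(x))
    return(NULL)
  }
  warn_unknown_keys(col, x, path, BLOCK_KEYS)
  origin <- NULL
  if (is.null(x[["BLOCK_ORIGIN"]])) {
    add_problem(col, "error", paste0(path, ".BLOCK_ORIGIN"),
                "BLOCK_ORIGIN required", "object", "missing")
  } else {
    bo <- x[["BLOCK_ORIGIN"]]
    warn_unknown_keys(col, bo, paste0(path, ".BLOCK_ORIGIN"),
                      c("ROW_INDEX", "COLUMN_INDEX"))
    r <- check_integer(col, bo, paste0(path, ".BLOCK_ORIGIN"), "ROW_INDEX",
                       required = TRUE, min = 0L)
    cc <- bo[["COLUMN_INDEX"]]
    if (is.character(cc)) cc <- col_letter_to_index(cc)
    else cc <- check_integer(col, bo, paste0(path, ".BLOCK_ORIGIN"),
                             "COLUMN_INDEX", required = TRUE, min = 0L)
    if (!is.null(r) && !is.null(cc)) origin <- c(r, as.integer(cc))
  }
  grid <- if (!is.null(x[["SUB_BLOCK_GRID"]]))
    parse_rowcol_pair(col, x[["SUB_BLOCK_GRID"]],
                      paste0(path, ".SUB_BLOCK_GRID")) else c(1L, 1L)
  size <- if (!is.null(x[["SUB_BLOCK_SIZE"]]))
    parse_rowcol_pair(col, x[["SUB_BLOCK_SIZE"]],
                      paste0(path, ".SUB_BLOCK_SIZE"))
  else {
    add_problem(col, "error", paste0(path, ".SUB_BLOCK_SIZE"),
                "SUB_BLOCK_SIZE required", "object", "missing")
    NULL
  }
  sheet_index <- check_integer(col, x, path, "SHEET_INDEX", min = 0L)
  sheet_name <- check_string(col, x, path, "SHEET_NAME")
  if (is.null(sheet_name) && is.null(sheet_index)) {
    sheet_name <- da$sheet_name
    sheet_index <- da$sheet_index
  }
  shared <- list()
  for (key in c("ENDPOINT", "ENDPOINT_TYPE", "UNIT", "SAMPLE_ID")) {
    if (!is.null(x[[key]])) {
      e <- parse_edl(col, x[[key]], paste0(path, ".", key))
      if (!is.null(e)) shared[[tolower(key)]] <- resolve_edl(e, da, col)
    }
  }
  if (is.null(x[["ENDPOINT"]])) {
    add_problem(col, "error", paste0(path, ".ENDPOINT"), "ENDPOINT required",
                "EDL", "missing")
  }
  vgs <- x[["VALUE_GROUPS"]]
  groups <- list()
  if (is.null(vgs) || !is.list(vgs) || !length(vgs)) {
    add_problem(col, "error", paste0(path, ".VALUE_GROUPS"),
                "at least one value group required", "array", json_kind(vgs))
  } else {
    groups <- lapply(seq_along(vgs), function(g) {
      pg <- sprintf("%s.VALUE_GROUPS[%d]", path, g - 1L)
      vg <- vgs[[g]]
      warn_unknown_keys(col, vg, pg, c("NAME", "VALUES", "PARAMETERS"))
      vals <- vg[["VALUES"]]
      offsets <- list()
      if (is.null(vals) || !is.list(vals) || !length(vals)) {
        add_problem(col, "error", paste0(pg, ".VALUES"),
                    "VALUES array required", "array", json_kind(vals))
      } else {
        offsets <- lapply(seq_along(vals), function(k) {
          pk <- sprintf("%s.VALUES[%d]", pg, k - 1L)
          ov <- vals[[k]]
          warn_unknown_keys(col, ov, pk, c("ROW_OFFSET", "COLUMN_OFFSET"))
          r <- check_integer(col, ov, pk, "ROW_OFFSET", required = TRUE, min = 0L)
          cc <- check_integer(col, ov, pk, "COLUMN_OFFSET", required = TRUE, min = 0L)
          if (is.null(r) || is.null(cc)) return(NULL)
          if (!is.null(size) && (r >= size[1] || cc >= size[2])) {
            add_problem(col, "error", pk,
                        sprintf("value offset (%d,%d) lies outside the %dx%d sub-block",
                                r, cc, size[1], size[2]),
                        sprintf("< (%d,%d)", size[1], size[2]),
                        sprintf("(%d,%d)", r, cc))
            return(NULL)
          }
          c(r, cc)
        })
        offsets <- offsets[!vapply(offsets, is.null, logical(1))]
      }
      params <- list()
      if (!is.null(vg[["PARAMETERS"]])) {
        pl <- vg[["PARAMETERS"]]
        if (!is.list(pl)) {
          add_problem(col, "error", paste0(pg, ".PARAMETERS"),
                      "PARAMETERS must be an array", "array", json_kind(pl))
        } else {
          params <- lapply(seq_along(pl), function(k) {
            pk <- sprintf("%s.PARAMETERS[%d]", pg, k - 1L)
            pp <- pl[[k]]
            warn_unknown_keys(col, pp, pk,
                              c("NAME", "SOURCE", "JSON_VALUE", "ROW_INDEX",
                                "COLUMN_INDEX", "UNIT"))
            nm <- check_string(col, pp, pk, "NAME", required = TRUE)
            src <- check_string(col, pp, pk, "SOURCE", required = TRUE)
            if (!is.null(src) && !src %in% PARAM_SOURCES) {
              add_problem(col, "error", paste0(pk, ".SOURCE"),
                          sprintf("unknown parameter source \"%s\"", src),
                          paste(PARAM_SOURCES, collapse = "|"), src)
              src <- NULL
            }
            ri <- check_integer(col, pp, pk, "ROW_INDEX", min = 0L)
            ci <- pp[["COLUMN_INDEX"]]
            if (is.character(ci)) ci <- col_letter_to_index(ci)
            else ci <- check_integer(col, pp, pk, "COLUMN_INDEX", min = 0L)
            if (identical(src, "COLUMN_HEADER") && is.null(ri)) {
              add_problem(col, "error", pk,
                          "COLUMN_HEADER source requires ROW_INDEX (the header row)",
                          "integer", "missing")
            }
            if (identical(src, "ROW_HEADER") && is.null(ci)) {
              add_problem(col, "error", pk,
                          "ROW_HEADER source requires COLUMN_INDEX (the header column)",
                          "integer|letter", "missing")
            }
            if (identical(src, "ABSOLUTE_LOCATION") &&
                (is.null(ri) || is.null(ci))) {
              add_problem(col, "error", pk,
                          "ABSOLUTE_LOCATION source requires ROW_INDEX and COLUMN_INDEX",
                          "integers", "missing")
            }
            if (identical(src, "JSON_VALUE") && is.null(pp[["JSON_VALUE"]])) {
              add_problem(col, "error", pk,
                          "JSON_VALUE source requires a JSON_VALUE literal",
                          "scalar", "missing")
            }
            list(name = nm, source = src, json_value = pp[["JSON_VALUE"]],
                 row_index = ri,
                 column_index = if (!is.null(ci)) as.integer(ci),
                 unit = check_string(col, pp, pk, "UNIT"))
          })
        }
      }
      list(name = check_string(col, vg, pg, "NAME"),
           values = offsets, parameters = params)
    })
  }
  list(origin = origin, grid = grid, size = size,
       sheet_index = sheet_index, sheet_name = sheet_name,
       shared = shared, value_groups = groups)
}

parse_protocol_application <- function(col, x, da, path) {
  if (!is.list(x)) {
    add_problem(col, "error", path,
                "PROTOCOL_APPLICATIONS entry must be an object",
                "object", json_kind(x))
    return(NULL)
  }
  warn_unknown_keys(col, x, path, PA_KEYS)
  out <- list()
  for (key in c("CITATION_TITLE", "CITATION_YEAR", "CITATION_OWNER",
                "INTERPRETATION_RESULT", "INTERPRETATION_CRITERIA",
                "INVESTIGATION_UUID", "ASSAY_UUID", "RELIABILITY_FLAG")) {
    if (!is.null(x[[key]])) {
      e <- parse_edl(col, x[[key]], paste0(path, ".", key))
      if (!is.null(e)) out[[tolower(key)]] <- resolve_edl(e, da, col)
    }
  }
  if (!is.null(x[["PROTOCOL_GUIDELINE"]])) {
    g <- x[["PROTOCOL_GUIDELINE"]]
    entries <- if (is.list(g) && (is.null(names(g)) || all(!nzchar(names(g)))))
      g else list(g)
    out$protocol_guideline <- lapply(seq_along(entries), function(i) {
      e <- parse_edl(col, entries[[i]],
                     sprintf("%s.PROTOCOL_GUIDELINE[%d]", path, i - 1L))
      if (!is.null(e)) resolve_edl(e, da, col)
    })
  }
  if (!is.null(x[["PARAMETERS"]])) {
    out$parameters <- parse_named_edls(col, x[["PARAMETERS"]], da,
                                       paste0(path, ".PARAMETERS"))
  }
  if (!is.null(x[["EFFECTS"]])) {
    eff <- x[["EFFECTS"]]
    if (!is.list(eff) || (!is.null(names(eff)) && any(nzchar(names(eff))))) {
      add_problem(col, "error", paste0(path, ".EFFECTS"),
                  "EFFECTS must be an array", "array", json_kind(eff))
    } else {
      out$effects <- purrr::compact(lapply(seq_along(eff), function(i) {
        parse_effect(col, eff[[i]], da,
                     sprintf("%s.EFFECTS[%d]", path, i - 1L))
      }))
    }
  }
  if (!is.null(x[["EFFECT_BLOCKS"]])) {
    blk <- x[["EFFECT_BLOCKS"]]
    if (!is.list(blk) || (!is.null(names(blk)) && any(nzchar(names(blk))))) {
      add_problem(col, "error", paste0(path, ".EFFECT_BLOCKS"),
                  "EFFECT_BLOCKS must be an array", "array", json_kind(blk))
    } else {
      out$effect_blocks <- purrr::compact(lapply(seq_along(blk), function(i) {
        parse_effect_block(col, blk[[i]], da,
                           sprintf("%s.EFFECT_BLOCKS[%d]", path, i - 1L))
      }))
    }
  }
  out
}

TOP_KEYS <- c("DATA_ACCESS", "SUBSTANCE_RECORD", "PROTOCOL_APPLICATIONS")

#' Load and validate a parser configuration
#'
#' Parses the JSON mapping document that binds a spreadsheet template layout
#' to the substance data model. The document has three top-level sections:
#' `DATA_ACCESS` (iteration defaults), `SUBSTANCE_RECORD` (data locations
#' for the substance identity fields) and `PROTOCOL_APPLICATIONS` (an array
#' of protocol-application mappings with `PARAMETERS`, `EFFECTS` and
#' `EFFECT_BLOCKS`). All short-syntax locations are expanded against the
#' `DATA_ACCESS` defaults.
#'
#' Validation collects every problem in one pass before failing, so a
#' configuration with several independent defects is reported completely;
#' each message names the dialect path (e.g.
#' `PROTOCOL_APPLICATIONS[0].EFFECTS[0].ENDPOINT`), the expected kind and
#' the found kind. Unknown keys are warnings, never fatal.
#'
#' @param config_document JSON text, a path to a JSON file, or an already
#'   parsed list.
#' @return A validated configuration of class `fs_parser_config`, with the
#'   full validation report (warnings included) in
#'   `attr(, "validation")`.
#' @seealso [validate_config()] for the report without an error,
#'   [resolve_edl()], [emit_schema()].
#' @export
load_config <- function(config_document) {
  parsed <- parse_config_document(config_document)
  col <- new_collector()
  cfg <- build_config(col, parsed)
  raise_problems(col, "Invalid parser configuration")
  tb <- problems_tibble(col)
  warns <- tb[tb$severity == "warning", , drop = FALSE]
  if (nrow(warns)) {
    rlang::warn(paste0("Parser configuration warnings:\n",
                       paste0("  - ", warns$path, ": ", warns$message,
                              collapse = "\n")))
  }
  attr(cfg, "validation") <- tb
  cfg
}

parse_config_document <- function(config_document) {
  if (is.list(config_document)) return(config_document)
  txt <- config_document
  if (length(txt) == 1L && !grepl("[{\\[]", txt) && file.exists(txt)) {
    txt <- readLines(txt, warn = FALSE)
  }
  tryCatch(jsonlite::parse_json(paste(txt, collapse = "\n")),
           error = function(e) {
             rlang::abort(paste0("Configuration is not valid JSON: ",
                                 conditionMessage(e)),
                         class = "fairsheet_json_error")
           })
}

build_config <- function(col, parsed) {
  if (!is.list(parsed)) {
    add_problem(col, "error", "$", "configuration must be a JSON object",
                "object", json_kind(parsed))
    parsed <- list()
  }
  warn_unknown_keys(col, parsed, "$", TOP_KEYS)
  da <- parse_data_access(col, parsed[["DATA_ACCESS"]])
  sr <- parse_substance_record(col, parsed[["SUBSTANCE_RECORD"]], da)
  pas <- list()
  if (!is.null(parsed[["PROTOCOL_APPLICATIONS"]])) {
    pa_raw <- parsed[["PROTOCOL_APPLICATIONS"]]
    if (!is.list(pa_raw) ||
        (!is.null(names(pa_raw)) && any(nzchar(names(pa_raw))))) {
      add_problem(col, "error", "PROTOCOL_APPLICATIONS",
                  "PROTOCOL_APPLICATIONS must be an array",
                  "array", json_kind(pa_raw))
    } else {
      pas <- purrr::compact(lapply(seq_along(pa_raw), function(i) {
        parse_protocol_application(col, pa_raw[[i]], da,
                                   sprintf("PROTOCOL_APPLICATIONS[%d]", i - 1L))
      }))
    }
  }
  structure(list(data_access = da, substance_record = sr,
                 protocol_applications = pas),
            class = "fs_parser_config")
}

#' Validate a configuration without loading it
#'
#' Runs the same one-pass validation as [load_config()] but returns the full
#' problem report instead of raising an error, for use by curator tooling
#' and the command-line `validate` command.
#'
#' @inheritParams load_config
#' @return A tibble with columns `severity`, `path`, `message`, `expected`,
#'   `found` (zero rows for a clean configuration).
#' @export
validate_config <- function(config_document) {
  parsed <- parse_config_document(config_document)
  col <- new_collector()
  build_config(col, parsed)
  problems_tibble(col)
}

#' @export
print.fs_parser_config <- function(x, ...) {
  cat(sprintf("<parser config> iteration %s, %d substance field(s), %d protocol application(s)\n",
              x$data_access$iteration,
              length(x$substance_record),
              length(x$protocol_applications)))
  invisible(x)
}
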