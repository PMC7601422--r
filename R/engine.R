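#' Parse a workbook under a mapping configuration
#'
#' Executes a validated [load_config()] configuration against a workbook:
#' iterates the substances, resolves every data location to a cell value,
#' and assembles substance records with their protocol applications and
#' effect records (including hierarchical effect-block expansion).
#'
#' In `ROW_SINGLE` mode each data row of the primary sheet yields one
#' record; iteration starts at `ROW_START`, and stops at `ROW_END` or —
#' when `ROW_END` is open — after `STOP_ON_BLANK_ROWS` consecutive fully
#' blank rows (real templates carry trailing notes). In the other modes the
#' workbook describes a single substance and exactly one record is built.
#'
#' Per-record problems (out-of-bounds locations, malformed cells) are
#' collected and continue by default, so a curator gets a full defect
#' report for the file; `strict = TRUE` turns the first problem into an
#' error.
#'
#' @param workbook An [workbook()] object or a path readable by
#'   [read_workbook()].
#' @param config An `fs_parser_config` (or JSON text/path, loaded on the
#'   fly).
#' @param strict Abort on the first per-record problem instead of
#'   collecting.
#' @return A list of [substance_record()] objects; the collected problem
#'   report is attached as `attr(, "problems")` (a tibble).
#' @export
parse_workbook <- function(workbook, config, strict = FALSE) {
  wb <- read_workbook(workbook)
  if (!inherits(config, "fs_parser_config")) config <- load_config(config)
  da <- config$data_access
  ctx <- new.env(parent = emptyenv())
  ctx$collector <- new_collector()
  ctx$na_markers <- da$na_markers
  ctx$strict <- strict
  records <- list()
  if (identical(da$iteration, "ROW_SINGLE")) {
    sheet <- wb_sheet(wb, da$sheet_name, da$sheet_index)
    row <- da$row_start
    blanks <- 0L
    last <- da$row_end
    repeat {
      if (!is.null(last) && row > last) break
      if (is.null(last)) {
        if (row > nrow(sheet) - 1L) break
        if (blank_row(sheet, row + 1L, ctx$na_markers)) {
          blanks <- blanks + 1L
          if (blanks >= da$stop_on_blank_rows) break
          row <- row + 1L
          next
        }
        blanks <- 0L
      } else if (row > nrow(sheet) - 1L) {
        break
      } else if (blank_row(sheet, row + 1L, ctx$na_markers)) {
        row <- row + 1L
        next
      }
      rec <- build_record(wb, config, cursor = list(current_row = row),
                         ctx = ctx)
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
      row <- row + 1L
    }
  } else {
    rec <- build_record(wb, config, cursor = list(current_row = NA_integer_),
                        ctx = ctx)
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  attr(records, "problems") <- problems_tibble(ctx$collector)
  records
}

blank_row <- function(sheet, row1, na_markers) {
  if (row1 > nrow(sheet)) return(TRUE)
  for (j in seq_len(ncol(sheet))) {
    v <- sheet[[row1, j]]
    if (is.null(v)) next
    if (is.character(v) &&
        stringi::stri_trim_both(v) %in% na_markers) next
    return(FALSE)
  }
  TRUE
}

record_problem <- function(ctx, path, message, cursor = NULL) {
  where <- if (!is.null(cursor) && !is.na(cursor$current_row)) {
    sprintf("%s (data row %d)", path, cursor$current_row)
  } else path
  if (isTRUE(ctx$strict)) {
    rlang::abort(paste0(where, ": ", message),
                 class = "fairsheet_parse_error")
  }
  add_problem(ctx$collector, "error", where, message)
}

#' Read one datum through a resolved data location
#'
#' `JSON_VALUE` locations return the configured literal; otherwise the
#' typed content of the addressed cell is returned: numbers stay numeric,
#' text is trimmed, date cells were already converted to ISO-8601 text on
#' workbook read, configured NA markers and blank cells yield `NULL`. Text
#' that looks like a locale decimal-comma number is kept as text with a
#' warning rather than silently converted.
#'
#' @param workbook An [workbook()] object.
#' @param edl A fully resolved [edl()].
#' @param cursor List with `current_row` (0-based data row for `ROW_SINGLE`
#'   iteration).
#' @param ctx Internal parse context (optional).
#' @return The cell value, or `NULL` when absent.
#' @export
read_cell <- function(workbook, edl, cursor = list(current_row = NA_integer_),
                      ctx = NULL) {
  if (identical(edl$iteration, "JSON_VALUE")) {
    v <- edl$json_value
    return(if (is.numeric(v)) as.numeric(v) else v)
  }
  reader <- mget(edl$iteration %||% "", envir = .iteration_registry,
                 ifnotfound = list(NULL))[[1]]
  if (!is.null(reader)) return(reader(workbook, edl, cursor))
  sheet <- wb_sheet(workbook, edl$sheet_name, edl$sheet_index)
  row0 <- if (identical(edl$iteration, "ROW_SINGLE")) cursor$current_row
          else edl$row_index
  if (is.null(row0) || is.na(row0)) {
    if (!is.null(ctx)) {
      record_problem(ctx, attr(edl, "path") %||% "EDL",
                     "no row available for this location", cursor)
    }
    return(NULL)
  }
  row1 <- row0 + 1L
  col1 <- edl$column_index + 1L
  if (row1 > nrow(sheet) || col1 > ncol(sheet)) {
    if (!is.null(ctx)) {
      add_problem(ctx$collector, "warning",
                  attr(edl, "path") %||% "EDL",
                  sprintf("cell %s (row %d, column %d, 0-based) outside sheet bounds",
                          rc_to_a1(row1, col1), row0, edl$column_index))
    }
    return(NULL)
  }
  clean_cell(sheet[[row1, col1]], ctx)
}

clean_cell <- function(v, ctx = NULL) {
  if (is.null(v)) return(NULL)
  if (is.character(v)) {
    v <- stringi::stri_trim_both(v)
    markers <- if (!is.null(ctx)) ctx$na_markers else DEFAULT_NA_MARKERS
    if (v %in% markers) return(NULL)
    if (grepl("^-?[0-9]+,[0-9]+$", v) && !is.null(ctx)) {
      add_problem(ctx$collector, "warning", "cell",
                  sprintf("\"%s\" looks like a decimal-comma number; kept as text", v))
    }
  }
  if (is.numeric(v)) v <- as.numeric(v)
  v
}

#' Parse a qualified value or interval expression
#'
#' Total function over text that failed plain numeric coercion. Recognizes
#' the qualified forms `"<3"`, `"<=3"`, `">3"`, `">=3"`, `"~3"`, `"=3"`
#' and the interval forms `"3-4"` / `"3–4"` (read as `3 <= x <= 4`).
#' Anything else parses to `NULL` and is stored by the caller as a text
#' value.
#'
#' @param raw Non-empty string.
#' @return `NULL`, or a list with `lo_qualifier`, `lo_value`,
#'   `up_qualifier`, `up_value` (absent members omitted).
#' @export
parse_value_expression <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L) return(NULL)
  s <- stringi::stri_trim_both(raw)
  num <- "[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?"
  m <- regmatches(s, regexec(
    sprintf("^(<=|>=|<|>|~|=)\\s*(-?%s)$", num), s))[[1]]
  if (length(m) == 3L) {
    q <- m[2]
    v <- as.numeric(m[3])
    if (q %in% c("<", "<=")) {
      return(list(up_qualifier = q, up_value = v))
    }
    if (q %in% c(">", ">=")) {
      return(list(lo_qualifier = q, lo_value = v))
    }
    return(list(lo_qualifier = q, lo_value = v))
  }
  m <- regmatches(s, regexec(
    sprintf("^(%s)\\s*[-–]\\s*(%s)$", num, num), s))[[1]]
  if (length(m) == 3L) {
    return(list(lo_qualifier = ">=", lo_value = as.numeric(m[2]),
                up_qualifier = "<=", up_value = as.numeric(m[3])))
  }
  NULL
}

read_text <- function(wb, e, cursor, ctx) {
  v <- read_cell(wb, e, cursor, ctx)
  if (is.null(v)) return(NULL)
  if (is.numeric(v)) {
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  } else {
    as.character(v)
  }
}

# assemble the numeric/interval/text value fields of one effect from a raw
# cell value; `as_value` carries the "VALUE is LO_VALUE with '=' " alias
effect_value_fields <- function(v, as_value = FALSE) {
  if (is.null(v)) return(list())
  if (is.numeric(v)) {
    if (as_value) return(list(lo_qualifier = "=", lo_value = v))
    return(list(lo_value = v))
  }
  parsed <- parse_value_expression(v)
  if (!is.null(parsed)) return(parsed)
  list(text_value = as.character(v))
}

read_value_obj <- function(wb, e, cursor, ctx) {
  v <- read_cell(wb, e, cursor, ctx)
  if (is.null(v)) return(NULL)
  if (is.numeric(v)) model_value(number = v, unit = e$unit)
  else model_value(text = as.character(v), unit = e$unit)
}

build_record <- function(wb, config, cursor, ctx) {
  sr <- config$substance_record
  get_txt <- function(e) if (is.null(e)) NULL else read_text(wb, e, cursor, ctx)
  substance_name <- get_txt(sr$substance_name)
  substance_uuid <- get_txt(sr$substance_uuid)
  owner_name <- get_txt(sr$owner_name)
  if (is.null(substance_name) && is.null(substance_uuid)) {
    return(NULL)  # nothing identifies a substance on this iteration unit
  }
  ids <- list()
  for (ide in sr$external_identifiers %||% list()) {
    sys_v <- get_txt(ide$system)
    val_v <- get_txt(ide$value)
    if (!is.null(sys_v) && !is.null(val_v)) {
      ids[[length(ids) + 1L]] <- external_identifier(sys_v, val_v)
    }
  }
  comps <- list()
  for (ce in sr$composition %||% list()) {
    members <- list()
    for (cmp in ce$components) {
      nm <- if (!is.null(cmp$name)) get_txt(cmp$name)
      st <- if (!is.null(cmp$structure)) get_txt(cmp$structure)
      if (is.null(cmp$role)) next
      members[[length(members) + 1L]] <-
        component(role = cmp$role, name = nm, structure = st)
    }
    if (length(members)) comps[[length(comps) + 1L]] <- composition(members)
  }
  rec <- substance_record(
    substance_name = substance_name,
    public_name = get_txt(sr$public_name),
    owner_name = owner_name,
    owner_uuid = get_txt(sr$owner_uuid),
    substance_uuid = substance_uuid,
    substance_type = get_txt(sr$substance_type),
    external_identifiers = ids,
    compositions = comps)
  pas <- list()
  for (pc in config$protocol_applications) {
    pa <- build_protocol_application(wb, pc, cursor, ctx,
                                     rec$substance_uuid)
    if (!is.null(pa)) pas[[length(pas) + 1L]] <- pa
  }
  rec$protocol_applications <- if (length(pas)) pas else NULL
  rec
}

build_protocol_application <- function(wb, pc, cursor, ctx, substance_uuid) {
  get_txt <- function(e) if (is.null(e)) NULL else read_text(wb, e, cursor, ctx)
  params <- list()
  for (nm in names(pc$parameters %||% list())) {
    v <- read_value_obj(wb, pc$parameters[[nm]], cursor, ctx)
    if (!is.null(v)) params[[nm]] <- v
  }
  guidelines <- character()
  for (ge in pc$protocol_guideline %||% list()) {
    v <- get_txt(ge)
    if (!is.null(v)) guidelines <- c(guidelines, v)
  }
  effects <- list()
  for (ec in pc$effects %||% list()) {
    ef <- build_effect(wb, ec, cursor, ctx)
    if (!is.null(ef)) effects[[length(effects) + 1L]] <- ef
  }
  for (bc in pc$effect_blocks %||% list()) {
    effects <- c(effects, expand_effect_block(wb, bc, cursor, ctx))
  }
  if (!length(effects) && !length(params) && !length(guidelines) &&
      is.null(pc$citation_title)) {
    return(NULL)
  }
  protocol_application(
    substance_uuid = substance_uuid,
    citation_title = get_txt(pc$citation_title),
    citation_year = get_txt(pc$citation_year),
    citation_owner = get_txt(pc$citation_owner),
    protocol_guideline = guidelines,
    interpretation_result = get_txt(pc$interpretation_result),
    interpretation_criteria = get_txt(pc$interpretation_criteria),
    parameters = params,
    effects = effects,
    investigation_uuid = get_txt(pc$investigation_uuid),
    assay_uuid = get_txt(pc$assay_uuid),
    reliability_flag = get_txt(pc$reliability_flag))
}

build_effect <- function(wb, ec, cursor, ctx) {
  get_txt <- function(e) if (is.null(e)) NULL else read_text(wb, e, cursor, ctx)
  get_num <- function(e) {
    if (is.null(e)) return(NULL)
    v <- read_cell(wb, e, cursor, ctx)
    if (is.null(v)) return(NULL)
    if (is.numeric(v)) v else NULL
  }
  endpoint <- get_txt(ec$endpoint)
  if (is.null(endpoint)) return(NULL)
  fields <- list(lo_value = get_num(ec$lo_value),
                 up_value = get_num(ec$up_value),
                 lo_qualifier = get_txt(ec$lo_qualifier),
                 up_qualifier = get_txt(ec$up_qualifier),
                 err_value = get_num(ec$err_value),
                 err_qualifier = get_txt(ec$err_qualifier),
                 text_value = get_txt(ec$text_value))
  if (!is.null(ec$value)) {
    v <- read_cell(wb, ec$value, cursor, ctx)
    vf <- effect_value_fields(v, as_value = TRUE)
    fields[names(vf)] <- vf
  }
  if (is.null(ec$value) && !is.null(ec$lo_value)) {
    raw <- read_cell(wb, ec$lo_value, cursor, ctx)
    if (!is.null(raw) && is.character(raw)) {
      vf <- effect_value_fields(raw)
      fields[names(vf)] <- vf
    }
  }
  if (is.null(fields$lo_value) && is.null(fields$up_value) &&
      is.null(fields$text_value)) {
    return(NULL)
  }
  conditions <- list()
  for (nm in names(ec$conditions %||% list())) {
    v <- read_value_obj(wb, ec$conditions[[nm]], cursor, ctx)
    if (!is.null(v)) conditions[[nm]] <- v
  }
  effect_record(endpoint = endpoint,
                sample_id = get_txt(ec$sample_id),
                endpoint_type = get_txt(ec$endpoint_type),
                lo_qualifier = fields$lo_qualifier,
                lo_value = fields$lo_value,
                up_qualifier = fields$up_qualifier,
                up_value = fields$up_value,
                err_qualifier = fields$err_qualifier,
                err_value = fields$err_value,
                text_value = fields$text_value,
                unit = get_txt(ec$unit),
                conditions = conditions)
}

#' Expand a configured block of measurements
#'
#' A measurement block is a rectangular region of the sheet divided into a
#' grid of sub-blocks; each sub-block contains value groups, and every
#' value cell of a group becomes one effect record whose experimental
#' conditions are assembled from the group's parameters (fixed literals,
#' row/column headers, sub-block grid coordinates, or fixed cells). Blank
#' or NA-marked value cells produce no record, so the number of records is
#' exactly the number of non-absent value cells.
#'
#' @param workbook An [workbook()] object.
#' @param block A parsed `EFFECT_BLOCKS` entry (from [load_config()]).
#' @param cursor Iteration cursor (unused by absolute block geometry, kept
#'   for interface symmetry).
#' @param ctx Internal parse context (optional).
#' @return List of [effect_record()] objects.
#' @export
expand_effect_block <- function(workbook, block,
                                cursor = list(current_row = NA_integer_),
                                ctx = NULL) {
  sheet <- wb_sheet(workbook, block$sheet_name, block$sheet_index)
  if (is.null(block$origin) || is.null(block$size)) {
    rlang::abort("Effect block is missing its origin or sub-block size.",
                 class = "fairsheet_parse_error")
  }
  r0 <- block$origin[1]; c0 <- block$origin[2]
  grid <- block$grid %||% c(1L, 1L)
  size <- block$size
  max_row <- r0 + grid[1] * size[1]
  max_col <- c0 + grid[2] * size[2]
  if (max_row > nrow(sheet) || max_col > ncol(sheet)) {
    rlang::abort(sprintf(
      "Effect block at %s exceeds sheet bounds: needs rows up to %d and columns up to %d (0-based), sheet is %d x %d.",
      rc_to_a1(r0 + 1L, c0 + 1L), max_row - 1L, max_col - 1L,
      nrow(sheet), ncol(sheet)),
      class = "fairsheet_parse_error")
  }
  get_txt <- function(e) {
    if (is.null(e)) return(NULL)
    v <- read_cell(workbook, e, cursor, ctx)
    if (is.null(v)) NULL
    else if (is.numeric(v)) format(v, digits = 15, trim = TRUE)
    else as.character(v)
  }
  endpoint <- get_txt(block$shared$endpoint)
  endpoint_type <- get_txt(block$shared$endpoint_type)
  unit <- get_txt(block$shared$unit)
  sample_id <- get_txt(block$shared$sample_id)
  out <- list()
  for (gi in seq_len(grid[1])) {
    for (gj in seq_len(grid[2])) {
      sb_r <- r0 + (gi - 1L) * size[1]   # 0-based origin of this sub-block
      sb_c <- c0 + (gj - 1L) * size[2]
      for (vg in block$value_groups) {
        for (off in vg$values) {
          vr <- sb_r + off[1]            # 0-based absolute value cell
          vc <- sb_c + off[2]
          v <- clean_cell(sheet_cell(sheet, vr + 1L, vc + 1L), ctx)
          if (is.null(v)) next
          conditions <- list()
          for (p in vg$parameters) {
            pv <- block_parameter_value(sheet, p, vr, vc, gi, gj, ctx)
            if (!is.null(pv)) conditions[[p$name]] <- pv
          }
          fields <- effect_value_fields(v, as_value = TRUE)
          out[[length(out) + 1L]] <- effect_record(
            endpoint = endpoint %||% "VALUE",
            sample_id = sample_id,
            endpoint_type = endpoint_type,
            lo_qualifier = fields$lo_qualifier,
            lo_value = fields$lo_value,
            up_qualifier = fields$up_qualifier,
            up_value = fields$up_value,
            text_value = fields$text_value,
            unit = unit,
            conditions = conditions)
        }
      }
    }
  }
  out
}

block_parameter_value <- function(sheet, p, vr, vc, gi, gj, ctx) {
  raw <- switch(p$source,
    JSON_VALUE = p$json_value,
    COLUMN_HEADER = clean_cell(sheet_cell(sheet, p$row_index + 1L, vc + 1L), ctx),
    ROW_HEADER = clean_cell(sheet_cell(sheet, vr + 1L, p$column_index + 1L), ctx),
    SUB_BLOCK_ROW = gi,
    SUB_BLOCK_COL = gj,
    ABSOLUTE_LOCATION = clean_cell(sheet_cell(sheet, p$row_index + 1L,
                                              p$column_index + 1L), ctx),
    NULL)
  if (is.null(raw)) return(NULL)
  if (is.numeric(raw)) model_value(number = as.numeric(raw), unit = p$unit)
  else model_value(text = as.character(raw), unit = p$unit)
}
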