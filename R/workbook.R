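#' In-memory workbook of typed cells
#'
#' The engine operates on a light workbook container: a named list of
#' sheets, each sheet a matrix of cells where every cell is `NULL` (blank),
#' a number, a string, or a logical. Date-typed spreadsheet cells are
#' converted to ISO-8601 text on read. Merged regions are resolved at read
#' time by propagating the anchor cell's value over the covered
#' coordinates, the way template headers label whole groups.
#'
#' @param sheets Named list; each element a list-matrix (`matrix(list(...))`)
#'   or a plain matrix/data.frame (coerced, column types preserved per cell).
#' @return An object of class `fs_workbook`.
#' @export
workbook <- function(sheets) {
  if (is.null(names(sheets)) || any(!nzchar(names(sheets)))) {
    rlang::abort("Every sheet must be named.",
                 class = "fairsheet_invalid_argument")
  }
  sheets <- lapply(sheets, as_cell_matrix)
  structure(list(sheets = sheets), class = "fs_workbook")
}

as_cell_matrix <- function(x) {
  if (is.matrix(x) && is.list(x)) return(x)
  if (is.data.frame(x)) {
    m <- matrix(list(), nrow = nrow(x), ncol = ncol(x))
    for (j in seq_len(ncol(x))) {
      for (i in seq_len(nrow(x))) {
        v <- x[[j]][[i]]
        if (!is.null(v) && length(v) == 1L && is.na(v)) v <- NULL
        m[[i, j]] <- v
      }
    }
    return(m)
  }
  if (is.matrix(x)) {
    m <- matrix(list(), nrow = nrow(x), ncol = ncol(x))
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      v <- x[[i, j]]
      if (length(v) == 1L && is.na(v)) v <- NULL
      m[[i, j]] <- v
    }
    return(m)
  }
  rlang::abort("Cannot interpret sheet content as a cell matrix.",
               class = "fairsheet_invalid_argument")
}

#' @export
print.fs_workbook <- function(x, ...) {
  cat("<workbook>", length(x$sheets), "sheet(s)\n")
  for (nm in names(x$sheets)) {
    cat(sprintf("  %s: %d x %d\n", nm, nrow(x$sheets[[nm]]),
                ncol(x$sheets[[nm]])))
  }
  invisible(x)
}

#' Sheet names of a workbook
#' @param wb An `fs_workbook`.
#' @return Character vector.
#' @export
sheet_names <- function(wb) names(wb$sheets)

# resolve a sheet reference: exact name wins over 0-based index
wb_sheet <- function(wb, sheet_name = NULL, sheet_index = NULL) {
  if (!is.null(sheet_name)) {
    if (!sheet_name %in% names(wb$sheets)) {
      rlang::abort(sprintf("Sheet \"%s\" not found (sheets: %s).", sheet_name,
                           paste(names(wb$sheets), collapse = ", ")),
                   class = "fairsheet_sheet_error")
    }
    return(wb$sheets[[sheet_name]])
  }
  i <- (sheet_index %||% 0) + 1L
  if (i < 1L || i > length(wb$sheets)) {
    rlang::abort(sprintf("Sheet index %d out of range (workbook has %d sheets).",
                         i - 1L, length(wb$sheets)),
                 class = "fairsheet_sheet_error")
  }
  wb$sheets[[i]]
}

# 1-based cell access; NULL when out of bounds or blank
sheet_cell <- function(sheet, row, col) {
  if (row < 1L || col < 1L || row > nrow(sheet) || col > ncol(sheet)) {
    return(NULL)
  }
  sheet[[row, col]]
}

#' Read a workbook
#'
#' Reads an XLSX file (through readxl, keeping per-cell types) or the
#' package's plain-text JSON workbook format, into an [workbook()] object.
#' For XLSX, merged regions are detected from the worksheet XML and the
#' anchor value is propagated across the covered cells.
#'
#' @param path Path to an `.xlsx` or `.json` workbook file.
#' @return An `fs_workbook`.
#' @export
read_workbook <- function(path) {
  if (inherits(path, "fs_workbook")) return(path)
  if (!file.exists(path)) {
    rlang::abort(sprintf("Workbook file not found: %s", path),
                 class = "fairsheet_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xlsm")) return(read_workbook_xlsx(path))
  if (ext == "json") return(workbook_from_json(readLines(path, warn = FALSE)))
  rlang::abort(sprintf("Unsupported workbook format: .%s", ext),
               class = "fairsheet_io_error")
}

read_workbook_xlsx <- function(path) {
  sheet_nms <- readxl::excel_sheets(path)
  sheets <- list()
  for (si in seq_along(sheet_nms)) {
    suppressMessages(df <- tryCatch(
      readxl::read_excel(path, sheet = si, col_names = FALSE,
                         col_types = "list", trim_ws = FALSE,
                         range = readxl::cell_limits(c(1L, 1L), c(NA, NA))),
      error = function(e) NULL))
    if (is.null(df) || nrow(df) == 0L || ncol(df) == 0L) {
      sheets[[sheet_nms[si]]] <- matrix(list(), 0L, 0L)
      next
    }
    m <- matrix(list(), nrow = nrow(df), ncol = ncol(df))
    for (j in seq_len(ncol(df))) {
      colj <- df[[j]]
      for (i in seq_len(nrow(df))) {
        v <- colj[[i]]
        if (is.null(v) || (length(v) == 1L && is.na(v))) next
        if (inherits(v, "POSIXt") || inherits(v, "Date")) {
          v <- iso8601(v)
        }
        m[[i, j]] <- v
      }
    }
    sheets[[sheet_nms[si]]] <- m
  }
  wb <- workbook(sheets)
  merges <- xlsx_merged_ranges(path, sheet_nms)
  for (nm in names(merges)) {
    wb$sheets[[nm]] <- propagate_merges(wb$sheets[[nm]], merges[[nm]])
  }
  wb
}

iso8601 <- function(v) {
  v <- as.POSIXct(v, tz = "UTC")
  if (format(v, "%H%M%S") == "000000") format(v, "%Y-%m-%d")
  else format(v, "%Y-%m-%dT%H:%M:%S")
}

# merged ranges per sheet, by reading the worksheet XML parts directly
xlsx_merged_ranges <- function(path, sheet_nms) {
  tmp <- tempfile("xlsxpeek")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  parts <- tryCatch(utils::unzip(path, exdir = tmp), error = function(e) character())
  wbxml <- file.path(tmp, "xl", "workbook.xml")
  relxml <- file.path(tmp, "xl", "_rels", "workbook.xml.rels")
  if (!file.exists(wbxml) || !file.exists(relxml)) return(list())
  wbdoc <- xml2::read_xml(wbxml)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(wbdoc), d1 = "m")
  sheets <- xml2::xml_find_all(wbdoc, ".//m:sheets/m:sheet", ns)
  rids <- xml2::xml_attr(sheets, "r:id")
  if (all(is.na(rids))) rids <- xml2::xml_attr(sheets, "id")
  nms <- xml2::xml_attr(sheets, "name")
  reldoc <- xml2::read_xml(relxml)
  rels <- xml2::xml_find_all(reldoc, ".//*[local-name()='Relationship']")
  relmap <- stats::setNames(xml2::xml_attr(rels, "Target"),
                            xml2::xml_attr(rels, "Id"))
  out <- list()
  for (k in seq_along(nms)) {
    if (is.na(rids[k]) || !rids[k] %in% names(relmap)) next
    target <- relmap[[rids[k]]]
    if (is.null(target) || is.na(target)) next
    p <- file.path(tmp, "xl", sub("^/?(xl/)?", "", target))
    if (!file.exists(p)) p <- file.path(tmp, sub("^/", "", target))
    if (!file.exists(p)) next
    sdoc <- xml2::read_xml(p)
    mc <- xml2::xml_find_all(sdoc, ".//*[local-name()='mergeCell']")
    refs <- xml2::xml_attr(mc, "ref")
    if (length(refs)) out[[nms[k]]] <- refs
  }
  out
}

propagate_merges <- function(sheet, refs) {
  for (ref in refs) {
    corners <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (length(corners) != 2L) next
    a <- a1_to_rc(corners[1]); b <- a1_to_rc(corners[2])
    if (a[1] > nrow(sheet) || a[2] > ncol(sheet)) next
    anchor <- sheet[[a[1], a[2]]]
    if (is.null(anchor)) next
    for (i in a[1]:min(b[1], nrow(sheet))) {
      for (j in a[2]:min(b[2], ncol(sheet))) {
        if (is.null(sheet[[i, j]])) sheet[[i, j]] <- anchor
      }
    }
  }
  sheet
}

#' Convert between A1 notation and 0-based row/column indices
#'
#' @param ref An A1-style cell reference such as `"B3"`.
#' @return For `a1_to_rc`, an integer vector `c(row, col)` (1-based,
#'   internal convention); for `rc_to_a1`, the A1 string for 1-based
#'   `row`/`col`.
#' @keywords internal
a1_to_rc <- function(ref) {
  m <- regmatches(ref, regexec("^\\$?([A-Za-z]+)\\$?([0-9]+)$", ref))[[1]]
  if (length(m) != 3L) {
    rlang::abort(sprintf("Not an A1 cell reference: \"%s\"", ref),
                 class = "fairsheet_invalid_argument")
  }
  c(as.integer(m[3]), col_letter_to_index(m[2]) + 1L)
}

rc_to_a1 <- function(row, col) {
  paste0(col_index_to_letter(col - 1L), row)
}

#' Convert a column letter to a 0-based index and back
#' @param letters Column letters, e.g. `"A"`, `"AB"`.
#' @return 0-based integer index.
#' @keywords internal
col_letter_to_index <- function(letters) {
  chars <- strsplit(toupper(letters), "")[[1]]
  as.integer(sum((match(chars, LETTERS)) * 26^(rev(seq_along(chars)) - 1L)) - 1L)
}

col_index_to_letter <- function(i) {
  i <- as.integer(i)
  out <- ""
  repeat {
    out <- paste0(LETTERS[(i %% 26L) + 1L], out)
    i <- i %/% 26L - 1L
    if (i < 0L) break
  }
  out
}

#' Write a workbook
#'
#' Writes an [workbook()] object either as a plain XLSX file (inline
#' strings and numbers, no styling) or as the package's JSON workbook
#' format. XLSX output is deterministic: the archive member timestamps are
#' pinned, so the same workbook always produces byte-identical files.
#'
#' @param wb An `fs_workbook`.
#' @param path Output path; format chosen by extension (`.xlsx` or `.json`).
#' @return `path`, invisibly.
#' @export
write_workbook <- function(wb, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") write_workbook_xlsx(wb, path)
  else if (ext == "json") writeLines(workbook_to_json(wb), path, useBytes = TRUE)
  else rlang::abort(sprintf("Unsupported workbook format: .%s", ext),
                    class = "fairsheet_io_error")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

cell_xml <- function(v, row, col) {
  ref <- rc_to_a1(row, col)
  if (is.numeric(v)) {
    sprintf('<c r="%s"><v>%s</v></c>', ref, formatC(v, digits = 17, format = "g"))
  } else if (is.logical(v)) {
    sprintf('<c r="%s" t="b"><v>%d</v></c>', ref, as.integer(v))
  } else {
    sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            ref, xml_escape(as.character(v)))
  }
}

sheet_xml <- function(m) {
  rows <- character()
  for (i in seq_len(nrow(m))) {
    cells <- character()
    for (j in seq_len(ncol(m))) {
      v <- m[[i, j]]
      if (is.null(v)) next
      cells <- c(cells, cell_xml(v, i, j))
    }
    if (length(cells)) {
      rows <- c(rows, sprintf('<row r="%d">%s</row>', i,
                              paste(cells, collapse = "")))
    }
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

write_workbook_xlsx <- function(wb, path) {
  d <- tempfile("fswb")
  dir.create(file.path(d, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(d, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(d, "_rels"), recursive = TRUE)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  n <- length(wb$sheets)
  overrides <- paste(sprintf(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    overrides, '</Types>'), file.path(d, "[Content_Types].xml"), useBytes = TRUE)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(d, "_rels", ".rels"), useBytes = TRUE)
  sheets_xml <- paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                              xml_escape(names(wb$sheets)), seq_len(n),
                              seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', sheets_xml, '</sheets></workbook>'),
    file.path(d, "xl", "workbook.xml"), useBytes = TRUE)
  rels <- paste(sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
    seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rels, '</Relationships>'),
    file.path(d, "xl", "_rels", "workbook.xml.rels"), useBytes = TRUE)
  for (k in seq_len(n)) {
    writeLines(sheet_xml(wb$sheets[[k]]),
               file.path(d, "xl", "worksheets", sprintf("sheet%d.xml", k)),
               useBytes = TRUE)
  }
  files <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels",
             sprintf("xl/worksheets/sheet%d.xml", seq_len(n)))
  # pin timestamps so identical content yields byte-identical archives
  Sys.setFileTime(file.path(d, files),
                  as.POSIXct("2000-01-01 00:00:00", tz = "UTC"))
  Sys.setFileTime(list.dirs(d, recursive = TRUE),
                  as.POSIXct("2000-01-01 00:00:00", tz = "UTC"))
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE), files, root = d,
           mode = "mirror")
  invisible(path)
}

#' JSON workbook interchange
#'
#' A plain-text serialization of a workbook: an object mapping sheet names
#' to row-major arrays of cells (`null`, number, string or boolean). Used
#' for version-controllable fixtures and diffable intermediates.
#'
#' @param wb An `fs_workbook`.
#' @param json JSON text as produced by `workbook_to_json()`.
#' @return `workbook_to_json()` returns a JSON string; `workbook_from_json()`
#'   an `fs_workbook`.
#' @export
workbook_to_json <- function(wb) {
  out <- lapply(wb$sheets, function(m) {
    lapply(seq_len(nrow(m)), function(i) {
      lapply(seq_len(ncol(m)), function(j) m[[i, j]])
    })
  })
  jsonlite::toJSON(out, auto_unbox = TRUE, null = "null", digits = NA)
}

#' @rdname workbook_to_json
#' @export
workbook_from_json <- function(json) {
  x <- jsonlite::parse_json(paste(json, collapse = "\n"))
  sheets <- lapply(x, function(rows) {
    ncols <- max(c(0L, vapply(rows, length, integer(1))))
    m <- matrix(list(), nrow = length(rows), ncol = ncols)
    for (i in seq_along(rows)) {
      for (j in seq_along(rows[[i]])) {
        v <- rows[[i]][[j]]
        if (is.null(v)) next
        m[[i, j]] <- if (is.numeric(v)) as.numeric(v) else v
      }
    }
    m
  })
  workbook(sheets)
}
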