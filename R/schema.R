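#' Machine-readable schema of the configuration dialect
#'
#' Emits a JSON Schema document (a pragmatic draft-07 subset: `type`,
#' `properties`, `required`, `items`, `enum`, `additionalProperties`,
#' `oneOf`) describing the mapping-configuration dialect, for use by
#' external validators and editors. The same document ships under
#' `inst/schema/parser-config.schema.json`.
#'
#' @return JSON text.
#' @export
emit_schema <- function() {
  colref <- list(oneOf = list(
    list(type = "integer", minimum = 0L),
    list(type = "string", pattern = "^[A-Za-z]{1,3}$")))
  edl_schema <- list(oneOf = list(
    list(type = "object",
         additionalProperties = FALSE,
         properties = list(
           ITERATION = list(enum = as.list(ITERATION_MODES)),
           SHEET_INDEX = list(type = "integer", minimum = 0L),
           SHEET_NAME = list(type = "string"),
           ROW_INDEX = list(type = "integer", minimum = 0L),
           COLUMN_INDEX = colref,
           JSON_VALUE = list(type = c("string", "number", "boolean")),
           UNIT = list(type = "string"))),
    colref$oneOf[[1]], colref$oneOf[[2]]))
  named_edls <- list(type = "object", additionalProperties = edl_schema)
  offset <- list(type = "object", additionalProperties = FALSE,
                 required = list("ROW_OFFSET", "COLUMN_OFFSET"),
                 properties = list(
                   ROW_OFFSET = list(type = "integer", minimum = 0L),
                   COLUMN_OFFSET = list(type = "integer", minimum = 0L)))
  param <- list(type = "object", additionalProperties = FALSE,
                required = list("NAME", "SOURCE"),
                properties = list(
                  NAME = list(type = "string"),
                  SOURCE = list(enum = as.list(PARAM_SOURCES)),
                  JSON_VALUE = list(type = c("string", "number", "boolean")),
                  ROW_INDEX = list(type = "integer", minimum = 0L),
                  COLUMN_INDEX = colref,
                  UNIT = list(type = "string")))
  value_group <- list(type = "object", additionalProperties = FALSE,
                      required = list("VALUES"),
                      properties = list(
                        NAME = list(type = "string"),
                        VALUES = list(type = "array", items = offset),
                        PARAMETERS = list(type = "array", items = param)))
  rowcol <- list(type = "object", additionalProperties = FALSE,
                 required = list("ROWS", "COLUMNS"),
                 properties = list(
                   ROWS = list(type = "integer", minimum = 1L),
                   COLUMNS = list(type = "integer", minimum = 1L)))
  block <- list(type = "object", additionalProperties = FALSE,
                required = list("BLOCK_ORIGIN", "SUB_BLOCK_SIZE", "ENDPOINT",
                                "VALUE_GROUPS"),
                properties = list(
                  BLOCK_ORIGIN = list(
                    type = "object", additionalProperties = FALSE,
                    required = list("ROW_INDEX", "COLUMN_INDEX"),
                    properties = list(
                      ROW_INDEX = list(type = "integer", minimum = 0L),
                      COLUMN_INDEX = colref)),
                  SUB_BLOCK_GRID = rowcol,
                  SUB_BLOCK_SIZE = rowcol,
                  SHEET_INDEX = list(type = "integer", minimum = 0L),
                  SHEET_NAME = list(type = "string"),
                  ENDPOINT = edl_schema,
                  ENDPOINT_TYPE = edl_schema,
                  UNIT = edl_schema,
                  SAMPLE_ID = edl_schema,
                  VALUE_GROUPS = list(type = "array", items = value_group)))
  effect <- list(type = "object", additionalProperties = FALSE,
                 required = list("ENDPOINT"),
                 properties = c(
                   stats::setNames(rep(list(edl_schema),
                                       length(EFFECT_KEYS) - 1L),
                                   setdiff(EFFECT_KEYS, "CONDITIONS")),
                   list(CONDITIONS = named_edls)))
  ext_id <- list(type = "object", additionalProperties = FALSE,
                 required = list("SYSTEM", "VALUE"),
                 properties = list(SYSTEM = edl_schema, VALUE = edl_schema))
  comp <- list(type = "object", additionalProperties = FALSE,
               required = list("COMPONENTS"),
               properties = list(COMPONENTS = list(
                 type = "array",
                 items = list(type = "object", additionalProperties = FALSE,
                              required = list("ROLE"),
                              properties = list(
                                ROLE = list(enum = as.list(COMPONENT_ROLES)),
                                NAME = edl_schema,
                                STRUCTURE = edl_schema)))))
  pa <- list(type = "object", additionalProperties = FALSE,
             properties = c(
               stats::setNames(rep(list(edl_schema), 9L),
                               c("CITATION_TITLE", "CITATION_YEAR",
                                 "CITATION_OWNER", "INTERPRETATION_RESULT",
                                 "INTERPRETATION_CRITERIA",
                                 "INVESTIGATION_UUID", "ASSAY_UUID",
                                 "RELIABILITY_FLAG", "PROTOCOL_GUIDELINE")),
               list(PARAMETERS = named_edls,
                    EFFECTS = list(type = "array", items = effect),
                    EFFECT_BLOCKS = list(type = "array", items = block))))
  pa$properties$PROTOCOL_GUIDELINE <- list(oneOf = c(
    edl_schema$oneOf, list(list(type = "array", items = edl_schema))))
  schema <- list(
    `$schema` = "http://json-schema.org/draft-07/schema#",
    title = "fairsheet parser configuration",
    type = "object",
    additionalProperties = TRUE,
    required = list("DATA_ACCESS", "SUBSTANCE_RECORD"),
    properties = list(
      DATA_ACCESS = list(
        type = "object", additionalProperties = FALSE,
        required = list("ITERATION"),
        properties = list(
          ITERATION = list(enum = as.list(ITERATION_MODES)),
          SHEET_INDEX = list(type = "integer", minimum = 0L),
          SHEET_NAME = list(type = "string"),
          ROW_START = list(type = "integer", minimum = 0L),
          ROW_END = list(type = "integer", minimum = 0L),
          STOP_ON_BLANK_ROWS = list(type = "integer", minimum = 1L),
          NA_MARKERS = list(type = "array",
                            items = list(type = "string")))),
      SUBSTANCE_RECORD = list(
        type = "object", additionalProperties = FALSE,
        properties = c(
          stats::setNames(rep(list(edl_schema), 6L),
                          c("SUBSTANCE_NAME", "PUBLIC_NAME", "OWNER_NAME",
                            "OWNER_UUID", "SUBSTANCE_UUID",
                            "SUBSTANCE_TYPE")),
          list(EXTERNAL_IDENTIFIERS = list(type = "array", items = ext_id),
               COMPOSITION = list(type = "array", items = comp)))),
      PROTOCOL_APPLICATIONS = list(type = "array", items = pa)))
  jsonlite::toJSON(schema, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Check a JSON document against a restricted JSON Schema
#'
#' A small structural checker for the schema subset the package emits and
#' ships (`type`, `properties`, `required`, `additionalProperties`, `items`,
#' `enum`, `oneOf`, `minimum`, `pattern`). Used to validate configurations
#' against [emit_schema()] output and serialized documents against the
#' bundled ISA material-extension schema.
#'
#' @param x Parsed JSON (as from `jsonlite::parse_json()`), JSON text, or a
#'   file path.
#' @param schema Parsed schema, schema JSON text, or a file path.
#' @return Character vector of problems, empty when the document conforms.
#' @export
check_schema <- function(x, schema) {
  x <- as_parsed_json(x)
  schema <- as_parsed_json(schema)
  schema_walk(x, schema, "$")
}

as_parsed_json <- function(x) {
  if (is.character(x)) {
    if (length(x) == 1L && !grepl("[{\\[]", x) && file.exists(x)) {
      x <- readLines(x, warn = FALSE)
    }
    x <- tryCatch(jsonlite::parse_json(paste(x, collapse = "\n")),
                  error = function(e) {
                    rlang::abort(paste0("Not valid JSON: ",
                                        conditionMessage(e)),
                                 class = "fairsheet_json_error")
                  })
  }
  x
}

schema_type_of <- function(x) {
  if (is.null(x)) "null"
  else if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) "object" else "array"
  }
  else if (is.character(x)) "string"
  else if (is.logical(x)) "boolean"
  else if (is.numeric(x)) {
    if (x == floor(x)) "integer" else "number"
  }
  else "unknown"
}

schema_walk <- function(x, sch, path) {
  probs <- character()
  if (!is.null(sch$oneOf)) {
    branches <- lapply(sch$oneOf, function(s) schema_walk(x, s, path))
    if (!any(vapply(branches, length, integer(1)) == 0L)) {
      probs <- c(probs, sprintf("%s: matches none of the allowed forms (%s)",
                                path, paste(unique(unlist(branches)),
                                            collapse = "; ")))
    }
    return(probs)
  }
  if (!is.null(sch$enum)) {
    hit <- any(vapply(sch$enum, function(e) identical(e, x), logical(1)))
    if (!hit) {
      probs <- c(probs, sprintf("%s: value %s not in enum {%s}", path,
                                deparse(x),
                                paste(unlist(sch$enum), collapse = ", ")))
    }
    return(probs)
  }
  if (!is.null(sch$type)) {
    want <- unlist(sch$type)
    have <- schema_type_of(x)
    ok <- have %in% want || (have == "integer" && "number" %in% want) ||
      (have == "array" && "object" %in% want && length(x) == 0L)
    if (!ok) {
      return(sprintf("%s: expected %s, found %s", path,
                     paste(want, collapse = "|"), have))
    }
  }
  if (!is.null(sch$minimum) && is.numeric(x) && x < sch$minimum) {
    probs <- c(probs, sprintf("%s: %s below minimum %s", path, format(x),
                              format(sch$minimum)))
  }
  if (!is.null(sch$pattern) && is.character(x) &&
      !grepl(sch$pattern, x, perl = TRUE)) {
    probs <- c(probs, sprintf("%s: \"%s\" does not match pattern %s", path,
                              x, sch$pattern))
  }
  if (identical(schema_type_of(x), "object")) {
    for (r in unlist(sch$required)) {
      if (is.null(x[[r]])) {
        probs <- c(probs, sprintf("%s.%s: required key missing", path, r))
      }
    }
    for (nm in names(x)) {
      sub <- sch$properties[[nm]]
      if (is.null(sub)) {
        ap <- sch$additionalProperties
        if (isFALSE(ap)) {
          probs <- c(probs, sprintf("%s.%s: key not allowed here", path, nm))
        } else if (is.list(ap)) {
          probs <- c(probs, schema_walk(x[[nm]], ap,
                                        paste0(path, ".", nm)))
        }
      } else {
        probs <- c(probs, schema_walk(x[[nm]], sub, paste0(path, ".", nm)))
      }
    }
  }
  if (identical(schema_type_of(x), "array") && !is.null(sch$items)) {
    for (i in seq_along(x)) {
      probs <- c(probs, schema_walk(x[[i]], sch$items,
                                    sprintf("%s[%d]", path, i - 1L)))
    }
  }
  probs
}
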