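# run code under a fixed seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic template workbook
#'
#' Describes a fixture to generate: either a row-per-substance layout
#' (one header row, one substance per data row, as in project-consortium
#' physicochemical templates) or a block layout (a single substance whose
#' dose-response measurements sit in a grid of replicate sub-blocks with
#' per-time value groups over a concentration series, as in
#' occupational-medicine style assay sheets).
#'
#' Measurement values are drawn from a seeded log-normal with a
#' configurable absent-cell probability — enough to exercise NA handling
#' and the record-count laws without making biological claims.
#'
#' @param layout `"ROW_LAYOUT"` or `"BLOCK_LAYOUT"`.
#' @param n_substances Number of substances (row layout).
#' @param seed Mandatory integer seed; generation is fully deterministic.
#' @param replicates,times,concentrations Block geometry (block layout).
#' @param meanlog,sdlog Log-normal parameters of the measured values.
#' @param absent_prob Probability that a value cell is left blank.
#' @return An object of class `fs_template_spec`.
#' @export
template_spec <- function(layout = c("ROW_LAYOUT", "BLOCK_LAYOUT"),
                          n_substances = 3L, seed,
                          replicates = 2L, times = 2L, concentrations = 9L,
                          meanlog = 3, sdlog = 0.4, absent_prob = 0) {
  layout <- match.arg(layout)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    rlang::abort("`seed` is mandatory: fixtures must be reproducible.",
                 class = "fairsheet_invalid_argument")
  }
  if (layout == "BLOCK_LAYOUT" &&
      (replicates < 1L || times < 1L || concentrations < 1L)) {
    rlang::abort("Block geometry must be at least 1 x 1 x 1.",
                 class = "fairsheet_invalid_argument")
  }
  if (n_substances < 0L) {
    rlang::abort("`n_substances` must be non-negative.",
                 class = "fairsheet_invalid_argument")
  }
  structure(list(layout = layout, n_substances = as.integer(n_substances),
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 times = as.integer(times),
                 concentrations = as.integer(concentrations),
                 meanlog = meanlog, sdlog = sdlog,
                 absent_prob = absent_prob),
            class = "fs_template_spec")
}

#' Generate a synthetic workbook with its mapping and ground truth
#'
#' Produces three mutually consistent artifacts from one seeded
#' specification: a workbook in the requested layout family, a parser
#' configuration that maps it, and the expected substance records. Running
#' [parse_workbook()] on the workbook with the companion configuration must
#' reproduce the expected records exactly — the package's central
#' end-to-end property.
#'
#' @param spec A [template_spec()].
#' @return List with elements `workbook` (an [workbook()]), `config`
#'   (`fs_parser_config`), `config_json` (the same mapping as JSON text)
#'   and `records` (list of [substance_record()]).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fs_template_spec"))
  local_seed(spec$seed, {
    if (spec$layout == "ROW_LAYOUT") row_layout_fixture(spec)
    else block_layout_fixture(spec)
  })
}

row_layout_fixture <- function(spec) {
  n <- spec$n_substances
  header <- c("Substance name", "CAS number", "Supplier",
              "Zeta potential", "pH")
  nmcode <- sprintf("NM-%03d", 100L + seq_len(n))
  cas <- sprintf("%d-%02d-%d", sample(10000:99999, n, replace = TRUE),
                 sample(10:99, n, replace = TRUE), sample(0:9, n, TRUE))
  supplier <- sample(c("LabOne", "NanoWorks", "OxideCo"), n, replace = TRUE)
  zeta <- round(-stats::rlnorm(n, spec$meanlog, spec$sdlog), 2)
  ph <- round(stats::runif(n, 5, 9), 1)
  zeta_absent <- stats::runif(n) < spec$absent_prob
  m <- matrix(list(), nrow = n + 1L, ncol = length(header))
  for (j in seq_along(header)) m[[1L, j]] <- header[j]
  for (i in seq_len(n)) {
    m[[i + 1L, 1L]] <- nmcode[i]
    m[[i + 1L, 2L]] <- cas[i]
    m[[i + 1L, 3L]] <- supplier[i]
    if (!zeta_absent[i]) m[[i + 1L, 4L]] <- zeta[i]
    m[[i + 1L, 5L]] <- ph[i]
  }
  cfg_list <- list(
    DATA_ACCESS = list(ITERATION = "ROW_SINGLE", SHEET_INDEX = 0L,
                       ROW_START = 1L, STOP_ON_BLANK_ROWS = 2L),
    SUBSTANCE_RECORD = list(
      SUBSTANCE_NAME = list(COLUMN_INDEX = 0L),
      OWNER_NAME = list(COLUMN_INDEX = 2L),
      EXTERNAL_IDENTIFIERS = list(
        list(SYSTEM = list(JSON_VALUE = "CASRN"),
             VALUE = list(COLUMN_INDEX = 1L)))),
    PROTOCOL_APPLICATIONS = list(list(
      CITATION_TITLE = list(JSON_VALUE = "Synthetic surface-charge assay"),
      PARAMETERS = list(medium = list(JSON_VALUE = "water")),
      EFFECTS = list(list(
        ENDPOINT = list(JSON_VALUE = "ZETA POTENTIAL"),
        VALUE = list(COLUMN_INDEX = 3L),
        UNIT = list(JSON_VALUE = "mV"),
        CONDITIONS = list(pH = list(COLUMN_INDEX = 4L)))))))
  config_json <- jsonlite::toJSON(cfg_list, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA)
  records <- lapply(seq_len(n), function(i) {
    uuid <- generate_uuid("SUBSTANCE", c(nmcode[i], supplier[i]))
    effects <- if (!zeta_absent[i]) {
      list(effect_record(endpoint = "ZETA POTENTIAL",
                         lo_qualifier = "=", lo_value = zeta[i],
                         unit = "mV",
                         conditions = list(pH = model_value(number = ph[i]))))
    } else list()
    substance_record(
      substance_name = nmcode[i], owner_name = supplier[i],
      external_identifiers = list(external_identifier("CASRN", cas[i])),
      protocol_applications = list(protocol_application(
        substance_uuid = uuid,
        citation_title = "Synthetic surface-charge assay",
        parameters = list(medium = model_value(text = "water")),
        effects = effects)))
  })
  list(workbook = workbook(list(Materials = m)),
       config = suppressWarnings(load_config(config_json)),
       config_json = config_json, records = records)
}

block_layout_fixture <- function(spec) {
  reps <- spec$replicates; times <- spec$times; K <- spec$concentrations
  conc <- signif(10 * 2^(seq_len(K) - 1L), 3)
  time_h <- seq_len(times) * 24
  # Test conditions sheet: substance identity at fixed cells
  tc <- matrix(list(), nrow = 6L, ncol = 2L)
  tc[[1L, 1L]] <- "Test substance"
  tc[[2L, 1L]] <- "Name"; tc[[2L, 2L]] <- "NM-203"
  tc[[3L, 1L]] <- "CAS number"; tc[[3L, 2L]] <- "14808-60-7"
  tc[[4L, 1L]] <- "Assay"; tc[[4L, 2L]] <- "Colony forming efficiency"
  tc[[5L, 1L]] <- "Laboratory"; tc[[5L, 2L]] <- "LabOne"
  # Test results sheet: header rows, then replicate sub-blocks of time rows
  nrow_res <- 3L + reps * times
  res <- matrix(list(), nrow = nrow_res, ncol = 2L + K)
  res[[1L, 1L]] <- "Colony Forming Efficiency"
  res[[2L, 2L]] <- "Concentration (ug/mL)"
  for (j in seq_len(K)) res[[2L, 2L + j]] <- conc[j]
  res[[3L, 1L]] <- "Replicate"; res[[3L, 2L]] <- "Time (h)"
  for (j in seq_len(K)) res[[3L, 2L + j]] <- sprintf("C%d", j)
  values <- array(stats::rlnorm(reps * times * K, spec$meanlog, spec$sdlog),
                  dim = c(reps, times, K))
  values <- round(values, 2)
  absent <- array(stats::runif(reps * times * K) < spec$absent_prob,
                  dim = c(reps, times, K))
  for (ri in seq_len(reps)) {
    for (ti in seq_len(times)) {
      row <- 3L + (ri - 1L) * times + ti
      res[[row, 1L]] <- ri
      res[[row, 2L]] <- time_h[ti]
      for (j in seq_len(K)) {
        if (!absent[ri, ti, j]) res[[row, 2L + j]] <- values[ri, ti, j]
      }
    }
  }
  value_groups <- lapply(seq_len(times), function(ti) {
    list(NAME = sprintf("T%d", ti),
         VALUES = lapply(seq_len(K), function(j) {
           list(ROW_OFFSET = ti - 1L, COLUMN_OFFSET = j - 1L)
         }),
         PARAMETERS = list(
           list(NAME = "concentration", SOURCE = "COLUMN_HEADER",
                ROW_INDEX = 1L, UNIT = "ug/mL"),
           list(NAME = "time", SOURCE = "ROW_HEADER", COLUMN_INDEX = 1L,
                UNIT = "h"),
           list(NAME = "replicate", SOURCE = "SUB_BLOCK_ROW")))
  })
  cfg_list <- list(
    DATA_ACCESS = list(ITERATION = "ABSOLUTE_LOCATION",
                       SHEET_NAME = "Test conditions"),
    SUBSTANCE_RECORD = list(
      SUBSTANCE_NAME = list(ROW_INDEX = 1L, COLUMN_INDEX = 1L),
      EXTERNAL_IDENTIFIERS = list(
        list(SYSTEM = list(JSON_VALUE = "CASRN"),
             VALUE = list(ROW_INDEX = 2L, COLUMN_INDEX = 1L)))),
    PROTOCOL_APPLICATIONS = list(list(
      CITATION_TITLE = list(ROW_INDEX = 3L, COLUMN_INDEX = 1L),
      CITATION_OWNER = list(ROW_INDEX = 4L, COLUMN_INDEX = 1L),
      EFFECT_BLOCKS = list(list(
        SHEET_NAME = "Test results",
        BLOCK_ORIGIN = list(ROW_INDEX = 3L, COLUMN_INDEX = 2L),
        SUB_BLOCK_GRID = list(ROWS = reps, COLUMNS = 1L),
        SUB_BLOCK_SIZE = list(ROWS = times, COLUMNS = K),
        ENDPOINT = list(JSON_VALUE = "COLONY FORMING EFFICIENCY"),
        UNIT = list(JSON_VALUE = "%"),
        VALUE_GROUPS = value_groups)))))
  config_json <- jsonlite::toJSON(cfg_list, auto_unbox = TRUE, pretty = TRUE,
                                  digits = NA)
  uuid <- generate_uuid("SUBSTANCE", c("NM-203", ""))
  effects <- list()
  for (ri in seq_len(reps)) {
    for (ti in seq_len(times)) {
      for (j in seq_len(K)) {
        if (absent[ri, ti, j]) next
        effects[[length(effects) + 1L]] <- effect_record(
          endpoint = "COLONY FORMING EFFICIENCY",
          lo_qualifier = "=", lo_value = values[ri, ti, j], unit = "%",
          conditions = list(
            concentration = model_value(number = conc[j], unit = "ug/mL"),
            time = model_value(number = time_h[ti], unit = "h"),
            replicate = model_value(number = ri)))
      }
    }
  }
  records <- list(substance_record(
    substance_name = "NM-203",
    external_identifiers = list(external_identifier("CASRN", "14808-60-7")),
    protocol_applications = list(protocol_application(
      substance_uuid = uuid,
      citation_title = "Colony forming efficiency",
      citation_owner = "LabOne",
      effects = effects))))
  list(workbook = workbook(list(`Test conditions` = tc,
                                `Test results` = res)),
       config = suppressWarnings(load_config(config_json)),
       config_json = config_json, records = records)
}

#' Extract a field inventory from a template workbook
#'
#' Walks every sheet and lists the non-blank cells with an inferred kind:
#' `"data"` for numeric or logical cells, `"label"` for text. A text cell
#' additionally counts as a header (`is_header`) when its column contains
#' at least one numeric cell below it — a simple, documented and
#' overridable heuristic for row-per-substance templates.
#'
#' @param workbook An [workbook()] or a readable path.
#' @return Tibble with columns `sheet`, `cell` (A1), `row`, `column`
#'   (0-based), `text`, `kind`, `is_header`.
#' @export
extract_template_fields <- function(workbook) {
  wb <- read_workbook(workbook)
  rows <- list()
  for (nm in names(wb$sheets)) {
    m <- wb$sheets[[nm]]
    if (!nrow(m) || !ncol(m)) next
    numeric_below <- function(i, j) {
      if (i >= nrow(m)) return(FALSE)
      any(vapply((i + 1L):nrow(m), function(k) {
        is.numeric(m[[k, j]])
      }, logical(1)))
    }
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        v <- m[[i, j]]
        if (is.null(v)) next
        kind <- if (is.numeric(v) || is.logical(v)) "data" else "label"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sheet = nm, cell = rc_to_a1(i, j), row = i - 1L, column = j - 1L,
          text = as.character(v), kind = kind,
          is_header = kind == "label" && numeric_below(i, j))
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(sheet = character(), cell = character(),
                          row = integer(), column = integer(),
                          text = character(), kind = character(),
                          is_header = logical()))
  }
  do.call(rbind, rows)
}

#' Draft a skeleton mapping configuration from a field inventory
#'
#' Builds a syntactically valid starting configuration for a curator: the
#' first detected header column on the first sheet is bound to the
#' substance name, every further header becomes a protocol-application
#' parameter whose name is flagged `TODO:` for manual model binding, and a
#' top-level `_TODO` note marks the draft as unreviewed. [load_config()]
#' accepts the result (with warnings).
#'
#' @param inventory Tibble from [extract_template_fields()].
#' @return JSON text of the draft configuration.
#' @export
skeleton_config <- function(inventory) {
  if (!nrow(inventory)) {
    rlang::abort("Cannot draft a configuration from an empty field inventory.",
                 class = "fairsheet_invalid_argument")
  }
  first_sheet <- inventory$sheet[1]
  heads <- inventory[inventory$sheet == first_sheet &
                       inventory$kind == "label", , drop = FALSE]
  if (!nrow(heads)) heads <- inventory[1, , drop = FALSE]
  heads <- heads[order(heads$row, heads$column), , drop = FALSE]
  header_row <- heads$row[1]
  heads <- heads[heads$row == header_row, , drop = FALSE]
  params <- list()
  if (nrow(heads) > 1L) {
    for (i in 2:nrow(heads)) {
      params[[paste0("TODO: ", heads$text[i])]] <-
        list(COLUMN_INDEX = heads$column[i])
    }
  }
  pa <- list(CITATION_TITLE = list(JSON_VALUE = "TODO: assay citation"))
  if (length(params)) pa$PARAMETERS <- params
  cfg <- list(
    `_TODO` = "draft configuration generated from a template field inventory; bind fields to the data model before use",
    DATA_ACCESS = list(ITERATION = "ROW_SINGLE", SHEET_INDEX = 0L,
                       ROW_START = header_row + 1L,
                       STOP_ON_BLANK_ROWS = 2L),
    SUBSTANCE_RECORD = list(
      SUBSTANCE_NAME = list(COLUMN_INDEX = heads$column[1])),
    PROTOCOL_APPLICATIONS = list(pa))
  jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
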