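test_that("cells are read by mode with types preserved", {
  wb <- tiny_row_workbook()
  da <- list(iteration = "ROW_SINGLE", sheet_index = 0L, sheet_name = NULL)
  lit <- resolve_edl(edl(json_value = "mV"), da)
  expect_identical(read_cell(wb, lit), "mV")
  abs <- resolve_edl(edl(iteration = "ABSOLUTE_LOCATION", row_index = 1L,
                         column_index = 2L), da)
  expect_identical(read_cell(wb, abs), -21.5)
  rowloc <- resolve_edl(edl(column_index = 0L), da)
  expect_identical(read_cell(wb, rowloc, list(current_row = 2L)), "NM-101")
  # blank cell and NA markers are absent
  m <- matrix(list(), 2, 2)
  m[[1, 1]] <- "n/a"; m[[2, 2]] <- "  trimmed  "
  wb2 <- workbook(list(S = m))
  a11 <- resolve_edl(edl(iteration = "ABSOLUTE_LOCATION", row_index = 0L,
                         column_index = 0L), da)
  expect_null(read_cell(wb2, a11))
  a22 <- resolve_edl(edl(iteration = "ABSOLUTE_LOCATION", row_index = 1L,
                         column_index = 1L), da)
  expect_identical(read_cell(wb2, a22), "trimmed")
  a12 <- resolve_edl(edl(iteration = "ABSOLUTE_LOCATION", row_index = 0L,
                         column_index = 1L), da)
  expect_null(read_cell(wb2, a12))
})

test_that("a missing sheet name is a configuration-time error", {
  wb <- tiny_row_workbook()
  da <- list(iteration = "ABSOLUTE_LOCATION", sheet_index = NULL,
             sheet_name = "NoSuchSheet")
  e <- resolve_edl(edl(row_index = 0L, column_index = 0L), da)
  expect_error(read_cell(wb, e), class = "fairsheet_sheet_error")
})

test_that("qualified values and intervals parse per the grammar", {
  # independent oracle: enumerate every production of the small grammar and
  # compute the expected decomposition with a literal table
  qualifier_cases <- list(
    list(raw = "<3", q = "<", side = "up", v = 3),
    list(raw = "<=3", q = "<=", side = "up", v = 3),
    list(raw = ">3", q = ">", side = "lo", v = 3),
    list(raw = ">= 2.5", q = ">=", side = "lo", v = 2.5),
    list(raw = "~3", q = "~", side = "lo", v = 3),
    list(raw = "=3", q = "=", side = "lo", v = 3),
    list(raw = "< 1e-3", q = "<", side = "up", v = 1e-3),
    list(raw = ">-4.5", q = ">", side = "lo", v = -4.5))
  for (cs in qualifier_cases) {
    got <- parse_value_expression(cs$raw)
    expect_false(is.null(got), info = cs$raw)
    if (cs$side == "up") {
      expect_identical(got$up_qualifier, cs$q, info = cs$raw)
      expect_equal(got$up_value, cs$v, info = cs$raw)
      expect_null(got$lo_value)
    } else {
      expect_identical(got$lo_qualifier, cs$q, info = cs$raw)
      expect_equal(got$lo_value, cs$v, info = cs$raw)
      expect_null(got$up_value)
    }
  }
  for (raw in c("3-4", "3 - 4", "3–4", "0.5-1.25")) {
    got <- parse_value_expression(raw)
    nums <- as.numeric(regmatches(raw, gregexpr("[0-9.]+", raw))[[1]])
    expect_identical(got$lo_qualifier, ">=", info = raw)
    expect_identical(got$up_qualifier, "<=", info = raw)
    expect_equal(got$lo_value, nums[1], info = raw)
    expect_equal(got$up_value, nums[2], info = raw)
  }
  for (raw in c("abc", "three", "1317-70-0", "", "3..4", "x<3")) {
    expect_null(parse_value_expression(raw), info = raw)
  }
})

test_that("row iteration yields one record per data row", {
  cfg <- load_config(tiny_row_config_json())
  recs <- parse_workbook(tiny_row_workbook(), cfg)
  expect_length(recs, 3L)
  expect_identical(recs[[1]]$substance_name, "NM-100")
  expect_identical(recs[[3]]$protocol_applications[[1]]$effects[[1]]$lo_value,
                   12.3)
  expect_identical(recs[[1]]$external_identifiers[[1]]$value, "1317-70-0")
})

test_that("a header-only sheet yields no records and no error", {
  m <- matrix(list(), 1, 3)
  m[[1, 1]] <- "Name"; m[[1, 2]] <- "CAS"; m[[1, 3]] <- "Zeta"
  recs <- parse_workbook(workbook(list(Sheet1 = m)),
                         load_config(tiny_row_config_json()))
  expect_length(recs, 0L)
})

test_that("iteration stops after consecutive blank rows unless ROW_END is set", {
  m <- matrix(list(), 9, 3)
  m[[1, 1]] <- "Name"
  m[[2, 1]] <- "NM-100"; m[[2, 3]] <- 1
  # rows 3 and 4 blank, then a trailing note that must not become a record
  m[[5, 1]] <- "note: all measurements at 25 C"
  recs <- parse_workbook(workbook(list(Sheet1 = m)),
                         load_config(tiny_row_config_json()))
  expect_length(recs, 1L)
  # with an explicit ROW_END the gap is crossed
  cfg2 <- jsonlite::parse_json(tiny_row_config_json())
  cfg2$DATA_ACCESS$ROW_END <- 5L
  recs2 <- parse_workbook(workbook(list(Sheet1 = m)), load_config(cfg2))
  expect_length(recs2, 2L)
})

test_that("each record depends only on its own row", {
  cfg <- load_config(tiny_row_config_json())
  wb <- tiny_row_workbook()
  before <- parse_workbook(wb, cfg)
  wb$sheets$Sheet1[2, ] <- list(NULL, NULL, NULL)  # blank out NM-100's row
  after <- parse_workbook(wb, cfg)
  expect_length(after, 2L)
  expect_identical(bare(after), bare(before)[2:3])
})

test_that("a degenerate one-cell block yields one record", {
  m <- matrix(list(), 2, 2)
  m[[2, 2]] <- 42
  cfg <- load_config('{
    "DATA_ACCESS": {"ITERATION": "ABSOLUTE_LOCATION", "SHEET_INDEX": 0},
    "SUBSTANCE_RECORD": {"SUBSTANCE_NAME": {"JSON_VALUE": "NM-1"}},
    "PROTOCOL_APPLICATIONS": [{
      "EFFECT_BLOCKS": [{
        "BLOCK_ORIGIN": {"ROW_INDEX": 1, "COLUMN_INDEX": 1},
        "SUB_BLOCK_SIZE": {"ROWS": 1, "COLUMNS": 1},
        "ENDPOINT": {"JSON_VALUE": "SIGNAL"},
        "VALUE_GROUPS": [{"VALUES": [{"ROW_OFFSET": 0, "COLUMN_OFFSET": 0}]}]
      }]
    }]
  }')
  recs <- parse_workbook(workbook(list(S = m)), cfg)
  effs <- recs[[1]]$protocol_applications[[1]]$effects
  expect_length(effs, 1L)
  expect_identical(effs[[1]]$lo_value, 42)
  expect_identical(effs[[1]]$lo_qualifier, "=")
})

test_that("the dose-response block expands to one effect per value cell", {
  fx <- generate_fixture(template_spec("BLOCK_LAYOUT", seed = 23,
                                       replicates = 2, times = 2,
                                       concentrations = 9))
  recs <- parse_workbook(fx$workbook, fx$config)
  effs <- recs[[1]]$protocol_applications[[1]]$effects
  expect_length(effs, 36L)
  for (ef in effs) {
    expect_setequal(names(ef$conditions),
                    c("concentration", "time", "replicate"))
  }
  # replicate comes from the sub-block grid row, time from the row header
  expect_identical(effs[[1]]$conditions$replicate$number, 1)
  expect_identical(effs[[36]]$conditions$replicate$number, 2)
  expect_identical(effs[[1]]$conditions$time$unit, "h")
  expect_identical(effs[[1]]$conditions$concentration$unit, "ug/mL")
})

test_that("absent value cells reduce the record count exactly", {
  fx <- generate_fixture(template_spec("BLOCK_LAYOUT", seed = 31))
  wb <- fx$workbook
  # blank three known value cells: block origin row 3, column 2 (0-based)
  wb$sheets$`Test results`[4, 3] <- list(NULL)
  wb$sheets$`Test results`[5, 7] <- list(NULL)
  wb$sheets$`Test results`[7, 11] <- list(NULL)
  recs <- parse_workbook(wb, fx$config)
  expect_length(recs[[1]]$protocol_applications[[1]]$effects, 33L)
})

test_that("the count law holds on randomized geometries", {
  set.seed(97)
  for (i in 1:60) {
    cs <- random_block_case()
    recs <- parse_workbook(cs$workbook, load_config_quietly(cs$config_json))
    pas <- recs[[1]]$protocol_applications
    n <- if (length(pas)) length(pas[[1]]$effects) else 0L
    expect_identical(n, cs$expected_count)
  }
})

test_that("block geometry outside the sheet is an error naming coordinates", {
  m <- matrix(list(), 3, 3)
  m[[1, 1]] <- 1
  cfg <- load_config('{
    "DATA_ACCESS": {"ITERATION": "ABSOLUTE_LOCATION", "SHEET_INDEX": 0},
    "SUBSTANCE_RECORD": {"SUBSTANCE_NAME": {"JSON_VALUE": "NM-1"}},
    "PROTOCOL_APPLICATIONS": [{
      "EFFECT_BLOCKS": [{
        "BLOCK_ORIGIN": {"ROW_INDEX": 2, "COLUMN_INDEX": 2},
        "SUB_BLOCK_GRID": {"ROWS": 2, "COLUMNS": 2},
        "SUB_BLOCK_SIZE": {"ROWS": 2, "COLUMNS": 2},
        "ENDPOINT": {"JSON_VALUE": "SIGNAL"},
        "VALUE_GROUPS": [{"VALUES": [{"ROW_OFFSET": 0, "COLUMN_OFFSET": 0}]}]
      }]
    }]
  }')
  expect_error(parse_workbook(workbook(list(S = m)), cfg, strict = TRUE),
               regexp = "C3", class = "fairsheet_parse_error")
})

test_that("value-group offsets outside the sub-block are configuration errors", {
  bad <- '{
    "DATA_ACCESS": {"ITERATION": "ABSOLUTE_LOCATION", "SHEET_INDEX": 0},
    "SUBSTANCE_RECORD": {"SUBSTANCE_NAME": {"JSON_VALUE": "NM-1"}},
    "PROTOCOL_APPLICATIONS": [{
      "EFFECT_BLOCKS": [{
        "BLOCK_ORIGIN": {"ROW_INDEX": 0, "COLUMN_INDEX": 0},
        "SUB_BLOCK_SIZE": {"ROWS": 2, "COLUMNS": 2},
        "ENDPOINT": {"JSON_VALUE": "SIGNAL"},
        "VALUE_GROUPS": [{"VALUES": [{"ROW_OFFSET": 2, "COLUMN_OFFSET": 0}]}]
      }]
    }]
  }'
  expect_error(load_config(bad), regexp = "outside the 2x2 sub-block",
               class = "fairsheet_config_error")
})

test_that("per-record problems are collected, or fatal under strict mode", {
  cfg_json <- '{
    "DATA_ACCESS": {"ITERATION": "ROW_SINGLE", "SHEET_INDEX": 0,
                    "ROW_START": 1},
    "SUBSTANCE_RECORD": {"SUBSTANCE_NAME": {"COLUMN_INDEX": 0}},
    "PROTOCOL_APPLICATIONS": [{
      "EFFECTS": [{"ENDPOINT": {"JSON_VALUE": "SIZE"},
                   "VALUE": {"COLUMN_INDEX": 40}}]
    }]
  }'
  recs <- parse_workbook(tiny_row_workbook(), load_config(cfg_json))
  expect_length(recs, 3L)
  probs <- attr(recs, "problems")
  expect_gte(nrow(probs), 3L)  # one out-of-bounds warning per data row
  expect_true(all(grepl("outside sheet bounds", probs$message)))
})

test_that("decimal-comma text is kept as text with a warning", {
  m <- matrix(list(), 2, 2)
  m[[1, 1]] <- "Name"
  m[[2, 1]] <- "NM-1"; m[[2, 2]] <- "3,14"
  cfg <- load_config('{
    "DATA_ACCESS": {"ITERATION": "ROW_SINGLE", "SHEET_INDEX": 0,
                    "ROW_START": 1},
    "SUBSTANCE_RECORD": {"SUBSTANCE_NAME": {"COLUMN_INDEX": 0}},
    "PROTOCOL_APPLICATIONS": [{
      "EFFECTS": [{"ENDPOINT": {"JSON_VALUE": "SIZE"},
                   "VALUE": {"COLUMN_INDEX": 1}}]
    }]
  }')
  recs <- parse_workbook(workbook(list(S = m)), cfg)
  ef <- recs[[1]]$protocol_applications[[1]]$effects[[1]]
  expect_identical(ef$text_value, "3,14")
  expect_null(ef$lo_value)
  probs <- attr(recs, "problems")
  expect_true(any(grepl("decimal-comma", probs$message)))
})
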