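# shared builders: tiny workbooks, configs and randomized model objects

tiny_row_workbook <- function() {
  m <- matrix(list(), nrow = 4L, ncol = 3L)
  m[[1, 1]] <- "Name"; m[[1, 2]] <- "CAS"; m[[1, 3]] <- "Zeta"
  m[[2, 1]] <- "NM-100"; m[[2, 2]] <- "1317-70-0"; m[[2, 3]] <- -21.5
  m[[3, 1]] <- "NM-101"; m[[3, 2]] <- "1317-80-2"; m[[3, 3]] <- -18.2
  m[[4, 1]] <- "NM-110"; m[[4, 2]] <- "1314-13-2"; m[[4, 3]] <- 12.3
  workbook(list(Sheet1 = m))
}

tiny_row_config_json <- function() {
  '{
    "DATA_ACCESS": {"ITERATION": "ROW_SINGLE", "SHEET_INDEX": 0,
                    "ROW_START": 1, "STOP_ON_BLANK_ROWS": 2},
    "SUBSTANCE_RECORD": {
      "SUBSTANCE_NAME": {"COLUMN_INDEX": 0},
      "EXTERNAL_IDENTIFIERS": [
        {"SYSTEM": {"JSON_VALUE": "CASRN"}, "VALUE": {"COLUMN_INDEX": 1}}
      ]
    },
    "PROTOCOL_APPLICATIONS": [{
      "CITATION_TITLE": {"JSON_VALUE": "Surface charge"},
      "EFFECTS": [{
        "ENDPOINT": {"JSON_VALUE": "ZETA POTENTIAL"},
        "VALUE": {"COLUMN_INDEX": 2},
        "UNIT": {"JSON_VALUE": "mV"}
      }]
    }]
  }'
}

load_config_quietly <- function(json) suppressWarnings(load_config(json))

# records list without the engine's report attribute, for identical() checks
bare <- function(records) {
  attributes(records) <- NULL
  records
}

random_condition <- function() {
  if (runif(1) < 0.5) {
    model_value(number = round(runif(1, 0, 100), 3),
                unit = sample(c("h", "ug/mL", NA), 1) |>
                  (\(u) if (is.na(u)) NULL else u)())
  } else {
    model_value(text = paste0("v", sample(1000, 1)))
  }
}

random_effect <- function() {
  form <- sample(c("exact", "interval", "upper", "text"), 1)
  args <- switch(form,
    exact = list(lo_qualifier = "=", lo_value = round(rnorm(1, 50, 10), 4)),
    interval = list(lo_qualifier = ">", lo_value = round(runif(1, 0, 3), 2),
                    up_qualifier = "<=", up_value = round(runif(1, 3, 9), 2)),
    upper = list(up_qualifier = "<", up_value = round(runif(1, 1, 5), 2)),
    text = list(text_value = paste0("free text ", sample(100, 1))))
  n_cond <- sample(0:3, 1)
  conds <- stats::setNames(
    lapply(seq_len(n_cond), function(i) random_condition()),
    if (n_cond) paste0("cond", seq_len(n_cond)) else character())
  do.call(effect_record, c(
    list(endpoint = sample(c("ZETA POTENTIAL", "CELL VIABILITY", "SIZE"), 1),
         unit = sample(c("mV", "%", "nm"), 1),
         err_qualifier = if (runif(1) < 0.3) "SD",
         err_value = if (runif(1) < 0.3) round(runif(1), 3),
         conditions = conds),
    args))
}

random_record <- function() {
  name <- paste0("NM-", sample(100:999, 1))
  owner <- sample(c("LabOne", "NanoWorks", "OxideCo"), 1)
  uuid <- generate_uuid("SUBSTANCE", c(name, owner))
  n_pa <- sample(1:2, 1)
  pas <- lapply(seq_len(n_pa), function(i) {
    protocol_application(
      substance_uuid = uuid,
      citation_title = paste("Assay", sample(10, 1)),
      citation_year = as.character(sample(2010:2020, 1)),
      protocol_guideline = if (runif(1) < 0.5) "OECD TG 318" else character(),
      parameters = list(medium = model_value(text = "water"),
                        temperature = model_value(number = 25, unit = "C")),
      effects = lapply(seq_len(sample(1:4, 1)), function(k) random_effect()))
  })
  comps <- if (runif(1) < 0.5) {
    list(composition(list(
      component("CORE", name = "silica"),
      component("COATING", name = "PEG",
                linkages = list(list(target = 1,
                                     relation = "covalently bonded"))))))
  } else list()
  substance_record(
    substance_name = name, owner_name = owner,
    public_name = if (runif(1) < 0.5) paste0(name, " (public)"),
    substance_type = if (runif(1) < 0.5) "NPO_1892",
    external_identifiers = list(
      external_identifier("CASRN", sprintf("%d-%02d-%d", sample(1e4:1e5, 1),
                                           sample(10:99, 1), sample(0:9, 1)))),
    compositions = comps,
    protocol_applications = pas)
}

# random small block geometry on a sheet, plus an independent brute-force
# count of the non-absent value cells the block should yield
random_block_case <- function() {
  grid <- c(sample(1:3, 1), sample(1:3, 1))
  size <- c(sample(1:4, 1), sample(1:4, 1))
  n_groups <- sample(1:3, 1)
  groups <- lapply(seq_len(n_groups), function(g) {
    n_vals <- sample(1:min(10, size[1] * size[2]), 1)
    cells <- sample(size[1] * size[2], n_vals)
    list(NAME = paste0("G", g),
         VALUES = lapply(cells, function(k) {
           list(ROW_OFFSET = (k - 1L) %/% size[2],
                COLUMN_OFFSET = (k - 1L) %% size[2])
         }),
         PARAMETERS = list(list(NAME = "grp", SOURCE = "JSON_VALUE",
                                JSON_VALUE = paste0("G", g))))
  })
  origin <- c(sample(0:3, 1), sample(0:3, 1))
  nr <- origin[1] + grid[1] * size[1] + sample(0:2, 1)
  nc <- origin[2] + grid[2] * size[2] + sample(0:2, 1)
  m <- matrix(list(), nrow = nr, ncol = nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (runif(1) < 0.2) next                      # absent cell
    m[[i, j]] <- if (runif(1) < 0.1) "n/a" else round(runif(1, 1, 99), 2)
  }
  cfg <- list(
    DATA_ACCESS = list(ITERATION = "ABSOLUTE_LOCATION", SHEET_INDEX = 0L),
    SUBSTANCE_RECORD = list(SUBSTANCE_NAME = list(JSON_VALUE = "NM-1")),
    PROTOCOL_APPLICATIONS = list(list(
      EFFECT_BLOCKS = list(list(
        BLOCK_ORIGIN = list(ROW_INDEX = origin[1], COLUMN_INDEX = origin[2]),
        SUB_BLOCK_GRID = list(ROWS = grid[1], COLUMNS = grid[2]),
        SUB_BLOCK_SIZE = list(ROWS = size[1], COLUMNS = size[2]),
        ENDPOINT = list(JSON_VALUE = "SIGNAL"),
        VALUE_GROUPS = groups)))))
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # independent walk: enumerate every (sub-block, group, offset) cell and
  # count the ones holding a usable value
  expected <- 0L
  for (gi in seq_len(grid[1])) for (gj in seq_len(grid[2])) {
    for (g in groups) {
      for (off in g$VALUES) {
        r1 <- origin[1] + (gi - 1L) * size[1] + off$ROW_OFFSET + 1L
        c1 <- origin[2] + (gj - 1L) * size[2] + off$COLUMN_OFFSET + 1L
        v <- m[[r1, c1]]
        if (!is.null(v) && !(is.character(v) && v %in% c("", "n/a", "N/A", "-", "–"))) {
          expected <- expected + 1L
        }
      }
    }
  }
  list(workbook = workbook(list(S = m)), config_json = json,
       expected_count = expected)
}
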