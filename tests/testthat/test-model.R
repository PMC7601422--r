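test_that("record identifiers are deterministic, distinct and stable", {
  expect_identical(generate_uuid("XLSX", c("NM-100", "ProjectA")),
                   generate_uuid("XLSX", c("NM-100", "ProjectA")))
  expect_false(generate_uuid("XLSX", "NM-100") ==
                 generate_uuid("XLSX", "NM-101"))
  # frozen regression value, computed once by hashing the canonical
  # serialization "XLSX|NM-100" with SHA-1 through an independent digest
  expect_identical(generate_uuid("XLSX", "NM-100"),
                   "XLSX-decf7ddc-3855-5514-8556-8c536bf12874")
  # namespace tags keep entity classes apart
  expect_false(generate_uuid("SUBSTANCE", "NM-100") ==
                 generate_uuid("PA", "NM-100"))
  expect_error(generate_uuid("XLSX", character()),
               class = "fairsheet_invalid_argument")
})

test_that("identifiers regenerate identically from a serialized record", {
  set.seed(41)
  for (i in 1:10) {
    r <- random_record()
    again <- substance_record(substance_name = r$substance_name,
                              owner_name = r$owner_name)
    expect_identical(again$substance_uuid, r$substance_uuid)
  }
})

test_that("values hold exactly one of number or text", {
  expect_error(model_value(), class = "fairsheet_invalid_argument")
  expect_error(model_value(number = 1, text = "x"),
               class = "fairsheet_invalid_argument")
  v <- model_value(number = 3.5, unit = "mV")
  expect_identical(v$number, 3.5)
  expect_null(v$text)
})

test_that("effect records enforce value presence and qualifier vocabulary", {
  expect_error(effect_record(endpoint = "SIZE"),
               class = "fairsheet_invalid_argument")
  expect_error(effect_record(endpoint = "SIZE", lo_value = 1,
                             lo_qualifier = "<<"),
               class = "fairsheet_invalid_argument")
  ef <- effect_record(endpoint = "SIZE", lo_qualifier = ">", lo_value = 3,
                      up_qualifier = "<=", up_value = 4, unit = "nm")
  expect_identical(ef$lo_qualifier, ">")
  expect_identical(ef$up_value, 4)
})

test_that("external identifiers must be non-empty and deduplicate", {
  expect_error(external_identifier(" ", "x"),
               class = "fairsheet_invalid_argument")
  r <- substance_record(
    substance_name = "NM-1",
    external_identifiers = list(external_identifier("CASRN", "1317-70-0"),
                                external_identifier("CASRN", "1317-70-0"),
                                external_identifier("EC", "215-280-1")))
  expect_length(r$external_identifiers, 2L)
})

test_that("composition linkage targets must reference existing components", {
  expect_error(composition(list()), class = "fairsheet_invalid_argument")
  expect_error(
    composition(list(component("CORE", name = "silica",
                               linkages = list(list(target = 3,
                                                    relation = "embedded"))))),
    class = "fairsheet_invalid_argument")
  cc <- composition(list(
    component("CORE", name = "silica"),
    component("COATING", name = "PEG",
              linkages = list(list(target = 1,
                                   relation = "covalently bonded")))))
  expect_length(cc$components, 2L)
  expect_error(component("SOLVENT"), class = "fairsheet_invalid_argument")
})

test_that("merging unions fragments of the same substance", {
  u <- generate_uuid("SUBSTANCE", c("NM-100", ""))
  a <- substance_record(substance_name = "NM-100",
                        external_identifiers = list(
                          external_identifier("CASRN", "1317-70-0")))
  b <- substance_record(
    substance_name = "NM-100",
    protocol_applications = list(protocol_application(
      substance_uuid = u, citation_title = "Assay",
      effects = lapply(1:3, function(i) {
        effect_record(endpoint = "SIZE", lo_qualifier = "=", lo_value = i)
      }))))
  merged <- merge_records(list(a, b))
  expect_length(merged, 1L)
  expect_length(merged[[1]]$external_identifiers, 1L)
  expect_length(merged[[1]]$protocol_applications[[1]]$effects, 3L)
})

test_that("merge keeps disjoint records apart and is idempotent", {
  set.seed(7)
  recs <- lapply(1:5, function(i) random_record())
  once <- merge_records(recs)
  expect_length(once, 5L)
  expect_identical(merge_records(once), once)
  # duplicated fragments also reach a fixed point after one merge
  dup <- merge_records(c(recs, recs[1:2]))
  expect_length(dup, 5L)
  expect_identical(merge_records(dup), dup)
})

test_that("merge reports conflicting names for one identifier", {
  u <- generate_uuid("SUBSTANCE", "X")
  a <- substance_record(substance_name = "NM100", substance_uuid = u)
  b <- substance_record(substance_name = "NM-200", substance_uuid = u)
  expect_error(merge_records(list(a, b)), regexp = "NM100.*NM-200",
               class = "fairsheet_merge_conflict")
})

test_that("effects tables flatten conditions into columns", {
  fx <- generate_fixture(template_spec("BLOCK_LAYOUT", seed = 5))
  tab <- effects_table(fx$records)
  expect_identical(nrow(tab), 36L)
  expect_true(all(c("condition_concentration", "condition_time",
                    "condition_replicate") %in% names(tab)))
  expect_true(all(tab$endpoint == "COLONY FORMING EFFICIENCY"))
})
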