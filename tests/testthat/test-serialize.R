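test_that("the empty record list serializes to an empty array and back", {
  expect_identical(as.character(to_native_json(list())), "[]")
  expect_identical(from_native_json("[]"), list())
})

test_that("interval measurements keep both bounds and qualifiers", {
  r <- substance_record(
    substance_name = "NM-1",
    protocol_applications = list(protocol_application(
      substance_uuid = "u",
      effects = list(effect_record(endpoint = "SIZE", lo_qualifier = ">",
                                   lo_value = 3, up_qualifier = "<=",
                                   up_value = 4, unit = "nm")))))
  doc <- jsonlite::parse_json(to_native_json(list(r)))
  ef <- doc[[1]]$protocolApplications[[1]]$effects[[1]]
  expect_identical(ef$loQualifier, ">")
  expect_identical(ef$loValue, 3L)
  expect_identical(ef$upQualifier, "<=")
  expect_identical(ef$upValue, 4L)
})

test_that("native JSON round-trips the fixtures exactly", {
  for (spec in list(template_spec("ROW_LAYOUT", n_substances = 3, seed = 5),
                    template_spec("BLOCK_LAYOUT", seed = 5))) {
    fx <- generate_fixture(spec)
    expect_identical(from_native_json(to_native_json(fx$records)),
                     fx$records)
  }
})

test_that("native JSON round-trips randomized records", {
  set.seed(2024)
  recs <- lapply(1:50, function(i) random_record())
  expect_identical(from_native_json(to_native_json(recs)), recs)
})

test_that("annotated records round-trip with their originals", {
  dicts <- list(endpoint = read_dictionary(
    system.file("extdata", "dictionary-endpoint.json", package = "fairsheet")),
    cell_type = read_dictionary(
      system.file("extdata", "dictionary-cell_type.json",
                  package = "fairsheet")))
  rec <- substance_record(
    substance_name = "NM-1",
    protocol_applications = list(protocol_application(
      substance_uuid = "u",
      effects = list(effect_record(
        endpoint = "Zeta Potential", lo_qualifier = "=", lo_value = -20,
        conditions = list(cell_type = model_value(text = "Beas 2B")))))))
  h <- harmonize_record(rec, dicts)
  attr(h, "harmonization_misses") <- NULL
  back <- from_native_json(to_native_json(list(h)))[[1]]
  expect_identical(back, h)
  expect_identical(back$protocol_applications[[1]]$effects[[1]]$endpoint$original,
                   "Zeta Potential")
})

test_that("serialization is deterministic byte for byte", {
  set.seed(3)
  recs <- lapply(1:5, function(i) random_record())
  expect_identical(as.character(to_native_json(recs)),
                   as.character(to_native_json(recs)))
  expect_identical(as.character(to_isa_json(recs)),
                   as.character(to_isa_json(recs)))
})

test_that("malformed documents fail with a JSON path", {
  expect_error(from_native_json('[{"substanceName": "NM-1"}]'),
               regexp = "substanceUuid", class = "fairsheet_json_error")
  expect_error(from_native_json('[{"substanceUuid": "u", "protocolApplications": [{}]}]'),
               regexp = "protocolApplications\\[0\\]",
               class = "fairsheet_json_error")
  expect_error(from_native_json('[{"substanceUuid"'), class = "fairsheet_json_error")
})

test_that("a minimal record maps to one study, one assay, one material", {
  r <- substance_record(
    substance_name = "NM-1",
    protocol_applications = list(protocol_application(
      substance_uuid = "u", citation_title = "Assay",
      effects = list(effect_record(endpoint = "SIZE", lo_qualifier = "=",
                                   lo_value = 12, unit = "nm",
                                   conditions = list(
                                     time = model_value(number = 24,
                                                        unit = "h")))))))
  doc <- jsonlite::parse_json(to_isa_json(list(r)))
  expect_length(doc$studies, 1L)
  st <- doc$studies[[1]]
  expect_length(st$assays, 1L)
  expect_length(st$materials$sources, 1L)
  expect_length(st$assays[[1]]$dataFiles, 1L)
  fv <- st$assays[[1]]$dataFiles[[1]]$factorValues[[1]]
  expect_identical(fv$category$annotationValue, "time")
  expect_identical(fv$value, 24L)
})

test_that("component linkages appear with both endpoints in ISA output", {
  r <- substance_record(
    substance_name = "NM-1",
    compositions = list(composition(list(
      component("CORE", name = "silica"),
      component("COATING", name = "PEG",
                linkages = list(list(target = 1,
                                     relation = "covalently bonded")))))))
  doc <- jsonlite::parse_json(to_isa_json(list(r)))
  comps <- doc$studies[[1]]$materials$sources[[1]]$components
  expect_length(comps, 2L)
  lk <- comps[[2]]$linkages[[1]]
  expect_identical(lk$relation, "covalently bonded")
  expect_identical(lk$target, comps[[1]]$`@id`)
})

test_that("empty input still yields a valid empty investigation", {
  doc <- jsonlite::parse_json(to_isa_json(list()))
  expect_identical(doc$identifier, "INV-1")
  expect_length(doc$studies, 0L)
})

test_that("ISA output validates against the bundled extension schema", {
  schema <- system.file("schema", "isa-material-extension.schema.json",
                        package = "fairsheet")
  set.seed(8)
  recs <- lapply(1:4, function(i) random_record())
  expect_length(check_schema(to_isa_json(recs), schema), 0L)
  fx <- generate_fixture(template_spec("BLOCK_LAYOUT", seed = 2))
  expect_length(check_schema(to_isa_json(fx$records), schema), 0L)
})

test_that("records grouped by investigation split into separate studies", {
  mk <- function(name, inv) substance_record(
    substance_name = name,
    protocol_applications = list(protocol_application(
      substance_uuid = name, citation_title = "Assay",
      investigation_uuid = inv,
      effects = list(effect_record(endpoint = "SIZE", lo_qualifier = "=",
                                   lo_value = 1)))))
  doc <- jsonlite::parse_json(to_isa_json(list(mk("NM-1", "INV-A"),
                                               mk("NM-2", "INV-B"))))
  expect_length(doc$studies, 2L)
  expect_setequal(vapply(doc$studies, `[[`, character(1), "identifier"),
                  c("INV-A", "INV-B"))
})

test_that("the experimental triple dump covers names, ids and endpoints", {
  fx <- generate_fixture(template_spec("ROW_LAYOUT", n_substances = 2,
                                       seed = 6))
  nt <- to_ntriples(fx$records)
  expect_true(all(grepl("^<urn:uuid:.+> <https://w3id\\.org/.+> .+ \\.$", nt)))
  expect_true(any(grepl("substanceName", nt)))
  expect_true(any(grepl("endpoint", nt)))
})
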