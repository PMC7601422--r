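test_that("spelling, case and spacing variants collapse to one key", {
  expect_identical(unique(normalize_key(c("BEAS 2B", "Beas 2B", "BEAS -2B"))),
                   "beas2b")
  expect_identical(normalize_key("Colony_forming.efficiency"),
                   "colonyformingefficiency")
  expect_identical(normalize_key(""), "")
  expect_identical(normalize_key(character()), character())
})

test_that("dictionaries require unique keys and fixed-point canonicals", {
  expect_error(dictionary(c("BEAS 2B" = "BEAS-2B", "beas-2b" = "Beas2B")),
               class = "fairsheet_invalid_argument")
  d <- dictionary(c("BEAS 2B" = "BEAS-2B"),
                  annotations = list("BEAS-2B" = list(
                    list(vocabulary = "BTO", id = "BTO:0001980",
                         label = "BEAS-2B cell"))))
  # the canonical term's own key resolves to itself
  expect_identical(d$entries[[normalize_key("BEAS-2B")]], "BEAS-2B")
})

test_that("bundled dictionaries load and hit", {
  path <- system.file("extdata", "dictionary-cell_type.json",
                      package = "fairsheet")
  d <- read_dictionary(path)
  for (variant in c("BEAS 2B", "Beas 2B", "BEAS -2B", "beas-2b")) {
    hit <- lookup_term(d, variant)
    expect_identical(hit$canonical, "BEAS-2B")
    expect_identical(hit$original, variant)
    expect_gte(length(hit$annotations), 1L)
  }
  expect_null(lookup_term(d, "HepG2"))
})

test_that("harmonization hits replace fields but keep originals verbatim", {
  dicts <- list(endpoint = read_dictionary(
    system.file("extdata", "dictionary-endpoint.json", package = "fairsheet")))
  rec <- substance_record(
    substance_name = "NM-1",
    protocol_applications = list(protocol_application(
      substance_uuid = "u", citation_title = "t",
      effects = list(effect_record(endpoint = "Zeta Potential",
                                   lo_qualifier = "=", lo_value = -20,
                                   unit = "mV")))))
  h <- harmonize_record(rec, dicts)
  ep <- h$protocol_applications[[1]]$effects[[1]]$endpoint
  expect_s3_class(ep, "fs_annotated_term")
  expect_identical(ep$original, "Zeta Potential")
  expect_identical(ep$canonical, "ZETA POTENTIAL")
  expect_gte(length(ep$annotations), 1L)
  expect_identical(nrow(attr(h, "harmonization_misses")), 0L)
})

test_that("unmatched terms pass through and land in the miss report", {
  dicts <- list(endpoint = dictionary(c("size" = "PARTICLE SIZE")))
  rec <- substance_record(
    substance_name = "NM-1",
    protocol_applications = list(protocol_application(
      substance_uuid = "u",
      effects = list(effect_record(endpoint = "Dustiness",
                                   lo_qualifier = "=", lo_value = 1)))))
  h <- harmonize_record(rec, dicts)
  expect_identical(h$protocol_applications[[1]]$effects[[1]]$endpoint,
                   "Dustiness")
  misses <- attr(h, "harmonization_misses")
  expect_identical(misses$original, "Dustiness")
  expect_identical(misses$field, "endpoint")
})

test_that("near-misses are suggested for curator review, never applied", {
  dicts <- list(endpoint = dictionary(c("dustiness" = "DUSTINESS")))
  rec <- substance_record(
    substance_name = "NM-1",
    protocol_applications = list(protocol_application(
      substance_uuid = "u",
      effects = list(effect_record(endpoint = "Dustines",  # one edit away
                                   lo_qualifier = "=", lo_value = 1)))))
  h <- harmonize_record(rec, dicts)
  expect_identical(h$protocol_applications[[1]]$effects[[1]]$endpoint,
                   "Dustines")
  expect_identical(attr(h, "harmonization_misses")$suggestion, "DUSTINESS")
})

test_that("condition values harmonize through a dictionary named like the condition", {
  dicts <- list(cell_type = read_dictionary(
    system.file("extdata", "dictionary-cell_type.json", package = "fairsheet")))
  rec <- substance_record(
    substance_name = "NM-1",
    protocol_applications = list(protocol_application(
      substance_uuid = "u",
      effects = list(effect_record(
        endpoint = "CELL VIABILITY", lo_qualifier = "=", lo_value = 80,
        conditions = list(`Cell type` = model_value(text = "BEAS -2B")))))))
  h <- harmonize_record(rec, dicts)
  cond <- h$protocol_applications[[1]]$effects[[1]]$conditions$`Cell type`
  expect_identical(cond$text, "BEAS-2B")
  expect_identical(cond$annotation$original, "BEAS -2B")
})

test_that("harmonization is idempotent on randomized records", {
  dicts <- list(endpoint = read_dictionary(
    system.file("extdata", "dictionary-endpoint.json", package = "fairsheet")))
  set.seed(13)
  for (i in 1:20) {
    r <- random_record()
    h1 <- harmonize_record(r, dicts)
    h2 <- harmonize_record(h1, dicts)
    expect_identical(h2, h1)
    # originals preserved bit-for-bit wherever a term was annotated
    for (k in seq_along(r$protocol_applications)) {
      efs0 <- r$protocol_applications[[k]]$effects
      efs1 <- h1$protocol_applications[[k]]$effects
      for (j in seq_along(efs0)) {
        if (inherits(efs1[[j]]$endpoint, "fs_annotated_term")) {
          expect_identical(efs1[[j]]$endpoint$original, efs0[[j]]$endpoint)
        }
      }
    }
  }
})

test_that("batch harmonization aggregates the miss report and writes it", {
  dicts <- list(endpoint = dictionary(c("size" = "PARTICLE SIZE")))
  fx <- generate_fixture(template_spec("ROW_LAYOUT", n_substances = 2,
                                       seed = 9))
  out <- harmonize_records(fx$records, dicts)
  misses <- attr(out, "harmonization_misses")
  expect_gte(nrow(misses), 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_miss_report(misses, path)
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), nrow(misses))
  expect_true("suggestion" %in% names(tab))
})
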