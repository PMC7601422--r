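#' Serialize records to the native JSON model
#'
#' Lossless, deterministic serialization of substance records: every field
#' of every entity appears under a stable lowerCamelCase key drawn from the
#' data-model attribute vocabulary (`substanceName`, `protocolGuideline`,
#' `loQualifier`, ...), absent fields are omitted, and key order is fixed,
#' so identical records always produce byte-identical output.
#'
#' @param records List of [substance_record()] objects.
#' @param pretty Pretty-print the JSON.
#' @return JSON text.
#' @seealso [from_native_json()] for the inverse.
#' @export
to_native_json <- function(records, pretty = FALSE) {
  out <- lapply(records, record_to_list)
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = pretty)
}

value_to_list <- function(v) {
  compact_fields(list(value = v$number %||% v$text, unit = v$unit,
                      qualifier = v$qualifier,
                      annotation = if (!is.null(v$annotation))
                        term_to_list(v$annotation)))
}

named_values_to_list <- function(vs) {
  lapply(seq_along(vs), function(i) {
    c(list(name = names(vs)[i]), value_to_list(vs[[i]]))
  })
}

term_to_list <- function(t) {
  list(original = t$original, canonical = t$canonical,
       annotations = lapply(t$annotations, function(a) {
         list(vocabulary = a$vocabulary, id = a$id, label = a$label)
       }))
}

text_or_term_to_list <- function(x) {
  if (inherits(x, "fs_annotated_term")) term_to_list(x) else x
}

effect_to_list <- function(ef) {
  compact_fields(list(
    sampleId = ef$sample_id,
    endpoint = text_or_term_to_list(ef$endpoint),
    endpointType = text_or_term_to_list(ef$endpoint_type),
    loQualifier = ef$lo_qualifier, loValue = ef$lo_value,
    upQualifier = ef$up_qualifier, upValue = ef$up_value,
    errQualifier = ef$err_qualifier, errValue = ef$err_value,
    textValue = ef$text_value, unit = ef$unit,
    conditions = if (length(ef$conditions %||% list()))
      named_values_to_list(ef$conditions)))
}

pa_to_list <- function(pa) {
  compact_fields(list(
    uuid = pa$uuid,
    citationTitle = pa$citation_title, citationYear = pa$citation_year,
    citationOwner = pa$citation_owner,
    protocolGuideline = if (length(pa$protocol_guideline %||% character()))
      as.list(pa$protocol_guideline),
    interpretationResult = pa$interpretation_result,
    interpretationCriteria = pa$interpretation_criteria,
    parameters = if (length(pa$parameters %||% list()))
      named_values_to_list(pa$parameters),
    effects = if (length(pa$effects %||% list()))
      lapply(pa$effects, effect_to_list),
    investigationUuid = pa$investigation_uuid,
    assayUuid = pa$assay_uuid,
    reliabilityFlag = pa$reliability_flag))
}

component_to_list <- function(cp) {
  compact_fields(list(
    role = cp$role, name = cp$name, structure = cp$structure,
    properties = if (length(cp$properties %||% list()))
      named_values_to_list(cp$properties),
    linkages = if (length(cp$linkages %||% list()))
      lapply(cp$linkages, function(l) {
        list(target = l$target, relation = l$relation)
      })))
}

record_to_list <- function(r) {
  compact_fields(list(
    substanceName = text_or_term_to_list(r$substance_name),
    publicName = r$public_name,
    ownerName = r$owner_name, ownerUuid = r$owner_uuid,
    substanceUuid = r$substance_uuid,
    substanceType = text_or_term_to_list(r$substance_type),
    externalIdentifiers = if (length(r$external_identifiers %||% list()))
      lapply(r$external_identifiers, function(x) {
        list(system = x$system, value = x$value)
      }),
    compositions = if (length(r$compositions %||% list()))
      lapply(r$compositions, function(cc) {
        list(compositionUuid = cc$composition_uuid,
             components = lapply(cc$components, component_to_list))
      }),
    protocolApplications = if (length(r$protocol_applications %||% list()))
      lapply(r$protocol_applications, pa_to_list)))
}

#' Read records back from native JSON
#'
#' Inverse of [to_native_json()]: `from_native_json(to_native_json(r))`
#' reconstructs `r` exactly. Documents are checked structurally while being
#' rebuilt; a violation raises an error naming the JSON path.
#'
#' @param json JSON text or a file path.
#' @return List of [substance_record()] objects.
#' @export
from_native_json <- function(json) {
  x <- as_parsed_json(json)
  if (!is.list(x) || (!is.null(names(x)) && any(nzchar(names(x))))) {
    rlang::abort("$: expected an array of substance records.",
                 class = "fairsheet_json_error")
  }
  lapply(seq_along(x), function(i) {
    list_to_record(x[[i]], sprintf("$[%d]", i - 1L))
  })
}

need_string <- function(x, key, path, required = FALSE) {
  v <- x[[key]]
  if (is.null(v)) {
    if (required) {
      rlang::abort(sprintf("%s.%s: required string missing", path, key),
                   class = "fairsheet_json_error")
    }
    return(NULL)
  }
  if (!is.character(v) || length(v) != 1L) {
    rlang::abort(sprintf("%s.%s: expected a string", path, key),
                 class = "fairsheet_json_error")
  }
  v
}

need_number <- function(x, key, path) {
  v <- x[[key]]
  if (is.null(v)) return(NULL)
  if (!is.numeric(v) || length(v) != 1L) {
    rlang::abort(sprintf("%s.%s: expected a number", path, key),
                 class = "fairsheet_json_error")
  }
  as.numeric(v)
}

list_to_term <- function(x) {
  annotated_term(
    original = x$original, canonical = x$canonical,
    annotations = lapply(x$annotations %||% list(), function(a) {
      list(vocabulary = a$vocabulary, id = a$id, label = a$label)
    }))
}

list_to_text_or_term <- function(x) {
  if (is.list(x) && !is.null(x$canonical)) list_to_term(x) else x
}

list_to_value <- function(x, path) {
  raw <- x$value
  v <- if (is.numeric(raw)) {
    model_value(number = as.numeric(raw), unit = x$unit,
                qualifier = x$qualifier)
  } else if (is.character(raw)) {
    model_value(text = raw, unit = x$unit, qualifier = x$qualifier)
  } else {
    rlang::abort(sprintf("%s.value: expected a number or string", path),
                 class = "fairsheet_json_error")
  }
  if (!is.null(x$annotation)) v$annotation <- list_to_term(x$annotation)
  v
}

list_to_named_values <- function(xs, path) {
  out <- list()
  for (i in seq_along(xs)) {
    p <- sprintf("%s[%d]", path, i - 1L)
    nm <- need_string(xs[[i]], "name", p, required = TRUE)
    out[[nm]] <- list_to_value(xs[[i]], p)
  }
  out
}

list_to_effect <- function(x, path) {
  effect_record(
    endpoint = list_to_text_or_term(x$endpoint),
    sample_id = need_string(x, "sampleId", path),
    endpoint_type = list_to_text_or_term(x$endpointType),
    lo_qualifier = need_string(x, "loQualifier", path),
    lo_value = need_number(x, "loValue", path),
    up_qualifier = need_string(x, "upQualifier", path),
    up_value = need_number(x, "upValue", path),
    err_qualifier = need_string(x, "errQualifier", path),
    err_value = need_number(x, "errValue", path),
    text_value = need_string(x, "textValue", path),
    unit = need_string(x, "unit", path),
    conditions = list_to_named_values(x$conditions %||% list(),
                                      paste0(path, ".conditions")))
}

list_to_pa <- function(x, path) {
  protocol_application(
    uuid = need_string(x, "uuid", path, required = TRUE),
    citation_title = need_string(x, "citationTitle", path),
    citation_year = need_string(x, "citationYear", path),
    citation_owner = need_string(x, "citationOwner", path),
    protocol_guideline = vapply(x$protocolGuideline %||% list(),
                                as.character, character(1)),
    interpretation_result = need_string(x, "interpretationResult", path),
    interpretation_criteria = need_string(x, "interpretationCriteria", path),
    parameters = list_to_named_values(x$parameters %||% list(),
                                      paste0(path, ".parameters")),
    effects = lapply(seq_along(x$effects %||% list()), function(i) {
      list_to_effect(x$effects[[i]], sprintf("%s.effects[%d]", path, i - 1L))
    }),
    investigation_uuid = need_string(x, "investigationUuid", path),
    assay_uuid = need_string(x, "assayUuid", path),
    reliability_flag = need_string(x, "reliabilityFlag", path))
}

list_to_record <- function(x, path) {
  substance_record(
    substance_name = list_to_text_or_term(x$substanceName),
    public_name = need_string(x, "publicName", path),
    owner_name = need_string(x, "ownerName", path),
    owner_uuid = need_string(x, "ownerUuid", path),
    substance_uuid = need_string(x, "substanceUuid", path, required = TRUE),
    substance_type = list_to_text_or_term(x$substanceType),
    external_identifiers = lapply(x$externalIdentifiers %||% list(),
                                  function(e) {
                                    external_identifier(e$system, e$value)
                                  }),
    compositions = lapply(x$compositions %||% list(), function(cc) {
      composition(
        composition_uuid = cc$compositionUuid,
        components = lapply(cc$components %||% list(), function(cp) {
          component(role = cp$role, name = cp$name,
                    structure = cp$structure,
                    properties = list_to_named_values(
                      cp$properties %||% list(), paste0(path, ".properties")),
                    linkages = lapply(cp$linkages %||% list(), function(l) {
                      list(target = l$target, relation = l$relation)
                    }))
        }))
    }),
    protocol_applications = lapply(
      seq_along(x$protocolApplications %||% list()), function(i) {
        list_to_pa(x$protocolApplications[[i]],
                   sprintf("%s.protocolApplications[%d]", path, i - 1L))
      }))
}

as_text <- function(x) {
  if (inherits(x, "fs_annotated_term")) x$canonical else x
}

#' Serialize records to ISA-JSON with the material extension
#'
#' Emits an ISA-JSON v1 skeleton: one investigation; one study per
#' investigation group (records whose protocol applications carry an
#' `investigation_uuid` are grouped by it, everything else goes to a
#' default study); one assay per protocol identity (citation title +
#' guidelines); substances as study source materials. The nanomaterial
#' extension describes the material's components, each with a `role`
#' (core, coating, ...) and `linkages` to sibling constituents (e.g.
#' "covalently bonded", "encapsulated"). Every effect record is reachable
#' as a data node of its assay, with the experimental conditions attached
#' as factor values.
#'
#' The extension layout follows the bundled schema
#' (`inst/schema/isa-material-extension.schema.json`), which is this
#' package's own reconstruction of a role-plus-linkage component model.
#'
#' @param records List of [substance_record()] objects.
#' @param identifier Investigation identifier.
#' @return JSON text (pretty-printed; deterministic for identical input).
#' @export
to_isa_json <- function(records, identifier = "INV-1") {
  groups <- list()
  material_of <- function(r) {
    comps <- list()
    for (cc in r$compositions %||% list()) {
      n <- length(cc$components)
      for (k in seq_len(n)) {
        cp <- cc$components[[k]]
        comps[[length(comps) + 1L]] <- compact_fields(list(
          `@id` = sprintf("#component/%s/%d", cc$composition_uuid, k),
          role = cp$role, name = cp$name,
          linkages = if (length(cp$linkages %||% list()))
            lapply(cp$linkages, function(l) {
              list(target = sprintf("#component/%s/%d",
                                    cc$composition_uuid, l$target),
                   relation = l$relation)
            })))
      }
    }
    compact_fields(list(
      `@id` = paste0("#material/", r$substance_uuid),
      name = as_text(r$substance_name) %||% r$substance_uuid,
      type = "Source Name",
      characteristics = if (length(r$external_identifiers %||% list()))
        lapply(r$external_identifiers, function(e) {
          list(category = list(annotationValue = e$system),
               value = list(annotationValue = e$value))
        }),
      components = if (length(comps)) comps))
  }
  for (r in records) {
    pas <- r$protocol_applications %||% list()
    inv_keys <- unique(vapply(pas, function(pa)
      pa$investigation_uuid %||% "default", character(1)))
    if (!length(pas)) inv_keys <- "default"
    for (key in inv_keys) {
      if (is.null(groups[[key]])) groups[[key]] <- list()
      groups[[key]][[length(groups[[key]]) + 1L]] <-
        list(record = r,
             pas = Filter(function(pa)
               identical(pa$investigation_uuid %||% "default", key), pas))
    }
  }
  studies <- list()
  study_i <- 0L
  for (key in names(groups)) {
    study_i <- study_i + 1L
    members <- groups[[key]]
    materials <- lapply(members, function(m) material_of(m$record))
    assays <- list()
    for (m in members) {
      for (pa in m$pas) {
        akey <- paste(c(pa$citation_title %||% "",
                        pa$protocol_guideline %||% character()),
                      collapse = "|")
        if (is.null(assays[[akey]])) {
          assays[[akey]] <- list(
            `@id` = paste0("#assay/", generate_uuid("ASSAY", akey)),
            measurementType = list(
              annotationValue = if (length(pa$effects %||% list()))
                as_text(pa$effects[[1]]$endpoint) else "unspecified"),
            technologyType = list(annotationValue =
                                    pa$citation_title %||% "unspecified"),
            dataFiles = list(), processSequence = list())
        }
        a <- assays[[akey]]
        params <- named_values_to_list(pa$parameters %||% list())
        for (ei in seq_along(pa$effects %||% list())) {
          ef <- pa$effects[[ei]]
          did <- sprintf("#data/%s/%d", pa$uuid, ei)
          a$dataFiles[[length(a$dataFiles) + 1L]] <- compact_fields(list(
            `@id` = did,
            name = as_text(ef$endpoint),
            type = "Raw Data File",
            result = compact_fields(list(
              loQualifier = ef$lo_qualifier, loValue = ef$lo_value,
              upQualifier = ef$up_qualifier, upValue = ef$up_value,
              errQualifier = ef$err_qualifier, errValue = ef$err_value,
              textValue = ef$text_value, unit = ef$unit)),
            factorValues = if (length(ef$conditions %||% list()))
              lapply(seq_along(ef$conditions), function(ci) {
                v <- ef$conditions[[ci]]
                compact_fields(list(
                  category = list(annotationValue = names(ef$conditions)[ci]),
                  value = v$number %||% v$text,
                  unit = if (!is.null(v$unit))
                    list(annotationValue = v$unit)))
              })))
          a$processSequence[[length(a$processSequence) + 1L]] <-
            compact_fields(list(
              `@id` = sprintf("#process/%s/%d", pa$uuid, ei),
              executesProtocol = list(`@id` = paste0("#protocol/", pa$uuid)),
              parameterValues = if (length(params)) params,
              inputs = list(list(`@id` = paste0("#material/",
                                                m$record$substance_uuid))),
              outputs = list(list(`@id` = did))))
        }
        assays[[akey]] <- a
      }
    }
    studies[[length(studies) + 1L]] <- list(
      identifier = if (identical(key, "default"))
        sprintf("STD-%d", study_i) else key,
      title = sprintf("Study %d", study_i),
      materials = list(sources = materials, samples = list(),
                       otherMaterials = list()),
      assays = unname(assays))
  }
  doc <- list(identifier = identifier,
              title = "Converted substance dataset",
              studies = studies)
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' Minimal N-Triples dump (experimental)
#'
#' A flat triple serialization over a small fixed vocabulary: the subject
#' is the substance identifier as a URN, predicates cover names,
#' identifiers and per-effect endpoint/value/unit. This is intentionally
#' not a full semantic mapping; it exists so downstream triple stores can
#' ingest the converted records at all, and is flagged experimental.
#'
#' @param records List of [substance_record()] objects.
#' @return Character vector of N-Triples lines.
#' @export
to_ntriples <- function(records) {
  voc <- "https://w3id.org/fairsheet/terms#"
  esc <- function(x) gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x))
  lit <- function(x) sprintf("\"%s\"", esc(as.character(x)))
  uri <- function(x) sprintf("<%s>", x)
  subj <- function(u) uri(paste0("urn:uuid:", u))
  out <- character()
  add <- function(s, p, o) out[[length(out) + 1L]] <<-
    paste(s, uri(paste0(voc, p)), o, ".")
  for (r in records) {
    s <- subj(r$substance_uuid)
    if (!is.null(r$substance_name)) {
      add(s, "substanceName", lit(as_text(r$substance_name)))
    }
    for (e in r$external_identifiers %||% list()) {
      add(s, "externalIdentifier", lit(paste0(e$system, ":", e$value)))
    }
    for (pa in r$protocol_applications %||% list()) {
      ps <- subj(pa$uuid)
      add(s, "protocolApplication", ps)
      for (ef in pa$effects %||% list()) {
        add(ps, "endpoint", lit(as_text(ef$endpoint)))
        if (!is.null(ef$lo_value)) add(ps, "loValue", lit(ef$lo_value))
        if (!is.null(ef$unit)) add(ps, "unit", lit(ef$unit))
      }
    }
  }
  out
}
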