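#' Deterministic name-based record identifiers
#'
#' Builds a stable, platform-independent identifier for a data-model entity
#' from its identity fields. The canonical serialization is the namespace tag
#' and the NFC-normalized fields joined with `"|"`; its SHA-1 digest is
#' formatted as a version-5-style UUID and prefixed with the namespace tag.
#' Identical inputs always yield identical identifiers, which is what makes
#' record linking and merging across parser runs possible.
#'
#' @param namespace_tag Short upper-case tag naming the entity class
#'   (e.g. `"SUBSTANCE"`, `"PA"`, `"INV"`, `"ASSAY"`). Distinct tags keep
#'   identifiers of different entity classes from ever colliding.
#' @param canonical_fields Character vector of identity fields, already
#'   trimmed; must be non-empty. `NA` entries are serialized as the empty
#'   string so that "value not reported" is still a stable identity.
#' @return A single string `"<tag>-xxxxxxxx-xxxx-5xxx-yxxx-xxxxxxxxxxxx"`.
#' @examples
#' generate_uuid("SUBSTANCE", c("NM-100", "ProjectA"))
#' @export
generate_uuid <- function(namespace_tag, canonical_fields) {
  stopifnot(is.character(namespace_tag), length(namespace_tag) == 1L,
            nzchar(namespace_tag))
  canonical_fields <- as.character(canonical_fields)
  if (length(canonical_fields) == 0L) {
    rlang::abort("`canonical_fields` must contain at least one field.",
                 class = "fairsheet_invalid_argument")
  }
  canonical_fields[is.na(canonical_fields)] <- ""
  canonical <- paste(
    c(namespace_tag, stringi::stri_trans_nfc(canonical_fields)),
    collapse = "|")
  hex <- digest::digest(canonical, algo = "sha1", serialize = FALSE)
  hex <- substr(hex, 1L, 32L)
  # force the version nibble to 5 and the variant nibble into [89ab]
  variant <- c("8", "9", "a", "b", "8", "9", "a", "b",
               "8", "9", "a", "b", "8", "9", "a", "b")
  v <- variant[strtoi(substr(hex, 17L, 17L), 16L) + 1L]
  paste0(namespace_tag, "-",
         substr(hex, 1L, 8L), "-", substr(hex, 9L, 12L), "-",
         "5", substr(hex, 14L, 16L), "-",
         v, substr(hex, 18L, 20L), "-", substr(hex, 21L, 32L))
}

# drop NULL fields but keep a fixed field order, so that identical records
# are structurally identical (round-trip tests rely on this)
compact_fields <- function(x) x[!vapply(x, is.null, logical(1))]

chr1 <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("`%s` must be a single string or NULL.", what),
                 class = "fairsheet_invalid_argument")
  }
  x
}

num1 <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("`%s` must be a single number or NULL.", what),
                 class = "fairsheet_invalid_argument")
  }
  as.numeric(x)
}

#' Dynamic parameter or condition value
#'
#' Carrier for one entry of a protocol-application parameter list or of the
#' per-measurement experimental conditions. Holds either a number or a text
#' string (never both), with an optional unit and qualifier.
#'
#' @param number,text Exactly one of the two must be non-NULL.
#' @param unit,qualifier Optional strings.
#' @return An object of class `fs_value`.
#' @export
model_value <- function(number = NULL, text = NULL, unit = NULL,
                        qualifier = NULL) {
  if (is.null(number) == is.null(text)) {
    rlang::abort("A value holds exactly one of `number` or `text`.",
                 class = "fairsheet_invalid_argument")
  }
  out <- compact_fields(list(
    number = num1(number, "number"),
    text = chr1(text, "text"),
    unit = chr1(unit, "unit"),
    qualifier = chr1(qualifier, "qualifier")))
  structure(out, class = "fs_value")
}

#' External identifier attached to a substance
#'
#' @param system Identifier system, e.g. `"CASRN"`.
#' @param value Identifier value within that system.
#' @return An object of class `fs_external_identifier`.
#' @export
external_identifier <- function(system, value) {
  system <- stringi::stri_trim_both(chr1(system, "system"))
  value <- stringi::stri_trim_both(chr1(value, "value"))
  if (!nzchar(system) || !nzchar(value)) {
    rlang::abort("`system` and `value` must be non-empty after trimming.",
                 class = "fairsheet_invalid_argument")
  }
  structure(list(system = system, value = value),
            class = "fs_external_identifier")
}

#' Roles a component can play within a composition
#' @export
COMPONENT_ROLES <- c("MAIN_CONSTITUENT", "IMPURITY", "ADDITIVE",
                     "CORE", "COATING", "FUNCTIONALISATION", "OTHER")

#' Component of a substance composition
#'
#' A constituent of the material: a classical main constituent, impurity or
#' additive, or (for nanomaterials) a core, coating or functionalisation
#' layer. Structure notation is carried as opaque text; no chemical
#' interpretation is attempted. Linkages describe relations to sibling
#' components of the same composition (e.g. "covalently bonded",
#' "encapsulated"), referenced by 1-based component index.
#'
#' @param role One of [COMPONENT_ROLES].
#' @param name,structure Optional strings.
#' @param properties Named list of [model_value()] objects.
#' @param linkages List of `list(target = <index>, relation = <text>)`.
#' @return An object of class `fs_component`.
#' @export
component <- function(role, name = NULL, structure = NULL,
                      properties = list(), linkages = list()) {
  role <- chr1(role, "role")
  if (is.null(role) || !role %in% COMPONENT_ROLES) {
    rlang::abort(paste0("`role` must be one of: ",
                        paste(COMPONENT_ROLES, collapse = ", ")),
                 class = "fairsheet_invalid_argument")
  }
  linkages <- lapply(linkages, function(l) {
    list(target = as.numeric(num1(l$target, "linkage target")),
         relation = chr1(l$relation, "linkage relation"))
  })
  out <- compact_fields(list(
    role = role, name = chr1(name, "name"),
    structure = chr1(structure, "structure"),
    properties = if (length(properties)) properties else NULL,
    linkages = if (length(linkages)) linkages else NULL))
  structure(out, class = "fs_component")
}

#' Composition of a substance
#'
#' @param components List of [component()] objects; at least one. Linkage
#'   targets must point at existing components of this composition.
#' @param composition_uuid Optional identifier; derived from the component
#'   content when missing.
#' @return An object of class `fs_composition`.
#' @export
composition <- function(components, composition_uuid = NULL) {
  if (length(components) < 1L) {
    rlang::abort("A composition needs at least one component.",
                 class = "fairsheet_invalid_argument")
  }
  n <- length(components)
  for (i in seq_along(components)) {
    for (l in components[[i]]$linkages) {
      if (l$target < 1 || l$target > n) {
        rlang::abort(sprintf(
          "Component %d linkage target %s does not reference an existing component (1..%d).",
          i, format(l$target), n), class = "fairsheet_invalid_argument")
      }
    }
  }
  if (is.null(composition_uuid)) {
    key <- vapply(components, function(cp) {
      paste(cp$role, cp$name %||% "", cp$structure %||% "", sep = ":")
    }, character(1))
    composition_uuid <- generate_uuid("COMPOSITION", key)
  }
  structure(list(composition_uuid = composition_uuid,
                 components = components),
            class = "fs_composition")
}

#' Single measurement (effect record)
#'
#' One measured outcome of applying a protocol: an endpoint with a numeric
#' value, an interval with qualifiers (`3 < x <= 4` is `lo_qualifier = ">"`,
#' `lo_value = 3`, `up_qualifier = "<="`, `up_value = 4`), an uncertainty
#' with its own qualifier (e.g. `"SD"`), or a plain text value, plus the
#' dynamic list of experimental conditions (concentration, time, replicate,
#' ...) the measurement was made under.
#'
#' @param endpoint Measured quantity (required). May be a string or an
#'   [annotated_term()].
#' @param sample_id,endpoint_type,text_value,unit Optional strings.
#' @param lo_qualifier,up_qualifier One of `=`, `<`, `<=`, `>`, `>=`, `~`.
#' @param err_qualifier Free text (e.g. `"SD"`).
#' @param lo_value,up_value,err_value Optional numbers.
#' @param conditions Named list of [model_value()]; insertion order kept.
#' @return An object of class `fs_effect_record`.
#' @export
effect_record <- function(endpoint, sample_id = NULL, endpoint_type = NULL,
                          lo_qualifier = NULL, lo_value = NULL,
                          up_qualifier = NULL, up_value = NULL,
                          err_qualifier = NULL, err_value = NULL,
                          text_value = NULL, unit = NULL,
                          conditions = list()) {
  qset <- c("=", "<", "<=", ">", ">=", "~")
  for (q in list(list(lo_qualifier, "lo_qualifier"),
                 list(up_qualifier, "up_qualifier"))) {
    if (!is.null(q[[1]]) && !q[[1]] %in% qset) {
      rlang::abort(sprintf("`%s` must be one of: %s", q[[2]],
                           paste(qset, collapse = " ")),
                   class = "fairsheet_invalid_argument")
    }
  }
  if (is.null(lo_value) && is.null(up_value) && is.null(text_value)) {
    rlang::abort(
      "An effect record needs at least one of lo_value, up_value, text_value.",
      class = "fairsheet_invalid_argument")
  }
  out <- compact_fields(list(
    sample_id = chr1(sample_id, "sample_id"),
    endpoint = if (inherits(endpoint, "fs_annotated_term")) endpoint
               else chr1(endpoint, "endpoint"),
    endpoint_type = endpoint_type,
    lo_qualifier = chr1(lo_qualifier, "lo_qualifier"),
    lo_value = num1(lo_value, "lo_value"),
    up_qualifier = chr1(up_qualifier, "up_qualifier"),
    up_value = num1(up_value, "up_value"),
    err_qualifier = chr1(err_qualifier, "err_qualifier"),
    err_value = num1(err_value, "err_value"),
    text_value = chr1(text_value, "text_value"),
    unit = chr1(unit, "unit"),
    conditions = if (length(conditions)) conditions else NULL))
  structure(out, class = "fs_effect_record")
}

#' Protocol application
#'
#' One event of applying an experimental protocol to a substance. Owns the
#' citation and interpretation metadata, the dynamic (ordered) parameter
#' list, and the measurement effects. The identifier is hash-based and
#' deterministic: it is derived from the owning substance identifier, the
#' protocol identity (citation title and guidelines) and the parameter list,
#' so re-parsing the same sheet reproduces the same identifier.
#'
#' @param substance_uuid Identifier of the owning substance (used only to
#'   derive `uuid` when `uuid` is missing).
#' @param uuid Optional explicit identifier.
#' @param citation_title,citation_year,citation_owner Optional strings.
#' @param protocol_guideline Character vector of guideline references.
#' @param interpretation_result,interpretation_criteria Optional strings.
#' @param parameters Named list of [model_value()]; insertion order kept.
#' @param effects List of [effect_record()] objects.
#' @param investigation_uuid,assay_uuid Optional grouping identifiers; only
#'   ever set explicitly through configuration, never inferred.
#' @param reliability_flag Optional data-quality flag.
#' @return An object of class `fs_protocol_application`.
#' @export
protocol_application <- function(substance_uuid = NULL, uuid = NULL,
                                 citation_title = NULL, citation_year = NULL,
                                 citation_owner = NULL,
                                 protocol_guideline = character(),
                                 interpretation_result = NULL,
                                 interpretation_criteria = NULL,
                                 parameters = list(), effects = list(),
                                 investigation_uuid = NULL, assay_uuid = NULL,
                                 reliability_flag = NULL) {
  if (is.null(uuid)) {
    par_sig <- vapply(seq_along(parameters), function(i) {
      v <- parameters[[i]]
      paste0(names(parameters)[i], "=",
             if (!is.null(v$number)) format(v$number, digits = 15) else v$text %||% "")
    }, character(1))
    uuid <- generate_uuid("PA", c(substance_uuid %||% "",
                                  citation_title %||% "",
                                  protocol_guideline, par_sig))
  }
  out <- compact_fields(list(
    uuid = uuid,
    citation_title = chr1(citation_title, "citation_title"),
    citation_year = chr1(citation_year, "citation_year"),
    citation_owner = chr1(citation_owner, "citation_owner"),
    protocol_guideline = if (length(protocol_guideline))
      as.character(protocol_guideline) else NULL,
    interpretation_result = chr1(interpretation_result, "interpretation_result"),
    interpretation_criteria = chr1(interpretation_criteria,
                                   "interpretation_criteria"),
    parameters = if (length(parameters)) parameters else NULL,
    effects = if (length(effects)) effects else NULL,
    investigation_uuid = chr1(investigation_uuid, "investigation_uuid"),
    assay_uuid = chr1(assay_uuid, "assay_uuid"),
    reliability_flag = chr1(reliability_flag, "reliability_flag")))
  structure(out, class = "fs_protocol_application")
}

#' Substance record
#'
#' Top-level unit of the data model: a chemical substance or nanomaterial,
#' identified by its names and a deterministic hash-based identifier,
#' characterized by one or more compositions and carrying its measurements
#' as protocol applications.
#'
#' @param substance_name Primary name (required unless `substance_uuid`
#'   given).
#' @param public_name,owner_name,owner_uuid,substance_type Optional strings.
#' @param substance_uuid Optional explicit identifier; derived from
#'   `substance_name` + `owner_name` when missing.
#' @param external_identifiers List of [external_identifier()]; duplicate
#'   (system, value) pairs are collapsed.
#' @param compositions List of [composition()] objects.
#' @param protocol_applications List of [protocol_application()] objects.
#' @return An object of class `fs_substance_record`.
#' @export
substance_record <- function(substance_name = NULL, public_name = NULL,
                             owner_name = NULL, owner_uuid = NULL,
                             substance_uuid = NULL, substance_type = NULL,
                             external_identifiers = list(),
                             compositions = list(),
                             protocol_applications = list()) {
  substance_name <- chr1(substance_name, "substance_name")
  if (is.null(substance_uuid)) {
    if (is.null(substance_name)) {
      rlang::abort("Need `substance_name` or an explicit `substance_uuid`.",
                   class = "fairsheet_invalid_argument")
    }
    substance_uuid <- generate_uuid("SUBSTANCE",
                                    c(substance_name, owner_name %||% ""))
  }
  external_identifiers <- dedupe_identifiers(external_identifiers)
  out <- compact_fields(list(
    substance_name = substance_name,
    public_name = chr1(public_name, "public_name"),
    owner_name = chr1(owner_name, "owner_name"),
    owner_uuid = chr1(owner_uuid, "owner_uuid"),
    substance_uuid = substance_uuid,
    substance_type = chr1(substance_type, "substance_type"),
    external_identifiers = if (length(external_identifiers))
      external_identifiers else NULL,
    compositions = if (length(compositions)) compositions else NULL,
    protocol_applications = if (length(protocol_applications))
      protocol_applications else NULL))
  structure(out, class = "fs_substance_record")
}

dedupe_identifiers <- function(ids) {
  if (!length(ids)) return(ids)
  key <- vapply(ids, function(x) paste0(x$system, "\r", x$value), character(1))
  ids[!duplicated(key)]
}

#' Merge substance-record fragments sharing an identifier
#'
#' Multiple sheets or configurations may each yield a fragment of the same
#' substance. Fragments sharing a `substance_uuid` are merged: external
#' identifiers are unioned, compositions and protocol applications
#' concatenated, and missing scalar fields filled from later fragments.
#' Order of first appearance is preserved; the result is idempotent under
#' repeated merging.
#'
#' @param records List of [substance_record()] objects, all with a
#'   `substance_uuid`.
#' @return List of merged `fs_substance_record` objects.
#' @export
merge_records <- function(records) {
  uuids <- vapply(records, function(r) r$substance_uuid %||% "", character(1))
  if (any(!nzchar(uuids))) {
    rlang::abort("All records must carry a substance_uuid before merging.",
                 class = "fairsheet_invalid_argument")
  }
  out <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    u <- uuids[i]
    if (is.null(out[[u]])) {
      out[[u]] <- r
      next
    }
    a <- out[[u]]
    if (!is.null(a$substance_name) && !is.null(r$substance_name) &&
        !identical(a$substance_name, r$substance_name)) {
      rlang::abort(sprintf(
        "Conflicting substance_name for uuid %s: \"%s\" vs \"%s\".",
        u, a$substance_name, r$substance_name),
        class = "fairsheet_merge_conflict")
    }
    for (f in c("substance_name", "public_name", "owner_name", "owner_uuid",
                "substance_type")) {
      if (is.null(a[[f]]) && !is.null(r[[f]])) a[[f]] <- r[[f]]
    }
    merged <- substance_record(
      substance_name = a$substance_name, public_name = a$public_name,
      owner_name = a$owner_name, owner_uuid = a$owner_uuid,
      substance_uuid = u, substance_type = a$substance_type,
      external_identifiers = c(a$external_identifiers %||% list(),
                               r$external_identifiers %||% list()),
      compositions = c(a$compositions %||% list(),
                       r$compositions %||% list()),
      protocol_applications = c(a$protocol_applications %||% list(),
                                r$protocol_applications %||% list()))
    out[[u]] <- merged
  }
  unname(out)
}

#' Flatten the effects of parsed records into a tibble
#'
#' Convenience accessor: one row per effect record, with the owning
#' substance and protocol application alongside, and one `condition_<name>`
#' column per distinct condition (numeric conditions stay numeric; text
#' conditions come out as text).
#'
#' @param records A list of [substance_record()] objects (e.g. the output of
#'   [parse_workbook()]).
#' @return A tibble.
#' @export
effects_table <- function(records) {
  rows <- list()
  for (r in records) {
    for (pa in r$protocol_applications %||% list()) {
      for (ef in pa$effects %||% list()) {
        endpoint <- if (inherits(ef$endpoint, "fs_annotated_term"))
          ef$endpoint$canonical else ef$endpoint
        row <- list(substance_name = r$substance_name %||% NA_character_,
                    substance_uuid = r$substance_uuid,
                    pa_uuid = pa$uuid,
                    endpoint = endpoint %||% NA_character_,
                    sample_id = ef$sample_id %||% NA_character_,
                    lo_qualifier = ef$lo_qualifier %||% NA_character_,
                    lo_value = ef$lo_value %||% NA_real_,
                    up_qualifier = ef$up_qualifier %||% NA_character_,
                    up_value = ef$up_value %||% NA_real_,
                    err_qualifier = ef$err_qualifier %||% NA_character_,
                    err_value = ef$err_value %||% NA_real_,
                    text_value = ef$text_value %||% NA_character_,
                    unit = ef$unit %||% NA_character_)
        for (nm in names(ef$conditions %||% list())) {
          v <- ef$conditions[[nm]]
          row[[paste0("condition_", nm)]] <-
            if (!is.null(v$number)) v$number else v$text
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(substance_name = character(),
                          substance_uuid = character(),
                          pa_uuid = character(), endpoint = character()))
  }
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(row) {
    row[setdiff(cols, names(row))] <- NA
    row[cols]
  })
  tibble::as_tibble(do.call(rbind, lapply(filled, function(r) {
    tibble::as_tibble(r)
  })))
}

#' @export
print.fs_substance_record <- function(x, ...) {
  n_pa <- length(x$protocol_applications %||% list())
  n_ef <- sum(vapply(x$protocol_applications %||% list(),
                     function(pa) length(pa$effects %||% list()), integer(1)))
  cat(sprintf("<substance record> %s (%s)\n  %d identifier(s), %d composition(s), %d protocol application(s), %d effect(s)\n",
              x$substance_name %||% "<unnamed>", x$substance_uuid,
              length(x$external_identifiers %||% list()),
              length(x$compositions %||% list()), n_pa, n_ef))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
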