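#' Normalize a term to its dictionary lookup key
#'
#' Deterministic minimal normalization covering the spelling, letter-case
#' and spacing variation typical of curated lab sheets: Unicode NFKC case
#' folding, then removal of whitespace and of the separator characters
#' `- _ . /`. No stemming or edit-distance matching is applied at lookup
#' time — aggressive correction unattended is riskier than a curator
#' reviewing a near-miss report. All of "BEAS 2B", "Beas 2B" and
#' "BEAS -2B" normalize to the same key.
#'
#' @param raw Character vector.
#' @return Character vector of keys (empty input stays empty).
#' @export
normalize_key <- function(raw) {
  if (!length(raw)) return(character())
  out <- stringi::stri_trans_nfkc_casefold(as.character(raw))
  stringi::stri_replace_all_regex(out, "[\\s\\-_./]+", "")
}

#' Harmonization dictionary
#'
#' Maps normalized spelling-variant keys to canonical terms, and canonical
#' terms to zero or more controlled-vocabulary annotations. Canonical terms
#' are required to be fixed points of the lookup (each canonical term's own
#' key maps back to itself), which is what makes harmonization idempotent.
#'
#' @param entries Named character vector or list: variant (any spelling) ->
#'   canonical term.
#' @param annotations Named list: canonical term -> list of annotation
#'   entries, each `list(vocabulary =, id =, label =)`.
#' @return An object of class `fs_dictionary`.
#' @export
dictionary <- function(entries, annotations = list()) {
  entries <- unlist(entries)
  keys <- normalize_key(names(entries))
  canon <- as.character(entries)
  map <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!nzchar(k)) next
    if (!is.null(map[[k]]) && !identical(map[[k]], canon[i])) {
      rlang::abort(sprintf(
        "Dictionary keys collide after normalization: \"%s\" maps to both \"%s\" and \"%s\".",
        k, map[[k]], canon[i]), class = "fairsheet_invalid_argument")
    }
    map[[k]] <- canon[i]
  }
  # canonical terms must be fixed points: add their own keys, then check
  for (cv in unique(canon)) {
    k <- normalize_key(cv)
    if (is.null(map[[k]])) map[[k]] <- cv
    else if (!identical(map[[k]], cv)) {
      rlang::abort(sprintf(
        "Canonical term \"%s\" is not a fixed point: its key resolves to \"%s\".",
        cv, map[[k]]), class = "fairsheet_invalid_argument")
    }
  }
  annotations <- lapply(annotations, function(terms) {
    lapply(terms, function(t) {
      list(vocabulary = t$vocabulary %||% NA_character_,
           id = t$id %||% NA_character_,
           label = t$label %||% NA_character_)
    })
  })
  structure(list(entries = map, annotations = annotations),
            class = "fs_dictionary")
}

#' Read / write a dictionary file
#'
#' Dictionaries are curator-editable UTF-8 JSON files of the form
#' `{"entries": {"variant": "canonical", ...},
#'   "annotations": {"canonical": [{"vocabulary":, "id":, "label":}, ...]}}`,
#' suitable for version control.
#'
#' @param path File path.
#' @param dict An `fs_dictionary`.
#' @return `read_dictionary()` returns an `fs_dictionary`;
#'   `write_dictionary()` returns `path` invisibly.
#' @export
read_dictionary <- function(path) {
  x <- jsonlite::parse_json(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"))
  dictionary(entries = x$entries %||% list(),
             annotations = x$annotations %||% list())
}

#' @rdname read_dictionary
#' @export
write_dictionary <- function(dict, path) {
  writeLines(jsonlite::toJSON(list(entries = dict$entries,
                                   annotations = dict$annotations),
                              auto_unbox = TRUE, pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' Annotated term
#'
#' The result of harmonizing a text field: the original spelling is kept
#' verbatim, the canonical form comes from the dictionary, and zero or more
#' vocabulary/ontology annotations may be attached (more than one is
#' explicitly allowed, so multiple — including private — dictionaries can
#' annotate the same entry).
#'
#' @param original Text as found in the source, preserved bit-for-bit.
#' @param canonical Canonical term.
#' @param annotations List of `list(vocabulary =, id =, label =)`.
#' @return An object of class `fs_annotated_term`.
#' @export
annotated_term <- function(original, canonical, annotations = list()) {
  structure(list(original = original, canonical = canonical,
                 annotations = annotations),
            class = "fs_annotated_term")
}

#' @export
print.fs_annotated_term <- function(x, ...) {
  cat(sprintf("<annotated> \"%s\" -> \"%s\" (%d annotation(s))\n",
              x$original, x$canonical, length(x$annotations)))
  invisible(x)
}

#' Look a term up in a dictionary
#'
#' @param dict An [dictionary()].
#' @param raw Text to look up (or an existing [annotated_term()], in which
#'   case its canonical form is looked up and the original kept).
#' @return An `fs_annotated_term` on a hit, else `NULL`.
#' @export
lookup_term <- function(dict, raw) {
  original <- if (inherits(raw, "fs_annotated_term")) raw$original else raw
  probe <- if (inherits(raw, "fs_annotated_term")) raw$canonical else raw
  hit <- dict$entries[[normalize_key(probe)]]
  if (is.null(hit)) return(NULL)
  annotated_term(original = original, canonical = hit,
                 annotations = dict$annotations[[hit]] %||% list())
}

# field classes with dedicated record slots; any other dictionary name is
# matched against parameter/condition names
HARMONIZE_FIELD_CLASSES <- c("endpoint", "endpoint_type", "substance_name",
                             "substance_type")

#' Harmonize the metadata of parsed records
#'
#' Post-parse dictionary lookup, applied deliberately after import so the
#' stored values stay as close as possible to the original source: matched
#' text fields are replaced by [annotated_term()] objects that carry the
#' original verbatim; unmatched terms pass through untouched and are listed
#' in the miss report. Applying the operation twice is a no-op because
#' canonical terms are fixed points of the lookup.
#'
#' Dictionaries named `endpoint`, `endpoint_type`, `substance_name` or
#' `substance_type` target those record fields; a dictionary under any
#' other name targets the text values of parameters and conditions whose
#' (normalized) name matches it — e.g. a `cell_type` dictionary harmonizes
#' a "Cell type" condition.
#'
#' @param record A [substance_record()].
#' @param dictionaries Named list of [dictionary()] objects.
#' @return The harmonized record; the miss report is attached as
#'   `attr(, "harmonization_misses")` (tibble with `field`, `original`,
#'   `key`, `suggestion`).
#' @export
harmonize_record <- function(record, dictionaries) {
  misses <- list()
  note_miss <- function(field, original, dict) {
    key <- normalize_key(if (inherits(original, "fs_annotated_term"))
      original$canonical else original)
    sugg <- near_miss(key, dict)
    misses[[length(misses) + 1L]] <<-
      list(field = field,
           original = if (inherits(original, "fs_annotated_term"))
             original$original else original,
           key = key, suggestion = sugg)
  }
  apply_dict <- function(x, dict, field) {
    if (is.null(x)) return(NULL)
    hit <- lookup_term(dict, x)
    if (is.null(hit)) {
      if (!inherits(x, "fs_annotated_term")) note_miss(field, x, dict)
      return(x)
    }
    hit
  }
  for (cls in intersect(names(dictionaries), HARMONIZE_FIELD_CLASSES)) {
    if (cls %in% c("substance_name", "substance_type")) {
      record[[cls]] <- apply_dict(record[[cls]], dictionaries[[cls]], cls)
    }
  }
  cond_dicts <- dictionaries[setdiff(names(dictionaries),
                                     HARMONIZE_FIELD_CLASSES)]
  cond_keys <- normalize_key(names(cond_dicts))
  harmonize_value <- function(v, owner, nm) {
    idx <- match(normalize_key(nm), cond_keys)
    if (is.na(idx) || is.null(v$text)) return(v)
    hit <- lookup_term(cond_dicts[[idx]], v$annotation %||% v$text)
    if (is.null(hit)) {
      if (is.null(v$annotation)) {
        note_miss(paste0(owner, ".", nm), v$text, cond_dicts[[idx]])
      }
      return(v)
    }
    v$text <- hit$canonical
    v$annotation <- hit
    v
  }
  pas <- record$protocol_applications %||% list()
  for (i in seq_along(pas)) {
    pa <- pas[[i]]
    for (nm in names(pa$parameters %||% list())) {
      pa$parameters[[nm]] <- harmonize_value(pa$parameters[[nm]],
                                             "parameters", nm)
    }
    effs <- pa$effects %||% list()
    for (k in seq_along(effs)) {
      ef <- effs[[k]]
      if (!is.null(dictionaries$endpoint)) {
        ef$endpoint <- apply_dict(ef$endpoint, dictionaries$endpoint,
                                  "endpoint")
      }
      if (!is.null(dictionaries$endpoint_type)) {
        ef$endpoint_type <- apply_dict(ef$endpoint_type,
                                       dictionaries$endpoint_type,
                                       "endpoint_type")
      }
      for (nm in names(ef$conditions %||% list())) {
        ef$conditions[[nm]] <- harmonize_value(ef$conditions[[nm]],
                                               "conditions", nm)
      }
      effs[[k]] <- ef
    }
    pa$effects <- effs
    pas[[i]] <- pa
  }
  record$protocol_applications <- pas
  attr(record, "harmonization_misses") <- miss_tibble(misses)
  record
}

miss_tibble <- function(misses) {
  if (!length(misses)) {
    return(tibble::tibble(field = character(), original = character(),
                          key = character(), suggestion = character()))
  }
  tibble::tibble(
    field = vapply(misses, `[[`, character(1), "field"),
    original = vapply(misses, `[[`, character(1), "original"),
    key = vapply(misses, `[[`, character(1), "key"),
    suggestion = vapply(misses, `[[`, character(1), "suggestion"))
}

# nearest dictionary key within edit distance 1, reported for curator
# review only — never applied automatically
near_miss <- function(key, dict) {
  keys <- names(dict$entries)
  if (!length(keys) || !nzchar(key)) return(NA_character_)
  d <- utils::adist(key, keys)[1, ]
  i <- which.min(d)
  if (d[i] <= 1L) dict$entries[[keys[i]]] else NA_character_
}

#' @rdname harmonize_record
#' @param records List of records.
#' @return `harmonize_records()` returns the list, with the combined miss
#'   report in `attr(, "harmonization_misses")`.
#' @export
harmonize_records <- function(records, dictionaries) {
  all_misses <- list()
  out <- lapply(records, function(r) {
    h <- harmonize_record(r, dictionaries)
    m <- attr(h, "harmonization_misses")
    if (nrow(m)) all_misses[[length(all_misses) + 1L]] <<- m
    h
  })
  attr(out, "harmonization_misses") <-
    if (length(all_misses)) unique(do.call(rbind, all_misses))
    else miss_tibble(list())
  out
}

#' Write a harmonization miss report
#'
#' Tab-delimited text listing every term no dictionary could harmonize,
#' with the normalized key and, where one exists within edit distance 1, a
#' suggested canonical term for curator review.
#'
#' @param misses Tibble as attached by [harmonize_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_miss_report <- function(misses, path) {
  utils::write.table(misses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
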