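# io_cli: entity/relation CSV writers, FHIR-style JSON output for family
# chains, and a minimal schema validator.

#' Convert extraction entities to the entity output record format
#'
#' The entity output record has exactly these columns, in this order:
#' `file_name`, `sentence_id`, `chunk_id`, `entity_type`, `concept`,
#' `certainty`. For observations the concept is the CUI, extended to
#' `CUI|SNOMED` when a SNOMED mapping is supplied (SNOMED codes only ever
#' appear when the separate, license-gated mapping file is provided).
#'
#' @param entities An [fh_extract()] entity tibble.
#' @param snomed_mapping Optional mapping (see [apply_snomed_mapping()]).
#' @return A tibble in entity-record column order.
#' @export
as_entity_records <- function(entities, snomed_mapping = NULL) {
  concept <- entities$concept
  if (!is.null(snomed_mapping)) {
    if (is.character(snomed_mapping)) {
      snomed_mapping <- data.frame(cui = names(snomed_mapping),
                                   snomed_code = unname(snomed_mapping))
    }
    idx <- match(concept, snomed_mapping$cui)
    hit <- entities$type == "Observation" & !is.na(idx)
    concept[hit] <- paste0(concept[hit], "|",
                           snomed_mapping$snomed_code[idx[hit]])
  }
  tibble::tibble(file_name = entities$doc_id,
                 sentence_id = entities$sent_id,
                 chunk_id = entities$chunk_id,
                 entity_type = entities$type,
                 concept = concept,
                 certainty = entities$certainty)
}

#' Convert extraction relations to the relation output record format
#'
#' The relation output record has exactly these columns, in this order:
#' `file_name`, `family_member`, `side_of_family`, `observation_text`,
#' `certainty`.
#'
#' @param relations An [fh_extract()] relation tibble.
#' @return A tibble in relation-record column order.
#' @export
as_relation_records <- function(relations) {
  tibble::tibble(file_name = relations$doc_id,
                 family_member = relations$fm_category,
                 side_of_family = relations$fm_side,
                 observation_text = relations$target_text,
                 certainty = relations$certainty)
}

write_csv_stable <- function(df, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, na = "",
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write entity / relation outputs
#'
#' CSV output is UTF-8 with a header row and the fixed column orders of
#' [as_entity_records()] / [as_relation_records()]; identical inputs yield
#' byte-identical files. An unknown format is a usage error. FHIR-style
#' output operates on chains; see [write_fhir()].
#'
#' @param entities,relations Extraction tibbles from [fh_extract()].
#' @param path Output file path.
#' @param format Only `"csv"` here.
#' @param snomed_mapping Optional mapping for [as_entity_records()].
#' @return `path`, invisibly.
#' @export
write_entities <- function(entities, path, format = "csv",
                           snomed_mapping = NULL) {
  if (!identical(format, "csv")) {
    stop("unknown entity output format: ", format,
         " (use 'csv', or write_fhir() for chain output)")
  }
  write_csv_stable(as_entity_records(entities, snomed_mapping), path)
}

#' @rdname write_entities
#' @export
write_relations <- function(relations, path, format = "csv") {
  if (!identical(format, "csv")) {
    stop("unknown relation output format: ", format,
         " (use 'csv', or write_fhir() for chain output)")
  }
  write_csv_stable(as_relation_records(relations), path)
}

#' @rdname write_entities
#' @param path CSV path to read back.
#' @export
read_entity_records <- function(path) {
  tibble::as_tibble(utils::read.csv(path, colClasses = c(
    file_name = "character", sentence_id = "integer", chunk_id = "integer",
    entity_type = "character", concept = "character",
    certainty = "character"), fileEncoding = "UTF-8"))
}

#' @rdname write_entities
#' @export
read_relation_records <- function(path) {
  tibble::as_tibble(utils::read.csv(path, colClasses = "character",
                                    fileEncoding = "UTF-8"))
}

#' Render family chains as FHIR-style JSON
#'
#' One FamilyMemberHistory-shaped object per chain: the relationship
#' (category and side of family) plus condition sub-entries carrying the
#' observation text, CUI, optional SNOMED code, certainty, and any
#' same-clause age annotations. The shape is documented by the JSON schema
#' shipped at `inst/schema/family-member-history.schema.json` and checked
#' by [validate_fhir()]; it is a faithful JSON rendering for downstream
#' interoperability, not a profiled server resource.
#'
#' @param chains A chain tibble from [assemble_chains()] /
#'   [fh_extract()].
#' @param snomed_mapping Optional CUI-to-SNOMED mapping.
#' @return A list of FamilyMemberHistory-shaped lists.
#' @export
chains_to_fhir <- function(chains, snomed_mapping = NULL) {
  if (is.character(snomed_mapping)) {
    snomed_mapping <- data.frame(cui = names(snomed_mapping),
                                 snomed_code = unname(snomed_mapping))
  }
  lapply(seq_len(nrow(chains)), function(i) {
    tg <- chains$targets[[i]]
    ages <- chains$ages[[i]]
    conds <- lapply(seq_len(nrow(tg)), function(j) {
      code <- list(cui = tg$target_cui[j])
      if (!is.null(snomed_mapping) && !is.na(tg$target_cui[j])) {
        k <- match(tg$target_cui[j], snomed_mapping$cui)
        if (!is.na(k)) code$snomed <- snomed_mapping$snomed_code[k]
      }
      if (is.na(code$cui)) code$cui <- NULL
      list(kind = tg$target_kind[j], text = tg$target_text[j],
           code = code, certainty = tg$certainty[j])
    })
    obj <- list(resourceType = "FamilyMemberHistory",
                fileName = chains$doc_id[i],
                relationship = list(text = chains$fm_category[i]),
                sideOfFamily = chains$fm_side[i],
                condition = conds)
    if (!is.null(ages) && nrow(ages) > 0) {
      obj$age <- list(value = ages$value[1], kind = ages$kind[1])
    }
    obj
  })
}

#' @rdname chains_to_fhir
#' @param path Output JSON path.
#' @export
write_fhir <- function(chains, path, snomed_mapping = NULL) {
  jsonlite::write_json(chains_to_fhir(chains, snomed_mapping), path,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Validate FHIR-style chain output
#'
#' Structural validation of [chains_to_fhir()] output (or a written JSON
#' file) against the shipped schema contract: resource type, non-empty
#' relationship, side-of-family vocabulary, condition entries with a
#' certainty from the binary vocabulary and well-formed CUI/SNOMED codes
#' when present.
#'
#' @param x A list from [chains_to_fhir()] or a path to a JSON file.
#' @return A list with `valid` (logical) and `problems` (character).
#' @export
validate_fhir <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- jsonlite::read_json(x)
  }
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))
  for (i in seq_along(x)) {
    o <- x[[i]]
    if (!identical(o$resourceType, "FamilyMemberHistory")) {
      note("[%d] resourceType is not FamilyMemberHistory", i)
    }
    if (is.null(o$relationship$text) || !nzchar(o$relationship$text)) {
      note("[%d] missing relationship.text", i)
    }
    if (is.null(o$sideOfFamily) ||
        !o$sideOfFamily %in% c("Maternal", "Paternal", "NA")) {
      note("[%d] bad sideOfFamily", i)
    }
    for (j in seq_along(o$condition)) {
      cd <- o$condition[[j]]
      if (is.null(cd$text) || !nzchar(cd$text)) {
        note("[%d] condition %d missing text", i, j)
      }
      if (is.null(cd$certainty) ||
          !cd$certainty %in% c("negated", "nonnegated")) {
        note("[%d] condition %d bad certainty", i, j)
      }
      if (!is.null(cd$code$cui) && !is_cui(cd$code$cui)) {
        note("[%d] condition %d malformed CUI", i, j)
      }
      if (!is.null(cd$code$snomed) && !grepl("^[0-9]+$", cd$code$snomed)) {
        note("[%d] condition %d malformed SNOMED code", i, j)
      }
    }
  }
  list(valid = length(problems) == 0, problems = problems)
}
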