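# End-to-end rule-based extraction: section -> sentences -> clauses ->
# entities -> relations -> chains, for one document or a corpus.

#' Run configuration for the rule-based extractor
#'
#' Bundles the tunable surface of the system. The defaults reproduce the
#' documented behavior: a three-sentence coreference window, the shipped
#' family-member rule table, negation triggers and cue set, and a
#' 20-patient threshold for the lexicon builder's curation queue.
#'
#' @param window Coreference window in sentences (the cue sentence plus
#'   `window - 1` preceding ones).
#' @param min_patients Distinct-patient threshold for curation queueing.
#' @param headers Family-history section header labels.
#' @param coref_cues Coreference cue set.
#' @param negation_triggers Negation trigger list.
#' @param fm_rules Family-member rule table (`NULL` = shipped table).
#' @param extended_fm `"drop"` or `"map"`; see
#'   [recognize_family_members()].
#' @param seed Optional integer seed for stages that draw random numbers
#'   (only the synthetic-corpus generator does).
#' @return A list of class `fh_config`.
#' @export
fh_config <- function(window = 3L, min_patients = 20L,
                      headers = fh_section_headers(),
                      coref_cues = fh_coref_cues(),
                      negation_triggers = fh_negation_triggers(),
                      fm_rules = NULL,
                      extended_fm = c("drop", "map"),
                      seed = NULL) {
  structure(list(window = as.integer(window),
                 min_patients = as.integer(min_patients),
                 headers = headers, coref_cues = coref_cues,
                 negation_triggers = negation_triggers,
                 fm_rules = fm_rules %||% fh_fm_rules(),
                 extended_fm = match.arg(extended_fm),
                 seed = seed),
            class = "fh_config")
}

entity_tibble <- function() {
  tibble::tibble(doc_id = character(0), sent_id = integer(0),
                 chunk_id = integer(0), type = character(0),
                 concept = character(0), side = character(0),
                 certainty = character(0), start = integer(0),
                 end = integer(0), text = character(0))
}

# clause containing a position (clauses partition the sentence)
chunk_of <- function(clauses, pos) {
  hit <- which(clauses$start <= pos & pos < clauses$end)
  if (length(hit) == 0) NA_integer_ else clauses$chunk_id[hit[[1]]]
}

#' Extract family-history entities and relations from one note
#'
#' The full rule-based pipeline: locate the family-history section, segment
#' sentences and clauses, recognize family members, dictionary-match
#' observations, extract living status and ages, assign certainty from
#' clause-level negation scope, link relations by same-clause co-occurrence
#' and cue-licensed cross-sentence coreference (backward, within a
#' three-sentence window), drop spouse relations, and assemble one chain
#' per family-member category and side.
#'
#' A target that shares a clause with *any* family-member mention —
#' including a spouse — is considered claimed by that clause and is not
#' re-linked across sentences; cross-sentence linking only rescues targets
#' with no family member at all in their clause.
#'
#' @param text Note text.
#' @param lexicon An [fh_lexicon()].
#' @param doc_id Document identifier carried into all outputs.
#' @param config An [fh_config()].
#' @return A list of class `fh_extraction` with `doc_id`, `section`,
#'   `sentences`, `entities` (tibble: `doc_id`, `sent_id`, `chunk_id`,
#'   `type`, `concept`, `side`, `certainty`, `start`, `end`, `text`),
#'   `relations` (see [link_within_clause()]), and `chains`
#'   (see [assemble_chains()]).
#' @examples
#' lex <- make_mini_lexicon(5, 3, seed = 7)
#' note <- paste0("FAMILY HISTORY: Mother has ", lex$variant[1], ".")
#' fh_extract(note, lex)$relations
#' @export
fh_extract <- function(text, lexicon, doc_id = "doc", config = fh_config()) {
  stopifnot(inherits(lexicon, "fh_lexicon"))
  rules <- config$fm_rules %||% fh_fm_rules()
  sec <- find_family_history_section(text, config$headers)
  sents <- segment_sentences(span_text(text, sec$start, sec$end),
                             offset = sec$start)

  fms_all <- list(); obs_all <- list(); liv_all <- list()
  ages_all <- list(); cues_all <- list(); clauses_all <- list()
  for (si in seq_len(nrow(sents))) {
    st <- sents$text[si]; off <- sents$start[si]; sid <- sents$sent_id[si]
    fms <- recognize_family_members(st, rules, offset = off, sent_id = sid,
                                    extended = config$extended_fm)
    obs <- match_observations(st, lexicon, offset = off, sent_id = sid)
    liv <- extract_living_status(st, offset = off, sent_id = sid)
    ages <- extract_age(st, offset = off, sent_id = sid)
    clauses <- split_clauses(st, fm_spans = fms, offset = off, sent_id = sid)
    cues <- detect_coreference_cues(st, config$coref_cues, offset = off)
    cues$sent_id <- rep(sid, nrow(cues))

    assign_chunk <- function(df) {
      if (nrow(df) == 0) return(df)
      df$chunk_id <- vapply(df$start, function(p) chunk_of(clauses, p),
                            integer(1))
      df
    }
    fms <- assign_chunk(fms)
    obs <- assign_chunk(obs)
    liv <- assign_chunk(liv)
    ages <- assign_chunk(ages)

    refine_certainty <- function(df) {
      for (r in seq_len(nrow(df))) {
        cl <- clauses[clauses$chunk_id == df$chunk_id[r], ]
        df$certainty[r] <- detect_certainty(
          cl$text[1], df$start[r] - cl$start[1],
          triggers = config$negation_triggers)
      }
      df
    }
    obs <- refine_certainty(obs)
    liv <- refine_certainty(liv)

    fms_all[[si]] <- fms; obs_all[[si]] <- obs; liv_all[[si]] <- liv
    ages_all[[si]] <- ages; clauses_all[[si]] <- clauses
    cues_all[[si]] <- cues
  }
  bindr <- function(x, proto) {
    if (length(x) == 0) proto else dplyr::bind_rows(x)
  }
  fms <- bindr(fms_all, recognize_family_members(""))
  obs <- bindr(obs_all, match_observations("", lexicon))
  liv <- bindr(liv_all, extract_living_status(""))
  ages <- bindr(ages_all, extract_age(""))
  clauses <- bindr(clauses_all, split_clauses("")[0, ])
  cues <- bindr(cues_all,
                tibble::tibble(cue = character(0), start = integer(0),
                               end = integer(0), sent_id = integer(0)))

  targets <- dplyr::bind_rows(
    if (nrow(obs) > 0) tibble::tibble(
      sent_id = obs$sent_id, chunk_id = obs$chunk_id, start = obs$start,
      end = obs$end, target_kind = "observation", target_text = obs$text,
      target_cui = obs$cui, certainty = obs$certainty),
    if (nrow(liv) > 0) tibble::tibble(
      sent_id = liv$sent_id, chunk_id = liv$chunk_id, start = liv$start,
      end = liv$end, target_kind = "living_status", target_text = liv$status,
      target_cui = NA_character_, certainty = liv$certainty)
  )
  if (is.null(targets) || ncol(targets) == 0) {
    targets <- tibble::tibble(sent_id = integer(0), chunk_id = integer(0),
                              start = integer(0), end = integer(0),
                              target_kind = character(0),
                              target_text = character(0),
                              target_cui = character(0),
                              certainty = character(0))
  }

  rel_same <- list()
  claimed <- rep(FALSE, nrow(targets))
  for (ci in seq_len(nrow(clauses))) {
    cl <- clauses[ci, ]
    in_cl <- function(df) {
      df$sent_id == cl$sent_id & df$start >= cl$start & df$start < cl$end
    }
    cl_fms <- fms[in_cl(fms), , drop = FALSE]
    cl_targets <- targets[in_cl(targets), , drop = FALSE]
    if (nrow(cl_fms) > 0) claimed[in_cl(targets)] <- TRUE
    rel_same[[length(rel_same) + 1L]] <-
      link_within_clause(cl, cl_fms, cl_targets, doc_id = doc_id)
  }
  rel_same <- bindr(rel_same, relation_tibble())
  rel_cross <- link_cross_sentence(fms, targets[!claimed, , drop = FALSE],
                                   cues, window = config$window,
                                   doc_id = doc_id)
  relations <- exclude_spouse(dplyr::bind_rows(rel_same, rel_cross))
  rkey <- paste(relations$fm_category, relations$fm_side,
                relations$target_kind, relation_target_key(relations),
                relations$certainty, sep = "\r")
  relations <- relations[!duplicated(rkey), , drop = FALSE]

  # same-clause family-member/age co-occurrences feed chain age slots
  age_links <- list()
  for (r in seq_len(nrow(ages))) {
    hit <- fms$sent_id == ages$sent_id[r] & !fms$is_spouse &
      fms$chunk_id == ages$chunk_id[r]
    if (any(hit)) {
      age_links[[length(age_links) + 1L]] <- tibble::tibble(
        fm_category = fms$category[hit], fm_side = fms$side[hit],
        value = ages$value[r], kind = ages$kind[r])
    }
  }
  age_links <- if (length(age_links) > 0) dplyr::bind_rows(age_links) else NULL
  chains <- assemble_chains(relations, ages = age_links, doc_id = doc_id)

  ent <- list()
  nb <- fms[!fms$is_spouse, , drop = FALSE]
  if (nrow(nb) > 0) {
    ent[[length(ent) + 1L]] <- tibble::tibble(
      doc_id = doc_id, sent_id = nb$sent_id, chunk_id = nb$chunk_id,
      type = "FamilyMember", concept = nb$category, side = nb$side,
      certainty = "nonnegated", start = nb$start, end = nb$end,
      text = nb$text)
  }
  if (nrow(obs) > 0) {
    ent[[length(ent) + 1L]] <- tibble::tibble(
      doc_id = doc_id, sent_id = obs$sent_id, chunk_id = obs$chunk_id,
      type = "Observation", concept = obs$cui, side = NA_character_,
      certainty = obs$certainty, start = obs$start, end = obs$end,
      text = obs$text)
  }
  if (nrow(liv) > 0) {
    ent[[length(ent) + 1L]] <- tibble::tibble(
      doc_id = doc_id, sent_id = liv$sent_id, chunk_id = liv$chunk_id,
      type = "LivingStatus", concept = liv$status, side = NA_character_,
      certainty = liv$certainty, start = liv$start, end = liv$end,
      text = liv$text)
  }
  if (nrow(ages) > 0) {
    ent[[length(ent) + 1L]] <- tibble::tibble(
      doc_id = doc_id, sent_id = ages$sent_id, chunk_id = ages$chunk_id,
      type = "Age", concept = as.character(ages$value), side = NA_character_,
      certainty = "nonnegated", start = ages$start, end = ages$end,
      text = ages$text)
  }
  entities <- bindr(ent, entity_tibble())
  entities <- entities[order(entities$sent_id, entities$start), , drop = FALSE]

  structure(list(doc_id = doc_id, section = sec, sentences = sents,
                 entities = entities, relations = relations,
                 chains = chains),
            class = "fh_extraction")
}

#' @export
print.fh_extraction <- function(x, ...) {
  cat(sprintf("<fh_extraction> %s: %d sentences, %d entities, %d relations, %d chains\n",
              x$doc_id, nrow(x$sentences), nrow(x$entities),
              nrow(x$relations), nrow(x$chains)))
  invisible(x)
}

#' Extract family-history information from a corpus of notes
#'
#' @param docs A named character vector of note texts (names are document
#'   ids), a directory of `.txt` files, or an `fh_corpus` from
#'   [generate_corpus()].
#' @param lexicon An [fh_lexicon()].
#' @param config An [fh_config()].
#' @return A list of class `fh_extraction_set` with pooled `entities`,
#'   `relations` and `chains` tibbles, plus `per_doc` (list of
#'   [fh_extract()] results).
#' @export
fh_extract_corpus <- function(docs, lexicon, config = fh_config()) {
  if (inherits(docs, "fh_corpus")) {
    texts <- stats::setNames(docs$documents$text, docs$documents$doc_id)
  } else if (is.character(docs) && length(docs) == 1 && dir.exists(docs)) {
    files <- sort(list.files(docs, pattern = "\\.txt$", full.names = TRUE))
    texts <- stats::setNames(
      vapply(files, function(f) {
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
      }, ""),
      sub("\\.txt$", "", basename(files)))
  } else {
    if (is.null(names(docs))) {
      names(docs) <- sprintf("doc%04d", seq_along(docs))
    }
    texts <- docs
  }
  per_doc <- lapply(names(texts), function(id) {
    fh_extract(texts[[id]], lexicon, doc_id = id, config = config)
  })
  structure(list(
    entities = dplyr::bind_rows(c(list(entity_tibble()),
                                  lapply(per_doc, `[[`, "entities"))),
    relations = dplyr::bind_rows(c(list(relation_tibble()),
                                   lapply(per_doc, `[[`, "relations"))),
    chains = dplyr::bind_rows(lapply(per_doc, `[[`, "chains")),
    per_doc = stats::setNames(per_doc, names(texts))
  ), class = "fh_extraction_set")
}
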