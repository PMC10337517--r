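# relation_linking: clause co-occurrence, bounded cross-sentence
# coreference, spouse exclusion and per-family-member chain assembly.

relation_tibble <- function() {
  tibble::tibble(doc_id = character(0), fm_category = character(0),
                 fm_side = character(0), fm_is_spouse = logical(0),
                 target_kind = character(0), target_text = character(0),
                 target_cui = character(0), certainty = character(0),
                 provenance = character(0), fm_sent_id = integer(0),
                 target_sent_id = integer(0))
}

make_relations <- function(doc_id, fms, targets, provenance,
                           force_certainty = NULL) {
  if (nrow(fms) == 0 || nrow(targets) == 0) return(relation_tibble())
  idx <- expand.grid(f = seq_len(nrow(fms)), t = seq_len(nrow(targets)))
  tibble::tibble(
    doc_id = doc_id,
    fm_category = fms$category[idx$f],
    fm_side = fms$side[idx$f],
    fm_is_spouse = fms$is_spouse[idx$f],
    target_kind = targets$target_kind[idx$t],
    target_text = targets$target_text[idx$t],
    target_cui = targets$target_cui[idx$t],
    certainty = force_certainty %||% targets$certainty[idx$t],
    provenance = provenance,
    fm_sent_id = fms$sent_id[idx$f],
    target_sent_id = targets$sent_id[idx$t]
  )
}

#' Link family members to targets within one clause
#'
#' Every non-spouse family member in the clause is linked to every
#' observation / living-status target in the same clause; the relation
#' certainty is copied from the target mention. This is the primary
#' co-occurrence rule: one clause of one sentence.
#'
#' @param clause A one-row clause (list or tibble row) with `start`, `end`.
#' @param fms Family-member mentions of the sentence
#'   ([recognize_family_members()] output).
#' @param targets Combined target tibble with columns `sent_id`, `start`,
#'   `end`, `target_kind` (`"observation"` or `"living_status"`),
#'   `target_text`, `target_cui` (`NA` for living status), `certainty`.
#' @param doc_id Document id stamped on relations.
#' @return A relation tibble (`provenance = "same_clause"`).
#' @export
link_within_clause <- function(clause, fms, targets, doc_id = "doc") {
  inside <- function(df) {
    df[df$start >= clause$start & df$start < clause$end, , drop = FALSE]
  }
  make_relations(doc_id, inside(fms[!fms$is_spouse, , drop = FALSE]),
                 inside(targets), "same_clause")
}

#' Link targets across adjacent sentences through coreference cues
#'
#' A target in sentence *i* that found no family member in its own clause
#' may link backward to a family member mentioned up to two sentences
#' earlier — a window of three adjacent sentences — but only when sentence
#' *i* itself contains a coreference cue. With an ordinary pronoun cue the
#' target links to the nearest preceding non-spouse family member in the
#' window; with the plural-negative cue "none of them" it links to every
#' family member in the window and the certainty is forced to `"negated"`.
#' Nothing ever links across a sentence distance greater than
#' `window - 1`.
#'
#' @param fms All family-member mentions of the document (with `sent_id`).
#' @param targets Unlinked targets (same shape as in
#'   [link_within_clause()]).
#' @param cues Per-sentence cue tibble with columns `sent_id`, `cue`.
#' @param window Number of adjacent sentences forming the coreference
#'   window (default 3: the cue sentence plus the two before it).
#' @param doc_id Document id stamped on relations.
#' @return A relation tibble (`provenance = "coreference"`).
#' @export
link_cross_sentence <- function(fms, targets, cues, window = 3L,
                                doc_id = "doc") {
  out <- list()
  fms <- fms[!fms$is_spouse, , drop = FALSE]
  for (t in seq_len(nrow(targets))) {
    tsent <- targets$sent_id[t]
    scues <- cues$cue[cues$sent_id == tsent]
    if (length(scues) == 0) next
    lo <- tsent - (window - 1L)
    cand <- fms[fms$sent_id >= lo & fms$sent_id < tsent, , drop = FALSE]
    if (nrow(cand) == 0) next
    if ("none of them" %in% scues) {
      out[[length(out) + 1L]] <- make_relations(
        doc_id, cand, targets[t, , drop = FALSE], "coreference",
        force_certainty = "negated")
    } else {
      cand <- cand[order(-cand$sent_id, -cand$start), , drop = FALSE]
      out[[length(out) + 1L]] <- make_relations(
        doc_id, cand[1, , drop = FALSE], targets[t, , drop = FALSE],
        "coreference")
    }
  }
  if (length(out) == 0) relation_tibble() else dplyr::bind_rows(out)
}

#' Remove relations attached to spouse or in-law mentions
#'
#' Family history concerns blood relatives only; relations whose family
#' member is spouse-flagged are dropped, all others pass through unchanged.
#' The linking rules never emit spouse relations themselves, so this acts
#' as a final invariant guard (and a filter for externally built relation
#' sets).
#'
#' @param relations A relation tibble.
#' @return The filtered relation tibble.
#' @export
exclude_spouse <- function(relations) {
  relations[!relations$fm_is_spouse, , drop = FALSE]
}

relation_target_key <- function(relations) {
  ifelse(relations$target_kind == "observation" & !is.na(relations$target_cui),
         relations$target_cui, norm_text(relations$target_text))
}

#' Assemble per-family-member chains
#'
#' Groups relations by `(fm_category, fm_side)` — one chain per combination
#' per document — merging duplicate targets (same concept and certainty)
#' while keeping the first provenance, in order of first appearance.
#' Same-clause age mentions can be attached via `ages`.
#'
#' @param relations A relation tibble (spouse-free).
#' @param ages Optional tibble of age attachments with columns
#'   `fm_category`, `fm_side`, `value`, `kind`.
#' @param doc_id Document id.
#' @return A tibble with one row per chain: `doc_id`, `fm_category`,
#'   `fm_side`, `targets` (list column of target tibbles), `ages` (list
#'   column).
#' @export
assemble_chains <- function(relations, ages = NULL, doc_id = "doc") {
  empty_ages <- tibble::tibble(value = integer(0), kind = character(0))
  if (nrow(relations) == 0) {
    return(tibble::tibble(doc_id = character(0), fm_category = character(0),
                          fm_side = character(0), targets = list(),
                          ages = list()))
  }
  key <- paste(relations$fm_category, relations$fm_side, sep = "\r")
  chains <- list()
  for (k in unique(key)) {
    rel <- relations[key == k, , drop = FALSE]
    tkey <- paste(rel$target_kind, relation_target_key(rel), rel$certainty,
                  sep = "\r")
    rel <- rel[!duplicated(tkey), , drop = FALSE]
    a <- if (is.null(ages) || nrow(ages) == 0) {
      empty_ages
    } else {
      hit <- ages$fm_category == rel$fm_category[1] &
        ages$fm_side == rel$fm_side[1]
      tibble::tibble(value = ages$value[hit], kind = ages$kind[hit])
    }
    chains[[length(chains) + 1L]] <- tibble::tibble(
      doc_id = doc_id,
      fm_category = rel$fm_category[1],
      fm_side = rel$fm_side[1],
      targets = list(rel[c("target_kind", "target_text", "target_cui",
                           "certainty", "provenance")]),
      ages = list(a))
  }
  dplyr::bind_rows(chains)
}
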