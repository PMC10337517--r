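# evaluation: challenge-style entity/relation scoring (precision, recall,
# F1) and lexicon-coverage recall at variant and concept level.

#' Build a precision/recall/F1 score report from raw counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2PR / (P + R)`; any metric with a zero denominator is reported as
#' 0, so an empty prediction set scores precision 0 rather than undefined.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A list of class `fh_score_report` with the counts and metrics.
#' @examples
#' score_report(2, 1, 1)
#' @export
score_report <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f1 = f1),
            class = "fh_score_report")
}

#' @export
print.fh_score_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | P %.4f  R %.4f  F1 %.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

# Kuhn's augmenting-path maximum bipartite matching.
# adj: list over gold items of integer vectors of compatible pred indices.
max_bipartite_matching <- function(adj, n_pred) {
  match_pred <- rep(0L, n_pred)
  try_aug <- function(g, seen) {
    for (p in adj[[g]]) {
      if (!seen[p]) {
        seen[p] <- TRUE
        if (match_pred[p] == 0L) {
          match_pred[p] <<- g
          return(TRUE)
        }
        prev <- match_pred[p]
        match_pred[p] <<- 0L
        if (try_aug(prev, seen)) {
          match_pred[p] <<- g
          return(TRUE)
        }
        match_pred[p] <<- prev
      }
    }
    FALSE
  }
  n <- 0L
  for (g in seq_along(adj)) {
    if (try_aug(g, rep(FALSE, n_pred))) n <- n + 1L
  }
  n
}

side_str <- function(x) ifelse(is.na(x) | !nzchar(x), "NA", x)

entity_pair_matches <- function(g, p, match_mode) {
  if (g$type != p$type) return(FALSE)
  if (g$type == "FamilyMember") {
    return(g$concept == p$concept && side_str(g$side) == side_str(p$side))
  }
  spans_ok <- !is.na(g$start) && !is.na(p$start)
  if (match_mode == "exact") {
    return(spans_ok && g$start == p$start && g$end == p$end &&
             identical(g$concept, p$concept))
  }
  if (g$type == "Observation") {
    if (spans_ok) return(g$start < p$end && p$start < g$end)
    return(identical(g$concept, p$concept))
  }
  # LivingStatus / Age: normalized form must agree; spans, when present,
  # must overlap
  if (!identical(as.character(g$concept), as.character(p$concept))) {
    return(FALSE)
  }
  if (spans_ok) return(g$start < p$end && p$start < g$end)
  TRUE
}

#' Score predicted entities against a gold standard
#'
#' Challenge task-1 style scoring. Family-member matches require equality
#' of category *and* side of family. Observation matches under the default
#' partial mode require character-span overlap of at least one character
#' (or, when spans are unavailable, equality of the normalized CUI); exact
#' mode requires identical spans. Each gold item consumes at most one
#' prediction: matching is a maximum bipartite matching per document and
#' type, so the scorer is order-independent. Documents present only in the
#' predictions contribute false positives, with a warning.
#'
#' @param gold,pred Entity tibbles with columns `doc_id`, `type`,
#'   `concept`, `side`, `certainty`, `start`, `end` (the [fh_extract()]
#'   entity format).
#' @param match_mode `"partial"` (default) or `"exact"`.
#' @return A list of class `fh_score` with `per_type` (named list of
#'   [score_report()]s) and `micro` (pooled counts over all types).
#' @export
score_entities <- function(gold, pred, match_mode = c("partial", "exact")) {
  match_mode <- match.arg(match_mode)
  extra <- setdiff(unique(pred$doc_id), unique(gold$doc_id))
  if (length(extra) > 0) {
    warning("predictions for document(s) absent from gold: ",
            paste(utils::head(extra, 5), collapse = ", "))
  }
  types <- union(unique(gold$type), unique(pred$type))
  per_type <- list()
  tot <- c(tp = 0L, fp = 0L, fn = 0L)
  for (ty in sort(types)) {
    g_ty <- gold[gold$type == ty, , drop = FALSE]
    p_ty <- pred[pred$type == ty, , drop = FALSE]
    tp <- 0L
    for (d in union(unique(g_ty$doc_id), unique(p_ty$doc_id))) {
      g <- g_ty[g_ty$doc_id == d, , drop = FALSE]
      p <- p_ty[p_ty$doc_id == d, , drop = FALSE]
      g <- g[order(g$start, g$end), , drop = FALSE]
      if (nrow(g) == 0 || nrow(p) == 0) next
      adj <- lapply(seq_len(nrow(g)), function(i) {
        which(vapply(seq_len(nrow(p)), function(j) {
          entity_pair_matches(g[i, ], p[j, ], match_mode)
        }, logical(1)))
      })
      tp <- tp + max_bipartite_matching(adj, nrow(p))
    }
    rep_ty <- score_report(tp, nrow(p_ty) - tp, nrow(g_ty) - tp)
    per_type[[ty]] <- rep_ty
    tot <- tot + c(tp = rep_ty$tp, fp = rep_ty$fp, fn = rep_ty$fn)
  }
  structure(list(per_type = per_type,
                 micro = score_report(tot[["tp"]], tot[["fp"]], tot[["fn"]])),
            class = "fh_score")
}

#' @export
print.fh_score <- function(x, ...) {
  for (ty in names(x$per_type)) {
    cat(sprintf("%-14s", ty)); print(x$per_type[[ty]])
  }
  cat(sprintf("%-14s", "micro")); print(x$micro)
  invisible(x)
}

canon_relations <- function(rel, with_certainty) {
  target <- ifelse(
    rel$target_kind == "observation" & !is.na(rel$target_cui) &
      nzchar(rel$target_cui),
    rel$target_cui, norm_text(rel$target_text))
  df <- tibble::tibble(doc_id = rel$doc_id,
                       fm_category = rel$fm_category,
                       fm_side = side_str(rel$fm_side),
                       target_kind = rel$target_kind,
                       target = target)
  if (with_certainty) df$certainty <- rel$certainty
  df[!duplicated(df), , drop = FALSE]
}

#' Score predicted relations against a gold standard
#'
#' Challenge task-2 style scoring. A relation matches when its family
#' member category, side of family, and normalized target (CUI for
#' observations, status for living status) all agree; with
#' `with_certainty = TRUE` the certainty attribute must also agree — the
#' stricter convention introduced by the 2019 task. Both sets are
#' deduplicated before counting.
#'
#' @param gold,pred Relation tibbles with columns `doc_id`, `fm_category`,
#'   `fm_side`, `target_kind`, `target_text`, `target_cui`, `certainty`
#'   (the [fh_extract()] relation format; for gold read by
#'   [read_gold_relations()] the canonical `target` column is accepted via
#'   `target_text`).
#' @param with_certainty Require certainty agreement?
#' @return A [score_report()].
#' @export
score_relations <- function(gold, pred, with_certainty = FALSE) {
  if (!"target_cui" %in% names(gold)) gold$target_cui <- NA_character_
  if (!"target_cui" %in% names(pred)) pred$target_cui <- NA_character_
  g <- canon_relations(gold, with_certainty)
  p <- canon_relations(pred, with_certainty)
  extra <- setdiff(unique(p$doc_id), unique(g$doc_id))
  if (length(extra) > 0) {
    warning("predictions for document(s) absent from gold: ",
            paste(utils::head(extra, 5), collapse = ", "))
  }
  gk <- do.call(paste, c(g, sep = "\r"))
  pk <- do.call(paste, c(p, sep = "\r"))
  tp <- sum(pk %in% gk)
  score_report(tp, length(pk) - tp, length(gk) - tp)
}

#' Build a lexicon-coverage report from raw counts
#'
#' Coverage is reported as recall `TP / (TP + FN)` at two levels. At the
#' variant level the units are gold entities: an entity counts as TP when
#' its text partially matches some lexicon variant. At the concept level,
#' credit is given for concepts reachable through the lexicon: TP concepts
#' plus the concepts of FN entities that are present in the lexicon under a
#' different variant, over that sum plus the FN entities whose concept is
#' missing from the lexicon entirely.
#'
#' @param tp_entities,fn_entities Entity-level TP / FN counts.
#' @param tp_concepts Distinct concepts among TP entities.
#' @param fn_concepts_present Distinct concepts among FN entities whose
#'   concept exists in the lexicon.
#' @param fn_concepts_missing FN entities whose concept is absent from the
#'   lexicon.
#' @return A list of class `fh_coverage_report` with the counts,
#'   `variant_recall` and `concept_recall` (fractions in \[0, 1\]).
#' @examples
#' coverage_report(137, 16, 128, 10, 6)   # variant 89.5%, concept 95.8%
#' @export
coverage_report <- function(tp_entities, fn_entities, tp_concepts,
                            fn_concepts_present, fn_concepts_missing) {
  den_v <- tp_entities + fn_entities
  num_c <- tp_concepts + fn_concepts_present
  den_c <- num_c + fn_concepts_missing
  structure(list(
    tp_entities = tp_entities, fn_entities = fn_entities,
    tp_concepts = tp_concepts,
    fn_concepts_present = fn_concepts_present,
    fn_concepts_missing = fn_concepts_missing,
    variant_recall = if (den_v > 0) tp_entities / den_v else 0,
    concept_recall = if (den_c > 0) num_c / den_c else 0
  ), class = "fh_coverage_report")
}

#' @export
print.fh_coverage_report <- function(x, ...) {
  cat(sprintf("variant-level recall: %.1f%%  (%d TP / %d FN entities)\n",
              100 * x$variant_recall, x$tp_entities, x$fn_entities))
  cat(sprintf("concept-level recall: %.1f%%  (%d TP + %d present / %d missing)\n",
              100 * x$concept_recall, x$tp_concepts, x$fn_concepts_present,
              x$fn_concepts_missing))
  invisible(x)
}

#' Evaluate lexicon coverage against gold entities
#'
#' An entity is a variant-level TP when its text shares at least
#' `min_token_overlap` alphanumeric tokens with some lexicon variant
#' (partial match). FN entities are split into those whose gold concept
#' exists in the lexicon under other variants and those whose concept is
#' absent; recalls follow [coverage_report()].
#'
#' @param gold_entities A data frame with columns `text` and `concept`
#'   (normalized CUI).
#' @param lexicon An [fh_lexicon()].
#' @param min_token_overlap Minimum shared token count for a partial match.
#' @return An [coverage_report()] object.
#' @export
coverage <- function(gold_entities, lexicon, min_token_overlap = 1L) {
  stopifnot(inherits(lexicon, "fh_lexicon"))
  lex_tokens <- unique(unlist(strsplit(norm_text(lexicon$variant),
                                       "[^a-z0-9]+")))
  lex_tokens <- lex_tokens[nzchar(lex_tokens)]
  ent_tokens <- strsplit(norm_text(gold_entities$text), "[^a-z0-9]+")
  tp <- vapply(ent_tokens, function(tk) {
    sum(unique(tk[nzchar(tk)]) %in% lex_tokens) >= min_token_overlap
  }, logical(1))
  present <- gold_entities$concept %in% lexicon$cui
  coverage_report(
    tp_entities = sum(tp),
    fn_entities = sum(!tp),
    tp_concepts = dplyr::n_distinct(gold_entities$concept[tp]),
    fn_concepts_present = dplyr::n_distinct(
      gold_entities$concept[!tp & present]),
    fn_concepts_missing = sum(!tp & !present)
  )
}

#' Read / write gold annotation files
#'
#' The gold TSV formats are the package's own documented exchange formats
#' (the original challenge files are distribution-restricted). Entities:
#' `doc_id`, `type`, `concept`, `side`, `certainty`, `start`, `end`.
#' Relations: `doc_id`, `fm_category`, `fm_side`, `target_kind`, `target`,
#' `certainty` (plus an optional `provenance` column).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_gold_entities <- function(path) {
  df <- read_tsv_file(path, c("doc_id", "type", "concept", "side",
                              "certainty", "start", "end"))
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df
}

#' @rdname read_gold_entities
#' @export
read_gold_relations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  need <- c("doc_id", "fm_category", "fm_side", "target_kind", "target",
            "certainty")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(df)
  out$target_text <- out$target
  out$target_cui <- ifelse(is_cui(out$target), out$target, NA_character_)
  out
}

#' @rdname read_gold_entities
#' @param entities,relations Tibbles in the gold formats above.
#' @export
write_gold_entities <- function(entities, path) {
  write_tsv_file(entities[c("doc_id", "type", "concept", "side",
                            "certainty", "start", "end")], path)
}

#' @rdname read_gold_entities
#' @export
write_gold_relations <- function(relations, path) {
  cols <- c("doc_id", "fm_category", "fm_side", "target_kind", "target",
            "certainty")
  if (!"target" %in% names(relations)) {
    relations$target <- ifelse(
      relations$target_kind == "observation" & !is.na(relations$target_cui),
      relations$target_cui, relations$target_text)
  }
  if ("provenance" %in% names(relations)) cols <- c(cols, "provenance")
  write_tsv_file(relations[cols], path)
}
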