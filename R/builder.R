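# lexicon_builder: corpus-driven lexicon construction with pluggable
# mention-source and normalizer adapters, semantic-type screening, a
# frequency-thresholded curation queue, and variant enrichment.

#' Dictionary-backed mention-source adapter
#'
#' A mention-source adapter is any function `text -> tibble(text, start,
#' end)` proposing candidate disorder/finding mentions with positions; the
#' corpus analysis model that proposes mentions is deliberately pluggable.
#' This reference adapter proposes exactly the spans of a reference lexicon
#' found by leftmost-longest dictionary matching, which makes the whole
#' pipeline deterministic and self-checking.
#'
#' @param lexicon The reference [fh_lexicon()] to scan with.
#' @return A mention-source function.
#' @seealso [fh_noisy_mention_source()], [collect_mentions()]
#' @export
fh_mention_source <- function(lexicon) {
  force(lexicon)
  function(text) {
    hits <- match_observations(text, lexicon)
    tibble::tibble(text = hits$text, start = hits$start, end = hits$end)
  }
}

# deterministic typo surrogate for EHR concatenation artifacts:
# drop digits and whitespace ("type 2 diabetes" -> "typediabetes")
typo_form <- function(text) gsub("[0-9 ]+", "", tolower(text))

#' Noisy mention-source adapter
#'
#' Wraps [fh_mention_source()] and additionally emits, for multi-token
#' hits, a concatenated typo form of the mention (digits and spaces
#' dropped), emulating run-together artifacts found in raw EHR text. The
#' typo form of a given surface string is a pure function of that string,
#' so repeated occurrences aggregate under one raw mention; `typo_rate`
#' selects mentions deterministically by a text hash, so the adapter is a
#' pure function of the corpus.
#'
#' @param lexicon The reference [fh_lexicon()].
#' @param typo_rate Fraction of multi-token hits that also emit a typo
#'   form (1 = all of them).
#' @return A mention-source function.
#' @export
fh_noisy_mention_source <- function(lexicon, typo_rate = 1) {
  stopifnot(typo_rate >= 0, typo_rate <= 1)
  base <- fh_mention_source(lexicon)
  function(text) {
    hits <- base(text)
    extra <- list()
    for (k in seq_len(nrow(hits))) {
      if (n_tokens(hits$text[k]) < 2) next
      h <- sum(utf8ToInt(tolower(hits$text[k]))) %% 100L
      if (h >= round(typo_rate * 100)) next
      tf <- typo_form(hits$text[k])
      if (identical(tf, norm_text(hits$text[k]))) next
      extra[[length(extra) + 1L]] <- tibble::tibble(
        text = tf, start = hits$start[k], end = hits$end[k])
    }
    dplyr::bind_rows(c(list(hits), extra))
  }
}

#' Dictionary-backed normalizer adapter
#'
#' A normalizer adapter is any pure function `mention text ->
#' tibble(cui, preferred_term, semantic_type)` proposing concept candidates
#' for a free-text problem description (possibly none). This reference
#' adapter performs an exact lookup of the normalized mention against a
#' concept table — either an [fh_lexicon()] or any data frame with columns
#' `variant`, `cui`, `preferred_term`, `semantic_type` (the latter may
#' contain non-FH semantic types, which is what the screening stage is
#' for).
#'
#' @param reference The lookup table.
#' @return A normalizer function.
#' @seealso [normalize_mentions()], [screen_semantic_types()]
#' @export
fh_dict_normalizer <- function(reference) {
  reference <- tibble::as_tibble(as.data.frame(reference))
  stopifnot(all(c("variant", "cui", "preferred_term", "semantic_type") %in%
                  names(reference)))
  reference$variant <- norm_text(reference$variant)
  function(mention) {
    hit <- reference[reference$variant == norm_text(mention), , drop = FALSE]
    hit <- hit[order(hit$cui), , drop = FALSE]
    hit <- hit[!duplicated(hit$cui), , drop = FALSE]
    tibble::tibble(cui = hit$cui, preferred_term = hit$preferred_term,
                   semantic_type = hit$semantic_type)
  }
}

#' Collect raw mentions from a patient-tagged corpus
#'
#' Runs the mention-source adapter over every text segment and aggregates
#' candidate mentions by normalized text: total occurrence frequency and
#' the number of distinct patients the mention occurred for. Segments on
#' which the adapter fails are skipped with a warning.
#'
#' @param adapter A mention-source function (see [fh_mention_source()]).
#' @param corpus A data frame with columns `patient_id` and `text`.
#' @return A tibble with columns `text` (normalized), `frequency`,
#'   `n_patients`, sorted by frequency descending.
#' @export
collect_mentions <- function(adapter, corpus) {
  per_seg <- list()
  failed <- 0L
  for (i in seq_len(nrow(corpus))) {
    hits <- tryCatch(adapter(corpus$text[i]), error = function(e) NULL)
    if (is.null(hits)) {
      failed <- failed + 1L
      next
    }
    if (nrow(hits) == 0) next
    per_seg[[length(per_seg) + 1L]] <- tibble::tibble(
      patient_id = corpus$patient_id[i], text = norm_text(hits$text))
  }
  if (failed > 0) {
    warning(sprintf("mention source failed on %d segment(s); skipped", failed))
  }
  if (length(per_seg) == 0) {
    return(tibble::tibble(text = character(0), frequency = integer(0),
                          n_patients = integer(0)))
  }
  all <- dplyr::bind_rows(per_seg)
  agg <- dplyr::summarise(dplyr::group_by(all, text),
                          frequency = dplyr::n(),
                          n_patients = dplyr::n_distinct(patient_id),
                          .groups = "drop")
  agg <- agg[order(-agg$frequency, agg$text), , drop = FALSE]
  agg
}

#' Normalize raw mentions through an adapter
#'
#' One result per mention; candidate order is preserved from the adapter.
#' Mentions with no candidates (or on which the adapter errors) appear with
#' `NA` candidates and route to the curation queue. Re-running on the same
#' input gives identical results.
#'
#' @param normalizer A normalizer function (see [fh_dict_normalizer()]).
#' @param mentions A tibble from [collect_mentions()] (only `text` is
#'   required).
#' @return A tibble with columns `mention`, `cui`, `preferred_term`,
#'   `semantic_type`, `source` (`"auto"`; `NA` rows for unnormalized
#'   mentions).
#' @export
normalize_mentions <- function(normalizer, mentions) {
  out <- lapply(mentions$text, function(m) {
    cand <- tryCatch(normalizer(m), error = function(e) NULL)
    if (is.null(cand) || nrow(cand) == 0) {
      return(tibble::tibble(mention = m, cui = NA_character_,
                            preferred_term = NA_character_,
                            semantic_type = NA_character_,
                            source = NA_character_))
    }
    tibble::tibble(mention = m, cui = cand$cui,
                   preferred_term = cand$preferred_term,
                   semantic_type = cand$semantic_type, source = "auto")
  })
  dplyr::bind_rows(c(list(tibble::tibble(mention = character(0),
                                         cui = character(0),
                                         preferred_term = character(0),
                                         semantic_type = character(0),
                                         source = character(0))), out))
}

#' Screen normalization candidates by semantic type
#'
#' Drops every candidate whose semantic type is not in the allowed set
#' (the FH-eligible types by default). A mention left with no candidates
#' becomes an `NA` row, routing it to the curation queue.
#'
#' @param results A tibble from [normalize_mentions()].
#' @param allowed Allowed semantic-type codes.
#' @return The screened results tibble (same shape).
#' @export
screen_semantic_types <- function(results, allowed = fh_eligible_types()) {
  ok <- !is.na(results$cui) & results$semantic_type %in% allowed
  kept <- results[ok, , drop = FALSE]
  lost <- setdiff(unique(results$mention), unique(kept$mention))
  if (length(lost) > 0) {
    kept <- dplyr::bind_rows(kept, tibble::tibble(
      mention = lost, cui = NA_character_, preferred_term = NA_character_,
      semantic_type = NA_character_, source = NA_character_))
  }
  kept[order(match(kept$mention, results$mention)), , drop = FALSE]
}

#' Build the manual-curation queue
#'
#' High-frequency unnormalized mentions deserve a human look: mentions with
#' no (surviving) automatic candidates that occurred across at least
#' `min_patients` distinct patients are queued, sorted by patient count
#' descending, with status `"pending"`.
#'
#' @param results Screened results from [screen_semantic_types()].
#' @param mentions The raw-mention tibble from [collect_mentions()]
#'   (supplies `frequency` and `n_patients`).
#' @param min_patients Distinct-patient threshold (default 20).
#' @return A tibble with columns `mention`, `frequency`, `n_patients`,
#'   `status`, `cui`.
#' @export
build_curation_queue <- function(results, mentions, min_patients = 20L) {
  stopifnot(min_patients >= 1)
  unnorm <- vapply(split(results$cui, results$mention),
                   function(x) all(is.na(x)), logical(1))
  unnorm_mentions <- names(unnorm)[unnorm]
  q <- mentions[mentions$text %in% unnorm_mentions &
                  mentions$n_patients >= min_patients, , drop = FALSE]
  q <- q[order(-q$n_patients, q$text), , drop = FALSE]
  tibble::tibble(mention = q$text, frequency = q$frequency,
                 n_patients = q$n_patients, status = "pending",
                 cui = NA_character_)
}

#' Replay curation decisions onto the queue
#'
#' Curation decisions live in a human-editable TSV (`mention`, `cui`,
#' `status`) so the manual step is reproducible: replaying the same
#' decision file always yields the same lexicon. Queue items named in the
#' decisions gain the assigned CUI and status `"mapped"` (or `"rejected"`);
#' unnamed items stay `"pending"`.
#'
#' @param queue A tibble from [build_curation_queue()].
#' @param decisions A data frame with columns `mention`, `cui`, `status`,
#'   or a path to such a TSV.
#' @return The updated queue tibble.
#' @export
apply_curation <- function(queue, decisions) {
  if (is.character(decisions) && length(decisions) == 1) {
    decisions <- read_tsv_file(decisions, c("mention", "cui", "status"))
  }
  decisions <- tibble::as_tibble(decisions)
  decisions$mention <- norm_text(decisions$mention)
  idx <- match(queue$mention, decisions$mention)
  hit <- !is.na(idx)
  queue$status[hit] <- decisions$status[idx[hit]]
  queue$cui[hit] <- ifelse(queue$status[hit] == "mapped",
                           decisions$cui[idx[hit]], NA_character_)
  queue
}

#' Enrich lexicon variants from a second lexicon-shaped resource
#'
#' For each CUI already in the lexicon, adds the variants that the variant
#' source holds for the same CUI. All individual concepts of the built
#' lexicon are kept and no new CUI is introduced: enrichment widens
#' variants, never concepts.
#'
#' @param lexicon The [fh_lexicon()] being built.
#' @param variant_source An [fh_lexicon()]-shaped resource.
#' @return The enriched [fh_lexicon()].
#' @export
enrich_variants <- function(lexicon, variant_source) {
  add <- variant_source[variant_source$cui %in% lexicon$cui, , drop = FALSE]
  fh_lexicon(dplyr::bind_rows(as.data.frame(lexicon), as.data.frame(add)))
}

#' Summary report of a builder run
#'
#' @param n_mentions Unique raw mentions entering normalization.
#' @param n_auto Mentions with at least one surviving automatic candidate.
#' @param n_curated Mentions mapped through curation decisions.
#' @param lexicon Optional final [fh_lexicon()] (adds [lexicon_stats()]).
#' @return A list of class `fh_builder_report` with `pct_auto` (percent of
#'   mentions auto-normalized, 2 decimals) and the counts.
#' @examples
#' builder_report(72518, 47250)$pct_auto   # 65.16
#' @export
builder_report <- function(n_mentions, n_auto, n_curated = 0L,
                           lexicon = NULL) {
  structure(list(
    n_mentions = n_mentions, n_auto = n_auto, n_curated = n_curated,
    pct_auto = if (n_mentions > 0) round(100 * n_auto / n_mentions, 2) else 0,
    stats = if (!is.null(lexicon)) lexicon_stats(lexicon)
  ), class = "fh_builder_report")
}

#' @export
print.fh_builder_report <- function(x, ...) {
  cat(sprintf("mentions: %d | auto-normalized: %d (%.2f%%) | curated: %d\n",
              x$n_mentions, x$n_auto, x$pct_auto, x$n_curated))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' Run the full corpus-driven lexicon construction pipeline
#'
#' Collect mentions, normalize them, screen candidates by semantic type,
#' queue high-frequency unnormalized mentions for curation, replay curation
#' decisions, optionally enrich variants from a second resource, and emit
#' the final lexicon with per-entry provenance (`auto`, `curated`,
#' `enriched`).
#'
#' Curated entries need a concept record (preferred term, semantic type,
#' optional SNOMED code) for their assigned CUI; these are looked up in
#' `concepts`. A curated CUI with no concept record is skipped with a
#' warning.
#'
#' @param corpus A data frame with columns `patient_id`, `text`.
#' @param mention_source A mention-source adapter.
#' @param normalizer A normalizer adapter.
#' @param concepts Concept reference: a data frame with columns `cui`,
#'   `preferred_term`, `semantic_type` and optionally `snomed_code`.
#' @param allowed Allowed semantic types (default FH-eligible set).
#' @param min_patients Curation-queue threshold.
#' @param decisions Optional curation decisions (data frame or TSV path).
#' @param variant_source Optional enrichment lexicon.
#' @return A list of class `fh_builder` with `lexicon`, `mentions`,
#'   `results` (screened), `queue`, `provenance`, `report`.
#' @export
build_fh_lexicon <- function(corpus, mention_source, normalizer, concepts,
                             allowed = fh_eligible_types(),
                             min_patients = 20L, decisions = NULL,
                             variant_source = NULL) {
  concepts <- tibble::as_tibble(as.data.frame(concepts))
  if (!"snomed_code" %in% names(concepts)) concepts$snomed_code <- ""
  concepts <- concepts[!duplicated(concepts$cui), , drop = FALSE]

  mentions <- collect_mentions(mention_source, corpus)
  results <- normalize_mentions(normalizer, mentions)
  results <- screen_semantic_types(results, allowed)
  queue <- build_curation_queue(results, mentions, min_patients)
  if (!is.null(decisions)) queue <- apply_curation(queue, decisions)

  auto <- results[!is.na(results$cui), , drop = FALSE]
  entries <- tibble::tibble(variant = auto$mention, cui = auto$cui,
                            snomed_code = concepts$snomed_code[
                              match(auto$cui, concepts$cui)],
                            preferred_term = auto$preferred_term,
                            semantic_type = auto$semantic_type,
                            provenance = "auto")
  entries$snomed_code[is.na(entries$snomed_code)] <- ""

  mapped <- queue[queue$status == "mapped" & !is.na(queue$cui), , drop = FALSE]
  if (nrow(mapped) > 0) {
    ci <- match(mapped$cui, concepts$cui)
    unknown <- is.na(ci)
    if (any(unknown)) {
      warning("curated CUI(s) missing from concept reference: ",
              paste(unique(mapped$cui[unknown]), collapse = ", "))
    }
    mapped <- mapped[!unknown, , drop = FALSE]
    ci <- ci[!unknown]
    entries <- dplyr::bind_rows(entries, tibble::tibble(
      variant = mapped$mention, cui = mapped$cui,
      snomed_code = concepts$snomed_code[ci],
      preferred_term = concepts$preferred_term[ci],
      semantic_type = concepts$semantic_type[ci],
      provenance = "curated"))
  }

  lexicon <- fh_lexicon(entries[LEXICON_COLS])
  provenance <- entries[c("variant", "cui", "provenance")]
  if (!is.null(variant_source)) {
    before <- paste(lexicon$variant, lexicon$cui)
    lexicon <- enrich_variants(lexicon, variant_source)
    new <- !(paste(lexicon$variant, lexicon$cui) %in% before)
    provenance <- dplyr::bind_rows(provenance, tibble::tibble(
      variant = lexicon$variant[new], cui = lexicon$cui[new],
      provenance = "enriched"))
  }
  provenance <- provenance[!duplicated(paste(provenance$variant,
                                             provenance$cui)), , drop = FALSE]

  structure(list(
    lexicon = lexicon, mentions = mentions, results = results,
    queue = queue, provenance = provenance,
    report = builder_report(
      n_mentions = nrow(mentions),
      n_auto = dplyr::n_distinct(results$mention[!is.na(results$cui)]),
      n_curated = sum(queue$status == "mapped"),
      lexicon = lexicon)
  ), class = "fh_builder")
}
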