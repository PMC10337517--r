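# entity_extraction: dictionary matching of observations, certainty,
# living status and age extraction.

#' Default negation trigger list
#'
#' A minimal NegEx-style scheme: a trigger preceding a mention within the
#' same clause negates it, unless an adversative conjunction ("but",
#' "however") intervenes and resets the scope. Editable via a replacement
#' TSV with a `trigger` column.
#'
#' @param path Optional path to a replacement trigger TSV.
#' @return Character vector of triggers, longest first.
#' @export
fh_negation_triggers <- function(path = NULL) {
  path <- path %||% system.file("extdata", "negation_triggers.tsv",
                                package = "fhlex")
  t <- read_tsv_file(path, "trigger")$trigger
  t[order(-nchar(t))]
}

#' Match lexicon observations in a sentence
#'
#' Case-insensitive, token-boundary-respecting, leftmost-longest dictionary
#' matching of lexicon variants over the sentence. Candidate spans start and
#' end on alphanumeric token boundaries and are compared after surface
#' normalization (case-fold, whitespace collapse), so hyphenated variants
#' match as written. A shorter variant inside a chosen longer match is
#' suppressed ("colon cancer" wins over "cancer"), and a variant never
#' matches inside a longer word ("cancerous" does not contain "cancer").
#'
#' When a variant is ambiguous across CUIs, all CUIs are kept: the
#' lexicographically first is reported in `cui` (the deterministic primary)
#' and the rest in `alt_cuis` (semicolon-separated).
#'
#' Certainty defaults to `"nonnegated"`; [detect_certainty()] refines it
#' once clause structure is known.
#'
#' @param sentence_text Sentence text.
#' @param lexicon An [fh_lexicon()].
#' @param offset Document offset (0-based) of the sentence.
#' @param sent_id Sentence id stamped on the mentions.
#' @return A tibble with columns `sent_id`, `chunk_id` (`NA` until clause
#'   assignment), `start`, `end`, `text`, `cui`, `alt_cuis`, `snomed_code`,
#'   `certainty`.
#' @examples
#' lex <- fh_lexicon(data.frame(variant = "diabetes", cui = "C0011854",
#'                              snomed_code = "", preferred_term = "",
#'                              semantic_type = "T047"))
#' match_observations("Her mother has diabetes.", lex)
#' @export
match_observations <- function(sentence_text, lexicon, offset = 0L,
                               sent_id = 0L) {
  stopifnot(inherits(lexicon, "fh_lexicon"))
  empty <- tibble::tibble(sent_id = integer(0), chunk_id = integer(0),
                          start = integer(0), end = integer(0),
                          text = character(0), cui = character(0),
                          alt_cuis = character(0), snomed_code = character(0),
                          certainty = character(0))
  if (nrow(lexicon) == 0) return(empty)
  vidx <- variant_index(lexicon)
  max_tok <- max(n_tokens(names(vidx)))
  toks <- token_spans(sentence_text)
  nt <- nrow(toks)
  if (nt == 0) return(empty)
  out <- list()
  i <- 1L
  while (i <= nt) {
    match_j <- 0L
    cand_key <- NULL
    for (j in seq(min(nt, i + max_tok - 1L), i)) {
      key <- norm_text(span_text(sentence_text, toks$start[i], toks$end[j]))
      if (!is.null(vidx[[key]])) {
        match_j <- j
        cand_key <- key
        break
      }
    }
    if (match_j > 0L) {
      rows <- lexicon[vidx[[cand_key]], ]
      cuis <- sort(unique(rows$cui))
      primary <- cuis[[1]]
      out[[length(out) + 1L]] <- data.frame(
        start = toks$start[i], end = toks$end[match_j],
        text = span_text(sentence_text, toks$start[i], toks$end[match_j]),
        cui = primary,
        alt_cuis = paste(cuis[-1], collapse = ";"),
        snomed_code = rows$snomed_code[match(primary, rows$cui)])
      # resume after the chosen match: overlapped shorter hits suppressed
      nxt <- which(toks$start >= toks$end[match_j])
      i <- if (length(nxt) > 0) nxt[[1]] else nt + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) return(empty)
  res <- dplyr::bind_rows(out)
  tibble::tibble(sent_id = sent_id, chunk_id = NA_integer_,
                 start = res$start + offset, end = res$end + offset,
                 text = res$text, cui = res$cui, alt_cuis = res$alt_cuis,
                 snomed_code = res$snomed_code, certainty = "nonnegated")
}

#' Assign certainty to a mention from its clause context
#'
#' A mention is `"negated"` iff a negation trigger precedes it within the
#' same clause with no intervening adversative reset ("but", "however");
#' otherwise `"nonnegated"`. This binary attribute follows the convention of
#' the 2019 relation-extraction task.
#'
#' @param clause_text Text of the clause containing the mention.
#' @param mention_start Mention start relative to the clause (0-based).
#' @param triggers Negation trigger list; see [fh_negation_triggers()].
#' @param resets Scope-resetting conjunctions.
#' @return `"negated"` or `"nonnegated"`.
#' @examples
#' detect_certainty("No family history of cancer.", 21)
#' @export
detect_certainty <- function(clause_text, mention_start,
                             triggers = fh_negation_triggers(),
                             resets = c("but", "however")) {
  reset_pat <- paste0("(?i)(?<![a-z0-9])(",
                      paste(escape_regex(resets), collapse = "|"),
                      ")(?![a-z0-9])")
  hits <- find_terms_multi(clause_text, triggers)
  hits <- hits[hits$term %in% norm_text(triggers), , drop = FALSE]
  for (k in seq_len(nrow(hits))) {
    if (hits$end[k] <= mention_start) {
      between <- span_text(clause_text, hits$end[k], mention_start)
      if (!grepl(reset_pat, between, perl = TRUE)) return("negated")
    }
  }
  "nonnegated"
}

LIVING_DEAD_CUES <- c("passed away", "deceased", "died", "dead", "death")
LIVING_ALIVE_CUES <- c("alive", "living", "well", "healthy")
LIVING_UNKNOWN_CUES <- c("unknown")
LIVING_HEALTHY_CUES <- c("good health", "healthy", "well")

#' Extract a living-status mention from a sentence
#'
#' Cue-table matching: deceased/died/passed-away style cues give status
#' `Dead`; alive/living/well/healthy give `Alive` (with the `healthy` flag
#' when a health qualifier is present); the hedge "unknown" gives `Unknown`.
#' Dead cues take precedence, and at most one mention is emitted per
#' sentence, anchored on the first deciding cue.
#'
#' @inheritParams match_observations
#' @return A tibble with columns `sent_id`, `start`, `end`, `text`,
#'   `status`, `healthy`, `certainty` (zero or one row).
#' @examples
#' extract_living_status("Mother is alive and well.")
#' @export
extract_living_status <- function(sentence_text, offset = 0L, sent_id = 0L) {
  empty <- tibble::tibble(sent_id = integer(0), start = integer(0),
                          end = integer(0), text = character(0),
                          status = character(0), healthy = logical(0),
                          certainty = character(0))
  hits <- find_terms_multi(sentence_text,
                           unique(c(LIVING_DEAD_CUES, LIVING_ALIVE_CUES,
                                    LIVING_UNKNOWN_CUES,
                                    LIVING_HEALTHY_CUES)))
  first_hit <- function(cues) {
    h <- hits[hits$term %in% cues, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    list(start = h$start[1], end = h$end[1])
  }
  dead <- first_hit(LIVING_DEAD_CUES)
  alive <- first_hit(LIVING_ALIVE_CUES)
  unknown <- first_hit(LIVING_UNKNOWN_CUES)
  healthy <- !is.null(first_hit(LIVING_HEALTHY_CUES))
  pick <- if (!is.null(dead)) {
    list(hit = dead, status = "Dead", healthy = FALSE)
  } else if (!is.null(alive)) {
    list(hit = alive, status = "Alive", healthy = healthy)
  } else if (!is.null(unknown)) {
    list(hit = unknown, status = "Unknown", healthy = FALSE)
  } else {
    return(empty)
  }
  tibble::tibble(sent_id = sent_id,
                 start = pick$hit$start + offset,
                 end = pick$hit$end + offset,
                 text = span_text(sentence_text, pick$hit$start, pick$hit$end),
                 status = pick$status, healthy = pick$healthy,
                 certainty = "nonnegated")
}

AGE_PATTERNS <- list(
  list(re = "(?i)(?<![a-z0-9])at (?:the )?age (?:of )?([0-9]{1,3})(?![0-9])",
       kind = "exact", mult = 1L),
  list(re = "(?i)(?<![a-z0-9])([0-9]{1,3}) years? old(?![a-z0-9])",
       kind = "exact", mult = 1L),
  list(re = "(?i)(?<![a-z0-9])([0-9]{1,3}) ?y\\.?o\\b",
       kind = "exact", mult = 1L),
  list(re = "(?i)(?<![a-z0-9])aged ([0-9]{1,3})(?![0-9])",
       kind = "exact", mult = 1L),
  list(re = "(?i)(?<![a-z0-9])in (?:his|her|their) ([1-9][0-9]?)0'?s(?![a-z0-9])",
       kind = "decade", mult = 10L)
)

#' Extract age mentions from a sentence
#'
#' Pattern set: "at (the) age (of) N", "N years old", "N y.o.", "aged N",
#' and the decade form "in his/her N0s" (value N0, kind `decade`). Values
#' outside plausible human ages (0–130) are rejected; bare numerals never
#' match ("Route 66" carries no age).
#'
#' @inheritParams match_observations
#' @return A tibble with columns `sent_id`, `start`, `end` (span of the
#'   numeral), `text`, `value` (years, integer), `kind`.
#' @examples
#' extract_age("She died of MI at age 62.")
#' @export
extract_age <- function(sentence_text, offset = 0L, sent_id = 0L) {
  out <- list()
  taken <- data.frame(start = integer(0), end = integer(0))
  for (p in AGE_PATTERNS) {
    m <- gregexpr(p$re, sentence_text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    for (k in seq_along(m)) {
      ms <- as.integer(m[k]) - 1L
      me <- ms + attr(m, "match.length")[k]
      if (nrow(taken) > 0 && any(spans_overlap(ms, me, taken$start, taken$end))) {
        next
      }
      value <- as.integer(substr(sentence_text, cs[k], cs[k] + cl[k] - 1L)) *
        p$mult
      if (is.na(value) || value < 0 || value > 130) next
      taken <- rbind(taken, data.frame(start = ms, end = me))
      s0 <- cs[k] - 1L
      e0 <- s0 + cl[k]
      out[[length(out) + 1L]] <- data.frame(
        start = s0, end = e0,
        text = span_text(sentence_text, s0, e0),
        value = value, kind = p$kind)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(sent_id = integer(0), start = integer(0),
                          end = integer(0), text = character(0),
                          value = integer(0), kind = character(0)))
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$start), , drop = FALSE]
  tibble::tibble(sent_id = sent_id, start = res$start + offset,
                 end = res$end + offset, text = res$text,
                 value = res$value, kind = res$kind)
}
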