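# text_prep: section finding, sentence segmentation, clause splitting and
# coreference-cue detection. All spans are 0-based half-open character
# intervals on the document text; sentence and chunk ids are 0-based.

#' Default family-history section headers
#'
#' Header labels recognized by [find_family_history_section()]. The set is
#' configurable because note-type conventions differ across institutions.
#' @return Character vector of header labels.
#' @export
fh_section_headers <- function() c("FAMILY HISTORY", "FAMILY HX", "FH")

#' Default coreference cue set
#'
#' Pronoun and plural-reference keywords that license cross-sentence linking
#' of an observation back to a previously mentioned family member. The core
#' cues are he/she/his/her and the plural "none of them"; they/them are a
#' minimal extension for plural antecedents.
#' @return Character vector of cue strings (lower case).
#' @export
fh_coref_cues <- function() {
  c("none of them", "he", "she", "his", "her", "they", "them")
}

# sentence-terminator guard list: a '.' ending one of these is not a break
fh_abbreviations <- function() {
  c("dr.", "mr.", "mrs.", "ms.", "st.", "jr.", "sr.", "vs.", "etc.",
    "e.g.", "i.e.", "y.o.", "approx.", "no.")
}

#' Locate the family-history section of a clinical note
#'
#' Finds the first matching section header (case-insensitive, at the start
#' of a line, followed by a colon or the end of the line) and returns the
#' span from just after the header up to the next all-caps `HEADER:` line or
#' the end of the note, trimmed of surrounding whitespace. When no header
#' matches, the whole document is returned with `fallback = TRUE` so that
#' downstream stages still run on header-less fragments.
#'
#' @param text Full note text.
#' @param headers Character vector of header labels to look for.
#' @return A list with `name`, `start`, `end` (0-based half-open span of the
#'   section body), `text`, and `fallback`.
#' @examples
#' find_family_history_section(
#'   "FAMILY HISTORY: Mother has diabetes.\nSOCIAL HISTORY: smoker")
#' @export
find_family_history_section <- function(text, headers = fh_section_headers()) {
  stopifnot(is.character(text), length(text) == 1)
  hdr_pat <- paste0("(?im)^[ \t]*(", paste(escape_regex(headers), collapse = "|"),
                    ")[ \t]*(:|\r?$)")
  m <- regexpr(hdr_pat, text, perl = TRUE)
  if (m == -1L) {
    return(list(name = NA_character_, start = 0L, end = nchar(text),
                text = text, fallback = TRUE))
  }
  body_start <- as.integer(m) + attr(m, "match.length")   # 1-based
  rest <- substr(text, body_start, nchar(text))
  nxt <- regexpr("(?m)^[ \t]*[A-Z][A-Z /]*[A-Z][ \t]*:", rest, perl = TRUE)
  body_end <- if (nxt == -1L) nchar(text) else body_start + as.integer(nxt) - 2L
  body <- substr(text, body_start, body_end)
  lead <- attr(regexpr("^\\s*", body), "match.length")
  trail <- attr(regexpr("\\s*$", body), "match.length")
  s0 <- body_start - 1L + lead                  # 0-based start
  e0 <- body_end - trail                        # 0-based half-open end
  if (e0 < s0) e0 <- s0
  hdr_txt <- regmatches(text, m)
  list(name = trimws(sub("[:\r\n]+$", "", hdr_txt)),
       start = s0, end = e0, text = span_text(text, s0, e0),
       fallback = FALSE)
}

#' Split text into sentences
#'
#' Deterministic rule-based segmentation: sentences end at `.`, `!`, `?` or
#' a newline, except that a period is kept inside a sentence when it closes
#' a guarded abbreviation (e.g. "Dr.", "vs.", "y.o.") or sits between two
#' digits (decimal numbers). Trimmed sentence spans tile the non-whitespace
#' text exactly.
#'
#' @param text Text to segment (typically a section body).
#' @param offset Document offset (0-based) of `text`; added to all spans.
#' @param abbreviations Guard list of abbreviation strings ending in `.`.
#' @return A tibble with columns `sent_id`, `start`, `end`, `text`.
#' @examples
#' segment_sentences("Father is deceased. He had colon cancer.")
#' @export
segment_sentences <- function(text, offset = 0L,
                              abbreviations = fh_abbreviations()) {
  n <- nchar(text)
  if (n == 0) {
    return(tibble::tibble(sent_id = integer(0), start = integer(0),
                          end = integer(0), text = character(0)))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_term <- chars %in% c("!", "?", "\n")
  dots <- which(chars == ".")
  abbr <- tolower(abbreviations)
  for (i in dots) {
    guarded <- FALSE
    if (i > 1 && i < n && grepl("[0-9]", chars[i - 1]) &&
        grepl("[0-9]", chars[i + 1])) {
      guarded <- TRUE
    }
    if (!guarded) {
      for (a in abbr) {
        ppos <- which(strsplit(a, "", fixed = TRUE)[[1]] == ".")
        for (p in ppos) {
          s <- i - p + 1L
          if (s < 1) next
          if (tolower(substr(text, s, s + nchar(a) - 1L)) == a &&
              (s == 1 || !grepl("[A-Za-z0-9.]", substr(text, s - 1, s - 1)))) {
            guarded <- TRUE
          }
        }
        if (guarded) break
      }
    }
    if (!guarded) is_term[i] <- TRUE
  }
  breaks <- c(which(is_term), n)
  out <- list()
  prev <- 0L          # 0-based position after previous terminator
  for (b in breaks) {
    seg_start <- prev                 # 0-based
    seg_end <- b                      # include terminator char (half-open)
    prev <- b
    seg <- span_text(text, seg_start, seg_end)
    lead <- attr(regexpr("^\\s*", seg), "match.length")
    trail <- attr(regexpr("\\s*$", seg), "match.length")
    s0 <- seg_start + lead
    e0 <- seg_end - trail
    if (e0 <= s0) next
    out[[length(out) + 1L]] <- data.frame(start = s0, end = e0)
  }
  if (length(out) == 0) {
    return(tibble::tibble(sent_id = integer(0), start = integer(0),
                          end = integer(0), text = character(0)))
  }
  df <- dplyr::bind_rows(out)
  df <- df[!duplicated(df$start), , drop = FALSE]
  tibble::tibble(sent_id = seq_len(nrow(df)) - 1L,
                 start = df$start + offset,
                 end = df$end + offset,
                 text = span_text(text, df$start, df$end))
}

#' Split a sentence into clauses
#'
#' Clauses are the co-occurrence unit for same-sentence relation linking.
#' The sentence is always split at semicolons; it is split at a comma or at
#' the conjunction "and" only when the material after the delimiter contains
#' a family-member span, so that observation lists attached to a single
#' family member ("Mother has diabetes and hypertension") stay in one
#' clause. Clause spans partition the sentence span exactly; `chunk_id` is
#' 0-based in order.
#'
#' @param sentence_text The sentence text.
#' @param fm_spans Optional data frame of family-member spans (`start`,
#'   `end`) in the same coordinates as `offset`.
#' @param offset Document offset (0-based) of the sentence start.
#' @param sent_id Sentence id to stamp on the clauses.
#' @return A tibble with columns `sent_id`, `chunk_id`, `start`, `end`,
#'   `text`.
#' @examples
#' split_clauses("Mother has diabetes; father has asthma.")
#' @export
split_clauses <- function(sentence_text, fm_spans = NULL, offset = 0L,
                          sent_id = 0L) {
  n <- nchar(sentence_text)
  fm_starts <- if (is.null(fm_spans) || nrow(fm_spans) == 0) {
    integer(0)
  } else {
    as.integer(fm_spans$start) - offset
  }
  cuts <- integer(0)       # 0-based half-open end of each delimiter
  chars <- strsplit(sentence_text, "", fixed = TRUE)[[1]]
  for (i in which(chars == ";")) cuts <- c(cuts, i)
  for (i in which(chars == ",")) {
    if (any(fm_starts >= i)) cuts <- c(cuts, i)
  }
  ands <- find_term(sentence_text, "and")
  for (k in seq_len(nrow(ands))) {
    if (any(fm_starts >= ands$end[k])) cuts <- c(cuts, ands$end[k])
  }
  cuts <- sort(unique(cuts))
  # a cut that leaves nothing but whitespace/punctuation behind is dropped
  cuts <- cuts[vapply(cuts, function(c) {
    grepl("[A-Za-z0-9]", span_text(sentence_text, c, n))
  }, logical(1))]
  starts <- c(0L, cuts)
  ends <- c(cuts, n)
  keep <- starts < ends
  starts <- starts[keep]; ends <- ends[keep]
  tibble::tibble(sent_id = sent_id,
                 chunk_id = seq_along(starts) - 1L,
                 start = starts + offset,
                 end = ends + offset,
                 text = span_text(sentence_text, starts, ends))
}

#' Detect coreference cue keywords in a sentence
#'
#' Case-insensitive whole-token matching of the configured cue set, with
#' multi-word cues ("none of them") claimed before their single-token parts.
#' Cues never match inside a longer word ("hershey" contains no cue).
#'
#' @param text Sentence text.
#' @param cues Cue set; see [fh_coref_cues()].
#' @param offset Document offset (0-based) of `text`.
#' @return A tibble with columns `cue` (lower-cased), `start`, `end`.
#' @examples
#' detect_coreference_cues("None of them smoked.")
#' @export
detect_coreference_cues <- function(text, cues = fh_coref_cues(),
                                    offset = 0L) {
  hits <- find_terms_multi(text, cues)
  hits <- hits[hits$term %in% norm_text(cues), , drop = FALSE]
  tibble::tibble(cue = hits$term, start = hits$start + offset,
                 end = hits$end + offset)
}
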