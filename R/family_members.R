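# Family-member recognition: trigger-table matching with side-of-family
# modifiers, possessive compounds, and spouse/in-law flagging.

#' Family-member identification rules
#'
#' Reads the editable rule table shipped with the package (or a user copy).
#' Each row maps a trigger term to a normalized family-member category, an
#' optional fixed side of family, a degree of consanguinity (1 =
#' parent/sibling/child, 2 = grandparent/aunt/uncle/half-sibling, 3 =
#' cousin/great-grandparent), and a spouse flag. Rows with category `EXT`
#' (niece/nephew) fall outside the 15-category challenge convention and are
#' handled by the `extended` argument of [recognize_family_members()].
#'
#' @param path Optional path to a replacement TSV with columns `trigger`,
#'   `category`, `side`, `degree`, `spouse`.
#' @return A tibble of rules.
#' @export
fh_fm_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fm_rules.tsv", package = "fhlex")
  df <- read_tsv_file(path, c("trigger", "category", "side", "degree",
                              "spouse"))
  df$trigger <- norm_text(df$trigger)
  df$category[!nzchar(df$category)] <- NA_character_
  df$side[!nzchar(df$side)] <- NA_character_
  df$degree <- suppressWarnings(as.integer(df$degree))
  df$spouse <- df$spouse == "1"
  df
}

# possessive compounds: owner's relative -> aggregated category + side
FM_COMPOSITIONS <- list(
  brother = list(category = "Uncle", degree = 2L),
  sister  = list(category = "Aunt", degree = 2L),
  mother  = list(category = "Grandmother", degree = 2L),
  father  = list(category = "Grandfather", degree = 2L)
)

#' Recognize family-member mentions in a sentence
#'
#' Leftmost-longest, case-insensitive matching of the trigger table with
#' token boundaries (punctuation around a trigger never blocks a match).
#' Three refinements run on top of plain triggers:
#'
#' * possessive compounds "mother's brother" / "father's sister" etc. are
#'   folded into the aggregated relative (Uncle, Maternal / Aunt, Paternal,
#'   ...), with the side inherited from the head word;
#' * a "maternal" / "paternal" modifier immediately before the trigger is
#'   absorbed into the span and sets the side of family;
#' * spouse and in-law terms are matched but flagged (`is_spouse = TRUE`,
#'   no category, no degree): they are recorded so that relation linking can
#'   exclude them, never treated as blood relatives.
#'
#' @param sentence_text Sentence text.
#' @param rules Rule table from [fh_fm_rules()].
#' @param offset Document offset (0-based) of the sentence.
#' @param sent_id Sentence id stamped on the mentions.
#' @param extended How to treat niece/nephew-type triggers outside the
#'   15-category set: `"drop"` (default) removes them, `"map"` maps them to
#'   the nearest-generation category `Child`.
#' @return A tibble with columns `sent_id`, `start`, `end`, `text`,
#'   `category`, `side`, `degree`, `is_spouse`.
#' @examples
#' recognize_family_members("Her maternal grandmother had asthma.")
#' @export
recognize_family_members <- function(sentence_text, rules = fh_fm_rules(),
                                     offset = 0L, sent_id = 0L,
                                     extended = c("drop", "map")) {
  extended <- match.arg(extended)
  hits <- list()

  # 1. possessive compounds claim their spans first
  comp_pat <- "(?i)(?<![a-z0-9])(mother|father)'s (mother|father|brother|sister)(?![a-z0-9])"
  m <- gregexpr(comp_pat, sentence_text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      s <- as.integer(m[k]) - 1L
      e <- s + attr(m, "match.length")[k]
      txt <- span_text(sentence_text, s, e)
      parts <- strsplit(tolower(txt), "'s ", fixed = TRUE)[[1]]
      comp <- FM_COMPOSITIONS[[parts[2]]]
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, end = e, text = txt,
        category = comp$category,
        side = if (parts[1] == "mother") "Maternal" else "Paternal",
        degree = comp$degree, is_spouse = FALSE)
    }
  }
  claimed <- if (length(hits) > 0) dplyr::bind_rows(hits) else
    data.frame(start = integer(0), end = integer(0))

  # 2. leftmost-longest trigger matching outside claimed spans
  cand <- find_terms_multi(sentence_text, rules$trigger)
  cand$rule <- match(cand$term, rules$trigger)
  cand <- cand[!is.na(cand$rule), , drop = FALSE]
  if (nrow(cand) > 0) {
    cand <- cand[!vapply(seq_len(nrow(cand)), function(i) {
      nrow(claimed) > 0 &&
        any(spans_overlap(cand$start[i], cand$end[i],
                          claimed$start, claimed$end))
    }, logical(1)), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      r <- cand$rule[i]
      s <- cand$start[i]; e <- cand$end[i]
      side <- rules$side[r]
      # absorb a maternal/paternal modifier directly before the trigger
      if (!rules$spouse[r]) {
        before <- substr(sentence_text, 1, s)
        mm <- regexpr("(?i)(maternal|paternal)[ \t]+$", before, perl = TRUE)
        if (mm != -1L) {
          side <- if (grepl("^m", tolower(regmatches(before, mm)))) {
            "Maternal"
          } else {
            "Paternal"
          }
          s <- as.integer(mm) - 1L
        }
      }
      hits[[length(hits) + 1L]] <- data.frame(
        start = s, end = e, text = span_text(sentence_text, s, e),
        category = rules$category[r], side = side,
        degree = rules$degree[r], is_spouse = rules$spouse[r])
    }
  }

  if (length(hits) == 0) {
    return(tibble::tibble(sent_id = integer(0), start = integer(0),
                          end = integer(0), text = character(0),
                          category = character(0), side = character(0),
                          degree = integer(0), is_spouse = logical(0)))
  }
  res <- dplyr::bind_rows(hits)
  res <- res[order(res$start), , drop = FALSE]
  if (extended == "drop") {
    res <- res[is.na(res$category) | res$category != "EXT", , drop = FALSE]
  } else {
    res$category[!is.na(res$category) & res$category == "EXT"] <- "Child"
  }
  res$side[is.na(res$side) & !res$is_spouse] <- "NA"
  tibble::tibble(sent_id = sent_id,
                 start = res$start + offset, end = res$end + offset,
                 text = res$text, category = res$category, side = res$side,
                 degree = res$degree, is_spouse = res$is_spouse)
}
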