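# Internal helpers shared across modules.
#
# Coordinate convention (fixed for output reproducibility): every span in
# this package is a 0-based, half-open character interval [start, end)
# measured on the document text. Sentence and chunk ids are 0-based.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Canonical surface-form normalization used for lexicon variants and
# dictionary lookup: case-fold, trim, collapse internal whitespace.
# Deliberately no stemming: raw EHR typo variants must survive as-is.
norm_text <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# 0-based half-open spans of alphanumeric token runs.
token_spans <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m) - 1L,
             end   = as.integer(m) + attr(m, "match.length") - 1L)
}

# Covered text of a 0-based half-open span (vectorized over spans).
span_text <- function(text, start, end) substring(text, start + 1L, end)

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

# All occurrences of a literal term with token boundaries on both sides.
# Internal single spaces in the term match any whitespace run. Returns
# 0-based half-open spans.
find_term <- function(text, term, ignore_case = TRUE) {
  body <- gsub(" ", "\\\\s+", escape_regex(term))
  pat <- paste0("(?<![A-Za-z0-9])", body, "(?![A-Za-z0-9])")
  m <- gregexpr(pat, text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m) - 1L,
             end   = as.integer(m) + attr(m, "match.length") - 1L)
}

spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# One-pass scan for any of several literal terms (token boundaries, case
# insensitive). Alternatives are ordered longest-first so the engine picks
# the longest term at each leftmost position; matches are non-overlapping.
# Returns 0-based half-open spans with the matched (normalized) term.
find_terms_multi <- function(text, terms) {
  if (length(terms) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      term = character(0)))
  }
  terms <- terms[order(-nchar(terms))]
  body <- paste(vapply(terms, function(t) gsub(" ", "\\\\s+",
                                               escape_regex(t)), ""),
                collapse = "|")
  pat <- paste0("(?<![A-Za-z0-9])(?:", body, ")(?![A-Za-z0-9])")
  m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      term = character(0)))
  }
  start <- as.integer(m) - 1L
  end <- as.integer(m) + attr(m, "match.length") - 1L
  data.frame(start = start, end = end,
             term = norm_text(span_text(text, start, end)))
}

# number of alphanumeric tokens in each string (vectorized)
n_tokens <- function(x) {
  if (length(x) == 0) return(integer(0))
  m <- gregexpr("[A-Za-z0-9]+", x)
  vapply(m, function(mm) if (mm[1] == -1L) 0L else length(mm), integer(1))
}

read_tsv_file <- function(path, col_names) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", fileEncoding = "UTF-8",
                          check.names = FALSE)
  missing <- setdiff(col_names, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(df[col_names])
}

write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0) {
               do.call(paste, c(lapply(df, as.character), sep = "\t"))
             })
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
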