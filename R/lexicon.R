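# lexicon_core: data model, I/O, filtering and statistics for the FH
# semantic lexicon.

LEXICON_COLS <- c("variant", "cui", "snomed_code", "preferred_term",
                  "semantic_type")

#' Construct a family-history lexicon
#'
#' A lexicon is a flat dictionary of surface-form variants, each mapped to a
#' UMLS concept unique identifier (CUI), an optional SNOMED-CT code, a
#' preferred term, and a UMLS semantic type. Variants are normalized
#' (case-folded, whitespace collapsed) on construction and exact duplicate
#' `(variant, cui)` pairs collapse silently to one entry; the same variant
#' mapped to different CUIs is kept as a deliberate ambiguity, resolved
#' downstream by [match_observations()].
#'
#' The constructor validates identifier *shape* (CUI pattern `C#######`,
#' semantic-type pattern `T###`, numeric-or-empty SNOMED code) but does not
#' restrict semantic types to the FH-eligible set, so that intermediate
#' screening stages can hold ineligible candidates; [load_lexicon()] is the
#' strict gate for lexicon files.
#'
#' @param entries A data frame with columns `variant`, `cui`, `snomed_code`,
#'   `preferred_term`, `semantic_type` (missing `snomed_code`/`preferred_term`
#'   are filled with `""`). `NULL` gives an empty lexicon.
#' @return An object of class `fh_lexicon` (a tibble of entries).
#' @seealso [load_lexicon()], [write_lexicon()], [lexicon_stats()]
#' @examples
#' fh_lexicon(data.frame(variant = "Diabetes", cui = "C0011854",
#'                       snomed_code = "73211009",
#'                       preferred_term = "Diabetes mellitus",
#'                       semantic_type = "T047"))
#' @export
fh_lexicon <- function(entries = NULL) {
  if (is.null(entries) || nrow(entries) == 0) {
    entries <- tibble::tibble(variant = character(0), cui = character(0),
                              snomed_code = character(0),
                              preferred_term = character(0),
                              semantic_type = character(0))
  }
  entries <- tibble::as_tibble(entries)
  if (!"snomed_code" %in% names(entries)) entries$snomed_code <- ""
  if (!"preferred_term" %in% names(entries)) entries$preferred_term <- ""
  missing <- setdiff(LEXICON_COLS, names(entries))
  if (length(missing) > 0) {
    stop("lexicon entries lack column(s): ", paste(missing, collapse = ", "))
  }
  entries <- entries[LEXICON_COLS]
  entries$variant <- norm_text(entries$variant)
  entries$snomed_code[is.na(entries$snomed_code)] <- ""
  bad <- !nzchar(entries$variant) | !is_cui(entries$cui) |
    !is_semantic_code(entries$semantic_type) | !is_snomed(entries$snomed_code)
  if (any(bad)) {
    stop("invalid lexicon entr", if (sum(bad) == 1) "y" else "ies",
         " at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
  }
  entries <- entries[!duplicated(paste0(entries$variant, "\r", entries$cui)), ]
  class(entries) <- c("fh_lexicon", class(tibble::tibble()))
  entries
}

#' @export
print.fh_lexicon <- function(x, ...) {
  s <- lexicon_stats(x)
  cat(sprintf("<fh_lexicon> %d entries, %d CUIs, %d SNOMED codes (%.2f variants/CUI)\n",
              s$n_variants, s$n_cuis, s$n_snomed, s$avg_variants_per_cui))
  NextMethod()
}

#' Read a lexicon from its tab-delimited file format
#'
#' The on-disk dialect is a UTF-8, LF-terminated, 5-column TSV:
#' `variant`, `cui`, `snomed_code`, `preferred_term`, `semantic_type_code`.
#' A header row is optional and auto-detected (first field equal to
#' `"variant"`). Rows must carry a non-empty variant, a well-formed CUI, an
#' empty or numeric SNOMED code, and a semantic type from the FH-eligible
#' set ([fh_eligible_types()]); with `strict = FALSE` offending rows are
#' skipped with a warning naming their line numbers, with `strict = TRUE`
#' the first offending row raises an error.
#'
#' @param path Path to (or connection readable as) a lexicon TSV.
#' @param strict Raise instead of skip on invalid rows?
#' @return An [fh_lexicon()].
#' @export
load_lexicon <- function(path, strict = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  first_data <- 1L
  if (length(lines) > 0) {
    f1 <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (length(f1) >= 1 && identical(tolower(f1[[1]]), "variant")) {
      first_data <- 2L
    }
  }
  keep <- list()
  problems <- character(0)
  if (length(lines) >= first_data) {
    for (i in seq(first_data, length(lines))) {
      ln <- lines[[i]]
      if (!nzchar(trimws(ln))) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      length(f) <- 5L                       # pad dropped trailing fields
      f[is.na(f)] <- ""
      variant <- norm_text(f[[1]])
      msg <- NULL
      if (!nzchar(variant)) {
        msg <- "empty variant"
      } else if (!is_cui(f[[2]])) {
        msg <- sprintf("malformed CUI '%s'", f[[2]])
      } else if (!is_snomed(f[[3]])) {
        msg <- sprintf("malformed SNOMED code '%s'", f[[3]])
      } else if (!f[[5]] %in% fh_eligible_types()) {
        msg <- sprintf("semantic type '%s' not FH-eligible", f[[5]])
      }
      if (!is.null(msg)) {
        if (strict) stop(sprintf("line %d: %s", i, msg))
        problems <- c(problems, sprintf("line %d: %s", i, msg))
        next
      }
      keep[[length(keep) + 1L]] <- data.frame(
        variant = variant, cui = f[[2]], snomed_code = f[[3]],
        preferred_term = f[[4]], semantic_type = f[[5]]
      )
    }
  }
  if (length(problems) > 0) {
    warning(sprintf("skipped %d invalid lexicon row(s): %s",
                    length(problems),
                    paste(utils::head(problems, 5), collapse = "; ")))
  }
  fh_lexicon(if (length(keep) > 0) dplyr::bind_rows(keep) else NULL)
}

#' Write a lexicon to its tab-delimited file format
#'
#' Writes the 5-column TSV dialect documented in [load_lexicon()], always
#' with a header row, UTF-8, LF line endings. `load_lexicon(write_lexicon(L))`
#' reproduces `L` up to entry order.
#'
#' @param lexicon An [fh_lexicon()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "fh_lexicon"))
  df <- as.data.frame(lexicon)
  names(df) <- c("variant", "cui", "snomed_code", "preferred_term",
                 "semantic_type_code")
  write_tsv_file(df, path)
}

#' Filter a lexicon by semantic type
#'
#' Keeps exactly the entries whose semantic type is in `allowed`. Used both
#' to enforce the FH-eligible set on candidate material and to slice a
#' lexicon for analysis. Idempotent; the input is unchanged.
#'
#' @param lexicon An [fh_lexicon()].
#' @param allowed Non-empty character vector of semantic-type codes;
#'   defaults to the FH-eligible set.
#' @return The filtered [fh_lexicon()].
#' @export
filter_by_semantic_type <- function(lexicon, allowed = fh_eligible_types()) {
  stopifnot(inherits(lexicon, "fh_lexicon"), length(allowed) > 0)
  fh_lexicon(lexicon[lexicon$semantic_type %in% allowed, ])
}

#' Summary statistics of a lexicon
#'
#' Counts distinct CUIs, entries (distinct `(variant, cui)` pairs), and
#' distinct non-empty SNOMED codes, and reports the average number of
#' variants per CUI (`n_variants / n_cuis`). An empty lexicon reports an
#' average of 0 with the `empty` flag set.
#'
#' @param lexicon An [fh_lexicon()].
#' @return A list of class `fh_lexicon_stats` with fields `n_cuis`,
#'   `n_variants`, `n_snomed`, `avg_variants_per_cui`, `empty`.
#' @examples
#' lex <- make_mini_lexicon(10, 5, seed = 1)
#' lexicon_stats(lex)
#' @export
lexicon_stats <- function(lexicon) {
  stopifnot(inherits(lexicon, "fh_lexicon"))
  n_variants <- nrow(lexicon)
  n_cuis <- dplyr::n_distinct(lexicon$cui)
  n_snomed <- dplyr::n_distinct(lexicon$snomed_code[nzchar(lexicon$snomed_code)])
  structure(list(
    n_cuis = n_cuis,
    n_variants = n_variants,
    n_snomed = n_snomed,
    avg_variants_per_cui = if (n_cuis > 0) n_variants / n_cuis else 0,
    empty = n_cuis == 0
  ), class = "fh_lexicon_stats")
}

#' @export
print.fh_lexicon_stats <- function(x, ...) {
  cat(sprintf("FH lexicon: %d variants, %d CUIs, %d SNOMED codes\n",
              x$n_variants, x$n_cuis, x$n_snomed))
  cat(sprintf("average variants per CUI: %.2f%s\n", x$avg_variants_per_cui,
              if (x$empty) " (empty lexicon)" else ""))
  invisible(x)
}

#' Apply a CUI-to-SNOMED mapping file to a lexicon
#'
#' SNOMED-CT codes are license-restricted, so they travel as a separate
#' 2-column mapping (`cui`, `snomed_code`) rather than inside a distributed
#' lexicon. Entries whose CUI is mapped gain (or replace) their SNOMED code;
#' unmapped entries are untouched; no entry is added or removed.
#'
#' @param lexicon An [fh_lexicon()].
#' @param mapping A data frame with columns `cui` and `snomed_code`, or a
#'   named character vector (names are CUIs). Malformed rows are skipped
#'   with a warning.
#' @return The updated [fh_lexicon()].
#' @export
apply_snomed_mapping <- function(lexicon, mapping) {
  stopifnot(inherits(lexicon, "fh_lexicon"))
  if (is.character(mapping)) {
    mapping <- data.frame(cui = names(mapping), snomed_code = unname(mapping))
  }
  mapping <- as.data.frame(mapping)
  bad <- !is_cui(mapping$cui) | !grepl("^[0-9]+$", mapping$snomed_code)
  if (any(bad)) {
    warning(sprintf("skipped %d malformed SNOMED mapping row(s)", sum(bad)))
    mapping <- mapping[!bad, , drop = FALSE]
  }
  idx <- match(lexicon$cui, mapping$cui)
  hit <- !is.na(idx)
  lexicon$snomed_code[hit] <- as.character(mapping$snomed_code[idx[hit]])
  lexicon
}

#' Read a CUI-to-SNOMED mapping file
#'
#' @param path 2-column TSV (`cui`, `snomed_code`), header optional.
#' @return A tibble with columns `cui`, `snomed_code`.
#' @export
load_snomed_mapping <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0 &&
      identical(tolower(strsplit(lines[[1]], "\t")[[1]][[1]]), "cui")) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    return(tibble::tibble(cui = character(0), snomed_code = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(cui = vapply(f, `[`, "", 1),
                 snomed_code = vapply(f, function(x) x[2] %||% "", ""))
}

#' Indexes over a lexicon
#'
#' `variant_index()` maps each normalized variant to the row indices of the
#' entries sharing it (several when the variant is ambiguous across CUIs);
#' `concept_index()` maps each CUI to the variants expressing it.
#'
#' @param lexicon An [fh_lexicon()].
#' @return A named list.
#' @export
variant_index <- function(lexicon) {
  split(seq_len(nrow(lexicon)), lexicon$variant)
}

#' @rdname variant_index
#' @export
concept_index <- function(lexicon) {
  split(lexicon$variant, lexicon$cui)
}
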