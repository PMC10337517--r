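#' UMLS semantic types admitted as family-history concepts
#'
#' The lexicon restricts family-history (FH) observations to eleven UMLS
#' semantic types drawn from the "DISO" (disorder) semantic group, plus the
#' "Finding" and "Sign or symptom" types. T050 (experimental model of
#' disease) is deliberately excluded: laboratory disease models are never
#' family-history content.
#'
#' @return A tibble with columns `code` (e.g. `"T047"`) and `label`.
#' @examples
#' fh_semantic_types()
#' @export
fh_semantic_types <- function() {
  tibble::tibble(
    code = c("T019", "T020", "T037", "T047", "T048", "T049",
             "T190", "T191", "T033", "T046", "T184"),
    label = c("Congenital abnormality",
              "Acquired abnormality",
              "Injury or poisoning",
              "Disease or syndrome",
              "Mental or behavioral dysfunction",
              "Cell or molecular dysfunction",
              "Anatomical abnormality",
              "Neoplastic process",
              "Finding",
              "Pathologic function",
              "Sign or symptom")
  )
}

#' @rdname fh_semantic_types
#' @return `fh_eligible_types()` returns the eleven eligible codes as a
#'   character vector.
#' @export
fh_eligible_types <- function() fh_semantic_types()$code

is_cui <- function(x) grepl("^C[0-9]{7}$", x)

is_semantic_code <- function(x) grepl("^T[0-9]{3}$", x)

is_snomed <- function(x) x == "" | grepl("^[0-9]+$", x)
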