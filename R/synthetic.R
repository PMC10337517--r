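# synthetic_corpus: generate FH-style notes with self-annotating gold
# entities/relations and a synthetic mini-lexicon, so that every other
# module is testable without access-restricted clinical corpora.

safe_sample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

MINI_LEX_PREFIXES <- c("cardi", "neur", "derm", "hepat", "nephr", "arthr",
                       "gastr", "pulmon", "angi", "oste", "myel", "retin",
                       "cephal", "thromb", "fibr")
MINI_LEX_SUFFIXES <- c("opathy", "itis", "osis", "algia", "emia", "oma",
                       "plasia", "ectasia")
MINI_LEX_MODIFIERS <- c("chronic", "acute", "mild", "severe", "familial",
                        "recurrent")

#' Generate a synthetic mini-lexicon
#'
#' Builds a small, fully synthetic [fh_lexicon()]: pseudo-disease names
#' from medical morpheme combinations, synthetic CUIs in the `C9xxxxxx`
#' range, 1..`max_variants` variants per concept (modifier and suffix
#' forms), semantic types drawn from the FH-eligible set, and SNOMED codes
#' for about 70% of concepts. With probability 0.2 a concept with a
#' multi-word variant also receives a run-together typo variant (spaces
#' stripped), emulating raw-EHR concatenation artifacts. Variants are
#' globally unique. The same seed always reproduces the same lexicon.
#'
#' @param n_concepts Number of concepts (max 120).
#' @param max_variants Maximum variants per concept.
#' @param seed Integer seed.
#' @return An [fh_lexicon()].
#' @examples
#' make_mini_lexicon(10, 5, seed = 1)
#' @export
make_mini_lexicon <- function(n_concepts = 20L, max_variants = 4L,
                              seed = 42L) {
  stopifnot(n_concepts >= 1,
            n_concepts <= length(MINI_LEX_PREFIXES) * length(MINI_LEX_SUFFIXES),
            max_variants >= 1)
  withr::with_seed(seed, {
    combos <- expand.grid(p = MINI_LEX_PREFIXES, s = MINI_LEX_SUFFIXES,
                          stringsAsFactors = FALSE)
    combos <- combos[sample.int(nrow(combos), n_concepts), , drop = FALSE]
    entries <- list()
    for (i in seq_len(n_concepts)) {
      base <- paste0(combos$p[i], combos$s[i])
      cui <- sprintf("C9%06d", i)
      snomed <- if (stats::runif(1) < 0.7) {
        sprintf("%d", 10000009 + i * 131)
      } else {
        ""
      }
      stype <- safe_sample(fh_eligible_types(), 1)
      cand <- c(base,
                paste(safe_sample(MINI_LEX_MODIFIERS, 3), base),
                paste(base, c("disorder", "syndrome")))
      n_var <- sample.int(max_variants, 1)
      vars <- cand[seq_len(min(n_var, length(cand)))]
      multi <- vars[n_tokens(vars) > 1]
      if (length(multi) > 0 && stats::runif(1) < 0.2) {
        vars <- c(vars, gsub(" ", "", multi[[1]], fixed = TRUE))
      }
      entries[[i]] <- tibble::tibble(
        variant = vars, cui = cui, snomed_code = snomed,
        preferred_term = paste0(toupper(substr(base, 1, 1)),
                                substr(base, 2, nchar(base))),
        semantic_type = stype)
    }
    lex <- dplyr::bind_rows(entries)
    lex <- lex[!duplicated(lex$variant), , drop = FALSE]
    fh_lexicon(lex)
  })
}

#' Configuration for the synthetic note generator
#'
#' The rates select, per statement, which construct is generated; the
#' remaining probability mass falls to plain single-clause
#' family-member/observation statements, and rates summing beyond 1 are
#' renormalized (set the other rates to 0 to generate a single construct
#' exclusively). The seed fixes the corpus (and its gold standard)
#' exactly.
#'
#' @param n_documents Number of notes.
#' @param seed Integer seed.
#' @param rate_negation Negated statements ("No family history of X." /
#'   "FM has no history of X.").
#' @param rate_cross_sentence Two-sentence coreference constructs
#'   ("FM is deceased. She had X.").
#' @param rate_spouse Spouse distractors ("Her husband has X."), which
#'   contribute no gold relations.
#' @param rate_obs_list Observation lists ("FM has X and Y.").
#' @param rate_living_status Living-status statements.
#' @param rate_age Age-at-diagnosis statements.
#' @param n_concepts,max_variants Mini-lexicon shape when none is supplied.
#' @param adversarial Also generate constructs the linking rules do not
#'   cover (cataphora, distance-3 coreference); their gold relations are
#'   expected misses, used to show recall degrading on harder text.
#' @return A list of class `fh_generation_config`.
#' @export
fh_generation_config <- function(n_documents = 20L, seed = 1L,
                                 rate_negation = 0.15,
                                 rate_cross_sentence = 0.20,
                                 rate_spouse = 0.10,
                                 rate_obs_list = 0.15,
                                 rate_living_status = 0.10,
                                 rate_age = 0.10,
                                 n_concepts = 20L, max_variants = 4L,
                                 adversarial = FALSE) {
  rates <- c(rate_negation, rate_cross_sentence, rate_spouse, rate_obs_list,
             rate_living_status, rate_age)
  stopifnot(all(rates >= 0), all(rates <= 1), n_documents >= 1)
  structure(list(n_documents = as.integer(n_documents),
                 seed = as.integer(seed),
                 rate_negation = rate_negation,
                 rate_cross_sentence = rate_cross_sentence,
                 rate_spouse = rate_spouse,
                 rate_obs_list = rate_obs_list,
                 rate_living_status = rate_living_status,
                 rate_age = rate_age,
                 n_concepts = as.integer(n_concepts),
                 max_variants = as.integer(max_variants),
                 adversarial = isTRUE(adversarial)),
            class = "fh_generation_config")
}

FM_POOL <- data.frame(
  surface = c("mother", "father", "sister", "brother", "aunt", "uncle",
              "maternal grandmother", "paternal grandmother",
              "maternal grandfather", "paternal grandfather",
              "daughter", "son"),
  category = c("Mother", "Father", "Sister", "Brother", "Aunt", "Uncle",
               "Grandmother", "Grandmother", "Grandfather", "Grandfather",
               "Daughter", "Son"),
  side = c("NA", "NA", "NA", "NA", "NA", "NA",
           "Maternal", "Paternal", "Maternal", "Paternal", "NA", "NA"),
  female = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
             TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

# sentence builder: accumulates text and tagged entity spans
new_sb <- function() {
  env <- new.env(parent = emptyenv())
  env$txt <- ""
  env$ents <- list()
  env
}
sb_add <- function(b, s) b$txt <- paste0(b$txt, s)
sb_tag <- function(b, s, type, concept, side = NA_character_,
                   certainty = "nonnegated") {
  start <- nchar(b$txt)
  sb_add(b, s)
  b$ents[[length(b$ents) + 1L]] <- tibble::tibble(
    type = type, concept = concept, side = side, certainty = certainty,
    start = start, end = nchar(b$txt), text = s)
}
sb_close <- function(b) {
  list(text = b$txt,
       ents = if (length(b$ents) > 0) dplyr::bind_rows(b$ents) else
         tibble::tibble(type = character(0), concept = character(0),
                        side = character(0), certainty = character(0),
                        start = integer(0), end = integer(0),
                        text = character(0)))
}

gold_rel <- function(fm, kind, target, certainty, provenance) {
  tibble::tibble(fm_category = fm$category, fm_side = fm$side,
                 target_kind = kind, target = target, certainty = certainty,
                 provenance = provenance)
}

# each emitter returns list(sentences = list of sb_close() results,
#                           relations = tibble)
emit_statement <- function(type, fm, obs, patient_her) {
  pron_p <- if (patient_her) "Her" else "His"
  fm_tag <- function(b, capital) {
    sb_tag(b, if (capital) cap1(fm$surface) else fm$surface,
           "FamilyMember", fm$category, fm$side)
  }
  obs_tag <- function(b, k = 1) {
    sb_tag(b, obs$variant[k], "Observation", obs$cui[k],
           certainty = "nonnegated")
  }
  obs_tag_neg <- function(b, k = 1) {
    sb_tag(b, obs$variant[k], "Observation", obs$cui[k],
           certainty = "negated")
  }
  fm_pron <- if (fm$female) "She" else "He"

  if (type == "simple") {
    b <- new_sb()
    if (stats::runif(1) < 0.5) {
      sb_add(b, paste0(pron_p, " "))
      fm_tag(b, capital = FALSE)
    } else {
      fm_tag(b, capital = TRUE)
    }
    sb_add(b, " has ")
    obs_tag(b)
    sb_add(b, ".")
    list(sentences = list(sb_close(b)),
         relations = gold_rel(fm, "observation", obs$cui[1], "nonnegated",
                              "same_clause"))
  } else if (type == "obs_list") {
    b <- new_sb()
    fm_tag(b, capital = TRUE)
    sb_add(b, " has ")
    obs_tag(b, 1)
    sb_add(b, " and ")
    obs_tag(b, 2)
    sb_add(b, ".")
    list(sentences = list(sb_close(b)),
         relations = dplyr::bind_rows(
           gold_rel(fm, "observation", obs$cui[1], "nonnegated",
                    "same_clause"),
           gold_rel(fm, "observation", obs$cui[2], "nonnegated",
                    "same_clause")))
  } else if (type == "negation") {
    b <- new_sb()
    if (stats::runif(1) < 0.5) {
      sb_add(b, "No family history of ")
      obs_tag_neg(b)
      sb_add(b, ".")
      list(sentences = list(sb_close(b)), relations = NULL)
    } else {
      fm_tag(b, capital = TRUE)
      sb_add(b, " has no history of ")
      obs_tag_neg(b)
      sb_add(b, ".")
      list(sentences = list(sb_close(b)),
           relations = gold_rel(fm, "observation", obs$cui[1], "negated",
                                "same_clause"))
    }
  } else if (type == "spouse") {
    b <- new_sb()
    sb_add(b, paste0(pron_p, " ",
                     if (patient_her) "husband" else "wife", " has "))
    obs_tag(b)
    sb_add(b, ".")
    list(sentences = list(sb_close(b)), relations = NULL)
  } else if (type == "living") {
    b <- new_sb()
    fm_tag(b, capital = TRUE)
    if (stats::runif(1) < 0.5) {
      sb_add(b, " is ")
      sb_tag(b, "alive", "LivingStatus", "Alive")
      sb_add(b, " and well.")
      status <- "Alive"
    } else {
      sb_add(b, " is ")
      sb_tag(b, "deceased", "LivingStatus", "Dead")
      sb_add(b, ".")
      status <- "Dead"
    }
    list(sentences = list(sb_close(b)),
         relations = gold_rel(fm, "living_status", status, "nonnegated",
                              "same_clause"))
  } else if (type == "cross") {
    b1 <- new_sb()
    fm_tag(b1, capital = TRUE)
    sb_add(b1, " is ")
    sb_tag(b1, "deceased", "LivingStatus", "Dead")
    sb_add(b1, ".")
    b2 <- new_sb()
    sb_add(b2, paste0(fm_pron, " had "))
    obs_tag(b2)
    sb_add(b2, ".")
    list(sentences = list(sb_close(b1), sb_close(b2)),
         relations = dplyr::bind_rows(
           gold_rel(fm, "living_status", "Dead", "nonnegated",
                    "same_clause"),
           gold_rel(fm, "observation", obs$cui[1], "nonnegated",
                    "coreference")))
  } else if (type == "age") {
    age <- sample(35:90, 1)
    b <- new_sb()
    fm_tag(b, capital = TRUE)
    sb_add(b, " was diagnosed with ")
    obs_tag(b)
    sb_add(b, " at age ")
    sb_tag(b, as.character(age), "Age", as.character(age))
    sb_add(b, ".")
    list(sentences = list(sb_close(b)),
         relations = gold_rel(fm, "observation", obs$cui[1], "nonnegated",
                              "same_clause"))
  } else if (type == "distance3") {
    b1 <- new_sb()
    fm_tag(b1, capital = TRUE)
    sb_add(b1, " is ")
    sb_tag(b1, "deceased", "LivingStatus", "Dead")
    sb_add(b1, ".")
    f1 <- new_sb(); sb_add(f1, "The patient was seen in clinic.")
    f2 <- new_sb(); sb_add(f2, "Records from outside were reviewed.")
    b2 <- new_sb()
    sb_add(b2, paste0(fm_pron, " had "))
    obs_tag(b2)
    sb_add(b2, ".")
    list(sentences = list(sb_close(b1), sb_close(f1), sb_close(f2),
                          sb_close(b2)),
         relations = dplyr::bind_rows(
           gold_rel(fm, "living_status", "Dead", "nonnegated",
                    "same_clause"),
           gold_rel(fm, "observation", obs$cui[1], "nonnegated",
                    "coreference")))
  } else if (type == "cataphora") {
    b1 <- new_sb()
    sb_add(b1, paste0(fm_pron, " had "))
    obs_tag(b1)
    sb_add(b1, ".")
    b2 <- new_sb()
    fm_tag(b2, capital = TRUE)
    sb_add(b2, " is ")
    sb_tag(b2, "deceased", "LivingStatus", "Dead")
    sb_add(b2, ".")
    list(sentences = list(sb_close(b1), sb_close(b2)),
         relations = dplyr::bind_rows(
           gold_rel(fm, "observation", obs$cui[1], "nonnegated",
                    "coreference"),
           gold_rel(fm, "living_status", "Dead", "nonnegated",
                    "same_clause")))
  } else {
    stop("unknown statement type: ", type)
  }
}

#' Generate a synthetic family-history corpus with gold annotations
#'
#' Each note is a FAMILY HISTORY section of 2–4 statements drawn from the
#' construct mix configured in [fh_generation_config()]: single-clause
#' family-member/observation statements, observation lists, two-sentence
#' coreference constructs with gender-consistent pronouns, negations,
#' spouse distractors, living-status and age statements. Gold entities and
#' relations are emitted from the template semantics during assembly, so
#' the gold standard is exactly consistent with the generated text: spouse
#' templates contribute no relations, negation templates set certainty to
#' negated, and cross-sentence relations carry `coreference` provenance.
#' Family members and concepts are sampled without replacement within a
#' document, so chains and deduplicated relation sets stay unambiguous.
#'
#' A fixed seed yields a byte-identical corpus and gold standard.
#'
#' @param config An [fh_generation_config()].
#' @param lexicon Optional [fh_lexicon()] to draw observation variants
#'   from; by default a mini-lexicon is generated from the config.
#' @return A list of class `fh_corpus` with `documents` (tibble: `doc_id`,
#'   `text`), `entities` (gold, [fh_extract()] entity format), `relations`
#'   (gold, with `provenance`), `lexicon`, `config`.
#' @examples
#' corp <- generate_corpus(fh_generation_config(n_documents = 3, seed = 9))
#' corp$documents$text[1]
#' @export
generate_corpus <- function(config = fh_generation_config(),
                            lexicon = NULL) {
  stopifnot(inherits(config, "fh_generation_config"))
  if (is.null(lexicon)) {
    lexicon <- make_mini_lexicon(config$n_concepts, config$max_variants,
                                 seed = config$seed %% 100000L + 7L)
  }
  stopifnot(nrow(lexicon) > 0)
  cidx <- concept_index(lexicon)
  all_cuis <- names(cidx)

  types <- c("negation", "cross", "spouse", "obs_list", "living", "age")
  probs <- c(config$rate_negation, config$rate_cross_sentence,
             config$rate_spouse, config$rate_obs_list,
             config$rate_living_status, config$rate_age)
  if (config$adversarial) {
    types <- c(types, "distance3", "cataphora")
    probs <- c(probs, 0.15, 0.15)
  }
  types <- c(types, "simple")
  probs <- c(probs, max(0, 1 - sum(probs)))
  probs <- probs / sum(probs)

  withr::with_seed(config$seed, {
    docs <- list(); ents <- list(); rels <- list()
    for (d in seq_len(config$n_documents)) {
      doc_id <- sprintf("doc%04d", d)
      n_stmt <- sample(2:4, 1)
      fm_rows <- FM_POOL[sample.int(nrow(FM_POOL), n_stmt), , drop = FALSE]
      need <- 2L * n_stmt
      cuis <- safe_sample(all_cuis, min(need, length(all_cuis)),
                          replace = need > length(all_cuis))
      stypes <- sample(types, n_stmt, replace = TRUE, prob = probs)
      patient_her <- stats::runif(1) < 0.5
      header <- "FAMILY HISTORY:\n"
      text <- header
      cur <- nchar(header)
      sent_counter <- 0L
      ci <- 1L
      for (s in seq_len(n_stmt)) {
        pick_cui <- cuis[((ci - 1L) %% length(cuis)) + 1L]
        pick_cui2 <- cuis[(ci %% length(cuis)) + 1L]
        ci <- ci + 2L
        obs <- tibble::tibble(
          cui = c(pick_cui, pick_cui2),
          variant = c(safe_sample(cidx[[pick_cui]], 1),
                      safe_sample(cidx[[pick_cui2]], 1)))
        st <- emit_statement(stypes[s], fm_rows[s, , drop = FALSE], obs,
                             patient_her)
        for (sent in st$sentences) {
          sep <- if (cur > nchar(header)) " " else ""
          base <- cur + nchar(sep)
          text <- paste0(text, sep, sent$text)
          cur <- nchar(text)
          if (nrow(sent$ents) > 0) {
            e <- sent$ents
            e$doc_id <- doc_id
            e$sent_id <- sent_counter
            e$chunk_id <- 0L
            e$start <- e$start + base
            e$end <- e$end + base
            ents[[length(ents) + 1L]] <- e
          }
          sent_counter <- sent_counter + 1L
        }
        if (!is.null(st$relations) && nrow(st$relations) > 0) {
          r <- st$relations
          r$doc_id <- doc_id
          rels[[length(rels) + 1L]] <- r
        }
      }
      docs[[d]] <- tibble::tibble(doc_id = doc_id, text = text)
    }
    entities <- dplyr::bind_rows(c(list(tibble::tibble(
      doc_id = character(0), sent_id = integer(0), chunk_id = integer(0),
      type = character(0), concept = character(0), side = character(0),
      certainty = character(0), start = integer(0), end = integer(0),
      text = character(0))), ents))
    entities <- entities[c("doc_id", "sent_id", "chunk_id", "type",
                           "concept", "side", "certainty", "start", "end",
                           "text")]
    relations <- dplyr::bind_rows(c(list(tibble::tibble(
      doc_id = character(0), fm_category = character(0),
      fm_side = character(0), target_kind = character(0),
      target = character(0), certainty = character(0),
      provenance = character(0))), rels))
    relations <- relations[c("doc_id", "fm_category", "fm_side",
                             "target_kind", "target", "certainty",
                             "provenance")]
    rkey <- do.call(paste, c(relations[c("doc_id", "fm_category", "fm_side",
                                         "target_kind", "target",
                                         "certainty")], sep = "\r"))
    relations <- relations[!duplicated(rkey), , drop = FALSE]
    relations$target_text <- relations$target
    relations$target_cui <- ifelse(is_cui(relations$target),
                                   relations$target, NA_character_)
    structure(list(documents = dplyr::bind_rows(docs), entities = entities,
                   relations = relations, lexicon = lexicon,
                   config = config),
              class = "fh_corpus")
  })
}

#' @export
print.fh_corpus <- function(x, ...) {
  cat(sprintf("<fh_corpus> %d documents, %d gold entities, %d gold relations, %d lexicon entries\n",
              nrow(x$documents), nrow(x$entities), nrow(x$relations),
              nrow(x$lexicon)))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' One `.txt` per note plus `gold_entities.tsv`, `gold_relations.tsv` and
#' `mini_lexicon.tsv`.
#'
#' @param corpus An `fh_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus$documents))) {
    con <- file(file.path(dir, paste0(corpus$documents$doc_id[i], ".txt")),
                open = "wb")
    writeLines(enc2utf8(corpus$documents$text[i]), con, sep = "\n",
               useBytes = TRUE)
    close(con)
  }
  write_gold_entities(corpus$entities, file.path(dir, "gold_entities.tsv"))
  write_gold_relations(corpus$relations,
                       file.path(dir, "gold_relations.tsv"))
  write_lexicon(corpus$lexicon, file.path(dir, "mini_lexicon.tsv"))
  invisible(dir)
}
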