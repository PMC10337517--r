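# Shared fixtures and independent oracles for the test suite.

# small hand-written lexicon used across unit tests
tiny_lexicon <- function() {
  fh_lexicon(data.frame(
    variant = c("diabetes", "diabetes mellitus", "cancer", "colon cancer",
                "asthma", "hypertension", "stroke"),
    cui = c("C0011854", "C0011854", "C0006826", "C0007102", "C0004096",
            "C0020538", "C0038454"),
    snomed_code = c("73211009", "73211009", "363346000", "363406005",
                    "195967001", "38341003", ""),
    preferred_term = c("Diabetes mellitus", "Diabetes mellitus",
                       "Malignant neoplastic disease",
                       "Malignant tumor of colon", "Asthma",
                       "Hypertensive disease", "Cerebrovascular accident"),
    semantic_type = c("T047", "T047", "T191", "T191", "T047", "T047",
                      "T047")))
}

# random but valid lexicon for round-trip property tests
random_lexicon <- function(n, seed) {
  withr::with_seed(seed, {
    word <- function() {
      paste(sample(letters, sample(3:8, 1), replace = TRUE), collapse = "")
    }
    variants <- vapply(seq_len(n), function(i) {
      paste(replicate(sample(1:3, 1), word()), collapse = " ")
    }, "")
    fh_lexicon(data.frame(
      variant = variants,
      cui = sprintf("C%07d", sample.int(max(2, n %/% 2), n, replace = TRUE)),
      snomed_code = ifelse(stats::runif(n) < 0.5,
                           as.character(sample.int(99999999, n)), ""),
      preferred_term = vapply(seq_len(n), function(i) word(), ""),
      semantic_type = sample(fh_eligible_types(), n, replace = TRUE)))
  })
}

# Independent oracle for dictionary matching: enumerate every token-aligned
# substring, keep lexicon hits, then apply leftmost-longest selection.
oracle_match_observations <- function(text, lexicon) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  empty <- data.frame(start = integer(0), end = integer(0),
                      variant = character(0))
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  vars <- unique(lexicon$variant)
  hits <- list()
  for (i in seq_along(starts)) {
    for (j in seq(i, length(starts))) {
      key <- tolower(gsub("\\s+", " ",
                          trimws(substring(text, starts[i] + 1, ends[j]))))
      if (key %in% vars) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = starts[i], end = ends[j], variant = key)
      }
    }
  }
  if (length(hits) == 0) return(empty)
  hits <- do.call(rbind, hits)
  chosen <- empty
  while (nrow(hits) > 0) {
    hits <- hits[order(hits$start, -(hits$end - hits$start)), , drop = FALSE]
    pick <- hits[1, , drop = FALSE]
    chosen <- rbind(chosen, pick)
    keep <- !(hits$start < pick$end & pick$start < hits$end)
    hits <- hits[keep, , drop = FALSE]
  }
  chosen[order(chosen$start), , drop = FALSE]
}

# random sentences mixing lexicon variants with filler words
random_sentence <- function(lexicon, max_tokens = 10) {
  fillers <- c("the", "patient", "has", "reports", "with", "history",
               "of", "and", "mild", "chronicle", "cancerous", "diabetic")
  pieces <- character(0)
  n <- sample.int(max_tokens, 1)
  while (sum(n_tok_helper(pieces)) < n) {
    pieces <- c(pieces, if (stats::runif(1) < 0.4) {
      sample(lexicon$variant, 1)
    } else {
      sample(fillers, 1)
    })
  }
  paste0(paste(pieces, collapse = " "), ".")
}

n_tok_helper <- function(x) {
  if (length(x) == 0) return(0L)
  lengths(regmatches(x, gregexpr("[A-Za-z0-9]+", x)))
}

# Independent oracle for scorers: exhaustive maximum bipartite matching by
# branch-and-bound over gold items.
oracle_max_matching <- function(adj, n_pred) {
  rec <- function(g, used) {
    if (g > length(adj)) return(0L)
    best <- rec(g + 1L, used)
    for (p in adj[[g]]) {
      if (!used[p]) {
        used[p] <- TRUE
        best <- max(best, 1L + rec(g + 1L, used))
        used[p] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, n_pred))
}

# random entity sets (one document) for scorer-equivalence tests
random_entity_sets <- function(seed) {
  withr::with_seed(seed, {
    mk <- function(n) {
      type <- sample(c("FamilyMember", "Observation"), n, replace = TRUE)
      start <- sample.int(40, n, replace = TRUE)
      tibble::tibble(
        doc_id = "d1", type = type,
        concept = ifelse(type == "FamilyMember",
                         sample(c("Mother", "Father", "Aunt"), n,
                                replace = TRUE),
                         sprintf("C00000%02d", sample.int(4, n,
                                                          replace = TRUE))),
        side = ifelse(type == "FamilyMember",
                      sample(c("NA", "Maternal"), n, replace = TRUE),
                      NA_character_),
        certainty = "nonnegated",
        start = start, end = start + sample.int(8, n, replace = TRUE),
        text = "")
    }
    list(gold = mk(sample.int(8, 1)), pred = mk(sample.int(8, 1)))
  })
}

entity_adjacency <- function(gold, pred, match_mode = "partial") {
  lapply(seq_len(nrow(gold)), function(i) {
    which(vapply(seq_len(nrow(pred)), function(j) {
      fhlex:::entity_pair_matches(gold[i, ], pred[j, ], match_mode)
    }, logical(1)))
  })
}

# reference lexicon WITHOUT run-together typo variants, so typos the noisy
# adapter injects stay unnormalized and route to curation
builder_reference <- function() {
  fh_lexicon(data.frame(
    variant = c("type 2 diabetes", "colon cancer", "asthma",
                "allergic asthma", "hypertension"),
    cui = c("C0011860", "C0007102", "C0004096", "C0155877", "C0020538"),
    snomed_code = c("44054006", "363406005", "195967001", "389145006",
                    "38341003"),
    preferred_term = c("Type 2 diabetes mellitus", "Malignant tumor of colon",
                       "Asthma", "Allergic asthma", "Hypertensive disease"),
    semantic_type = c("T047", "T191", "T047", "T047", "T047")))
}

builder_corpus <- function(n_patients = 25) {
  tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n_patients)),
    text = paste("Family history of type 2 diabetes and asthma.",
                 "Mother had colon cancer."))
}

# all-of-one-construct generator configs used in boundary tests
only_rate <- function(which, n_documents, seed) {
  rates <- list(rate_negation = 0, rate_cross_sentence = 0, rate_spouse = 0,
                rate_obs_list = 0, rate_living_status = 0, rate_age = 0)
  rates[[which]] <- 1
  do.call(fh_generation_config,
          c(list(n_documents = n_documents, seed = seed), rates))
}
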