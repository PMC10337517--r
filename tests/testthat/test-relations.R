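# relation linking: clause co-occurrence, cross-sentence coreference,
# spouse exclusion, chain assembly

targets_of <- function(text, lex = tiny_lexicon(), sent_id = 0L,
                       offset = 0L) {
  obs <- match_observations(text, lex, offset = offset, sent_id = sent_id)
  liv <- extract_living_status(text, offset = offset, sent_id = sent_id)
  dplyr::bind_rows(
    if (nrow(obs) > 0) tibble::tibble(
      sent_id = obs$sent_id, start = obs$start, end = obs$end,
      target_kind = "observation", target_text = obs$text,
      target_cui = obs$cui, certainty = obs$certainty),
    if (nrow(liv) > 0) tibble::tibble(
      sent_id = liv$sent_id, start = liv$start, end = liv$end,
      target_kind = "living_status", target_text = liv$status,
      target_cui = NA_character_, certainty = liv$certainty))
}

test_that("same-clause linking pairs every family member with every target", {
  tx <- "Her mother has diabetes."
  fms <- recognize_family_members(tx)
  rel <- link_within_clause(list(start = 0L, end = nchar(tx)), fms,
                            targets_of(tx))
  expect_equal(nrow(rel), 1)
  expect_equal(rel$fm_category, "Mother")
  expect_equal(rel$target_cui, "C0011854")
  expect_equal(rel$certainty, "nonnegated")
  expect_equal(rel$provenance, "same_clause")

  # observation list: two relations for one family member
  tx2 <- "Mother has diabetes and hypertension."
  rel2 <- link_within_clause(list(start = 0L, end = nchar(tx2)),
                             recognize_family_members(tx2), targets_of(tx2))
  expect_equal(nrow(rel2), 2)
  expect_setequal(rel2$target_cui, c("C0011854", "C0020538"))

  # target with no family member: nothing from this operation
  tx3 <- "History of diabetes."
  rel3 <- link_within_clause(list(start = 0L, end = nchar(tx3)),
                             recognize_family_members(tx3), targets_of(tx3))
  expect_equal(nrow(rel3), 0)
})

test_that("cross-sentence linking needs a cue and respects the window", {
  ex <- fh_extract("Father is deceased. He had colon cancer.",
                   tiny_lexicon())
  expect_setequal(ex$relations$target_text, c("Dead", "colon cancer"))
  expect_equal(ex$relations$fm_category, c("Father", "Father"))
  expect_equal(
    ex$relations$provenance[ex$relations$target_kind == "observation"],
    "coreference")

  # no cue in the observation sentence: no cross-sentence relation
  ex2 <- fh_extract("Father is deceased. There was colon cancer.",
                    tiny_lexicon())
  expect_equal(nrow(ex2$relations[ex2$relations$target_kind ==
                                    "observation", ]), 0)

  # family member three sentences back is outside the window
  fms <- recognize_family_members("Father")
  fms$sent_id <- 0L
  tgt <- tibble::tibble(sent_id = 3L, start = 0L, end = 6L,
                        target_kind = "observation", target_text = "cancer",
                        target_cui = "C0006826", certainty = "nonnegated")
  cues <- tibble::tibble(sent_id = 3L, cue = "he")
  expect_equal(nrow(link_cross_sentence(fms, tgt, cues)), 0)
  # distance 2 is the boundary: still linked
  tgt$sent_id <- 2L
  cues$sent_id <- 2L
  expect_equal(nrow(link_cross_sentence(fms, tgt, cues)), 1)
})

test_that("nearest preceding family member wins; none-of-them links all", {
  fms <- dplyr::bind_rows(
    recognize_family_members("Father", sent_id = 0L),
    recognize_family_members("Mother", sent_id = 1L))
  tgt <- tibble::tibble(sent_id = 2L, start = 0L, end = 6L,
                        target_kind = "observation", target_text = "cancer",
                        target_cui = "C0006826", certainty = "nonnegated")
  rel <- link_cross_sentence(fms, tgt,
                             tibble::tibble(sent_id = 2L, cue = "she"))
  expect_equal(rel$fm_category, "Mother")   # nearest

  rel2 <- link_cross_sentence(
    fms, tgt, tibble::tibble(sent_id = 2L, cue = "none of them"))
  expect_setequal(rel2$fm_category, c("Father", "Mother"))
  expect_true(all(rel2$certainty == "negated"))
})

test_that("spouse relations are excluded end to end", {
  ex <- fh_extract("Her husband has diabetes.", tiny_lexicon())
  expect_equal(nrow(ex$relations), 0)
  # the observation entity itself is still recorded
  expect_true("Observation" %in% ex$entities$type)
  expect_false("FamilyMember" %in% ex$entities$type)

  # mixed clause: only the blood relative is linked
  ex2 <- fh_extract("Her husband and her mother have diabetes.",
                    tiny_lexicon())
  expect_equal(ex2$relations$fm_category, "Mother")
  expect_equal(nrow(ex2$relations), 1)

  # a spouse in the preceding context never receives cross-sentence links
  ex3 <- fh_extract("Her husband is deceased. He had colon cancer.",
                    tiny_lexicon())
  expect_equal(nrow(ex3$relations), 0)

  # exclude_spouse is the identity on spouse-free relation sets
  rel <- ex2$relations
  expect_equal(exclude_spouse(rel), rel)
})

test_that("a clause-level family member blocks cross-sentence rescue", {
  # "her" cue present, but diabetes is already claimed by its own clause
  ex <- fh_extract("Father is deceased. Her mother has diabetes.",
                   tiny_lexicon())
  obs_rel <- ex$relations[ex$relations$target_kind == "observation", ]
  expect_equal(obs_rel$fm_category, "Mother")
  # a same-clause spouse also blocks it (the cue refers to the patient)
  ex2 <- fh_extract("Mother has asthma. Her husband has diabetes.",
                    tiny_lexicon())
  expect_false("C0011854" %in% ex2$relations$target_cui)
})

test_that("chains group by category and side and deduplicate targets", {
  rel <- dplyr::bind_rows(
    tibble::tibble(doc_id = "d", fm_category = "Mother", fm_side = "NA",
                   fm_is_spouse = FALSE, target_kind = "observation",
                   target_text = "diabetes", target_cui = "C0011854",
                   certainty = "nonnegated", provenance = "same_clause",
                   fm_sent_id = 0L, target_sent_id = 0L),
    tibble::tibble(doc_id = "d", fm_category = "Mother", fm_side = "NA",
                   fm_is_spouse = FALSE, target_kind = "observation",
                   target_text = "diabetes", target_cui = "C0011854",
                   certainty = "nonnegated", provenance = "coreference",
                   fm_sent_id = 0L, target_sent_id = 1L),
    tibble::tibble(doc_id = "d", fm_category = "Mother", fm_side = "NA",
                   fm_is_spouse = FALSE, target_kind = "living_status",
                   target_text = "Dead", target_cui = NA_character_,
                   certainty = "nonnegated", provenance = "same_clause",
                   fm_sent_id = 0L, target_sent_id = 0L),
    tibble::tibble(doc_id = "d", fm_category = "Grandmother",
                   fm_side = "Maternal", fm_is_spouse = FALSE,
                   target_kind = "observation", target_text = "asthma",
                   target_cui = "C0004096", certainty = "nonnegated",
                   provenance = "same_clause", fm_sent_id = 2L,
                   target_sent_id = 2L),
    tibble::tibble(doc_id = "d", fm_category = "Grandmother",
                   fm_side = "Paternal", fm_is_spouse = FALSE,
                   target_kind = "observation", target_text = "asthma",
                   target_cui = "C0004096", certainty = "nonnegated",
                   provenance = "same_clause", fm_sent_id = 3L,
                   target_sent_id = 3L))
  ch <- assemble_chains(rel, doc_id = "d")
  expect_equal(nrow(ch), 3)     # Mother, Grandmother x2 sides
  mother <- ch[ch$fm_category == "Mother", ]
  expect_equal(nrow(mother$targets[[1]]), 2)   # duplicate merged
  expect_equal(mother$targets[[1]]$provenance[1], "same_clause")

  # conservation: total chain targets equal deduplicated relations
  key <- paste(rel$fm_category, rel$fm_side, rel$target_kind,
               ifelse(is.na(rel$target_cui), rel$target_text,
                      rel$target_cui), rel$certainty)
  expect_equal(sum(vapply(ch$targets, nrow, 0L)), length(unique(key)))
})

test_that("relation invariants hold over random synthetic corpora", {
  for (seed in c(21, 22, 23)) {
    corp <- generate_corpus(fh_generation_config(n_documents = 8,
                                                 seed = seed))
    ex <- fh_extract_corpus(corp, corp$lexicon)
    expect_true(all(!ex$relations$fm_is_spouse))
    dist <- abs(ex$relations$target_sent_id - ex$relations$fm_sent_id)
    expect_true(all(dist <= 2))
    expect_true(all(dist[ex$relations$provenance == "same_clause"] == 0))
  }
})
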