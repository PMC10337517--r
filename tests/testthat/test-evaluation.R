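# challenge-style scoring and lexicon-coverage evaluation

test_that("score_report computes the standard formulas and degenerate cases", {
  r <- score_report(2, 1, 1)
  expect_equal(r$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(r$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(r$f1, 2 / 3, tolerance = 1e-12)
  r0 <- score_report(0, 0, 3)
  expect_equal(r0$precision, 0)
  expect_equal(r0$recall, 0)
  expect_equal(r0$f1, 0)
})

test_that("identical entity sets score perfectly; empty predictions score zero", {
  corp <- generate_corpus(fh_generation_config(n_documents = 5, seed = 12))
  g <- corp$entities
  s <- score_entities(g, g)
  expect_equal(s$micro$precision, 1)
  expect_equal(s$micro$recall, 1)
  expect_equal(s$micro$f1, 1)
  s0 <- score_entities(g, g[0, ])
  expect_equal(s0$micro$precision, 0)
  expect_equal(s0$micro$recall, 0)
})

test_that("family-member matches require category AND side", {
  g <- tibble::tibble(doc_id = "d", type = "FamilyMember",
                      concept = "Grandmother", side = "Maternal",
                      certainty = "nonnegated", start = 0L, end = 10L,
                      text = "")
  p_side <- g; p_side$side <- "Paternal"
  expect_equal(score_entities(g, p_side)$micro$tp, 0)
  p_ok <- g; p_ok$start <- 50L; p_ok$end <- 60L   # span ignored for FM
  expect_equal(score_entities(g, p_ok)$micro$tp, 1)
})

test_that("observation matching honors partial vs exact span modes", {
  g <- tibble::tibble(doc_id = "d", type = "Observation",
                      concept = "C0011854", side = NA, certainty = "nonnegated",
                      start = 10L, end = 25L, text = "")
  p <- g; p$start <- 20L; p$end <- 30L           # overlapping span
  expect_equal(score_entities(g, p, "partial")$micro$tp, 1)
  expect_equal(score_entities(g, p, "exact")$micro$tp, 0)
  p2 <- g; p2$start <- 30L; p2$end <- 40L        # disjoint span
  expect_equal(score_entities(g, p2, "partial")$micro$tp, 0)
  # spans unavailable: falls back to CUI equality
  g3 <- g; g3$start <- NA_integer_
  expect_equal(score_entities(g3, p2, "partial")$micro$tp, 1)
})

test_that("entity scorer equals exhaustive bipartite matching on random sets", {
  for (seed in 5000 + 1:120) {
    sets <- random_entity_sets(seed)
    s <- suppressWarnings(score_entities(sets$gold, sets$pred))
    adj <- entity_adjacency(sets$gold, sets$pred)
    expect_equal(s$micro$tp, oracle_max_matching(adj, nrow(sets$pred)),
                 info = seed)
  }
})

test_that("relation scoring handles certainty per the task convention", {
  corp <- generate_corpus(fh_generation_config(n_documents = 6, seed = 31))
  g <- corp$relations
  expect_equal(score_relations(g, g)$f1, 1)
  # flip one certainty: fp+fn under the certainty-aware convention only
  p <- g
  flip <- which(p$certainty == "nonnegated")[1]
  p$certainty[flip] <- "negated"
  s_with <- score_relations(g, p, with_certainty = TRUE)
  s_without <- score_relations(g, p, with_certainty = FALSE)
  expect_equal(s_with$tp, nrow(unique(g[c("doc_id", "fm_category", "fm_side",
                                          "target_kind", "target",
                                          "certainty")])) - 1)
  expect_equal(s_with$fp, 1)
  expect_equal(s_with$fn, 1)
  expect_equal(s_without$f1, 1)
})

test_that("adding predictions moves precision and recall monotonically", {
  corp <- generate_corpus(fh_generation_config(n_documents = 6, seed = 41))
  g <- corp$relations
  half <- g[seq_len(nrow(g) %/% 2), ]
  base <- score_relations(g, half)
  # adding a correct prediction never lowers recall
  more <- g[seq_len(nrow(g) %/% 2 + 1), ]
  expect_gte(score_relations(g, more)$recall, base$recall)
  # adding a spurious prediction never raises precision
  spurious <- dplyr::bind_rows(half, tibble::tibble(
    doc_id = g$doc_id[1], fm_category = "Cousin", fm_side = "NA",
    target_kind = "observation", target = "C9999999",
    certainty = "nonnegated", provenance = "same_clause",
    target_text = "C9999999", target_cui = "C9999999"))
  expect_lte(score_relations(g, spurious)$precision, base$precision)
})

test_that("coverage recall formulas reproduce the worked counts", {
  cov <- coverage_report(137, 16, 128, 10, 6)
  expect_equal(round(100 * cov$variant_recall, 1), 89.5)
  expect_equal(round(100 * cov$concept_recall, 1), 95.8)
  cov2 <- coverage_report(507, 62, 214, 26, 33)
  expect_equal(round(100 * cov2$variant_recall, 1), 89.1)
  expect_equal(round(100 * cov2$concept_recall, 1), 87.9)
})

test_that("coverage evaluation splits misses by concept availability", {
  lex <- tiny_lexicon()
  gold <- tibble::tibble(
    text = c("diabetes", "colon cancer", "brain tumor", "copd"),
    concept = c("C0011854", "C0007102", "C0006826", "C0024117"))
  cov <- coverage(gold, lex)
  expect_equal(cov$tp_entities, 2)
  expect_equal(cov$fn_entities, 2)
  # "brain tumor" misses but its concept is in the lexicon via "cancer"
  expect_equal(cov$fn_concepts_present, 1)
  expect_equal(cov$fn_concepts_missing, 1)
  expect_equal(cov$variant_recall, 0.5)
  expect_equal(cov$concept_recall, 3 / 4)
  # empty lexicon: both recalls zero
  cov0 <- coverage(gold, fh_lexicon())
  expect_equal(cov0$variant_recall, 0)
  expect_equal(cov0$concept_recall, 0)
})

test_that("gold files round trip through their TSV formats", {
  corp <- generate_corpus(fh_generation_config(n_documents = 4, seed = 17))
  d <- withr::local_tempdir()
  fe <- file.path(d, "ents.tsv")
  fr <- file.path(d, "rels.tsv")
  write_gold_entities(corp$entities, fe)
  write_gold_relations(corp$relations, fr)
  ents <- read_gold_entities(fe)
  expect_equal(nrow(ents), nrow(corp$entities))
  expect_equal(ents$concept, corp$entities$concept)
  rels <- read_gold_relations(fr)
  expect_equal(nrow(rels), nrow(corp$relations))
  expect_equal(score_relations(corp$relations, rels)$f1, 1)
})
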