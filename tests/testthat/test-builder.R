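# lexicon construction pipeline: adapters, screening, curation, enrichment

test_that("mention collection aggregates frequency and patient counts", {
  ref <- builder_reference()
  src <- fh_mention_source(ref)
  corpus <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3"),
    text = c("asthma noted", "asthma again and asthma", "asthma", "no match"))
  m <- collect_mentions(src, corpus)
  expect_equal(m$text, "asthma")
  expect_equal(m$frequency, 4L)      # 1 + 2 + 1 occurrences
  expect_equal(m$n_patients, 2L)     # p1 and p2; p3 has no hit
  expect_true(all(m$n_patients <= m$frequency))

  expect_equal(nrow(collect_mentions(src, corpus[0, ])), 0)

  # case variants merge under the normalized text
  m2 <- collect_mentions(src, tibble::tibble(
    patient_id = c("p1", "p2"), text = c("ASTHMA", "Asthma")))
  expect_equal(nrow(m2), 1)

  # adapter failure on a segment: skipped with a warning
  bad <- function(text) if (grepl("boom", text)) stop("x") else src(text)
  expect_warning(
    m3 <- collect_mentions(bad, tibble::tibble(
      patient_id = c("p1", "p2"), text = c("asthma", "boom"))),
    "failed")
  expect_equal(m3$n_patients, 1L)
})

test_that("normalization is idempotent and preserves candidate order", {
  norm <- fh_dict_normalizer(builder_reference())
  mentions <- tibble::tibble(text = c("asthma", "unseen phrase"))
  r1 <- normalize_mentions(norm, mentions)
  r2 <- normalize_mentions(norm, mentions)
  expect_identical(r1, r2)
  expect_equal(r1$cui[r1$mention == "asthma"], "C0004096")
  expect_true(is.na(r1$cui[r1$mention == "unseen phrase"]))
})

test_that("semantic screening drops ineligible candidates and flags orphans", {
  # the classic two-candidate case: eligible concept kept, patch-test
  # substance (non-disorder semantic type) removed
  norm <- fh_dict_normalizer(data.frame(
    variant = c("allergy-induced asthma", "allergy-induced asthma",
                "patch test"),
    cui = c("C0155877", "C0440102", "C0440102"),
    preferred_term = c("Allergic asthma", "Various patch test substance",
                       "Various patch test substance"),
    semantic_type = c("T047", "T167", "T167")))
  res <- normalize_mentions(norm, tibble::tibble(
    text = c("allergy-induced asthma", "patch test")))
  expect_setequal(res$cui[res$mention == "allergy-induced asthma"],
                  c("C0155877", "C0440102"))
  scr <- screen_semantic_types(res)
  expect_equal(scr$cui[scr$mention == "allergy-induced asthma"], "C0155877")
  # a mention whose candidates are all ineligible becomes an NA row
  expect_true(is.na(scr$cui[scr$mention == "patch test"]))
  expect_false(any(stats::na.omit(scr$semantic_type) %in% "T167"))
  # identity when everything is eligible
  ok <- res[res$cui %in% "C0155877" & !is.na(res$cui), ]
  expect_equal(screen_semantic_types(ok), ok)
})

test_that("curation queue applies the distinct-patient threshold", {
  mentions <- tibble::tibble(text = c("typediabetes", "rare thing"),
                             frequency = c(3693L, 19L),
                             n_patients = c(25L, 19L))
  results <- tibble::tibble(mention = mentions$text, cui = NA_character_,
                            preferred_term = NA_character_,
                            semantic_type = NA_character_,
                            source = NA_character_)
  q <- build_curation_queue(results, mentions, min_patients = 20)
  expect_equal(q$mention, "typediabetes")
  expect_equal(q$status, "pending")
  # threshold 1 queues every unnormalized mention
  q1 <- build_curation_queue(results, mentions, min_patients = 1)
  expect_setequal(q1$mention, c("typediabetes", "rare thing"))
  # boundary: exactly at the threshold is included
  q20 <- build_curation_queue(results,
                              within(mentions, n_patients[2] <- 20L),
                              min_patients = 20)
  expect_equal(nrow(q20), 2)

  dec <- data.frame(mention = "typediabetes", cui = "C0011854",
                    status = "mapped")
  qd <- apply_curation(q, dec)
  expect_equal(qd$status, "mapped")
  expect_equal(qd$cui, "C0011854")
})

test_that("variant enrichment adds variants but never new concepts", {
  lex <- fh_lexicon(data.frame(variant = "diabetes", cui = "C0011854",
                               snomed_code = "", preferred_term = "Diabetes",
                               semantic_type = "T047"))
  src <- fh_lexicon(data.frame(
    variant = c("diabetes mellitus", "asthma"),
    cui = c("C0011854", "C0004096"), snomed_code = "",
    preferred_term = c("Diabetes", "Asthma"), semantic_type = "T047"))
  out <- enrich_variants(lex, src)
  expect_setequal(out$variant, c("diabetes", "diabetes mellitus"))
  # set algebra: result CUIs = lexicon CUIs; variants = union restricted
  # to those CUIs
  expect_setequal(unique(out$cui), unique(lex$cui))
  expect_setequal(out$variant,
                  union(lex$variant, src$variant[src$cui %in% lex$cui]))
  expect_equal(enrich_variants(lex, fh_lexicon()), lex)
})

test_that("builder report reproduces the percent arithmetic", {
  expect_equal(builder_report(72518, 47250)$pct_auto, 65.16)
  expect_equal(builder_report(10, 0)$pct_auto, 0)
  expect_equal(builder_report(10, 10)$pct_auto, 100)
  expect_equal(builder_report(0, 0)$pct_auto, 0)
})

test_that("the full pipeline routes typos to curation and replays decisions", {
  ref <- builder_reference()
  corpus <- builder_corpus(25)
  decisions <- data.frame(
    mention = c("typediabetes", "coloncancer"),
    cui = c("C0011860", "C0007102"),
    status = c("mapped", "mapped"))
  b <- build_fh_lexicon(
    corpus,
    mention_source = fh_noisy_mention_source(ref, typo_rate = 1),
    normalizer = fh_dict_normalizer(ref),
    concepts = ref[c("cui", "preferred_term", "semantic_type",
                     "snomed_code")],
    min_patients = 20, decisions = decisions)

  # planted run-together typos reached the queue (>= 20 patients each)
  expect_true(all(c("typediabetes", "coloncancer") %in% b$queue$mention))
  expect_true(all(b$queue$n_patients[b$queue$mention == "typediabetes"] >= 20))
  # after replaying decisions their CUIs are in the final lexicon
  expect_true("typediabetes" %in% b$lexicon$variant)
  expect_equal(b$lexicon$cui[b$lexicon$variant == "typediabetes"],
               "C0011860")
  expect_equal(
    b$provenance$provenance[b$provenance$variant == "typediabetes"],
    "curated")
  # every auto entry traces to an eligible candidate
  expect_true(all(b$lexicon$semantic_type %in% fh_eligible_types()))
  expect_equal(b$report$n_curated, 2)
  expect_gt(b$report$pct_auto, 0)
})

test_that("pipeline provenance covers every final entry", {
  ref <- builder_reference()
  b <- build_fh_lexicon(
    builder_corpus(10),
    mention_source = fh_mention_source(ref),
    normalizer = fh_dict_normalizer(ref),
    concepts = ref[c("cui", "preferred_term", "semantic_type",
                     "snomed_code")],
    min_patients = 5,
    variant_source = fh_lexicon(data.frame(
      variant = "adult onset diabetes", cui = "C0011860",
      snomed_code = "44054006", preferred_term = "Type 2 diabetes mellitus",
      semantic_type = "T047")))
  key <- function(df) paste(df$variant, df$cui)
  expect_setequal(key(b$lexicon), key(b$provenance))
  expect_true(all(b$provenance$provenance %in%
                    c("auto", "curated", "enriched")))
  expect_equal(
    b$provenance$provenance[b$provenance$variant == "adult onset diabetes"],
    "enriched")
})
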