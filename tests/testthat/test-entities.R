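# observation matching, family members, certainty, living status, age

test_that("dictionary matching is leftmost-longest with token boundaries", {
  lex <- tiny_lexicon()
  m <- match_observations("Her mother has diabetes.", lex)
  expect_equal(nrow(m), 1)
  expect_equal(m$cui, "C0011854")
  expect_equal(m$text, "diabetes")

  # longest match wins over its substrings
  m2 <- match_observations("History of colon cancer here.", lex)
  expect_equal(m2$text, "colon cancer")
  expect_equal(m2$cui, "C0007102")

  # token boundary: no match inside a longer word
  expect_equal(nrow(match_observations("cancerous growth discussion", lex)),
               0)

  # case and internal whitespace are normalized away
  m3 <- match_observations("DIABETES  MELLITUS noted", lex)
  expect_equal(m3$text, "DIABETES  MELLITUS")
})

test_that("ambiguous variants report all CUIs with a deterministic primary", {
  lex <- fh_lexicon(data.frame(
    variant = c("ms", "ms"), cui = c("C0026769", "C0026691"),
    snomed_code = "", preferred_term = "x", semantic_type = "T047"))
  m <- match_observations("History of MS.", lex)
  expect_equal(m$cui, "C0026691")          # lexicographically first
  expect_equal(m$alt_cuis, "C0026769")
})

test_that("matching equals the exhaustive-substring oracle on random text", {
  lex <- tiny_lexicon()
  withr::with_seed(4242, {
    for (i in 1:300) {
      tx <- random_sentence(lex)
      got <- match_observations(tx, lex)
      want <- oracle_match_observations(tx, lex)
      expect_equal(got$start, want$start, info = tx)
      expect_equal(got$end, want$end, info = tx)
    }
  })
})

test_that("family-member recognition maps categories, sides and degrees", {
  r <- recognize_family_members("mother")
  expect_equal(r$category, "Mother")
  expect_equal(r$side, "NA")
  expect_equal(r$degree, 1L)

  r2 <- recognize_family_members("maternal grandmother")
  expect_equal(r2$category, "Grandmother")
  expect_equal(r2$side, "Maternal")
  expect_equal(r2$degree, 2L)
  expect_equal(r2$text, "maternal grandmother")

  # spouse terms are flagged and carry no category
  r3 <- recognize_family_members("husband")
  expect_true(r3$is_spouse)
  expect_true(is.na(r3$category))
  expect_true(is.na(r3$degree))

  # possessive compounds fold into the aggregated relative
  r4 <- recognize_family_members("Her mother's brother had cancer.")
  expect_equal(r4$category, "Uncle")
  expect_equal(r4$side, "Maternal")

  # in-law compounds beat their head-word triggers
  r5 <- recognize_family_members("mother-in-law")
  expect_true(r5$is_spouse)
  expect_equal(nrow(r5), 1)

  expect_equal(recognize_family_members("half brother")$category, "Sibling")
  expect_equal(recognize_family_members("cousins")$degree, 3L)
})

test_that("family-member matching ignores case and punctuation context", {
  withr::with_seed(31, {
    forms <- c("MOTHER", "Mother", "mother", "(mother)", "mother,",
               "mother.")
    for (f in forms) {
      r <- recognize_family_members(paste("Note:", f, "has asthma"))
      expect_equal(r$category, "Mother", info = f)
    }
  })
})

test_that("niece/nephew handling is switchable", {
  expect_equal(nrow(recognize_family_members("Her niece has asthma.")), 0)
  r <- recognize_family_members("Her niece has asthma.", extended = "map")
  expect_equal(r$category, "Child")
})

test_that("degree is consistent with category across the rule table", {
  rules <- fh_fm_rules()
  blood <- rules[!rules$spouse & rules$category != "EXT", ]
  deg1 <- c("Mother", "Father", "Parent", "Brother", "Sister", "Son",
            "Daughter", "Child")
  expect_true(all(blood$degree[blood$category %in% deg1 &
                                 !grepl("half", blood$trigger)] == 1L))
  expect_true(all(blood$degree[blood$category %in% c("Aunt", "Uncle")] == 2L))
  expect_true(all(blood$degree[blood$category == "Cousin"] == 3L))
  expect_true(all(blood$degree[grepl("great", blood$trigger)] == 3L))
})

test_that("negation is clause-scoped with conjunction resets", {
  trig <- fh_negation_triggers()
  expect_equal(detect_certainty("No family history of cancer.", 21, trig),
               "negated")
  expect_equal(detect_certainty("Mother has diabetes.", 11, trig),
               "nonnegated")
  # "Denies cancer but has diabetes": reset after "but"
  cl <- "Denies cancer but has diabetes"
  expect_equal(detect_certainty(cl, 7, trig), "negated")      # cancer
  expect_equal(detect_certainty(cl, 22, trig), "nonnegated")  # diabetes
  # trigger after the mention does not negate
  expect_equal(detect_certainty("cancer was not found", 0, trig),
               "nonnegated")
})

test_that("certainty never reports negated without a trigger in scope", {
  safe <- c("mother", "has", "history", "notable", "for", "asthma",
            "known", "butter")   # "butter" != reset token "but"
  withr::with_seed(77, {
    for (i in 1:50) {
      cl <- paste(sample(safe, sample(3:7, 1), replace = TRUE),
                  collapse = " ")
      pos <- sample.int(nchar(cl), 1) - 1L
      expect_equal(detect_certainty(cl, pos), "nonnegated", info = cl)
    }
  })
})

test_that("living status follows the cue table", {
  d <- extract_living_status("Father is deceased.")
  expect_equal(d$status, "Dead")
  expect_equal(d$text, "deceased")

  a <- extract_living_status("Mother is alive and well.")
  expect_equal(a$status, "Alive")
  expect_true(a$healthy)

  expect_equal(nrow(extract_living_status("Mother has asthma.")), 0)
  expect_equal(extract_living_status("Status unknown.")$status, "Unknown")
  # dead cues take precedence within a sentence
  expect_equal(extract_living_status("She was well before she died.")$status,
               "Dead")
})

test_that("ages parse from the pattern set and reject non-ages", {
  a <- extract_age("died of MI at age 62")
  expect_equal(a$value, 62L)
  expect_equal(a$kind, "exact")
  expect_equal(a$text, "62")

  expect_equal(extract_age("in his 50s")$value, 50L)
  expect_equal(extract_age("in his 50s")$kind, "decade")
  expect_equal(extract_age("she is 45 years old")$value, 45L)
  expect_equal(extract_age("Mother, 62 y.o., has asthma")$value, 62L)
  expect_equal(extract_age("aged 80")$value, 80L)

  expect_equal(nrow(extract_age("Route 66 closed")), 0)
  expect_equal(nrow(extract_age("at age 400")), 0)   # outside [0, 130]
})
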