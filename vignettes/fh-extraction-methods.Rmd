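---
title: "Methods: the family-history lexicon and rule-based extractor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the family-history lexicon and rule-based extractor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhlex)
```

## The problem

A patient's family history (FH) — which blood relatives had which
conditions, whether they are alive, at what age they were affected — drives
risk assessment and decision support, but it is mostly recorded as free
text in the FAMILY HISTORY section of clinical notes. `fhlex` implements
the symbolic half of an FH information-extraction stack: a normalized FH
lexicon with a reproducible construction pipeline, a rule-based extractor
of FH entities and relations, challenge-style evaluation, and a synthetic
corpus generator so that everything is testable without access-restricted
clinical data.

## The lexicon model

The knowledge base is a flat dictionary of surface *variants*, each mapped
to a UMLS concept unique identifier (CUI, `C#######`), an optional
SNOMED-CT code, a preferred term, and a UMLS semantic type. Three modeling
commitments matter:

* **Semantic scope.** FH observations are restricted to eleven
  disorder/finding semantic types (T019, T020, T037, T047, T048, T049,
  T190, T191, T033, T046, T184). T050, experimental disease models, is
  excluded by construction: lab models are never family history. The
  in-memory container intentionally admits other types so that the builder
  can hold unscreened candidates; the lexicon *file* loader enforces
  eligibility.
* **Conservative normalization.** Variants are case-folded and
  whitespace-collapsed, nothing more. Raw EHR text contains informative
  typo variants (run-together forms such as "typediabetes"); stemming or
  spell-correction would destroy exactly the surface forms the lexicon
  exists to capture.
* **Ambiguity is data.** The same variant mapped to several CUIs is kept.
  The matcher reports all candidate CUIs and deterministically marks the
  lexicographically first as primary, so output is reproducible without
  pretending the ambiguity is resolved.

SNOMED-CT codes are license-restricted, so they travel as a separate
2-column CUI-to-code mapping file applied with `apply_snomed_mapping()`;
a distributed lexicon works without them.

## The construction pipeline

`build_fh_lexicon()` is organized around two adapter contracts precisely
because the two hard components — proposing candidate mentions in raw
text, and normalizing free-text problem descriptions to concepts — are
replaceable model components, not fixed algorithms:

* a **mention source** maps note text to candidate mention spans. The
  shipped reference adapter proposes dictionary hits of a reference
  lexicon; the shipped noisy adapter additionally emits deterministic
  run-together typo forms of multi-token hits, emulating EHR concatenation
  artifacts. A neural tagger can be dropped in as any function with the
  same signature.
* a **normalizer** maps a mention string to candidate
  (CUI, preferred term, semantic type) triples. The shipped adapter is an
  exact dictionary lookup; an external clinical-problem standardization
  service has the same contract.

Around the adapters the pipeline is fixed: aggregate mentions by
normalized text with occurrence and distinct-patient counts; normalize;
**screen** candidates against the eligible semantic types (a mention such
as "allergy-induced asthma" may normalize to both an eligible disorder
concept and an ineligible substance concept — only the former survives);
route mentions left without candidates to a **curation queue** when they
occurred across at least `min_patients = 20` distinct patients; replay a
human-editable decision TSV so the manual step is reproducible; and
optionally **enrich** variants from a second lexicon-shaped resource,
adding variants only for concepts already present. The threshold counts
*patients*, not raw frequency: a form repeated thousands of times by one
author is weaker evidence of sublanguage than one spread across twenty
patients. Every final entry carries provenance (`auto`, `curated`,
`enriched`).

## The extractor

Coordinates are fixed once for reproducibility: 0-based half-open
character spans, 0-based sentence and chunk ids.

1. **Sectioning.** The first `FAMILY HISTORY` / `FAMILY HX` / `FH` header
   (configurable) opens the section; the next all-caps `HEADER:` line or
   the end of the note closes it. Header-less input falls back to the
   whole document, flagged.
2. **Sentences.** Deterministic splitting at `.`, `!`, `?`, newline, with
   an abbreviation guard list (`Dr.`, `vs.`, `y.o.`, ...) and a
   digit-period-digit guard for decimals. Trimmed sentence spans tile the
   non-whitespace text exactly — a property the tests quantify.
3. **Clauses.** Semicolons always split; a comma or `and` splits only when
   a family-member mention follows the delimiter. This keeps observation
   lists ("Mother has diabetes and hypertension") in one clause while
   separating genuine conjoined clauses ("Mother has diabetes and father
   has asthma"). The clause is the co-occurrence unit; its spans partition
   the sentence.
4. **Entities.** Family members come from an editable trigger table with
   category, fixed side, degree of consanguinity, and spouse flag,
   refined by possessive compounds ("mother's brother" → Uncle, Maternal)
   and maternal/paternal modifiers. Observations come from
   case-insensitive, token-boundary, leftmost-longest dictionary matching
   (verified against an exhaustive-substring oracle). Living status and
   ages come from small cue/pattern tables. Certainty is a minimal
   NegEx-style rule: a trigger preceding the mention in the same clause
   negates it unless `but`/`however` intervenes.
5. **Relations.** Every non-spouse family member in a clause links to
   every observation/living-status target in the same clause. A target
   with *no* family member in its clause may link backward to the nearest
   preceding non-spouse family member within a three-sentence window —
   but only if its own sentence contains a coreference cue (he, she, his,
   her, they, them, "none of them"). The plural-negative cue "none of
   them" links to *all* window family members with certainty forced to
   negated, because the cue itself asserts a negative over a plurality.
   Spouse/in-law mentions are recorded but never yield relations.
6. **Chains.** Relations group into one chain per (category, side) per
   document, deduplicating targets and attaching same-clause ages.

### Design choices where the rules were genuinely open

* **Window semantics.** "Three adjacent sentences" is read as the cue
  sentence plus the two preceding ones (distance ≤ 2). The alternative
  reading (three sentences *between*) would make the cue list do work at
  ranges where pronoun anaphora is unreliable.
* **Backward only.** Cues license anaphora, not cataphora; the
  adversarial generator templates exist precisely to show the cataphora
  construct failing.
* **Claim blocking.** A target sharing a clause with *any* family member
  — including a spouse — is claimed by that clause and is not rescued
  cross-sentence. Without this, "Mother has asthma. Her husband has
  diabetes." would attach the husband's diabetes to Mother through the
  "her" cue, contradicting spouse exclusion.
* **Niece/nephew** fall outside the 15-category convention used by the FH
  challenges; they are dropped by default and can be mapped to `Child`
  (`extended = "map"`) as a nearest-generation approximation.
* **Clause definition.** No standard definition exists for "clause" in
  this setting; the semicolon/conditional-comma/conditional-`and` rule is
  a deliberate, documented decision and is configurable territory for
  tuning against real challenge data.

## Evaluation

`score_entities()` scores the entity task: family members match on
category *and* side; observations match under partial mode on ≥ 1
character of span overlap (CUI equality when spans are unavailable), or
exact spans under exact mode. Matching is a maximum bipartite matching per
document and type, so scores cannot depend on prediction order; the tests
verify equality with exhaustive matching. `score_relations()` scores the
relation task on (category, side, normalized target), optionally plus
certainty — the stricter 2019-style convention — after deduplication.
Degenerate denominators report 0 rather than NaN.

`coverage()` evaluates a lexicon against gold observation entities:
variant-level recall counts entities whose text token-overlaps some
variant; concept-level recall credits concepts reachable through the
lexicon, with misses split by whether the gold concept exists in the
lexicon under other variants. The concept-level bookkeeping counts
present-concept misses as distinct concepts and absent-concept misses per
entity, matching the convention of the published worked examples that the
acceptance script reproduces.

## The synthetic corpus

`generate_corpus()` emulates the constructs the rules target — and only
those, unless asked otherwise: single-clause statements, observation
lists, two-sentence coreference with gender-consistent pronouns
(mother → she, so the cue mechanism rather than gender resolution is under
test), negations (with and without a family member), spouse distractors,
living status, and age statements. Gold entities and relations are emitted
from the template semantics during assembly, making the corpus
self-annotating: the headline property is that the extractor scores
P = R = F1 = 1.0 on both tasks on such corpora, which the acceptance suite
checks on 200 documents.

Default construct mix (chosen once as a realistic FH-section profile):
negation 0.15, cross-sentence 0.20, spouse 0.10, observation list 0.15,
living status 0.10, age 0.10, remainder plain statements; 2–4 statements
per note; a 20-concept mini-lexicon with up to 4 variants per concept and
a 0.2 typo-variant rate. Family members and concepts are drawn without
replacement within a note so deduplicated gold stays unambiguous.

What passing does **not** show: real notes contain section noise,
abbreviation soup, list formatting, hedging, multi-layer relations and
annotation idiosyncrasies that the generator deliberately omits. The
`adversarial = TRUE` flag adds two uncovered constructs — cataphora and
distance-3 coreference — whose gold relations the rules are expected to
miss, so recall degrades below 1 on harder text by design, mirroring the
known limits of simple heuristic linking.

```{r adversarial}
adv <- generate_corpus(fh_generation_config(n_documents = 30, seed = 3,
                                            adversarial = TRUE))
ex <- fh_extract_corpus(adv, adv$lexicon)
score_relations(adv$relations, ex$relations)$recall
```

## Numerical and degenerate-input conventions

* Empty lexicon: statistics report 0 with an `empty` flag; matching
  returns no mentions; coverage recalls are 0.
* Empty prediction sets: precision reported as 0, not undefined.
* Tie-breaks are all deterministic: lexicographic primary CUI, nearest
  (then rightmost) family member for coreference, first deciding cue for
  living status, first-pattern-wins for overlapping age patterns.
* All generator and pipeline randomness flows through a single integer
  seed; fixed seed means byte-identical corpora and outputs.

## Problem sizes used by the test and acceptance suites

Oracle equivalence runs on 1,000 random sentences (matcher) and 500
random gold/prediction sets of up to 8 items (scorers); self-consistency
runs on a 200-document corpus; the boundary suite uses 100 small corpora.
These sizes make every property run comfortably on one CPU while keeping
the combinatorial oracles exact.

## Known limitations

* The extractor is a deliberately simple heuristic system: multi-layer
  relations, long-range coreference, hedged temporality and procedure
  mentions are out of scope, and the clause rule is a heuristic, not a
  parser.
* The shipped mini-lexicon is synthetic fixture content with the real
  schema; the full corpus-derived lexicon is distribution-restricted
  content that users drop in as a TSV.
* Coverage's partial match (token overlap ≥ 1 by default) is permissive;
  the threshold is a parameter, not a claim about the single right
  overlap criterion.
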