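# fhlex

Family-history (FH) information — which blood relatives had which
conditions, whether they are alive, and at what age they were affected —
shapes risk assessment and clinical decision support, yet it is mostly
buried in the free-text FAMILY HISTORY section of clinical notes. `fhlex`
is an R toolkit for clinical-NLP practitioners and EHR-based researchers
that provides:

- **An FH semantic lexicon model**: surface variants mapped to UMLS CUIs
  (`C#######`) and optional SNOMED-CT codes, restricted to eleven
  disorder/finding semantic types (T050, experimental disease models, is
  excluded), stored as a diff-able 5-column TSV. SNOMED codes travel as a
  separate license-gated mapping file.
- **A corpus-driven lexicon builder** with pluggable mention-source and
  normalizer adapters, semantic-type screening, a ≥ 20-distinct-patient
  curation queue replayed from an editable decision file, and variant
  enrichment — with per-entry provenance.
- **A rule-based extractor**: family members (category, side of family,
  degree of consanguinity, spouse flagging), leftmost-longest dictionary
  matching of observations, living status, ages, and clause-scoped
  negation (certainty ∈ {negated, nonnegated}).
- **Relation linking** by clause co-occurrence, plus cue-licensed
  backward coreference across a three-sentence window ("Father is
  deceased. **He** had colon cancer."), excluding spouses; relations
  assemble into one chain per family member.
- **Challenge-style evaluation** — entity and relation precision/recall/F1
  (optionally certainty-aware) via maximum bipartite matching — and
  lexicon-coverage recall at variant and concept level.
- **A synthetic note generator** whose gold annotations are emitted from
  the template semantics, so the whole stack is testable without
  data-use-restricted clinical corpora.

## Scoring model

For gold/prediction sets matched per document and entity type,

    precision = TP / (TP + FP),  recall = TP / (TP + FN),
    F1 = 2PR / (P + R)

with family members matching on (category, side), observations on partial
span overlap (or CUI equality), and relations on
(category, side, normalized target[, certainty]). Lexicon coverage reports
recall `TP / (TP + FN)` at the variant level (entities whose text
partially matches a variant) and the concept level (concepts reachable
through the lexicon, with misses split by concept availability).

## Worked example

```r
library(fhlex)

lex <- load_lexicon(system.file("extdata", "mini_lexicon.tsv",
                                package = "fhlex"))
note <- paste(
  "FAMILY HISTORY: Mother has diabetes and hypertension.",
  "Father is deceased. He had colon cancer.",
  "No family history of asthma. Her husband has breast cancer.\n",
  "SOCIAL HISTORY: former smoker")
ex <- fh_extract(note, lex, doc_id = "note-001")
ex
#> <fh_extraction> note-001: 5 sentences, 8 entities, 4 relations, 2 chains
ex$relations[, c("fm_category", "fm_side", "target_kind",
                 "target_text", "certainty", "provenance")]
#> # A tibble: 4 × 6
#>   fm_category fm_side target_kind   target_text  certainty  provenance
#>   <chr>       <chr>   <chr>         <chr>        <chr>      <chr>
#> 1 Mother      NA      observation   diabetes     nonnegated same_clause
#> 2 Mother      NA      observation   hypertension nonnegated same_clause
#> 3 Father      NA      living_status Dead         nonnegated same_clause
#> 4 Father      NA      observation   colon cancer nonnegated coreference
```

Reading the output: "diabetes and hypertension" stayed in one clause, so
both observations link to Mother; "colon cancer" sits in the next sentence
but the cue "He" licenses the backward link to Father, alongside his
living status; the negated asthma is extracted as an entity with
`certainty = "negated"` but has no family member to link to; and the
husband's breast cancer is recorded as an entity while contributing no FH
relation — spouses are not blood relatives.

Extraction on a synthetic corpus scores perfectly against its own gold
standard, which is the designed self-consistency property:

```r
corp <- generate_corpus(fh_generation_config(n_documents = 50, seed = 42))
pred <- fh_extract_corpus(corp, corp$lexicon)
score_entities(corp$entities, pred$entities)
#> Age           TP 16  FP 0  FN 0 | P 1.0000  R 1.0000  F1 1.0000
#> FamilyMember  TP 121  FP 0  FN 0 | P 1.0000  R 1.0000  F1 1.0000
#> LivingStatus  TP 41  FP 0  FN 0 | P 1.0000  R 1.0000  F1 1.0000
#> Observation   TP 163  FP 0  FN 0 | P 1.0000  R 1.0000  F1 1.0000
#> micro         TP 341  FP 0  FN 0 | P 1.0000  R 1.0000  F1 1.0000
score_relations(corp$relations, pred$relations, with_certainty = TRUE)
#> TP 183  FP 0  FN 0 | P 1.0000  R 1.0000  F1 1.0000
```

A command-line interface wrapping the same functions ships at
`inst/cli/fhlex.R` with subcommands `simulate`, `extract`,
`build-lexicon` and `evaluate` (CSV or FHIR-style JSON output; see
`Rscript $(Rscript -e 'cat(system.file("cli","fhlex.R",package="fhlex"))')`).

## Layout

- `R/` — lexicon model and I/O, builder pipeline, text preparation,
  entity extraction, relation linking, evaluation, synthetic corpus,
  output writers.
- `inst/extdata/` — editable rule tables (family-member triggers,
  negation triggers), a synthetic mini-lexicon fixture, example SNOMED
  mapping and curation-decision files.
- `inst/schema/` — JSON schema documenting the FHIR-style chain output.
- `vignettes/fh-extraction-methods.Rmd` — the methods vignette: models,
  rules, parameters, design decisions, limitations.
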