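---
title: "Clause-scoped detection and classification of adverse drug event mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clause-scoped detection and classification of adverse drug event mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinade)
```

## The problem

Psychiatric clinical notes document adverse drug events (ADEs) almost
exclusively in free text, and they do so in ways that defeat naive keyword
search: the same note may *affirm* an ADE ("still suffering from a light
headache"), *negate* one ("no complaints of dizziness"), discuss one
*hypothetically* ("if dizziness develops..."), *historically*
("previously experienced seizures"), about *someone else* ("his mother
suffers from anxiety"), as a *warning or monitoring plan* ("warned of
dizziness", "monitor for signs of myocarditis"), inside *questionnaire
boilerplate* ("Fainting/ dizziness \*No \* Yes"), or inside an
*organisation name or address* ("CENTRE FOR ANXIETY DISORDERS AND
TRAUMA"). Only the first of these is a positive occurrence; a useful
annotation tool must detect every mention and label it positive or
negative from its context.

`clinade` implements a rule-based pipeline for exactly this task, plus an
evaluation harness and a seeded synthetic-note generator so that the whole
system can be developed and tested with no access to patient data.

## Pipeline

Four stages run in sequence for every document:

1. **Segmentation.** Sentences are split at `.?!` runs (guarding common
   abbreviations and decimal numbers) and at line breaks; sentences are
   split into clauses at commas and semicolons (not inside numbers). The
   clause is the annotation scope: two observations drive this design —
   clinical text is written in short delimiter-bounded clauses each
   carrying one ADE-related statement, and contextual cues rarely apply
   beyond their clause. A paragraph-scope mode
   (`annotate_document(scope = "paragraph")`) is retained as the coarse
   baseline; on the bundled worked example it wrongly negates *headache*
   because the negation of *constipation* leaks across the sentence
   boundary.
2. **Mention detection.** ADE dictionary surfaces are located within each
   clause by case-insensitive, token-boundary, leftmost-longest gazetteer
   matching (`match_terms()`); each hit becomes a provisional positive
   mention. Clauses containing two or more mentions (about 5% of
   mention-bearing clauses in practice) are re-split immediately before
   any termination term ("but", "however") separating two mentions, which
   turns "still complaining of headache but not constipation" into two
   single-ADE clauses with opposite statuses.
3. **Context assignment.** Contextual trigger terms in the mention's
   clause set four dimensions: experiencer (patient/other), negation
   (affirmed/negated), temporality (recent/historical) and categorical
   value (assertive/hypothetical/retrospective/general_discussion).
   Forward triggers govern from the trigger to the first termination term
   or the clause end; backward triggers govern from the last termination
   term (or clause start) to the trigger; scopes never cross clause
   boundaries. Within a dimension the nearest in-scope trigger wins, ties
   to the leftmost; any in-scope negation trigger negates the mention
   regardless of other triggers.
4. **Refinement.** A declarative catalogue of 9 *retention* and 26
   *removal* rules corrects the two systematic failure modes of plain
   trigger scoping, with the total override order retention > removal >
   context.

The final status is a pure function of the features: a mention is
**positive** iff experiencer = patient, negation resolves affirmed after
refinement, temporality = recent and categorical value = assertive.

## The dictionary

Four categories (TSV files under `inst/extdata/lexicon/`, replaceable via
`load_lexicon()`): **ade** surfaces mapped to canonical concepts (e.g.
"drowsy" → *sedation*), **drug** names (generic terms plus common
antipsychotics/antidepressants and frequent misspellings), **helping**
terms in five subcategories (occurrence, administration, monitoring,
negative_effect, drug_link) consumed by the refinement patterns, and
**contextual** triggers in five subcategories with exactly 75 experiencer,
413 negation, 44 possibility, 106 termination and 72
temporality/hypothetical entries (710 in total). Entries carry a
per-entry case-sensitivity flag (used for acronyms such as the helping
term "SE") and, for contextual entries, a scope direction.

**Trigger directions** were the one genuinely open design point. Most
negation triggers are forward ("no", "did not complain of"), a small set
is backward ("not seen", "was ruled out"), and the bare auxiliary+not
family ("not", "has not", "didn't") is *bidirectional*. The bidirectional
choice is deliberate: in clauses like "restlessness has not worsened" or
"disorientated and not taking his medication" the negation cue follows
the mention, and the context stage must (mis)classify these as negated so
that the retention rules — whose entire purpose is to rescue such cases —
see them. With forward-only bare negation those clauses would bypass the
retention stage; final statuses would mostly coincide, but the staged
architecture would be vacuous.

Where a trigger subcategory drives two output dimensions
(temporality/hypothetical), each entry's canonical value says which: a
temporal trigger sets temporality = historical *and* categorical value =
retrospective; a hypothetical trigger sets categorical value only. When a
hypothetical and a temporal trigger both cover a mention, the nearest one
decides the categorical value — the tie-break is recorded rather than
hidden because no principled precedence exists.

## The refinement catalogue

The catalogue is a versioned TSV (`inst/extdata/rules/`) so users can
extend it: each rule is an ordered token pattern over lexicon-subcategory
slots, literal alternations and bounded wildcards (gaps of at most five
tokens), or one of a small set of built-in surface detectors (email, URL,
all-caps run of ≥ 3 words, slash-adjacency, anchored regexes).

*Retention* rules fire only on negated mentions and recognise negation
whose object is not the event: negated drug administration
("not taking his medication": negation + administration slot + drug
slot), negated compliance/tolerance, and negated change-of-state verbs
("has not worsened", "no increase in"). *Removal* rules mark mentions
negative in four situations: (a) warnings, monitoring, explanations and
risk discussions; (b) uncertainty ("unstable", "query", a trailing "?");
(c) questionnaire layout (checkbox patterns, "Yes/No", trailing "x N"
scores, slash-separated symptom menus, rating-scale wording); and
(d) surface contexts — emails, URLs, all-caps organisation names,
token-level organisation patterns and address lines. Uncertainty removals
additionally record categorical value = general_discussion, an explicit
interpretation choice.

Two scoping details matter. Layout and surface rules (categories c and d)
match at *sentence* scope: in "I become irritable, restless and nervous
x 5" the comma isolates "irritable" in a clause without the trailing
score, yet the whole line is questionnaire text. And the catalogue is
applied in file order with first-match-wins, ordered so that the most
specific surface detectors (email, URL, caps-run) precede the layout
patterns that could also match inside them.

Exactly 9 retention and 26 removal rules are registered; the test suite
keeps one firing fixture and one non-firing close variant per rule, so the
catalogue cannot silently shrink or change meaning.

## Evaluation conventions

`match_and_count()` pairs gold and predicted mentions within each
(document, concept) by span overlap, preferring exact spans. TP/TN/FP/FN
follow the usual definitions against the gold status; unpaired gold
positives count FN, unpaired gold negatives TN, unpaired predicted
positives FP, and unpaired predicted negatives are ignored (they assert
nothing a gold annotator weighed in on). Pairs that overlap only
partially *and* disagree on status resolve to TN under the default
`partial = "negative"` policy — the convention that a partial match is
treated as a negative agreement — with `partial = "strict"` available
since the convention is a documented interpretation, not a law.
`compute_metrics()` reports precision, sensitivity, specificity, accuracy
and F-measure, with zero-denominator ratios as `NA` (never 0); rounding
to two decimals happens only in the CSV presentation layer.

The package bundles a reference results table
(`inst/extdata/reference/reported_results.tsv`) of published per-ADE
evaluation figures for the same task. Twelve of its nineteen rows are
self-consistent at printed precision — recomputing accuracy as
(TP+TN)/Total and F as 2PR/(P+R) reproduces the printed cells exactly at
two decimals — and the acceptance checks assert those identities; the
remaining rows carry rounding artefacts in the published table itself
(three accuracy cells are inconsistent with their own counts), which the
tests document rather than paper over.

## The synthetic corpus

`generate_corpus()` emulates the catalogued phenomena, not clinical
language: each document is 1–30 sentences, roughly half carrying one ADE
template instantiation and half neutral ward-note filler. Template
categories follow a configurable mix (defaults: affirmed 0.35, negated
0.25, warning/monitoring 0.10, historical 0.08, hypothetical 0.06,
other-experiencer 0.06, questionnaire 0.04, uncertainty 0.04,
organisation/email 0.02 — a plausible profile for progress notes, chosen
once and fixed). A mention-bearing clause carries two ADEs with
probability 0.05, matching the approximate multi-ADE rate reported for
psychiatric notes. Every insertion is logged as a gold annotation whose
status is implied by its template category; with `n_docs >= 19` the
corpus opens with fixed canonical fixture documents covering the worked
examples of every stage, including the retention cases (labelled
positive). The patient placeholder "ZZZZZ" mimics de-identification
masking. Typo injection (character transpositions) touches filler
sentences only, never mention or trigger tokens, and the typo draws are
consumed at every rate so corpora generated from the same seed share
layout and gold annotations across typo rates.

Because generator and pipeline share only the lexicon, perfect end-to-end
accuracy on a clean corpus is a meaningful soundness check rather than a
tautology — but it shows soundness on the catalogued phenomena only.
Real notes contain misspelled ADE terms, section headers, coordination
("denies nausea or vomiting" split across clauses), and precautionary
phrasing outside the catalogue; accuracy there will be lower, which is
precisely why the evaluation harness accepts external gold standards.

## Numerical and degenerate-input choices

Offsets are 1-based inclusive in memory (R convention) and 0-based
half-open in JSONL/BRAT files; conversion happens only in readers and
writers. Empty documents, documents without ADE terms, and empty clauses
yield empty annotation frames, never errors. Matching is deterministic:
identical text and lexicon give identical output, and annotating twice
produces byte-identical JSONL. The checks in this package use a
500-document synthetic corpus (≈ 4,000 gold mentions) for the end-to-end
properties and 1,000 random instances for the oracle-equivalence
properties; both sizes give binomial error well inside the asserted
bounds while keeping a full run in minutes on one CPU.

## Known limitations

- No spelling correction or fuzzy matching: misspellings are covered only
  as explicit dictionary variants.
- No concept normalisation to UMLS/SNOMED; canonical labels are plain
  strings.
- No drug–ADE causality linkage; the tool annotates mentions, not
  reactions attributed to a specific prescription.
- Section-level context (e.g. a "Family History:" header governing
  following sentences) is out of scope; experiencer is clause-local.
- The questionnaire heuristics target line-level artefacts; tables
  rendered as ASCII art beyond those patterns are not handled.
- Rare-ADE precautionary phrasing is covered only by the catalogued
  removal categories; the catalogue is deliberately extensible via its
  TSV resource.
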