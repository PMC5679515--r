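# clinade

Rule-based detection and context classification of adverse drug event
(ADE) mentions in free-text clinical notes.

## What problem it solves, and for whom

Psychiatric EHR notes hold most of their ADE information in free text, and
a mention of an ADE term is usually *not* an occurrence: notes negate ADEs
("no complaints of dizziness"), discuss them hypothetically ("if dizziness
develops"), historically, about relatives, as warnings or monitoring plans
("warned of dizziness", "monitor for signs of myocarditis"), inside
questionnaire boilerplate ("Fainting/ dizziness \*No \* Yes"), or inside
organisation names and addresses. `clinade` is for researchers mining
EHR-style text for pharmacovigilance who need every ADE mention located
and labelled **positive** (the event occurred in the patient, recently,
assertively) or **negative** (everything else), with the evidence for each
decision.

## The method

A four-stage pipeline, each stage a rule base over a bundled,
user-extensible dictionary:

1. **Clause segmentation** — sentences split at `.?!`/newlines
   (abbreviation- and decimal-safe), clauses at `,`/`;`. The clause is the
   annotation scope. Clauses holding several ADE mentions are re-split at
   termination terms ("but", "however") so each fragment carries one
   mention.
2. **Mention detection** — leftmost-longest, token-boundary gazetteer
   matching of ADE surfaces (each mapped to a canonical concept, e.g.
   "drowsy" → *sedation*); every hit starts as provisionally positive.
3. **Context assignment** — trigger terms co-located in the clause set
   experiencer, negation, temporality and categorical value. A forward
   trigger governs text from the trigger to the first termination term or
   clause end; a backward trigger governs back to the last termination
   term or clause start; nearest in-scope trigger wins per dimension, and
   any in-scope negation trigger negates the mention.
4. **Refinement** — a declarative catalogue of 9 *retention* rules
   (negation whose object is drug administration or a change-of-state
   verb: "not taking his medication", "has not worsened" → keep positive)
   and 26 *removal* rules (warnings/monitoring, uncertainty,
   questionnaires, organisation names/emails/URLs → mark negative), with
   override order retention > removal > context.

A mention's final status is positive iff experiencer = patient, negation
resolves affirmed, temporality = recent and categorical value = assertive.
An evaluation harness (precision, sensitivity, specificity, accuracy,
F-measure = 2PR/(P+R) against gold annotations) and a seeded synthetic
note generator complete the package, so everything is testable without
patient data.

## Worked example

```r
library(clinade)

tx <- paste("He did not complain of constipation.",
            "The patient is still complaining of headache but not constipation.",
            "Monitor for signs of myocarditis.")
annotate_document(tx, doc_id = "note-001")[, c("ade_type", "negation",
    "categorical_value", "refinement_rule", "ade_status", "clause")]
#>       ade_type negation categorical_value refinement_rule ade_status
#> 1 constipation  negated         assertive            <NA>   negative
#> 2     headache affirmed         assertive            <NA>   positive
#> 3 constipation  negated         assertive            <NA>   negative
#> 4  myocarditis  negated         assertive          REM-01   negative
#>                                         clause
#> 1         He did not complain of constipation.
#> 2 The patient is still complaining of headache
#> 3                        but not constipation.
#> 4            Monitor for signs of myocarditis.
```

Row 1: the forward negation "did not complain" scopes over *constipation*
within its sentence only, so the *headache* in the next sentence stays
positive. Rows 2–3: the multi-ADE clause was re-split at "but", affirming
*headache* while negating *constipation*. Row 4: no negation trigger is
present, but removal rule REM-01 (monitoring language) marks the
*myocarditis* mention negative — it is a screening instruction, not an
event.

Scoring a synthetic corpus end to end:

```r
cfg  <- generation_config(n_docs = 50, seed = 42)
corp <- generate_corpus(cfg)
pred <- annotate_corpus(corp$documents)
evaluate_annotations(corp$gold, pred)
#>    TP FP  TN FN total precision sensitivity specificity accuracy f_measure
#> 1 110  0 187  0   297         1           1           1        1         1
```

On a clean synthetic corpus (no typos) the pipeline reproduces every gold
label: the generator emits exactly the contextual phenomena the rule base
catalogues, which checks the machinery, not real-world coverage (see the
methods vignette for what this does and does not show).

A command-line wrapper is installed with the package
(`system.file("exec", "clinade", package = "clinade")`) with `annotate`,
`evaluate` and `synth` subcommands over plain text, JSONL and BRAT
standoff files.

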