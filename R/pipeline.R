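# Package-level cache for the bundled lexicon and rule catalogue so repeated
# annotate_document() calls do not re-read the TSVs.
.clinade_state <- new.env(parent = emptyenv())

default_lexicon <- function() {
  if (is.null(.clinade_state$lexicon)) {
    .clinade_state$lexicon <- load_lexicon()
  }
  .clinade_state$lexicon
}

default_rules <- function() {
  if (is.null(.clinade_state$rules)) {
    .clinade_state$rules <- load_rule_catalogue()
  }
  .clinade_state$rules
}

#' Derive the final positive/negative status from the four context features
#'
#' A mention is a positive occurrence if and only if the subject is the
#' patient, no negation stands after refinement, the event is recent, and
#' the statement is assertive (not hypothetical, retrospective or a general
#' discussion).
#'
#' @param experiencer,negation,temporality,categorical_value Character
#'   vectors of feature values (recycled to a common length).
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
ade_status_from_features <- function(experiencer, negation, temporality,
                                     categorical_value) {
  ifelse(experiencer == "patient" & negation == "affirmed" &
           temporality == "recent" & categorical_value == "assertive",
         "positive", "negative")
}

empty_annotations <- function() {
  new_df(doc_id = character(), ade_type = character(),
         experiencer = character(), negation = character(),
         temporality = character(), categorical_value = character(),
         refinement_rule = character(), ade_status = character(),
         clause = character(), start = integer(), end = integer())
}

#' Annotate one document end to end
#'
#' Runs the full pipeline: sentence splitting, clause splitting, ADE mention
#' detection, re-splitting of multi-ADE clauses at termination terms,
#' clause-scoped context assignment (experiencer, negation, temporality,
#' categorical value), retention/removal refinement, and final status
#' derivation.  With `scope = "paragraph"` the whole paragraph is used as
#' the annotation boundary instead of the clause (no clause or multi-ADE
#' splitting), which reproduces the coarse baseline that clause-level
#' scoping improves upon.
#'
#' @param text Document string.
#' @param doc_id Document identifier.
#' @param lexicon A `clinade_lexicon`; `NULL` for the bundled dictionary.
#' @param rules A `clinade_rules` catalogue; `NULL` for the bundled one.
#' @param scope `"clause"` (default) or `"paragraph"`.
#' @return Data frame of annotations ordered by offset, one row per ADE
#'   mention, with columns `doc_id`, `ade_type`, `experiencer`, `negation`,
#'   `temporality`, `categorical_value`, `refinement_rule`, `ade_status`,
#'   `clause` (verbatim clause text), `start`, `end` (1-based inclusive
#'   character offsets into `text`).
#' @examples
#' annotate_document(paste("He did not complain of constipation.",
#'   "The patient is still suffering from a light headache."))
#' @export
annotate_document <- function(text, doc_id = "doc", lexicon = NULL,
                              rules = NULL, scope = c("clause", "paragraph")) {
  scope <- match.arg(scope)
  lexicon <- lexicon %||% default_lexicon()
  rules <- rules %||% default_rules()
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    return(empty_annotations())
  }

  if (scope == "paragraph") {
    sentences <- split_paragraphs(text, doc_id)
    clauses <- sentences
    clauses$clause_id <- clauses$sentence_id
    clauses$split_origin <- "whole_sentence"
  } else {
    sentences <- split_sentences(text, doc_id)
    clauses <- split_clauses(sentences, text)
  }
  if (nrow(clauses) == 0) return(empty_annotations())

  mentions <- detect_mentions(clauses, text, lexicon, doc_id)
  if (nrow(mentions) == 0) return(empty_annotations())

  if (scope == "clause") {
    clauses <- split_multi_ade_clause(clauses, mentions, text, lexicon)
    mentions <- assign_clause(mentions[, setdiff(names(mentions),
                                                 "clause_id")], clauses)
  }
  triggers <- find_triggers(clauses, text, lexicon)
  cache <- new.env(parent = emptyenv())

  rows <- vector("list", nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    m <- mentions[i, , drop = FALSE]
    cl <- clauses[clauses$clause_id == m$clause_id, , drop = FALSE]
    sent <- sentences[sentences$sentence_id == cl$sentence_id, , drop = FALSE]
    ctx <- assign_context(m, triggers)
    ret <- apply_retention_rules(m, ctx, cl, sent, text, lexicon, rules,
                                 cache)
    rem <- apply_removal_rules(m, ctx, cl, sent, text, lexicon, rules, cache)
    fin <- resolve_refinement(ctx, ret, rem)
    categorical <- ctx$categorical_value
    if (identical(rem$category, "b") &&
          !identical(ret$action, "retain_positive")) {
      # uncertainty removals are recorded as general discussion
      categorical <- "general_discussion"
    }
    status <- if (identical(ret$action, "retain_positive")) "positive" else
      ade_status_from_features(ctx$experiencer, fin$negation,
                               ctx$temporality, categorical)
    rows[[i]] <- new_df(
      doc_id = m$doc_id, ade_type = m$ade_concept,
      experiencer = ctx$experiencer, negation = fin$negation,
      temporality = ctx$temporality, categorical_value = categorical,
      refinement_rule = fin$rule_id %||% NA_character_,
      ade_status = status,
      clause = substr(text, cl$start, cl$end),
      start = m$start, end = m$end)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate a corpus of documents
#'
#' @param docs Data frame with columns `id` and `text` (one row per
#'   document), as produced by [generate_corpus()] or [read_corpus()].
#' @inheritParams annotate_document
#' @return Row-bound annotation data frame across all documents.
#' @export
annotate_corpus <- function(docs, lexicon = NULL, rules = NULL,
                            scope = c("clause", "paragraph")) {
  scope <- match.arg(scope)
  lexicon <- lexicon %||% default_lexicon()
  rules <- rules %||% default_rules()
  out <- lapply(seq_len(nrow(docs)), function(i) {
    annotate_document(docs$text[i], doc_id = docs$id[i], lexicon = lexicon,
                      rules = rules, scope = scope)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty_annotations() else res
}
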