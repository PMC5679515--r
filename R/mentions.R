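#' Detect ADE mentions within clauses
#'
#' Locates ADE dictionary terms in each clause (leftmost-longest,
#' word-boundary matching via [match_terms()]) and creates one provisional
#' mention per hit.  Every mention starts life as a positive occurrence; the
#' context and refinement stages may later flip it.  Repeated hits of the
#' same term, within or across clauses, all become distinct mentions.
#'
#' @param clauses Output of [split_clauses()] or [split_multi_ade_clause()].
#' @param text The document string.
#' @param lexicon A `clinade_lexicon`.
#' @param doc_id Document identifier.
#' @return Data frame with one row per mention: `doc_id`, `clause_id`,
#'   `ade_concept`, `surface`, `start`, `end` (document-absolute, 1-based
#'   inclusive), `provisional_status` (always `"positive"`); ordered by
#'   `start`.
#' @export
detect_mentions <- function(clauses, text, lexicon, doc_id = "doc") {
  empty <- new_df(doc_id = character(), clause_id = integer(),
                  ade_concept = character(), surface = character(),
                  start = integer(), end = integer(),
                  provisional_status = character())
  if (nrow(clauses) == 0) return(empty)
  segs <- substr(rep(text, nrow(clauses)), clauses$start, clauses$end)
  hits <- match_terms(segs, lexicon, "ade")
  if (nrow(hits) == 0) return(empty)
  off <- clauses$start[hits$text_id] - 1L
  res <- new_df(doc_id = doc_id,
                clause_id = clauses$clause_id[hits$text_id],
                ade_concept = hits$canonical,
                surface = hits$surface,
                start = hits$start + off,
                end = hits$end + off,
                provisional_status = "positive")
  res[order(res$start), , drop = FALSE]
}
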