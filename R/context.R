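#' Find contextual trigger terms and their scopes within clauses
#'
#' Scans each clause for contextual dictionary entries and computes the text
#' region each trigger governs.  Forward triggers (most negation,
#' possibility, hypothetical and temporal terms, e.g. `"no"`, `"if"`) govern
#' from the trigger to the first termination term after it, or the clause
#' end.  Backward triggers (e.g. `"was ruled out"`, `"in the past"`) govern
#' from the last termination term before them (or the clause start) up to
#' the trigger.  Bidirectional triggers (the bare `not` family) govern both
#' sides.  Termination terms themselves carry an empty scope: they only end
#' the scope of other triggers, and a scope never crosses a clause boundary.
#'
#' @inheritParams detect_mentions
#' @return Data frame with one row per trigger hit: `clause_id`, `surface`,
#'   `entry`, `canonical`, `subcategory`, `direction`, `start`, `end`,
#'   `scope_start`, `scope_end` (all offsets document-absolute, 1-based
#'   inclusive; `NA` scope for termination terms and empty scopes).
#' @examples
#' lex <- load_lexicon()
#' cl <- split_clauses(split_sentences("No complaints of dizziness"),
#'                     "No complaints of dizziness")
#' find_triggers(cl, "No complaints of dizziness", lex)
#' @export
find_triggers <- function(clauses, text, lexicon) {
  empty <- new_df(clause_id = integer(), surface = character(),
                  entry = character(), canonical = character(),
                  subcategory = character(), direction = character(),
                  start = integer(), end = integer(),
                  scope_start = integer(), scope_end = integer())
  if (nrow(clauses) == 0) return(empty)
  segs <- substr(rep(text, nrow(clauses)), clauses$start, clauses$end)
  hits <- match_terms(segs, lexicon, "contextual")
  if (nrow(hits) == 0) return(empty)
  off <- clauses$start[hits$text_id] - 1L
  hits$start <- hits$start + off
  hits$end <- hits$end + off
  hits$clause_id <- clauses$clause_id[hits$text_id]
  hits$scope_start <- NA_integer_
  hits$scope_end <- NA_integer_

  for (cid in unique(hits$clause_id)) {
    in_cl <- which(hits$clause_id == cid)
    cl <- clauses[clauses$clause_id == cid, , drop = FALSE]
    terms <- hits[in_cl, , drop = FALSE]
    term_hits <- terms[terms$subcategory == "termination", , drop = FALSE]
    for (j in in_cl) {
      if (hits$subcategory[j] == "termination") next
      dir <- hits$direction[j]
      fwd_end <- NA_integer_
      bwd_start <- NA_integer_
      if (dir %in% c("forward", "bidirectional")) {
        stop_at <- term_hits$start[term_hits$start > hits$end[j]]
        fwd_end <- if (length(stop_at) > 0) min(stop_at) - 1L else cl$end
      }
      if (dir %in% c("backward", "bidirectional")) {
        start_at <- term_hits$end[term_hits$end < hits$start[j]]
        bwd_start <- if (length(start_at) > 0) max(start_at) + 1L
          else cl$start
      }
      scope_start <- switch(dir,
        forward = hits$end[j] + 1L,
        backward = bwd_start,
        bidirectional = bwd_start)
      scope_end <- switch(dir,
        forward = fwd_end,
        backward = hits$start[j] - 1L,
        bidirectional = fwd_end)
      if (!is.na(scope_start) && !is.na(scope_end) &&
            scope_start <= scope_end) {
        hits$scope_start[j] <- scope_start
        hits$scope_end[j] <- scope_end
      }
    }
  }
  hits[, c("clause_id", "surface", "entry", "canonical", "subcategory",
           "direction", "start", "end", "scope_start", "scope_end")]
}

#' Assign contextual values to one mention
#'
#' Combines the trigger hits of the mention's clause into the four
#' contextual dimensions.  A mention defaults to
#' (`patient`, `affirmed`, `recent`, `assertive`); each dimension is then
#' set by the nearest in-scope trigger of that dimension (ties broken by the
#' leftmost trigger).  Any in-scope negation trigger negates the mention
#' regardless of other triggers; only the refinement rules can override
#' that.  A temporal trigger sets `temporality = "historical"` and
#' `categorical_value = "retrospective"`; a hypothetical trigger sets
#' `categorical_value = "hypothetical"`; a possibility trigger sets
#' `categorical_value = "general_discussion"`.
#'
#' @param mention A one-row data frame (or list) with `start`, `end` and
#'   `clause_id`.
#' @param triggers Trigger hits from [find_triggers()] (any clauses; only
#'   the mention's clause is consulted).
#' @return A list with elements `experiencer`, `negation`, `temporality`,
#'   `categorical_value` and `triggers_fired` (character vector of trigger
#'   surfaces justifying non-default values).
#' @export
assign_context <- function(mention, triggers) {
  res <- list(experiencer = "patient", negation = "affirmed",
              temporality = "recent", categorical_value = "assertive",
              triggers_fired = character(0))
  if (is.null(triggers) || nrow(triggers) == 0) return(res)
  tr <- triggers[!is.na(triggers$clause_id) &
                   triggers$clause_id == mention$clause_id &
                   triggers$subcategory != "termination" &
                   !is.na(triggers$scope_start), , drop = FALSE]
  if (nrow(tr) == 0) return(res)
  in_scope <- tr$scope_start <= mention$end & tr$scope_end >= mention$start
  tr <- tr[in_scope, , drop = FALSE]
  if (nrow(tr) == 0) return(res)

  dist <- pmax(0L, pmax(tr$start - mention$end, mention$start - tr$end))
  nearest <- function(rows) {
    if (length(rows) == 0) return(NA_integer_)
    rows[order(dist[rows], tr$start[rows])][1]
  }
  fired <- integer(0)

  j <- nearest(which(tr$subcategory == "experiencer"))
  if (!is.na(j)) {
    res$experiencer <- tr$canonical[j]
    if (tr$canonical[j] != "patient") fired <- c(fired, j)
  }
  neg <- which(tr$subcategory == "negation")
  if (length(neg) > 0) {
    res$negation <- "negated"
    fired <- c(fired, nearest(neg))
  }
  temp <- which(tr$subcategory == "temporality_hypothetical" &
                  tr$canonical == "historical")
  if (length(temp) > 0) {
    res$temporality <- "historical"
    fired <- c(fired, nearest(temp))
  }
  cat_rows <- which(tr$subcategory == "possibility" |
                      tr$subcategory == "temporality_hypothetical")
  j <- nearest(cat_rows)
  if (!is.na(j)) {
    res$categorical_value <- switch(
      tr$subcategory[j],
      possibility = "general_discussion",
      temporality_hypothetical = if (tr$canonical[j] == "historical")
        "retrospective" else "hypothetical")
    fired <- c(fired, j)
  }
  res$triggers_fired <- unique(tr$surface[sort(fired)])
  res
}
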