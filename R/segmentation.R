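#' Split a document into sentences
#'
#' Sentences end at runs of `.`, `?` or `!` followed by whitespace or end of
#' text, and at line breaks.  Common abbreviations (`Dr.`, `Mr.`, `e.g.`,
#' `i.e.`, `etc.`, `vs.`) and decimal numbers do not split.  Offsets are
#' document-absolute, 1-based and inclusive, and sentence spans never
#' overlap.
#'
#' @param text A single document string.
#' @param doc_id Document identifier carried into the output.
#' @return Data frame with columns `doc_id`, `sentence_id`, `start`, `end`.
#' @examples
#' split_sentences(paste("He did not complain of constipation.",
#'                       "The patient is still suffering from a light headache."))
#' @export
split_sentences <- function(text, doc_id = "doc") {
  empty <- new_df(doc_id = character(), sentence_id = integer(),
                  start = integer(), end = integer())
  if (length(text) != 1 || is.na(text) || nchar(text) == 0) return(empty)

  n <- nchar(text)
  # candidate terminator runs followed by whitespace or end of text
  runs <- stringi::stri_locate_all_regex(text, "[.!?]+(?=\\s|$)")[[1]]
  cuts <- integer(0)
  if (!all(is.na(runs[, 1]))) {
    abbrev <- "(?i)\\b(?:dr|mr|mrs|ms|prof|st|vs|etc|approx|e\\.g|i\\.e)$"
    for (r in seq_len(nrow(runs))) {
      before <- substr(text, max(1L, runs[r, 1] - 8L), runs[r, 1] - 1L)
      if (stringi::stri_detect_regex(before, abbrev)) next
      cuts <- c(cuts, runs[r, 2])
    }
  }
  nl <- stringi::stri_locate_all_fixed(text, "\n")[[1]]
  if (!all(is.na(nl[, 1]))) cuts <- c(cuts, nl[, 1])
  cuts <- sort(unique(c(cuts, n)))

  starts <- c(1L, utils::head(cuts, -1) + 1L)
  out <- vector("list", length(cuts))
  k <- 0L
  for (i in seq_along(cuts)) {
    sp <- trim_span(text, starts[i], cuts[i])
    if (is.na(sp[1])) next
    k <- k + 1L
    out[[k]] <- new_df(doc_id = doc_id, sentence_id = k,
                       start = sp[1], end = sp[2])
  }
  if (k == 0) return(empty)
  do.call(rbind, out[seq_len(k)])
}

#' Split a document into paragraphs
#'
#' Paragraphs are blocks separated by blank lines.  Used as the coarse
#' annotation scope when comparing paragraph-level against clause-level
#' classification.
#'
#' @inheritParams split_sentences
#' @return Data frame shaped like [split_sentences()] output.
#' @export
split_paragraphs <- function(text, doc_id = "doc") {
  empty <- new_df(doc_id = character(), sentence_id = integer(),
                  start = integer(), end = integer())
  if (length(text) != 1 || is.na(text) || nchar(text) == 0) return(empty)
  n <- nchar(text)
  gaps <- stringi::stri_locate_all_regex(text, "\\n[ \\t]*\\n+")[[1]]
  bounds <- if (all(is.na(gaps[, 1]))) integer(0) else gaps[, 1] - 1L
  cuts <- sort(unique(c(bounds, n)))
  starts <- c(1L, if (!all(is.na(gaps[, 1]))) gaps[, 2] + 1L)
  out <- list()
  for (i in seq_along(cuts)) {
    sp <- trim_span(text, starts[i], cuts[i])
    if (is.na(sp[1])) next
    out[[length(out) + 1L]] <- new_df(doc_id = doc_id,
                                      sentence_id = length(out) + 1L,
                                      start = sp[1], end = sp[2])
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Split sentences into delimiter-bounded clauses
#'
#' Clauses are the annotation scope unit: the text between commas and
#' semicolons within a sentence (sentence-final punctuation has already been
#' consumed by [split_sentences()]).  Commas inside numbers (`1,204`) do not
#' split; slash-separated symptom lists stay within one clause.
#'
#' @param sentences Output of [split_sentences()] (or [split_paragraphs()]).
#' @param text The document string the offsets refer to.
#' @return Data frame with columns `doc_id`, `sentence_id`, `clause_id`,
#'   `start`, `end`, `split_origin` (`delimiter`, `termination_term` or
#'   `whole_sentence`).
#' @export
split_clauses <- function(sentences, text) {
  empty <- new_df(doc_id = character(), sentence_id = integer(),
                  clause_id = integer(), start = integer(), end = integer(),
                  split_origin = character())
  if (nrow(sentences) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(sentences))) {
    s0 <- sentences$start[i]
    s1 <- sentences$end[i]
    seg <- substr(text, s0, s1)
    loc <- stringi::stri_locate_all_regex(seg, "[,;]")[[1]]
    delims <- integer(0)
    if (!all(is.na(loc[, 1]))) {
      for (r in seq_len(nrow(loc))) {
        p <- loc[r, 1]
        ch <- substr(seg, p, p)
        if (ch == ",") {
          prev <- if (p > 1) substr(seg, p - 1, p - 1) else ""
          nxt <- if (p < nchar(seg)) substr(seg, p + 1, p + 1) else ""
          if (grepl("[0-9]", prev) && grepl("[0-9]", nxt)) next
        }
        delims <- c(delims, p)
      }
    }
    origin <- if (length(delims) == 0) "whole_sentence" else "delimiter"
    piece_starts <- c(1L, delims + 1L)
    piece_ends <- c(delims - 1L, nchar(seg))
    for (k in seq_along(piece_starts)) {
      sp <- trim_span(text, s0 + piece_starts[k] - 1L, s0 + piece_ends[k] - 1L)
      if (is.na(sp[1])) next
      out[[length(out) + 1L]] <- new_df(
        doc_id = sentences$doc_id[i], sentence_id = sentences$sentence_id[i],
        clause_id = NA_integer_, start = sp[1], end = sp[2],
        split_origin = origin)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res$clause_id <- seq_len(nrow(res))
  res
}

#' Re-split clauses that contain multiple ADE mentions
#'
#' A clause containing two or more ADE term hits is divided into single-ADE
#' clauses at the dictionary's termination terms (`but`, `however`, ...):
#' the clause is split immediately before each termination-term hit that
#' separates two ADE hits.  Clauses with fewer than two hits, or whose hits
#' are not separated by a termination term, are returned unchanged.
#'
#' @param clauses Output of [split_clauses()].
#' @param ade_hits Data frame of ADE term hits with document-absolute
#'   `start`/`end` columns and a `clause_id` column referring to `clauses`.
#' @param text The document string.
#' @param lexicon A `clinade_lexicon` (supplies the termination terms).
#' @return A clause data frame shaped like [split_clauses()] output; clauses
#'   created here have `split_origin = "termination_term"`.
#' @export
split_multi_ade_clause <- function(clauses, ade_hits, text, lexicon) {
  if (nrow(clauses) == 0) return(clauses)
  out <- list()
  for (i in seq_len(nrow(clauses))) {
    cl <- clauses[i, , drop = FALSE]
    hits <- ade_hits[!is.na(ade_hits$clause_id) &
                       ade_hits$clause_id == cl$clause_id, , drop = FALSE]
    if (nrow(hits) < 2) {
      out[[length(out) + 1L]] <- cl
      next
    }
    seg <- substr(text, cl$start, cl$end)
    terms <- match_terms(seg, lexicon, "contextual", "termination")
    if (nrow(terms) > 0) {
      terms$start <- terms$start + cl$start - 1L
      terms$end <- terms$end + cl$start - 1L
    }
    hits <- hits[order(hits$start), , drop = FALSE]
    splits <- integer(0)
    if (nrow(terms) > 0) {
      for (k in seq_len(nrow(hits) - 1L)) {
        between <- which(terms$start > hits$end[k] &
                           terms$end < hits$start[k + 1L])
        if (length(between) > 0) {
          splits <- c(splits, terms$start[between[1]])
        }
      }
    }
    splits <- sort(unique(splits))
    if (length(splits) == 0) {
      out[[length(out) + 1L]] <- cl
      next
    }
    frag_starts <- c(cl$start, splits)
    frag_ends <- c(splits - 1L, cl$end)
    for (k in seq_along(frag_starts)) {
      sp <- trim_span(text, frag_starts[k], frag_ends[k])
      if (is.na(sp[1])) next
      frag <- cl
      frag$start <- sp[1]
      frag$end <- sp[2]
      frag$split_origin <- "termination_term"
      out[[length(out) + 1L]] <- frag
    }
  }
  res <- do.call(rbind, out)
  res$clause_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

# Assign each hit (document-absolute span) to the clause containing it.
assign_clause <- function(hits, clauses) {
  if (nrow(hits) == 0) {
    hits$clause_id <- integer(0)
    return(hits)
  }
  hits$clause_id <- NA_integer_
  for (i in seq_len(nrow(hits))) {
    j <- which(clauses$start <= hits$start[i] & clauses$end >= hits$end[i])
    if (length(j) > 0) hits$clause_id[i] <- clauses$clause_id[j[1]]
  }
  hits
}
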