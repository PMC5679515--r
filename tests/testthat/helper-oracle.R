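# Shared fixtures and independent brute-force oracles used by the tests.

bundled_lexicon <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- load_lexicon()
    lex
  }
})

bundled_rules <- local({
  rules <- NULL
  function() {
    if (is.null(rules)) rules <<- load_rule_catalogue()
    rules
  }
})

# A tiny in-code lexicon for unit tests that should not depend on the
# bundled dictionary contents.
toy_lexicon <- function() {
  lexicon_from_entries(data.frame(
    surface = c("dizziness", "dry mouth", "mouth", "nausea", "vomiting",
                "headache",
                "medication",
                "taking",
                "signs of",
                "no", "not", "did not complain",
                "mother",
                "if", "previously", "in the past",
                "possible",
                "however", "but", "moreover"),
    canonical = c("dizziness", "dry mouth", "dry mouth", "nausea", "vomiting",
                  "headache",
                  "medication",
                  "taking",
                  "signs of",
                  "negated", "negated", "negated",
                  "other",
                  "hypothetical", "historical", "historical",
                  "general_discussion",
                  "termination", "termination", "termination"),
    category = c(rep("ade", 6), "drug", "helping", "helping",
                 rep("contextual", 11)),
    subcategory = c(rep(NA, 6), NA, "administration", "monitoring",
                    "negation", "negation", "negation",
                    "experiencer",
                    "temporality_hypothetical", "temporality_hypothetical",
                    "temporality_hypothetical",
                    "possibility",
                    "termination", "termination", "termination"),
    direction = c(rep(NA, 9), "forward", "bidirectional", "forward",
                  "forward", "forward", "forward", "backward", "forward",
                  "forward", "forward", "forward"),
    stringsAsFactors = FALSE))
}

# Brute-force reference for match_terms(): enumerate every (position,
# surface) candidate with case-folded equality and non-alphanumeric
# boundaries, then select leftmost-longest non-overlapping matches.
oracle_match <- function(text, surfaces) {
  n <- nchar(text)
  low <- tolower(text)
  cand <- list()
  for (s in surfaces) {
    sl <- tolower(s)
    len <- nchar(sl)
    if (len == 0 || len > n) next
    for (i in seq_len(n - len + 1)) {
      if (substr(low, i, i + len - 1) != sl) next
      before <- if (i > 1) substr(text, i - 1, i - 1) else ""
      after <- if (i + len <= n) substr(text, i + len, i + len) else ""
      if (grepl("[[:alnum:]]", before) || grepl("[[:alnum:]]", after)) next
      cand[[length(cand) + 1L]] <- c(start = i, end = i + len - 1L)
    }
  }
  if (length(cand) == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  m <- do.call(rbind, cand)
  m <- m[order(m[, 1], -(m[, 2] - m[, 1])), , drop = FALSE]
  keep <- logical(nrow(m))
  last_end <- 0L
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] > last_end) {
      keep[r] <- TRUE
      last_end <- m[r, 2]
    }
  }
  m[keep, , drop = FALSE]
}

# Brute-force reference for trigger scope: given clause text, trigger span,
# direction, and termination spans, walk outward from the trigger.
oracle_scope <- function(clause_start, clause_end, trig, direction,
                         term_spans) {
  fwd <- function() {
    stops <- term_spans[, 1][term_spans[, 1] > trig[2]]
    c(trig[2] + 1L, if (length(stops)) min(stops) - 1L else clause_end)
  }
  bwd <- function() {
    starts <- term_spans[, 2][term_spans[, 2] < trig[1]]
    c(if (length(starts)) max(starts) + 1L else clause_start, trig[1] - 1L)
  }
  sc <- switch(direction,
               forward = fwd(),
               backward = bwd(),
               bidirectional = c(bwd()[1], fwd()[2]))
  if (sc[1] > sc[2]) NULL else sc
}

# Random word pool free of substring traps (no word is a prefix of another
# at a boundary because matching is boundary-checked anyway).
random_words <- function(n, rng_len = 3:8) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(rng_len, 1), replace = TRUE), collapse = "")
  }, character(1))
}
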