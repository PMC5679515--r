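sent_texts <- function(text) {
  s <- split_sentences(text)
  substr(rep(text, nrow(s)), s$start, s$end)
}

clause_texts <- function(text) {
  cl <- split_clauses(split_sentences(text), text)
  substr(rep(text, nrow(cl)), cl$start, cl$end)
}

test_that("sentence splitting handles punctuation, abbreviations, decimals", {
  two <- paste("He did not complain of constipation.",
               "The patient is still suffering from a light headache.")
  expect_equal(sent_texts(two),
               c("He did not complain of constipation.",
                 "The patient is still suffering from a light headache."))

  expect_equal(sent_texts("Dose 2.5 mg daily."), "Dose 2.5 mg daily.")
  expect_equal(sent_texts("Seen by Dr. Smith today. Plan unchanged."),
               c("Seen by Dr. Smith today.", "Plan unchanged."))
  expect_equal(sent_texts("Check bloods e.g. lithium levels."),
               "Check bloods e.g. lithium levels.")
  expect_equal(nrow(split_sentences("")), 0)

  # newlines and blank lines break sentences even without punctuation
  expect_equal(sent_texts("Ward round\n\nSettled overnight"),
               c("Ward round", "Settled overnight"))

  # sentences are ordered, non-overlapping, within the document
  tx <- "One. Two? Three! Four.\nFive"
  s <- split_sentences(tx)
  expect_true(all(s$start <= s$end))
  expect_true(all(diff(s$start) > 0))
  expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  expect_true(max(s$end) <= nchar(tx))
})

test_that("clause splitting at commas and semicolons", {
  tx <- paste("She has had 4 seizures within the last 2 weeks,",
              "unstable partial complex seizures")
  expect_equal(clause_texts(tx),
               c("She has had 4 seizures within the last 2 weeks",
                 "unstable partial complex seizures"))

  # no delimiter: one clause equal to the sentence
  expect_equal(clause_texts("Settled on the ward"), "Settled on the ward")
  expect_equal(clause_texts("a, b; c"), c("a", "b", "c"))

  # commas inside numbers do not split
  expect_equal(clause_texts("Serving 1,204 patients"),
               "Serving 1,204 patients")

  # slash-separated symptom lists stay within one clause
  expect_equal(clause_texts("Fainting/ dizziness on standing"),
               "Fainting/ dizziness on standing")
})

test_that("clauses partition the non-delimiter text of their sentence", {
  texts <- c("a, b; c", "No nausea, no vomiting; settled, calm.",
             "One clause only.", "x,,y")
  for (tx in texts) {
    s <- split_sentences(tx)
    cl <- split_clauses(s, tx)
    covered <- rep(0L, nchar(tx))
    for (i in seq_len(nrow(cl))) {
      covered[cl$start[i]:cl$end[i]] <- covered[cl$start[i]:cl$end[i]] + 1L
    }
    chars <- strsplit(tx, "")[[1]]
    essential <- !grepl("[,;[:space:]]", chars)
    expect_true(all(covered[essential] == 1L), info = tx)
    expect_true(all(covered <= 1L), info = tx)
  }
})

test_that("multi-ADE clauses are re-split at termination terms", {
  lex <- toy_lexicon()
  run <- function(tx) {
    cl <- split_clauses(split_sentences(tx), tx)
    hits <- detect_mentions(cl, tx, lex)
    out <- split_multi_ade_clause(cl, hits, tx, lex)
    substr(rep(tx, nrow(out)), out$start, out$end)
  }
  tx <- "The patient is still complaining of headache but not vomiting"
  expect_equal(run(tx), c("The patient is still complaining of headache",
                          "but not vomiting"))

  # no termination term between the hits: clause unchanged
  tx2 <- "headache and vomiting reported"
  expect_equal(run(tx2), tx2)

  # one split point per separated pair, one mention per fragment
  tx3 <- "nausea however no vomiting moreover dizziness"
  frags <- run(tx3)
  expect_equal(frags, c("nausea", "however no vomiting",
                        "moreover dizziness"))
  cl3 <- split_clauses(split_sentences(tx3), tx3)
  hits3 <- detect_mentions(cl3, tx3, lex)
  out3 <- split_multi_ade_clause(cl3, hits3, tx3, lex)
  per_frag <- vapply(seq_len(nrow(out3)), function(i) {
    nrow(match_terms(substr(tx3, out3$start[i], out3$end[i]), lex, "ade"))
  }, integer(1))
  expect_true(all(per_frag == 1L))
  expect_equal(out3$split_origin, rep("termination_term", 3))

  # monotone refinement: never fewer clauses, never more hits per clause
  expect_gte(nrow(out3), nrow(cl3))

  # single-ADE clause keeps its termination term (no split)
  tx4 <- "nausea however settled"
  expect_equal(run(tx4), tx4)
})
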