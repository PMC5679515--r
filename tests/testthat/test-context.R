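ctx_for <- function(tx, concept, lex = bundled_lexicon()) {
  cl <- split_clauses(split_sentences(tx), tx)
  m <- detect_mentions(cl, tx, lex)
  m <- m[m$ade_concept == concept, , drop = FALSE][1, , drop = FALSE]
  assign_context(m, find_triggers(cl, tx, lex))
}

test_that("forward negation trigger scopes over the mention", {
  tx <- "No complaints of dizziness"
  lex <- bundled_lexicon()
  cl <- split_clauses(split_sentences(tx), tx)
  tr <- find_triggers(cl, tx, lex)
  neg <- tr[tr$subcategory == "negation", , drop = FALSE]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$direction, "forward")
  m <- detect_mentions(cl, tx, lex)
  expect_true(neg$scope_start <= m$start && neg$scope_end >= m$end)
  expect_equal(ctx_for(tx, "dizziness")$negation, "negated")
})

test_that("clause with no contextual terms yields the defaults", {
  tx <- "light headache"
  lex <- bundled_lexicon()
  cl <- split_clauses(split_sentences(tx), tx)
  expect_equal(nrow(find_triggers(cl, tx, lex)), 0)
  ctx <- ctx_for(tx, "headache")
  expect_equal(ctx[c("experiencer", "negation", "temporality",
                     "categorical_value")],
               list(experiencer = "patient", negation = "affirmed",
                    temporality = "recent", categorical_value = "assertive"))
  expect_length(ctx$triggers_fired, 0)
})

test_that("termination terms end trigger scopes within the clause", {
  # negation scope ends before "however"; the later mention escapes it
  tx <- "no nausea however vomiting"
  expect_equal(ctx_for(tx, "nausea")$negation, "negated")
  expect_equal(ctx_for(tx, "vomiting")$negation, "affirmed")

  # brute-force scope recomputation for every trigger in random clauses
  lex <- toy_lexicon()
  set.seed(7)
  vocab <- c("no", "if", "in the past", "however", "but", "moreover",
             "nausea", "vomiting", "alpha", "beta", "gamma", "delta")
  for (rep in 1:100) {
    tx <- paste(sample(vocab, sample(3:10, 1), replace = TRUE),
                collapse = " ")
    cl <- split_clauses(split_sentences(tx), tx)
    tr <- find_triggers(cl, tx, lex)
    term <- tr[tr$subcategory == "termination", c("start", "end"),
               drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      if (tr$subcategory[j] == "termination") {
        expect_true(is.na(tr$scope_start[j]))
        next
      }
      cli <- cl[cl$clause_id == tr$clause_id[j], ]
      want <- oracle_scope(cli$start, cli$end,
                           c(tr$start[j], tr$end[j]), tr$direction[j],
                           as.matrix(term))
      if (is.null(want)) {
        expect_true(is.na(tr$scope_start[j]), info = tx)
      } else {
        expect_equal(c(tr$scope_start[j], tr$scope_end[j]), want, info = tx)
      }
    }
  }
})

test_that("each dimension is set by its nearest in-scope trigger", {
  ctx <- ctx_for("his mother had no nausea in the past", "nausea")
  expect_equal(ctx$experiencer, "other")
  expect_equal(ctx$negation, "negated")
  expect_equal(ctx$temporality, "historical")
  expect_equal(ctx$categorical_value, "retrospective")
  expect_true(all(c("mother", "no") %in% ctx$triggers_fired))

  expect_equal(ctx_for("if dizziness occurs", "dizziness")$categorical_value,
               "hypothetical")
  expect_equal(ctx_for("possible dizziness", "dizziness")$categorical_value,
               "general_discussion")
  expect_equal(ctx_for("previously reported dizziness",
                       "dizziness")$temporality, "historical")
})

test_that("negation has priority over every other trigger", {
  # hypothetical and possibility triggers in scope do not lift negation
  for (tx in c("if no dizziness develops",
               "possible but no dizziness",
               "no possible dizziness")) {
    ctx <- ctx_for(tx, "dizziness")
    expect_equal(ctx$negation, "negated", info = tx)
  }
})

test_that("triggers outside every scope never change an assignment", {
  base <- ctx_for("nausea however settled", "nausea")
  # "not" sits behind the termination term, out of the mention's reach
  with_extra <- ctx_for("nausea however not settled", "nausea")
  expect_equal(base[c("experiencer", "negation", "temporality",
                      "categorical_value")],
               with_extra[c("experiencer", "negation", "temporality",
                            "categorical_value")])
  # a trigger in a different clause never reaches the mention
  other_clause <- ctx_for("headache reported, no improvement expected",
                          "headache")
  expect_equal(other_clause$negation, "affirmed")
})
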