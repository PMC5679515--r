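test_that("bundled lexicon loads with the pinned contextual subcategory sizes", {
  counts <- lexicon_counts(bundled_lexicon())
  ctx <- counts[counts$category == "contextual", ]
  got <- stats::setNames(ctx$n, ctx$subcategory)
  expect_equal(got[["experiencer"]], 75)
  expect_equal(got[["negation"]], 413)
  expect_equal(got[["possibility"]], 44)
  expect_equal(got[["termination"]], 106)
  expect_equal(got[["temporality_hypothetical"]], 72)
  expect_equal(sum(ctx$n), 710)
  # every category non-empty, ade entries all carry a canonical concept
  expect_setequal(unique(counts$category),
                  c("ade", "drug", "helping", "contextual"))
  e <- bundled_lexicon()$entries
  expect_true(all(nzchar(e$canonical[e$category == "ade"])))
})

test_that("loader validates inputs and collapses duplicates", {
  dir <- withr::local_tempdir()
  write_lexicon(bundled_lexicon(), dir)
  paths <- stats::setNames(file.path(dir, paste0(c("ade", "drug", "helping",
                                                   "contextual"), ".tsv")),
                           c("ade", "drug", "helping", "contextual"))

  # round trip reproduces the same entry set
  lex2 <- load_lexicon(paths)
  key <- function(l) paste(tolower(l$entries$surface), l$entries$category,
                           l$entries$subcategory)
  expect_setequal(key(lex2), key(bundled_lexicon()))

  # header-only category file is a hard error naming the category
  writeLines("surface\tcanonical\tsubcategory", file.path(dir, "ade.tsv"))
  expect_error(load_lexicon(paths), "no entries for category ade")

  # duplicated row collapses to one entry with a warning
  writeLines(c("surface\tcanonical", "dizzy\tdizziness", "dizzy\tdizziness"),
             file.path(dir, "ade.tsv"))
  expect_warning(lex3 <- load_lexicon(paths), "duplicate")
  expect_equal(sum(lex3$entries$category == "ade"), 1)

  # missing file names the category
  paths2 <- paths
  paths2[["drug"]] <- file.path(dir, "absent.tsv")
  expect_error(load_lexicon(paths2), "category 'drug'")

  # unknown subcategory reports the line number
  writeLines(c("surface\tcanonical\tsubcategory",
               "monitor\tmonitor\tmonitoring",
               "foo\tfoo\tbogus"), file.path(dir, "helping.tsv"))
  writeLines(c("surface\tcanonical", "dizzy\tdizziness"),
             file.path(dir, "ade.tsv"))
  expect_error(load_lexicon(paths), "subcategory 'bogus'.*line 3")
})

test_that("match_terms finds terms at word boundaries, leftmost-longest", {
  lex <- toy_lexicon()
  hits <- match_terms("No complaints of dizziness", lex, "ade")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$canonical, "dizziness")
  expect_equal(substr("No complaints of dizziness", hits$start, hits$end),
               "dizziness")

  # word-boundary rule: no match inside a longer word
  expect_equal(nrow(match_terms("weight gainer", bundled_lexicon(), "ade")),
               0)

  # longest match wins when surfaces nest ("dry mouth" vs "mouth")
  hits <- match_terms("complains of dry mouth", lex, "ade")
  expect_equal(hits$entry, "dry mouth")
  oracle <- oracle_match("complains of dry mouth", c("dry mouth", "mouth"))
  expect_equal(as.matrix(hits[, c("start", "end")]), oracle,
               ignore_attr = TRUE)

  # empty text, empty result
  expect_equal(nrow(match_terms("", lex, "ade")), 0)
  expect_equal(nrow(match_terms(character(0), lex, "ade")), 0)
})

test_that("match_terms output never overlaps and matches entry surfaces", {
  lex <- bundled_lexicon()
  texts <- c("No complaints of dizziness, nausea or dry mouth today.",
             "Seizures, seizure, and more seizures.",
             "dry  mouth with odd   spacing")
  for (tx in texts) {
    h <- match_terms(tx, lex, "ade")
    if (nrow(h) > 1) {
      expect_true(all(h$start[-1] > h$end[-nrow(h)]))
    }
    expect_equal(tolower(gsub("\\s+", " ", h$surface)),
                 tolower(h$entry))
  }
})

test_that("match_terms agrees with the brute-force scanner on random cases", {
  set.seed(42)
  for (rep in 1:150) {
    pool <- unique(random_words(30))
    n_surf <- sample(3:min(20, length(pool)), 1)
    single <- sample(pool, n_surf)
    multi <- replicate(3, paste(sample(pool, 2), collapse = " "))
    surfaces <- unique(c(single, multi))
    lex <- suppressWarnings(lexicon_from_entries(
      data.frame(surface = surfaces, canonical = surfaces,
                 category = "ade", stringsAsFactors = FALSE)))
    words <- sample(c(pool, surfaces), sample(3:25, 1), replace = TRUE)
    text <- paste(words, collapse = " ")
    text <- substr(text, 1, 200)
    got <- match_terms(text, lex, "ade")
    want <- oracle_match(text, surfaces)
    got_m <- as.matrix(got[, c("start", "end")])
    storage.mode(got_m) <- "integer"
    storage.mode(want) <- "integer"
    expect_equal(got_m, want, ignore_attr = TRUE,
                 info = paste("text:", text))
  }
})
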