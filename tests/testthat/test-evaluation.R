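gold_df <- function(...) {
  rows <- list(...)
  empty <- data.frame(doc_id = character(), ade_concept = character(),
                      start = integer(), end = integer(),
                      gold_status = character(), stringsAsFactors = FALSE)
  if (length(rows) == 0) return(empty)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(doc_id = r[[1]], ade_concept = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               gold_status = r[[5]], stringsAsFactors = FALSE)
  }))
}

pred_df <- function(...) {
  g <- gold_df(...)
  names(g)[names(g) == "ade_concept"] <- "ade_type"
  names(g)[names(g) == "gold_status"] <- "ade_status"
  g
}

test_that("matched pairs land in the expected confusion cells", {
  # agreement on a negative mention is a true negative
  c1 <- match_and_count(gold_df(list("d1", "dizziness", 10, 18, "negative")),
                        pred_df(list("d1", "dizziness", 10, 18, "negative")))
  expect_equal(unlist(c1), c(TP = 0, FP = 0, TN = 1, FN = 0))

  # empty gold and empty pred: all zeros
  c0 <- match_and_count(gold_df(), pred_df())
  expect_equal(unlist(c0), c(TP = 0, FP = 0, TN = 0, FN = 0))

  # 3 gold positives, 2 predicted positive and 1 negative
  g <- gold_df(list("d1", "nausea", 1, 6, "positive"),
               list("d1", "nausea", 20, 25, "positive"),
               list("d2", "nausea", 1, 6, "positive"))
  p <- pred_df(list("d1", "nausea", 1, 6, "positive"),
               list("d1", "nausea", 20, 25, "negative"),
               list("d2", "nausea", 1, 6, "positive"))
  expect_equal(unlist(match_and_count(g, p)),
               c(TP = 2, FP = 0, TN = 0, FN = 1))

  # unpaired gold positive -> FN; unpaired prediction positive -> FP
  expect_equal(unlist(match_and_count(
    gold_df(list("d1", "nausea", 1, 6, "positive")),
    pred_df(list("d1", "nausea", 40, 45, "positive")))),
    c(TP = 0, FP = 1, TN = 0, FN = 1))

  # partial overlap with conflicting status resolves to TN by default,
  # to the ordinary error cell under the strict policy
  g2 <- gold_df(list("d1", "sedation", 10, 17, "positive"))
  p2 <- pred_df(list("d1", "sedation", 14, 21, "negative"))
  expect_equal(unlist(match_and_count(g2, p2)),
               c(TP = 0, FP = 0, TN = 1, FN = 0))
  expect_equal(unlist(match_and_count(g2, p2, partial = "strict")),
               c(TP = 0, FP = 0, TN = 0, FN = 1))

  # a predicted doc_id absent from the gold corpus is a validation error
  expect_error(match_and_count(
    gold_df(list("d1", "nausea", 1, 6, "positive")),
    pred_df(list("dX", "nausea", 1, 6, "positive"))), "absent from gold")
})

test_that("metrics follow the standard definitions with NA on 0/0", {
  m <- compute_metrics(data.frame(TP = 132, FP = 6, TN = 64, FN = 13))
  expect_equal(m$total, 215)
  expect_equal(round(m$accuracy, 2), 0.91)
  expect_equal(round(m$precision, 2), 0.96)
  expect_equal(round(m$sensitivity, 2), 0.91)
  expect_equal(round(m$f_measure, 2), 0.93)

  m2 <- compute_metrics(data.frame(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_equal(m2$specificity, 1)
  expect_true(is.na(m2$precision))
  expect_true(is.na(m2$f_measure))
  expect_equal(m2$accuracy, 1)

  expect_error(compute_metrics(data.frame(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty evaluation set")
})

test_that("metric invariants hold on random confusion tables", {
  set.seed(99)
  for (i in 1:200) {
    cnt <- data.frame(TP = rpois(1, 20), FP = rpois(1, 5),
                      TN = rpois(1, 15), FN = rpois(1, 5))
    if (sum(cnt) == 0) next
    m <- compute_metrics(cnt)
    vals <- unlist(m[c("precision", "sensitivity", "specificity",
                       "accuracy", "f_measure")])
    expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
    if (!is.na(m$f_measure)) {
      expect_gte(m$f_measure, min(m$precision, m$sensitivity) - 1e-12)
      expect_lte(m$f_measure, max(m$precision, m$sensitivity) + 1e-12)
    }
  }
})

test_that("counts are order-invariant and per-ADE counts sum to overall", {
  g <- gold_df(list("d1", "nausea", 1, 6, "positive"),
               list("d1", "dizziness", 10, 18, "negative"),
               list("d2", "nausea", 1, 6, "positive"),
               list("d2", "sedation", 9, 16, "negative"))
  p <- pred_df(list("d2", "sedation", 9, 16, "positive"),
               list("d1", "nausea", 1, 6, "positive"),
               list("d1", "dizziness", 10, 18, "negative"),
               list("d2", "nausea", 1, 6, "negative"))
  c_all <- match_and_count(g, p)
  shuffle <- function(df) df[sample(nrow(df)), , drop = FALSE]
  set.seed(1)
  expect_equal(match_and_count(shuffle(g), shuffle(p)), c_all)
  per <- match_and_count(g, p, per_ade = TRUE)
  expect_equal(colSums(per[, c("TP", "FP", "TN", "FN")]),
               unlist(c_all[c("TP", "FP", "TN", "FN")]))
})

test_that("gold JSONL round-trips and the CSV report has the table layout", {
  g <- gold_df(list("d1", "nausea", 1, 6, "positive"),
               list("d1", "dizziness", 10, 18, "negative"))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_gold(g, f)
  expect_equal(read_gold(f)[names(g)], g, ignore_attr = TRUE)

  p <- pred_df(list("d1", "nausea", 1, 6, "positive"),
               list("d1", "dizziness", 10, 18, "negative"))
  rep <- evaluate_annotations(g, p, per_ade = TRUE)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rep, csv)
  got <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(names(got),
               c("ADE", "Total", "TP", "TN", "Precision", "Sensitivity",
                 "Specificity", "Accuracy", "F-measure"))
  expect_equal(got$Total, c(1, 1))
})
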