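# Evaluation against gold-standard annotations.

# Pair gold and predicted mentions within each (doc_id, ade_concept) by span
# overlap, preferring exact spans.  Returns a data frame with one row per
# gold mention (pred_status NA when unmatched) plus one row per unpaired
# prediction (gold_status NA).
pair_annotations <- function(gold, pred) {
  pred_status <- if ("ade_status" %in% names(pred)) pred$ade_status else
    pred$gold_status
  p <- new_df(doc_id = pred$doc_id,
              concept = if ("ade_type" %in% names(pred)) pred$ade_type else
                pred$ade_concept,
              start = pred$start, end = pred$end, status = pred_status,
              used = logical(nrow(pred)))
  out <- vector("list", nrow(gold) + nrow(p))
  k <- 0L
  for (i in seq_len(nrow(gold))) {
    cand <- which(!p$used & p$doc_id == gold$doc_id[i] &
                    p$concept == gold$ade_concept[i] &
                    p$start <= gold$end[i] & p$end >= gold$start[i])
    k <- k + 1L
    if (length(cand) == 0) {
      out[[k]] <- new_df(doc_id = gold$doc_id[i],
                         ade_concept = gold$ade_concept[i],
                         gold_status = gold$gold_status[i],
                         pred_status = NA_character_, exact = NA)
      next
    }
    exact <- cand[p$start[cand] == gold$start[i] &
                    p$end[cand] == gold$end[i]]
    j <- if (length(exact) > 0) exact[1] else {
      ov <- pmin(p$end[cand], gold$end[i]) - pmax(p$start[cand],
                                                  gold$start[i])
      cand[which.max(ov)]
    }
    p$used[j] <- TRUE
    out[[k]] <- new_df(doc_id = gold$doc_id[i],
                       ade_concept = gold$ade_concept[i],
                       gold_status = gold$gold_status[i],
                       pred_status = p$status[j],
                       exact = p$start[j] == gold$start[i] &
                         p$end[j] == gold$end[i])
  }
  for (j in which(!p$used)) {
    k <- k + 1L
    out[[k]] <- new_df(doc_id = p$doc_id[j], ade_concept = p$concept[j],
                       gold_status = NA_character_,
                       pred_status = p$status[j], exact = NA)
  }
  if (k == 0) {
    return(new_df(doc_id = character(), ade_concept = character(),
                  gold_status = character(), pred_status = character(),
                  exact = logical()))
  }
  do.call(rbind, out[seq_len(k)])
}

count_cells <- function(pairs, partial = c("negative", "strict")) {
  partial <- match.arg(partial)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gold_status[i]
    q <- pairs$pred_status[i]
    if (is.na(g)) {            # unpaired prediction
      if (identical(q, "positive")) fp <- fp + 1L
      next
    }
    if (is.na(q)) {            # unpaired gold mention
      if (g == "positive") fn <- fn + 1L else tn <- tn + 1L
      next
    }
    if (!isTRUE(pairs$exact[i]) && g != q && partial == "negative") {
      # partial-overlap pair with conflicting status resolves to TN
      tn <- tn + 1L
      next
    }
    if (g == "positive" && q == "positive") tp <- tp + 1L
    else if (g == "negative" && q == "negative") tn <- tn + 1L
    else if (g == "negative" && q == "positive") fp <- fp + 1L
    else fn <- fn + 1L
  }
  new_df(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Match predictions to gold annotations and count the confusion cells
#'
#' Mentions are paired within each document and ADE concept by span overlap
#' (exact spans preferred).  TP: both positive; TN: both negative; FP:
#' predicted positive, gold negative; FN: predicted negative, gold positive.
#' Unpaired gold positives count as FN (unpaired gold negatives as TN), and
#' unpaired predicted positives as FP.  Pairs that overlap only partially
#' and disagree on status resolve to the negative cell (TN) under the
#' default `partial = "negative"` policy; use `partial = "strict"` to count
#' them as ordinary errors instead.
#'
#' @param gold Gold data frame (`doc_id`, `ade_concept`, `start`, `end`,
#'   `gold_status`).
#' @param pred Annotation data frame from [annotate_document()] /
#'   [annotate_corpus()].
#' @param per_ade If `TRUE`, return one row of counts per ADE concept.
#' @param partial Handling of partial-overlap status conflicts (see above).
#' @return Data frame of counts (`TP`, `FP`, `TN`, `FN`), with an
#'   `ade_concept` column when `per_ade = TRUE`.
#' @export
match_and_count <- function(gold, pred, per_ade = FALSE,
                            partial = c("negative", "strict")) {
  partial <- match.arg(partial)
  if (nrow(gold) > 0 && nrow(pred) > 0) {
    orphan <- setdiff(unique(pred$doc_id), unique(gold$doc_id))
    if (length(orphan) > 0) {
      stop("prediction doc_id(s) absent from gold corpus: ",
           paste(utils::head(orphan, 3), collapse = ", "), call. = FALSE)
    }
  }
  pairs <- pair_annotations(gold, pred)
  if (!per_ade) return(count_cells(pairs, partial))
  concepts <- sort(unique(pairs$ade_concept))
  out <- lapply(concepts, function(cc) {
    cbind(new_df(ade_concept = cc),
          count_cells(pairs[pairs$ade_concept == cc, , drop = FALSE],
                      partial))
  })
  do.call(rbind, out)
}

#' Compute the evaluation metrics from confusion counts
#'
#' precision = TP/(TP+FP); sensitivity (recall) = TP/(TP+FN); specificity =
#' TN/(TN+FP); accuracy = (TP+TN)/total; F-measure = 2PR/(P+R).  Ratios with
#' a zero denominator are reported as `NA`, never 0.
#'
#' @param counts Data frame or list with `TP`, `FP`, `TN`, `FN` (one row, or
#'   several rows e.g. from `match_and_count(per_ade = TRUE)`).
#' @return Data frame with columns `total`, `precision`, `sensitivity`,
#'   `specificity`, `accuracy`, `f_measure` (plus any id columns of the
#'   input).
#' @export
compute_metrics <- function(counts) {
  counts <- as.data.frame(counts)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (any(total == 0)) stop("empty evaluation set", call. = FALSE)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  precision <- ratio(tp, tp + fp)
  sensitivity <- ratio(tp, tp + fn)
  f <- ifelse(!is.na(precision) & !is.na(sensitivity) &
                (precision + sensitivity) > 0,
              2 * precision * sensitivity / (precision + sensitivity),
              NA_real_)
  cbind(counts, new_df(total = total,
                       precision = precision,
                       sensitivity = sensitivity,
                       specificity = ratio(tn, tn + fp),
                       accuracy = (tp + tn) / total,
                       f_measure = f))
}

#' Score a predicted corpus against gold annotations
#'
#' Convenience wrapper: [match_and_count()] then [compute_metrics()].
#'
#' @inheritParams match_and_count
#' @return Metrics data frame (one row overall, or one per ADE concept).
#' @export
evaluate_annotations <- function(gold, pred, per_ade = FALSE,
                                 partial = c("negative", "strict")) {
  compute_metrics(match_and_count(gold, pred, per_ade = per_ade,
                                  partial = match.arg(partial)))
}

#' Per-gold-mention agreement with the pipeline
#'
#' For each gold mention, reports the paired predicted status and whether
#' the pipeline classified it correctly.  Used e.g. to check that every
#' mention classified correctly under paragraph scope stays correct under
#' clause scope.
#'
#' @inheritParams match_and_count
#' @return The gold data frame with added `pred_status` and `correct`
#'   columns (unpaired gold mentions count as incorrect).
#' @export
classification_agreement <- function(gold, pred) {
  pairs <- pair_annotations(gold, pred)
  pairs <- pairs[!is.na(pairs$gold_status), , drop = FALSE]
  pairs$correct <- !is.na(pairs$pred_status) &
    pairs$pred_status == pairs$gold_status
  pairs
}

#' Write a per-ADE metrics report as CSV
#'
#' Columns follow the conventional report order: ADE, Total, TP, TN,
#' Precision, Sensitivity, Specificity, Accuracy, F-measure (rounded to two
#' decimals at presentation time only).
#'
#' @param report Output of `evaluate_annotations(per_ade = TRUE)`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_metrics_csv <- function(report, path) {
  out <- new_df(ADE = report$ade_concept %||% "overall",
                Total = report$total, TP = report$TP, TN = report$TN,
                Precision = round(report$precision, 2),
                Sensitivity = round(report$sensitivity, 2),
                Specificity = round(report$specificity, 2),
                Accuracy = round(report$accuracy, 2),
                `F-measure` = round(report$f_measure, 2),
                check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
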