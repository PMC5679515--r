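# Readers and writers.  File formats use 0-based half-open character
# offsets (the BRAT standoff convention); in-memory data frames use R's
# 1-based inclusive offsets.  The conversion happens only here.

to_file_offsets <- function(df) {
  df$start <- df$start - 1L
  df
}

from_file_offsets <- function(df) {
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df
}

#' Read a corpus of documents
#'
#' Accepts either a JSON-lines file of `{"id": ..., "text": ...}` records or
#' a directory of plain-text files (one document per file; the file name
#' without extension becomes the document id).
#'
#' @param path File or directory path.
#' @return Data frame with columns `id`, `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    return(new_df(id = sub("\\.txt$", "", basename(files)),
                  text = vapply(files, function(f)
                    paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                          collapse = "\n"), character(1))))
  }
  recs <- jsonlite::stream_in(file(path), verbose = FALSE)
  if (!all(c("id", "text") %in% names(recs))) {
    stop("corpus JSONL must contain 'id' and 'text' fields", call. = FALSE)
  }
  new_df(id = as.character(recs$id), text = as.character(recs$text))
}

#' Write annotations to JSONL or BRAT standoff
#'
#' JSONL writes one JSON object per annotation with all fields; offsets are
#' converted to 0-based half-open.  BRAT writes a standoff `.ann` file with
#' one `T` line per mention (span and ADE type) and `A` attribute lines for
#' Experiencer, Negation, Temporality, Categorical_Value and ADE_status;
#' when `text` is supplied the matching source `.txt` is written alongside
#' so offsets line up byte for byte.
#'
#' @param annotations Annotation data frame from [annotate_document()].
#' @param path Output file path (for BRAT, the `.ann` path).
#' @param format `"jsonl"` or `"brat"`.
#' @param text For `format = "brat"`, the source document text; written to
#'   the sibling `.txt` file when supplied.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path,
                              format = c("jsonl", "brat"), text = NULL) {
  format <- match.arg(format)
  if (format == "jsonl") {
    out <- to_file_offsets(annotations)
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, , drop = FALSE]), auto_unbox = TRUE,
                       na = "null", digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  ann <- to_file_offsets(annotations)
  lines <- character(0)
  aid <- 0L
  for (i in seq_len(nrow(ann))) {
    surface <- substr(text %||% "", annotations$start[i], annotations$end[i])
    if (is.null(text)) surface <- ann$ade_type[i]
    lines <- c(lines, sprintf("T%d\t%s %d %d\t%s", i, "ADE",
                              ann$start[i], ann$end[i], surface))
    attrs <- c(Experiencer = ann$experiencer[i],
               Negation = ann$negation[i],
               Temporality = ann$temporality[i],
               Categorical_Value = ann$categorical_value[i],
               ADE_status = ann$ade_status[i])
    for (nm in names(attrs)) {
      aid <- aid + 1L
      lines <- c(lines, sprintf("A%d\t%s T%d %s", aid, nm, i, attrs[[nm]]))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  if (!is.null(text)) {
    txt_path <- sub("\\.ann$", ".txt", path)
    if (identical(txt_path, path)) txt_path <- paste0(path, ".txt")
    con2 <- file(txt_path, open = "wb")
    writeChar(text, con2, eos = NULL)
    close(con2)
  }
  invisible(path)
}

#' Read annotations back from JSONL
#'
#' Inverse of [write_annotations()] for the JSONL format.
#'
#' @param path JSONL file path.
#' @return Annotation data frame (1-based inclusive offsets).
#' @export
read_annotations <- function(path) {
  recs <- jsonlite::stream_in(file(path), verbose = FALSE)
  if (nrow(recs) == 0) return(empty_annotations())
  recs$refinement_rule <- as.character(recs$refinement_rule)
  from_file_offsets(recs)
}

#' Write gold-standard annotations to JSONL
#'
#' @param gold Data frame with columns `doc_id`, `ade_concept`, `start`,
#'   `end`, `gold_status` (1-based inclusive offsets in memory).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gold <- function(gold, path) {
  out <- to_file_offsets(gold)
  lines <- vapply(seq_len(nrow(out)), function(i) {
    jsonlite::toJSON(as.list(out[i, , drop = FALSE]), auto_unbox = TRUE,
                     na = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read gold-standard annotations from JSONL
#'
#' @param path JSONL file with `doc_id`, `ade_concept`, `start`, `end`,
#'   `gold_status` fields (0-based half-open offsets on disk).
#' @return Gold data frame with 1-based inclusive offsets.
#' @export
read_gold <- function(path) {
  recs <- jsonlite::stream_in(file(path), verbose = FALSE)
  need <- c("doc_id", "ade_concept", "start", "end", "gold_status")
  miss <- setdiff(need, names(recs))
  if (length(miss) > 0) {
    stop("gold JSONL missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  from_file_offsets(recs)
}
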