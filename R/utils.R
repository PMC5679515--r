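# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Collapse runs of whitespace to single spaces and trim the ends.
squish <- function(x) {
  stringi::stri_trim_both(stringi::stri_replace_all_regex(x, "\\s+", " "))
}

# Escape regex metacharacters, leaving spaces to be generalised separately.
escape_regex <- function(x) {
  stringi::stri_replace_all_regex(x, "([\\\\.^$|()\\[\\]{}*+?/#&~-])", "\\\\$1")
}

# Word-ish token spans (letters, digits, apostrophes), 1-based inclusive.
token_spans <- function(text) {
  loc <- stringi::stri_locate_all_regex(text, "[\\p{L}\\p{N}']+")[[1]]
  if (all(is.na(loc[, 1]))) loc <- loc[0, , drop = FALSE]
  loc
}

# Number of tokens lying strictly between two spans (inclusive coordinates).
tokens_between <- function(toks, left_end, right_start) {
  if (nrow(toks) == 0) return(0L)
  sum(toks[, 1] > left_end & toks[, 2] < right_start)
}

# Trim a [start, end] span of `text` so it excludes leading/trailing
# whitespace; returns c(NA, NA) when nothing remains.
trim_span <- function(text, start, end) {
  if (is.na(start) || start > end) return(c(NA_integer_, NA_integer_))
  seg <- substr(text, start, end)
  m <- stringi::stri_locate_first_regex(seg, "\\S")
  if (is.na(m[1, 1])) return(c(NA_integer_, NA_integer_))
  first <- start + m[1, 1] - 1L
  m2 <- stringi::stri_locate_last_regex(seg, "\\S")
  last <- start + m2[1, 2] - 1L
  c(as.integer(first), as.integer(last))
}

new_df <- function(...) data.frame(..., stringsAsFactors = FALSE)

empty_hits <- function() {
  new_df(text_id = integer(), start = integer(), end = integer(),
         surface = character(), entry = character(), canonical = character(),
         category = character(), subcategory = character(),
         direction = character())
}
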