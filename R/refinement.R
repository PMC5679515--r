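#' Load the retention/removal rule catalogue
#'
#' The refinement stage corrects the two systematic failure modes of plain
#' trigger-term context classification: *retention* rules rescue mentions
#' that are surrounded by negation but are nevertheless positive (the
#' negation scopes over drug administration or a change-of-state verb, not
#' the event itself), and *removal* rules negate mentions that carry no
#' negation trigger but occur in warnings, monitoring or explanation
#' clauses, uncertainty contexts, questionnaire fragments, or organisation
#' names/addresses.  The bundled catalogue registers 9 retention and 26
#' removal rules as a declarative TSV (pattern = ordered sequence of
#' lexicon-subcategory slots, literal token alternations and bounded
#' wildcards, or a small set of built-in surface detectors), so users can
#' extend it.
#'
#' @param path Path to a rule TSV; `NULL` loads the bundled catalogue.
#' @return Data frame of class `clinade_rules` with columns `rule_id`,
#'   `action` (`retain`/`remove`), `category`, `scope` (`clause`/`sentence`),
#'   `type`, `pattern`, `description`.  Rules are applied in file order;
#'   the first match wins within each action.
#' @export
load_rule_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rules", "refinement_rules.tsv",
                        package = "clinade")
  }
  if (!file.exists(path)) stop("rule catalogue not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8", colClasses = "character")
  need <- c("rule_id", "action", "category", "scope", "type", "pattern")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("rule catalogue missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$action %in% c("retain", "remove"))
  if (length(bad) > 0) {
    stop("unknown rule action '", df$action[bad[1]], "' for rule ",
         df$rule_id[bad[1]], call. = FALSE)
  }
  if (anyDuplicated(df$rule_id)) stop("duplicate rule_id in catalogue",
                                      call. = FALSE)
  class(df) <- c("clinade_rules", "data.frame")
  compile_rule_catalogue(df)
}

# Pre-parse token patterns and build the combined literal vocabulary so the
# engine scans each clause once for all rule literals.
compile_rule_catalogue <- function(df) {
  parsed <- stats::setNames(vector("list", nrow(df)), df$rule_id)
  words <- character(0)
  for (i in seq_len(nrow(df))) {
    if (df$type[i] == "tokens") {
      elems <- parse_token_pattern(df$pattern[i])
      parsed[[i]] <- elems
      for (el in elems) {
        if (el$kind == "literal") {
          words <- c(words, tolower(strsplit(el$value, "|",
                                             fixed = TRUE)[[1]]))
        }
      }
    }
  }
  words <- unique(words)
  vocab_pattern <- paste0(
    "(?<![\\p{L}\\p{N}])(?:",
    paste(escape_regex(words[order(-nchar(words))]), collapse = "|"),
    ")(?![\\p{L}\\p{N}])")
  attr(df, "parsed") <- parsed
  attr(df, "vocab_pattern") <- vocab_pattern
  df
}

no_outcome <- function() {
  list(rule_id = NA_character_, action = "none", category = NA_character_,
       evidence_start = NA_integer_, evidence_end = NA_integer_)
}

# Parse a token pattern into a list of elements with gap constraints.
parse_token_pattern <- function(pattern) {
  parts <- strsplit(squish(pattern), " ", fixed = TRUE)[[1]]
  elems <- list()
  gap <- 0L
  for (p in parts) {
    if (grepl("^\\.\\.[0-9]+$", p)) {
      gap <- as.integer(sub("^\\.\\.", "", p))
    } else {
      kind <- if (grepl("^<.*>$", p)) "slot" else "literal"
      elems[[length(elems) + 1L]] <- list(
        kind = kind,
        value = if (kind == "slot") gsub("[<>]", "", p) else p,
        gap_before = if (length(elems) == 0) NA_integer_ else gap)
      gap <- 0L
    }
  }
  elems
}

# Candidate spans (doc-absolute, one row per hit, sorted by start) for a
# pattern element evaluated inside one clause.  `env` caches per-clause
# anchor scans; all rule literals are located with one combined vocabulary
# scan per clause.
element_spans <- function(elem, mention, clause, text, lexicon, env,
                          vocab_pattern) {
  seg_key <- paste0("seg", clause$clause_id)
  seg <- env[[seg_key]]
  if (is.null(seg)) {
    seg <- substr(text, clause$start, clause$end)
    env[[seg_key]] <- seg
  }
  offset <- clause$start - 1L
  if (elem$kind == "slot") {
    if (elem$value == "ade") {
      return(matrix(c(mention$start, mention$end), ncol = 2))
    }
    key <- paste0(elem$value, "@", clause$clause_id)
    sp <- env[[key]]
    if (is.null(sp)) {
      hits <- switch(elem$value,
        negation = match_terms(seg, lexicon, "contextual", "negation"),
        drug = match_terms(seg, lexicon, "drug"),
        match_terms(seg, lexicon, "helping", elem$value))
      sp <- if (nrow(hits) == 0) matrix(integer(0), ncol = 2) else
        cbind(hits$start + offset, hits$end + offset)
      env[[key]] <- sp
    }
    return(sp)
  }
  vkey <- paste0("vocab@", clause$clause_id)
  vocab <- env[[vkey]]
  if (is.null(vocab)) {
    loc <- stringi::stri_locate_all_regex(
      seg, vocab_pattern,
      opts_regex = stringi::stri_opts_regex(case_insensitive = TRUE))[[1]]
    vocab <- if (all(is.na(loc[, 1]))) {
      list(words = character(0), spans = matrix(integer(0), ncol = 2))
    } else {
      list(words = tolower(substr(rep(seg, nrow(loc)), loc[, 1], loc[, 2])),
           spans = cbind(loc[, 1] + offset, loc[, 2] + offset))
    }
    env[[vkey]] <- vocab
  }
  want <- tolower(strsplit(elem$value, "|", fixed = TRUE)[[1]])
  vocab$spans[vocab$words %in% want, , drop = FALSE]
}

# Depth-first leftmost search for a chain of element spans satisfying the
# token-gap constraints; returns c(start, end) of the evidence or NULL.
match_token_pattern <- function(elems, mention, clause, text, lexicon, env,
                                vocab_pattern) {
  # evaluate elements with early exit: an element with no candidates in the
  # clause rules the pattern out before the remaining elements are scanned
  spans <- vector("list", length(elems))
  for (i in seq_along(elems)) {
    spans[[i]] <- element_spans(elems[[i]], mention, clause, text, lexicon,
                                env, vocab_pattern)
    if (nrow(spans[[i]]) == 0) return(NULL)
  }
  tok_key <- paste0("tok@", clause$clause_id)
  toks <- env[[tok_key]]
  if (is.null(toks)) {
    seg <- substr(text, clause$start, clause$end)
    toks <- token_spans(seg)
    if (nrow(toks) > 0) toks <- toks + clause$start - 1L
    env[[tok_key]] <- toks
  }

  rec <- function(ei, prev_end) {
    cand <- spans[[ei]]
    for (r in seq_len(nrow(cand))) {
      if (!is.na(prev_end)) {
        if (cand[r, 1] <= prev_end) next
        if (tokens_between(toks, prev_end, cand[r, 1]) >
              elems[[ei]]$gap_before) next
      }
      if (ei == length(elems)) return(cand[r, , drop = FALSE])
      res <- rec(ei + 1L, cand[r, 2])
      if (!is.null(res)) return(rbind(cand[r, , drop = FALSE], res))
    }
    NULL
  }
  chain <- rec(1L, NA_integer_)
  if (is.null(chain)) return(NULL)
  c(min(chain[, 1]), max(chain[, 2]))
}

# Built-in surface detectors (removal categories c and d).  Scans that do
# not depend on the mention are cached per (rule, scope span) in `env`.
match_builtin <- function(rule, mention, clause, sentence, text,
                          env = new.env(parent = emptyenv())) {
  scope <- if (identical(rule$scope, "clause")) clause else sentence
  seg <- substr(text, scope$start, scope$end)
  offset <- scope$start - 1L
  ckey <- paste0(rule$rule_id, "@", scope$start, ":", scope$end)
  cached_spans <- function(compute) {
    sp <- env[[ckey]]
    if (is.null(sp)) {
      sp <- compute()
      env[[ckey]] <- sp
    }
    sp
  }
  contains_mention <- function(spans) {
    hit <- which(spans[, 1] <= mention$start & spans[, 2] >= mention$end)
    if (length(hit) == 0) return(NULL)
    c(spans[hit[1], 1], spans[hit[1], 2])
  }
  locate_spans <- function(pattern, case_insensitive = FALSE) {
    loc <- stringi::stri_locate_all_regex(
      seg, pattern,
      opts_regex = stringi::stri_opts_regex(
        case_insensitive = case_insensitive))[[1]]
    if (all(is.na(loc[, 1]))) matrix(integer(0), ncol = 2) else loc + offset
  }
  switch(rule$type,
    email = contains_mention(cached_spans(function()
      locate_spans("[A-Za-z0-9._%+-]+@[A-Za-z0-9][A-Za-z0-9.-]*"))),
    url = contains_mention(cached_spans(function()
      locate_spans("(?:https?://|www\\.)[^\\s]+"))),
    caps_run = {
      runs_m <- cached_spans(function() {
        toks <- token_spans(seg)
        if (nrow(toks) == 0) return(matrix(integer(0), ncol = 2))
        words <- substr(rep(seg, nrow(toks)), toks[, 1], toks[, 2])
        is_caps <- stringi::stri_detect_regex(words, "^[A-Z][A-Z0-9'&-]+$")
        runs <- rle(is_caps)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        sel <- which(runs$values & runs$lengths >= 3)
        if (length(sel) == 0) return(matrix(integer(0), ncol = 2))
        cbind(toks[starts[sel], 1], toks[ends[sel], 2]) + offset
      })
      contains_mention(runs_m)
    },
    slash_adjacent = {
      before <- substr(text, max(scope$start, mention$start - 2L),
                       mention$start - 1L)
      after <- substr(text, mention$end + 1L,
                      min(scope$end, mention$end + 2L))
      if (stringi::stri_detect_regex(before, "/\\s?$")) {
        c(mention$start - nchar(before), mention$end)
      } else if (stringi::stri_detect_regex(after, "^\\s?/")) {
        c(mention$start, mention$end + nchar(after))
      } else NULL
    },
    regex_after = {
      after <- substr(text, mention$end + 1L, sentence$end)
      loc <- stringi::stri_locate_first_regex(after, rule$pattern)
      if (is.na(loc[1, 1])) NULL else
        c(mention$start, mention$end + loc[1, 2])
    },
    regex = ,
    regex_cs = {
      sp <- cached_spans(function()
        locate_spans(rule$pattern,
                     case_insensitive = !identical(rule$type, "regex_cs")))
      if (nrow(sp) == 0) NULL else c(sp[1, 1], sp[1, 2])
    },
    stop("unknown rule type: ", rule$type, call. = FALSE))
}

apply_rule_set <- function(catalogue, action, mention, context, clause,
                           sentence, text, lexicon, env) {
  if (is.null(attr(catalogue, "vocab_pattern"))) {
    catalogue <- compile_rule_catalogue(catalogue)
  }
  parsed <- attr(catalogue, "parsed")
  vocab_pattern <- attr(catalogue, "vocab_pattern")
  idx <- which(catalogue$action == action)
  for (i in idx) {
    rule <- list(rule_id = catalogue$rule_id[i],
                 action = catalogue$action[i],
                 category = catalogue$category[i],
                 scope = catalogue$scope[i],
                 type = catalogue$type[i],
                 pattern = catalogue$pattern[i])
    ev <- if (identical(rule$type, "tokens")) {
      scope <- if (identical(rule$scope, "sentence")) {
        new_df(clause_id = paste0("sent-", sentence$sentence_id),
               start = sentence$start, end = sentence$end)
      } else {
        clause
      }
      elems <- parsed[[rule$rule_id]] %||% parse_token_pattern(rule$pattern)
      match_token_pattern(elems, mention, scope, text, lexicon, env,
                          vocab_pattern)
    } else {
      match_builtin(rule, mention, clause, sentence, text, env)
    }
    if (!is.null(ev)) {
      return(list(rule_id = rule$rule_id,
                  action = if (rule$action == "retain") "retain_positive"
                           else "mark_negative",
                  category = rule$category,
                  evidence_start = as.integer(ev[1]),
                  evidence_end = as.integer(ev[2])))
    }
  }
  no_outcome()
}

#' Apply the retention rules to one mention
#'
#' Retention rules fire only on mentions the context engine has negated;
#' they recognise negations whose object is drug administration or a
#' change-of-state verb rather than the event itself, and retain the mention
#' as positive.  The first matching rule in catalogue order wins.
#'
#' @param mention One-row mention data frame (from [detect_mentions()]).
#' @param context Context assignment from [assign_context()].
#' @param clause,sentence One-row span data frames containing the mention.
#' @param text The document string.
#' @param lexicon A `clinade_lexicon`.
#' @param catalogue A `clinade_rules` catalogue.
#' @param env Optional environment caching per-clause term scans.
#' @return A refinement outcome: list with `rule_id`, `action`
#'   (`retain_positive` or `none`), `category`, `evidence_start`,
#'   `evidence_end`.
#' @export
apply_retention_rules <- function(mention, context, clause, sentence, text,
                                  lexicon, catalogue,
                                  env = new.env(parent = emptyenv())) {
  if (!identical(context$negation, "negated")) return(no_outcome())
  apply_rule_set(catalogue, "retain", mention, context, clause, sentence,
                 text, lexicon, env)
}

#' Apply the removal rules to one mention
#'
#' Removal rules mark mentions negative when the clause (or sentence, for
#' layout-level patterns) shows the mention is not an actual occurrence:
#' warnings/monitoring/explanations (category a), uncertainty (b),
#' questionnaire fragments (c), and organisation names, emails, URLs or
#' addresses (d).  First matching rule in catalogue order wins.
#'
#' @inheritParams apply_retention_rules
#' @return A refinement outcome: list with `rule_id`, `action`
#'   (`mark_negative` or `none`), `category`, `evidence_start`,
#'   `evidence_end`.
#' @export
apply_removal_rules <- function(mention, context, clause, sentence, text,
                                lexicon, catalogue,
                                env = new.env(parent = emptyenv())) {
  apply_rule_set(catalogue, "remove", mention, context, clause, sentence,
                 text, lexicon, env)
}

#' Resolve context and refinement outcomes into a final negation state
#'
#' The override order is total: retention beats removal beats the context
#' assignment.  A fired retention rule makes the mention affirmed (hence
#' positive) regardless of removal and of the context negation; otherwise a
#' fired removal rule makes it negated; otherwise the context assignment
#' stands.
#'
#' @param context Context assignment from [assign_context()].
#' @param retention,removal Outcomes from [apply_retention_rules()] and
#'   [apply_removal_rules()].
#' @return List with `negation` (`"affirmed"`/`"negated"`) and `rule_id`
#'   (the deciding rule, or `NA` if none fired).
#' @export
resolve_refinement <- function(context, retention, removal) {
  if (identical(retention$action, "retain_positive")) {
    list(negation = "affirmed", rule_id = retention$rule_id)
  } else if (identical(removal$action, "mark_negative")) {
    list(negation = "negated", rule_id = removal$rule_id)
  } else {
    list(negation = context$negation, rule_id = NA_character_)
  }
}
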