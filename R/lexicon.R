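#' Lexicon: the term dictionary driving every pipeline stage
#'
#' The pipeline is driven by a four-category dictionary: `ade` terms (the
#' adverse-event surface forms to annotate, each mapped to a canonical
#' concept), `drug` terms, `helping` terms (occurrence, drug administration,
#' monitoring, negative-effect and drug-link phrases used by the refinement
#' rules) and `contextual` trigger terms (experiencer, negation, possibility,
#' termination, and temporality/hypothetical indicators used by the
#' clause-scoped context engine).
#'
#' Each entry carries a `surface` (the literal form matched in text), a
#' `canonical` label (e.g. `"sedation"` for `"drowsy"`; for contextual
#' entries the context value the trigger drives), a `subcategory` (helping
#' and contextual entries only), a per-entry `case_sensitive` flag (off by
#' default; used for acronyms such as `"SE"`), and for contextual entries a
#' scope `direction` (`forward`, `backward` or `bidirectional`).
#'
#' @param paths Named list/character vector with elements `ade`, `drug`,
#'   `helping` and `contextual`, each the path of a UTF-8 TSV file with a
#'   header containing at least `surface`; optional columns are `canonical`,
#'   `subcategory`, `case_sensitive` (0/1) and `direction`.  `NULL` (the
#'   default) loads the dictionary bundled with the package.
#' @return An object of class `clinade_lexicon`: a list with `entries`
#'   (a data frame) and a pattern cache.  Per-category entry counts are
#'   available via [lexicon_counts()].
#' @examples
#' lex <- load_lexicon()
#' lexicon_counts(lex)
#' @export
load_lexicon <- function(paths = NULL) {
  if (is.null(paths)) paths <- default_lexicon_paths()
  paths <- as.list(paths)
  need <- c("ade", "drug", "helping", "contextual")
  missing_cat <- setdiff(need, names(paths))
  if (length(missing_cat) > 0) {
    stop("lexicon configuration is missing the ",
         paste(missing_cat, collapse = ", "), " categor",
         if (length(missing_cat) > 1) "ies" else "y", call. = FALSE)
  }
  parts <- lapply(need, function(cat) {
    path <- paths[[cat]]
    if (!file.exists(path)) {
      stop("lexicon file for category '", cat, "' not found: ", path,
           call. = FALSE)
    }
    read_lexicon_file(path, cat)
  })
  lexicon_from_entries(do.call(rbind, parts))
}

read_lexicon_file <- function(path, category) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8",
                          colClasses = "character")
  if (!"surface" %in% names(df)) {
    stop("lexicon file for category '", category,
         "' has no 'surface' column: ", path, call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop("no entries for category ", category, call. = FALSE)
  }
  df$category <- category
  if (is.null(df$canonical) || all(df$canonical == "")) {
    df$canonical <- df$surface
  }
  df$canonical[df$canonical == ""] <- df$surface[df$canonical == ""]
  if (is.null(df$subcategory)) df$subcategory <- NA_character_
  df$subcategory[df$subcategory %in% ""] <- NA_character_
  df$case_sensitive <- if (is.null(df$case_sensitive)) FALSE else
    df$case_sensitive %in% c("1", "TRUE", "true", "yes")
  if (is.null(df$direction)) df$direction <- NA_character_
  df$direction[df$direction %in% ""] <- NA_character_
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  df[, c("surface", "canonical", "category", "subcategory",
         "case_sensitive", "direction", "line")]
}

#' Build a lexicon from an in-memory entry table
#'
#' Mainly useful for tests and for programmatic dictionary extension.
#'
#' @param entries Data frame with columns `surface`, `category` and
#'   optionally `canonical`, `subcategory`, `case_sensitive`, `direction`.
#' @return A `clinade_lexicon` object.
#' @export
lexicon_from_entries <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (is.null(entries$canonical)) entries$canonical <- entries$surface
  if (is.null(entries$subcategory)) entries$subcategory <- NA_character_
  if (is.null(entries$case_sensitive)) entries$case_sensitive <- FALSE
  entries$case_sensitive <- as.logical(entries$case_sensitive)
  if (is.null(entries$direction)) entries$direction <- NA_character_
  if (is.null(entries$line)) entries$line <- seq_len(nrow(entries))

  entries$surface <- squish(entries$surface)
  bad <- which(is.na(entries$surface) | entries$surface == "")
  if (length(bad) > 0) {
    stop("empty surface in category '", entries$category[bad[1]],
         "' at line ", entries$line[bad[1]], call. = FALSE)
  }
  valid_cat <- c("ade", "drug", "helping", "contextual")
  bad <- which(!entries$category %in% valid_cat)
  if (length(bad) > 0) {
    stop("unknown category '", entries$category[bad[1]], "'", call. = FALSE)
  }
  allowed_sub <- list(
    helping = c("occurrence", "administration", "monitoring",
                "negative_effect", "drug_link"),
    contextual = c("experiencer", "negation", "possibility", "termination",
                   "temporality_hypothetical")
  )
  for (cat in names(allowed_sub)) {
    rows <- entries$category == cat
    bad <- which(rows & (is.na(entries$subcategory) |
                           !entries$subcategory %in% allowed_sub[[cat]]))
    if (length(bad) > 0) {
      stop("unknown or missing subcategory '", entries$subcategory[bad[1]],
           "' for category '", cat, "' at line ", entries$line[bad[1]],
           call. = FALSE)
    }
  }
  # subcategory is carried only by helping/contextual entries
  entries$subcategory[entries$category %in% c("ade", "drug")] <- NA_character_

  key <- paste(tolower(entries$surface), entries$category,
               entries$subcategory, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate lexicon entr",
            if (sum(dup) > 1) "ies" else "y", " collapsed", call. = FALSE)
    entries <- entries[!dup, , drop = FALSE]
  }
  # default trigger directions: contextual triggers are forward unless the
  # table marks them otherwise
  fill <- entries$category == "contextual" & is.na(entries$direction)
  entries$direction[fill] <- "forward"
  rownames(entries) <- NULL
  entries$line <- NULL
  lex <- list(entries = entries, cache = new.env(parent = emptyenv()))
  class(lex) <- "clinade_lexicon"
  lex
}

#' @export
print.clinade_lexicon <- function(x, ...) {
  cat("<clinade_lexicon> with", nrow(x$entries), "entries\n")
  print(lexicon_counts(x))
  invisible(x)
}

#' Per-category (and per-subcategory) entry counts of a lexicon
#'
#' @param lexicon A `clinade_lexicon`.
#' @return Data frame with columns `category`, `subcategory`, `n`.
#' @export
lexicon_counts <- function(lexicon) {
  e <- lexicon$entries
  agg <- stats::aggregate(list(n = seq_len(nrow(e))),
                          by = list(category = e$category,
                                    subcategory = ifelse(is.na(e$subcategory),
                                                         "", e$subcategory)),
                          FUN = length)
  agg[order(agg$category, agg$subcategory), , drop = FALSE]
}

#' Write a lexicon back to the four-file TSV layout
#'
#' Inverse of [load_lexicon()]: `load_lexicon(write_lexicon(lex, dir))`
#' reproduces the same entry set.
#'
#' @param lexicon A `clinade_lexicon`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_lexicon <- function(lexicon, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cats <- c("ade", "drug", "helping", "contextual")
  paths <- stats::setNames(file.path(dir, paste0(cats, ".tsv")), cats)
  for (cat in cats) {
    e <- lexicon$entries[lexicon$entries$category == cat, , drop = FALSE]
    out <- new_df(surface = e$surface, canonical = e$canonical,
                  subcategory = ifelse(is.na(e$subcategory), "",
                                       e$subcategory),
                  case_sensitive = as.integer(e$case_sensitive),
                  direction = ifelse(is.na(e$direction), "", e$direction))
    utils::write.table(out, paths[[cat]], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(paths)
}

default_lexicon_paths <- function() {
  dir <- system.file("extdata", "lexicon", package = "clinade")
  stats::setNames(file.path(dir, c("ade.tsv", "drug.tsv", "helping.tsv",
                                   "contextual.tsv")),
                  c("ade", "drug", "helping", "contextual"))
}

# Compiled scanning artefacts for one (category, subcategory) selection:
# one alternation regex per (case-sensitivity, boundary-class) group, plus a
# key -> entry-row map.  Cached inside the lexicon object.
scan_index <- function(lexicon, category, subcategory = NULL) {
  key <- paste(category, subcategory %||% "*", sep = "|")
  cached <- lexicon$cache[[key]]
  if (!is.null(cached)) return(cached)
  e <- lexicon$entries
  rows <- which(e$category == category &
                  (is.null(subcategory) | e$subcategory %in% subcategory))
  sel <- e[rows, , drop = FALSE]
  idx <- list(groups = list(), rows = rows, entries = sel)
  if (nrow(sel) > 0) {
    norm <- squish(sel$surface)
    first_alnum <- stringi::stri_detect_regex(norm, "^[\\p{L}\\p{N}]")
    last_alnum <- stringi::stri_detect_regex(norm, "[\\p{L}\\p{N}]$")
    grp <- paste0(as.integer(sel$case_sensitive), as.integer(first_alnum),
                  as.integer(last_alnum))
    for (g in unique(grp)) {
      in_g <- grp == g
      surfs <- norm[in_g]
      ord <- order(-nchar(surfs))
      alts <- escape_regex(surfs[ord])
      alts <- stringi::stri_replace_all_fixed(alts, " ", "\\s+")
      ci <- substr(g, 1, 1) == "0"
      pat <- paste0(
        if (substr(g, 2, 2) == "1") "(?<![\\p{L}\\p{N}])" else "",
        "(?:", paste(alts, collapse = "|"), ")",
        if (substr(g, 3, 3) == "1") "(?![\\p{L}\\p{N}])" else "")
      map_keys <- if (ci) tolower(surfs) else surfs
      map <- stats::setNames(which(in_g), map_keys)
      map <- map[!duplicated(names(map))]
      idx$groups[[length(idx$groups) + 1L]] <-
        list(pattern = pat, case_insensitive = ci, map = map)
    }
  }
  lexicon$cache[[key]] <- idx
  idx
}

#' Locate dictionary terms in text
#'
#' Scans each element of `text` (typically a clause) for lexicon surfaces of
#' the requested category.  Matching is case-insensitive unless an entry is
#' flagged case-sensitive, applies at token boundaries (a surface never
#' matches inside a longer word), generalises internal whitespace in
#' multi-word surfaces, and resolves overlaps with the conventional
#' leftmost-longest gazetteer policy, so the returned spans never overlap.
#'
#' @param text Character vector of texts to scan.
#' @param lexicon A `clinade_lexicon`.
#' @param category One of `"ade"`, `"drug"`, `"helping"`, `"contextual"`.
#' @param subcategory Optional subcategory filter (may be a vector).
#' @return Data frame with one row per hit: `text_id` (index into `text`),
#'   `start`, `end` (1-based inclusive character offsets), `surface` (the
#'   matched text), `entry` (the lexicon surface), `canonical`, `category`,
#'   `subcategory`, `direction`; ordered by `text_id` then `start`.
#' @examples
#' lex <- load_lexicon()
#' match_terms("No complaints of dizziness", lex, "ade")
#' @export
match_terms <- function(text, lexicon, category, subcategory = NULL) {
  stopifnot(inherits(lexicon, "clinade_lexicon"))
  if (length(text) == 0) return(empty_hits())
  idx <- scan_index(lexicon, category, subcategory)
  if (length(idx$groups) == 0) return(empty_hits())
  text <- as.character(text)
  per_group <- lapply(idx$groups, function(g) {
    loc <- stringi::stri_locate_all_regex(
      text, g$pattern,
      opts_regex = stringi::stri_opts_regex(case_insensitive =
                                              g$case_insensitive))
    loc
  })
  out <- vector("list", length(text))
  for (i in seq_along(text)) {
    cand <- list()
    for (gi in seq_along(per_group)) {
      loc <- per_group[[gi]][[i]]
      if (nrow(loc) == 0 || is.na(loc[1, 1])) next
      cand[[length(cand) + 1L]] <-
        cbind(loc, group = rep(gi, nrow(loc)))
    }
    if (length(cand) == 0) next
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
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0) next
    surf <- substr(rep(text[i], nrow(m)), m[, 1], m[, 2])
    rowi <- integer(nrow(m))
    for (r in seq_len(nrow(m))) {
      g <- idx$groups[[m[r, 3]]]
      k <- squish(surf[r])
      if (g$case_insensitive) k <- tolower(k)
      rowi[r] <- g$map[[k]]
    }
    sel <- idx$entries[rowi, , drop = FALSE]
    out[[i]] <- new_df(text_id = i, start = as.integer(m[, 1]),
                       end = as.integer(m[, 2]), surface = surf,
                       entry = sel$surface, canonical = sel$canonical,
                       category = sel$category, subcategory = sel$subcategory,
                       direction = sel$direction)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
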