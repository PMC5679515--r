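#' Configuration for the synthetic clinical-note generator
#'
#' The generator emulates the phenomena the pipeline targets in short,
#' noisy, clause-structured psychiatric notes: affirmed and negated ADE
#' mentions, hypothetical and historical discussions, mentions about someone
#' other than the patient, warning/monitoring/explanation clauses,
#' questionnaire fragments, organisation names/emails/URLs, uncertainty
#' qualifiers, and multi-ADE clauses joined by termination terms.  Every ADE
#' insertion is logged as a gold annotation whose status is implied by its
#' template category.
#'
#' @param n_docs Number of documents.
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   corpus.
#' @param ade_concepts Canonical ADE concepts to draw from; defaults to the
#'   19 core antipsychotic/antidepressant ADEs in the bundled dictionary.
#' @param context_mix Named probability vector over the template categories
#'   `affirmed`, `negated`, `hypothetical`, `historical`,
#'   `other_experiencer`, `warning_monitoring`, `questionnaire`,
#'   `org_name_email`, `uncertainty`; must sum to 1.
#' @param multi_ade_clause_rate Probability that a mention-bearing clause
#'   carries two ADE mentions (default 0.05, the approximate rate observed
#'   in psychiatric notes).
#' @param typo_rate Per-word probability of a character transposition in
#'   filler (non-mention, non-trigger) sentences.
#' @return A list of class `clinade_genconfig`.
#' @export
generation_config <- function(n_docs = 100, seed = 1, ade_concepts = NULL,
                              context_mix = NULL,
                              multi_ade_clause_rate = 0.05, typo_rate = 0) {
  if (is.null(ade_concepts)) {
    ade_concepts <- c("agitation", "akathisia", "arrhythmia",
                      "cardiomyopathy", "constipation", "convulsions",
                      "diarrhoea", "dizziness", "dry mouth", "galactorrhoea",
                      "hypersalivation", "insomnia", "myocarditis", "nausea",
                      "pneumonia", "sedation", "sjs", "tachycardia",
                      "weight gain")
  }
  if (is.null(context_mix)) {
    context_mix <- c(affirmed = 0.35, negated = 0.25, hypothetical = 0.06,
                     historical = 0.08, other_experiencer = 0.06,
                     warning_monitoring = 0.10, questionnaire = 0.04,
                     org_name_email = 0.02, uncertainty = 0.04)
  }
  cats <- c("affirmed", "negated", "hypothetical", "historical",
            "other_experiencer", "warning_monitoring", "questionnaire",
            "org_name_email", "uncertainty")
  if (!setequal(names(context_mix), cats)) {
    stop("context_mix must be named over: ", paste(cats, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(context_mix) - 1) > 1e-9) {
    stop("context_mix probabilities must sum to 1", call. = FALSE)
  }
  if (multi_ade_clause_rate < 0 || multi_ade_clause_rate > 1 ||
        typo_rate < 0 || typo_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 ade_concepts = ade_concepts,
                 context_mix = context_mix[cats],
                 multi_ade_clause_rate = multi_ade_clause_rate,
                 typo_rate = typo_rate),
            class = "clinade_genconfig")
}

# Sentence templates per context category.  {ade} is replaced by a surface
# form; {Ade} capitalises it, {ADE} upper-cases it, {ade1w} restricts to
# single-word surfaces.  Templates are worded so that they contain no
# dictionary terms other than the ones they are designed to exercise.
synth_templates <- function() {
  list(
    affirmed = list(
      list(text = "ZZZZZ is complaining of {ade} today.", status = "positive"),
      list(text = "The patient is still suffering from {ade}.",
           status = "positive"),
      list(text = "ZZZZZ continues to experience {ade}.", status = "positive"),
      list(text = "On examination there was marked {ade}.",
           status = "positive"),
      list(text = "ZZZZZ developed {ade} over the weekend.",
           status = "positive")),
    negated = list(
      list(text = "He did not complain of {ade}.", status = "negative"),
      list(text = "No complaints of {ade} today.", status = "negative"),
      list(text = "ZZZZZ denies {ade}.", status = "negative"),
      list(text = "There was no evidence of {ade} on review.",
           status = "negative"),
      list(text = "She has not reported {ade} this week.",
           status = "negative")),
    hypothetical = list(
      list(text = "If {ade} develops, contact the duty team.",
           status = "negative"),
      list(text = "Call the ward if {ade} occurs.", status = "negative"),
      list(text = "Should she develop {ade}, restart the review.",
           status = "negative")),
    historical = list(
      list(text = "ZZZZZ previously experienced {ade}.", status = "negative"),
      list(text = "There is a history of {ade} from years back.",
           status = "negative"),
      list(text = "She had {ade} in the past.", status = "negative")),
    other_experiencer = list(
      list(text = "His mother suffers from {ade}.", status = "negative"),
      list(text = "Her brother reports {ade}.", status = "negative"),
      list(text = "ZZZZZ says her daughter developed {ade}.",
           status = "negative")),
    warning_monitoring = list(
      list(text = "I have warned ZZZZZ of {ade}.", status = "negative"),
      list(text = "Monitor for signs of {ade} at each visit.",
           status = "negative"),
      list(text = "Started olanzapine, explained as it can cause {ade}.",
           status = "negative"),
      list(text = "There is a risk of {ade} with this medication.",
           status = "negative"),
      list(text = "Watch for {ade} over the next week.", status = "negative")),
    questionnaire = list(
      list(text = "{Ade} *No * Yes.", status = "negative"),
      list(text = "{Ade} Yes/No.", status = "negative"),
      list(text = "I have been troubled by {ade} x 3.", status = "negative")),
    org_name_email = list(
      list(text = "Referred to the CENTRE FOR {ADE} DISORDERS AND TRAUMA.",
           status = "negative"),
      list(text = "Contact {ade1w}@sydenham.lewisham.sch.uk for records.",
           status = "negative"),
      list(text = "See www.nhs.uk/conditions/{ade1w} for details.",
           status = "negative")),
    uncertainty = list(
      list(text = "Query {ade}.", status = "negative"),
      list(text = "Unstable {ade} noted on the ward.", status = "negative"),
      list(text = "{Ade}? To be reviewed.", status = "negative"))
  )
}

synth_multi_templates <- function() {
  list(
    list(text = "ZZZZZ is still complaining of {a} but not {b}.",
         status = c("positive", "negative")),
    list(text = "ZZZZZ reports both {a} and {b} this week.",
         status = c("positive", "positive"))
  )
}

synth_fillers <- function() {
  c("ZZZZZ spent the morning in the communal area.",
    "Attended art group and engaged with staff.",
    "Slept through the night without incident.",
    "Ate breakfast in the dining room.",
    "Seen by the duty doctor during the morning round.",
    "Care plan updated this afternoon.",
    "ZZZZZ watched television in the lounge.",
    "Escorted leave to the local shop went ahead as planned.",
    "Family visit took place in the garden.",
    "Remains settled on the current plan.")
}

# Canonical fixture documents: worked examples of every pipeline behaviour,
# emitted as the first documents whenever n_docs >= 19 so regression tests
# can pin them.  Gold entries: surface, occurrence index, concept, status.
synth_fixtures <- function() {
  g <- function(surface, occ, concept, status) {
    new_df(surface = surface, occ = occ, concept = concept, status = status)
  }
  list(
    list(text = paste("Late shift ZZZZZ has wandered in and out of her room",
                      "throughout the afternoon. No complaints of dizziness."),
         gold = g("dizziness", 1, "dizziness", "negative")),
    list(text = paste("He did not complain of constipation. The patient is",
                      "still suffering from a light headache."),
         gold = rbind(g("constipation", 1, "constipation", "negative"),
                      g("headache", 1, "headache", "positive"))),
    list(text = "The patient is still complaining of headache but not constipation.",
         gold = rbind(g("headache", 1, "headache", "positive"),
                      g("constipation", 1, "constipation", "negative"))),
    list(text = "ZZZZZ appeared to be disorientated and not taking his medication.",
         gold = g("disorientated", 1, "disorientation", "positive")),
    list(text = "ZZZZZ restlessness has not worsened on the increased dose of beta-blocker.",
         gold = g("restlessness", 1, "restlessness", "positive")),
    list(text = "I am changing the dose and have warned ZZZZ of dizziness.",
         gold = g("dizziness", 1, "dizziness", "negative")),
    list(text = "Signs of myocarditis, on going investigation.",
         gold = g("myocarditis", 1, "myocarditis", "negative")),
    list(text = "The patient is starting Olanzapine, explained her as it can cause weight gain.",
         gold = g("weight gain", 1, "weight gain", "negative")),
    list(text = "She has had 4 seizures within the last 2 weeks, unstable partial complex seizures.",
         gold = rbind(g("seizures", 1, "convulsions", "positive"),
                      g("seizures", 2, "convulsions", "negative"))),
    list(text = "Fainting/ dizziness *No * Yes.",
         gold = rbind(g("Fainting", 1, "fainting", "negative"),
                      g("dizziness", 1, "dizziness", "negative"))),
    list(text = "I become irritable, restless and nervous x 5.",
         gold = rbind(g("irritable", 1, "irritability", "negative"),
                      g("restless", 1, "restlessness", "negative"))),
    list(text = "Referred by the CENTRE FOR ANXIETY DISORDERS AND TRAUMA.",
         gold = g("ANXIETY", 1, "anxiety", "negative")),
    list(text = "Please email sjs@sydenham.lewisham.sch.uk with any queries.",
         gold = g("sjs", 1, "sjs", "negative")),
    list(text = "More details at www.nhs.uk/Conditions/Anxiety.",
         gold = g("Anxiety", 1, "anxiety", "negative"))
  )
}

capitalise <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# Transpose two mid-word characters.  Deterministic given the word so the
# RNG stream is identical across typo rates (the per-word typo draw alone
# decides whether a word is perturbed).
swap_chars <- function(word) {
  n <- nchar(word)
  if (n < 4) return(word)
  i <- 2L + (n %% 3L)
  paste0(substr(word, 1, i - 1), substr(word, i + 1, i + 1),
         substr(word, i, i), substr(word, i + 2, n))
}

# Instantiate one template: substitute surfaces for the placeholders and
# return the sentence text plus mention records (sentence-relative offsets).
instantiate_template <- function(template, statuses, concepts, surface_pool,
                                 single_word_concepts) {
  text <- template
  loc <- stringi::stri_locate_first_regex(text, "\\{[A-Za-z0-9]+\\}")
  mentions <- list()
  k <- 0L
  while (!is.na(loc[1, 1])) {
    k <- k + 1L
    ph <- substr(text, loc[1, 1] + 1L, loc[1, 2] - 1L)
    if (ph == "ade1w") {
      concept <- sample(single_word_concepts, 1)
      pool <- surface_pool[[concept]]
      pool <- pool[!grepl("[ -]", pool)]
      surface <- tolower(sample(pool, 1))
    } else {
      concept <- concepts[min(k, length(concepts))]
      surface <- sample(surface_pool[[concept]], 1)
      if (ph == "Ade") surface <- capitalise(surface)
      if (ph == "ADE") surface <- toupper(surface)
    }
    text <- paste0(substr(text, 1, loc[1, 1] - 1L), surface,
                   substr(text, loc[1, 2] + 1L, nchar(text)))
    mentions[[k]] <- new_df(
      start = loc[1, 1], end = loc[1, 1] + nchar(surface) - 1L,
      concept = concept, status = statuses[min(k, length(statuses))])
    loc <- stringi::stri_locate_first_regex(text, "\\{[A-Za-z0-9]+\\}")
  }
  list(text = text, mentions = do.call(rbind, mentions))
}

#' Generate a synthetic corpus with gold annotations
#'
#' Each document is 1 to 30 sentences assembled from templates instantiated
#' with dictionary surfaces (roughly half the sentences carry an ADE
#' mention; the rest are neutral ward-note filler).  Every ADE insertion is
#' logged as a gold annotation with the status implied by its template
#' category (affirmed templates are positive; negated, hypothetical,
#' historical, other-experiencer, warning/monitoring, questionnaire,
#' organisation-name and uncertainty templates are negative).  When
#' `n_docs >= 19` the corpus starts with a fixed set of canonical fixture
#' documents covering the worked examples of every pipeline stage,
#' including the retention-rule cases (labelled positive).  Typo injection
#' perturbs filler sentences only, never mention or trigger tokens.
#'
#' @param config A [generation_config()].
#' @param lexicon A `clinade_lexicon`; `NULL` for the bundled one.
#' @return List with `documents` (data frame `id`, `text`) and `gold` (data
#'   frame `doc_id`, `ade_concept`, `start`, `end`, `gold_status`,
#'   `context`; 1-based inclusive offsets).
#' @export
generate_corpus <- function(config, lexicon = NULL) {
  stopifnot(inherits(config, "clinade_genconfig"))
  lexicon <- lexicon %||% default_lexicon()
  e <- lexicon$entries
  known <- unique(e$canonical[e$category == "ade"])
  unknown <- setdiff(config$ade_concepts, known)
  if (length(unknown) > 0) {
    stop("unknown ade_concept(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  surface_pool <- split(e$surface[e$category == "ade"],
                        e$canonical[e$category == "ade"])
  surface_pool <- surface_pool[config$ade_concepts]
  single_word <- names(surface_pool)[vapply(surface_pool, function(s)
    any(!grepl("[ -]", s)), logical(1))]

  templates <- synth_templates()
  multi <- synth_multi_templates()
  fillers <- synth_fillers()
  fixtures <- synth_fixtures()

  withr::with_seed(config$seed, {
    docs <- vector("list", config$n_docs)
    gold <- list()
    use_fixtures <- config$n_docs >= 19
    n_fix <- if (use_fixtures) length(fixtures) else 0L

    for (d in seq_len(config$n_docs)) {
      id <- sprintf("synth-%04d", d)
      if (d <= n_fix) {
        fx <- fixtures[[d]]
        docs[[d]] <- new_df(id = id, text = fx$text)
        for (r in seq_len(nrow(fx$gold))) {
          occ <- stringi::stri_locate_all_fixed(
            fx$text, fx$gold$surface[r],
            opts_fixed = stringi::stri_opts_fixed(case_insensitive = FALSE)
          )[[1]]
          sp <- occ[fx$gold$occ[r], ]
          gold[[length(gold) + 1L]] <- new_df(
            doc_id = id, ade_concept = fx$gold$concept[r],
            start = as.integer(sp[1]), end = as.integer(sp[2]),
            gold_status = fx$gold$status[r], context = "fixture")
        }
        next
      }
      n_sent <- sample(1:30, 1)
      sents <- character(n_sent)
      pos <- 0L
      for (s in seq_len(n_sent)) {
        if (stats::runif(1) < 0.5) {
          if (stats::runif(1) < config$multi_ade_clause_rate) {
            tpl <- multi[[sample(length(multi), 1)]]
            concepts <- sample(config$ade_concepts, 2)
            inst <- instantiate_template(tpl$text, tpl$status, concepts,
                                         surface_pool, single_word)
            context <- "multi_ade"
          } else {
            cat_name <- sample(names(config$context_mix), 1,
                               prob = config$context_mix)
            cat_tpls <- templates[[cat_name]]
            tpl <- cat_tpls[[sample(length(cat_tpls), 1)]]
            concepts <- sample(config$ade_concepts, 1)
            inst <- instantiate_template(tpl$text, tpl$status, concepts,
                                         surface_pool, single_word)
            context <- cat_name
          }
          if (!is.null(inst$mentions)) {
            for (r in seq_len(nrow(inst$mentions))) {
              gold[[length(gold) + 1L]] <- new_df(
                doc_id = id, ade_concept = inst$mentions$concept[r],
                start = pos + inst$mentions$start[r],
                end = pos + inst$mentions$end[r],
                gold_status = inst$mentions$status[r], context = context)
            }
          }
          sents[s] <- inst$text
        } else {
          filler <- sample(fillers, 1)
          # typo draws happen even at rate 0 so corpora with different typo
          # rates share the same RNG stream (identical layout and gold)
          words <- strsplit(filler, " ", fixed = TRUE)[[1]]
          hit <- stats::runif(length(words)) < config$typo_rate
          if (any(hit)) {
            words[hit] <- vapply(words[hit], swap_chars, character(1))
            filler <- paste(words, collapse = " ")
          }
          sents[s] <- filler
        }
        pos <- pos + nchar(sents[s]) + 1L  # sentences joined by one space
      }
      docs[[d]] <- new_df(id = id, text = paste(sents, collapse = " "))
    }
    documents <- do.call(rbind, docs)
    gold <- if (length(gold) == 0) {
      new_df(doc_id = character(), ade_concept = character(),
             start = integer(), end = integer(), gold_status = character(),
             context = character())
    } else {
      do.call(rbind, gold)
    }
    list(documents = documents, gold = gold)
  })
}
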