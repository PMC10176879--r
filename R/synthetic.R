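#' Configuration for the synthetic EHR corpus generator
#'
#' Builds and validates the parameter set that defines a synthetic memory
#' clinic corpus: per-category true prevalences, lexical cue phrases, a
#' negation model, paired imperfect annotators, and an imperfect NPI
#' reporting process. Defaults emulate the structure of a memory clinic
#' cohort: most affective/behavioural categories are common, euphoria is
#' rare (1% of notes), and roughly two-thirds of patients have an NPI
#' assessment available.
#'
#' @param n_patients number of patients (one note cluster each).
#' @param true_prevalence named numeric vector over the 13 categories,
#'   probabilities in `[0, 1]`. Partial vectors are merged over the defaults.
#' @param cue_lexicon named list: category -> character vector of cue
#'   phrases. Must be non-empty for every category with positive prevalence.
#' @param negation_rate probability that a gold-negative document mentions a
#'   category cue inside a negated phrase ("no apathy").
#' @param background_vocab_size size of the synthetic background vocabulary.
#' @param notes_per_patient note sections concatenated per document.
#' @param note_span_days maximum spread of note dates within a cluster
#'   (default 90, the three-month diagnostic window).
#' @param annotator_sensitivity,annotator_specificity length-2 numeric
#'   vectors in `(0, 1]`: per-rater probabilities of labelling a truly
#'   present / truly absent category correctly.
#' @param npi_report_prob_given_present,npi_report_prob_given_absent
#'   probability that an NPI domain score is positive given the gold label.
#' @param npi_availability probability a patient has an NPI assessment.
#' @param cue_insertion if FALSE, cue phrases are never inserted, so text
#'   carries no signal about the gold labels (null/calibration corpora).
#' @param center cohort label, `"A"` or `"B"`.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 500,
                             true_prevalence = NULL,
                             cue_lexicon = NULL,
                             negation_rate = 0.15,
                             background_vocab_size = 400,
                             notes_per_patient = 3,
                             note_span_days = 90,
                             annotator_sensitivity = c(0.90, 0.88),
                             annotator_specificity = c(0.97, 0.96),
                             npi_report_prob_given_present = 0.45,
                             npi_report_prob_given_absent = 0.05,
                             npi_availability = 0.67,
                             cue_insertion = TRUE,
                             center = "A",
                             seed = 13) {
  prev <- default_true_prevalence()
  if (!is.null(true_prevalence)) {
    stopifnot(is.numeric(true_prevalence), !is.null(names(true_prevalence)))
    unknown <- setdiff(names(true_prevalence), nps_categories())
    if (length(unknown) > 0) {
      stop("unknown categories in true_prevalence: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    prev[names(true_prevalence)] <- true_prevalence
  }
  check_prob(prev, "true_prevalence")

  lex <- default_cue_lexicon()
  if (!is.null(cue_lexicon)) {
    stopifnot(is.list(cue_lexicon), !is.null(names(cue_lexicon)))
    lex[names(cue_lexicon)] <- cue_lexicon
  }
  empty <- vapply(nps_categories(),
                  function(cc) prev[[cc]] > 0 && length(lex[[cc]]) == 0,
                  logical(1))
  if (any(empty)) {
    stop("categories with prevalence > 0 but empty cue lexicon: ",
         paste(nps_categories()[empty], collapse = ", "), call. = FALSE)
  }

  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  stopifnot(notes_per_patient >= 1, note_span_days >= 0,
            background_vocab_size >= 1)
  check_prob(negation_rate, "negation_rate")
  check_prob(annotator_sensitivity, "annotator_sensitivity", allow_zero = FALSE)
  check_prob(annotator_specificity, "annotator_specificity", allow_zero = FALSE)
  stopifnot(length(annotator_sensitivity) == 2,
            length(annotator_specificity) == 2)
  check_prob(npi_report_prob_given_present, "npi_report_prob_given_present")
  check_prob(npi_report_prob_given_absent, "npi_report_prob_given_absent")
  check_prob(npi_availability, "npi_availability")
  center <- match.arg(center, c("A", "B"))

  structure(list(
    n_patients = as.integer(n_patients),
    true_prevalence = prev,
    cue_lexicon = lex,
    negation_rate = negation_rate,
    background_vocab_size = as.integer(background_vocab_size),
    notes_per_patient = as.integer(notes_per_patient),
    note_span_days = as.integer(note_span_days),
    annotator_sensitivity = annotator_sensitivity,
    annotator_specificity = annotator_specificity,
    npi_report_prob_given_present = npi_report_prob_given_present,
    npi_report_prob_given_absent = npi_report_prob_given_absent,
    npi_availability = npi_availability,
    cue_insertion = isTRUE(cue_insertion),
    center = center,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Default per-category true prevalences. The common categories follow
# adjusted note-derived prevalences reported for memory clinic cohorts
# (apathy ~0.69 down to hallucinations ~0.07); euphoria is set to 0.01,
# i.e. ~5 positive documents in a 500-document training set.
default_true_prevalence <- function() {
  c(delusions = 0.12, hallucinations = 0.07, agitation = 0.25,
    depression = 0.385, anxiety = 0.537, euphoria = 0.01, apathy = 0.694,
    disinhibition = 0.14, irritability = 0.426,
    aberrant_motor_behavior = 0.475, sleeping_behavior = 0.31,
    eating_behavior = 0.26, nps_general = 0.52)
}

# Cue phrases per category. Deliberately disjoint from the background
# vocabulary (background tokens look like "w0123") and from each other.
default_cue_lexicon <- function() {
  list(
    delusions = c("paranoid delusions", "delusional beliefs",
                  "thinks others steal"),
    hallucinations = c("visual hallucinations", "hears voices",
                       "sees figures"),
    agitation = c("agitated behaviour", "restless and agitated",
                  "verbally aggressive"),
    depression = c("depressive symptoms", "low mood", "feels hopeless"),
    anxiety = c("anxious complaints", "panic episodes", "constant worrying"),
    euphoria = c("euphoric mood", "inappropriately elated"),
    apathy = c("apathetic presentation", "loss of initiative",
               "shows little interest"),
    disinhibition = c("disinhibited remarks", "socially inappropriate",
                      "impulsive comments"),
    irritability = c("irritable during consult", "short tempered",
                     "easily annoyed"),
    aberrant_motor_behavior = c("pacing around", "repetitive rummaging",
                                "purposeless movements"),
    sleeping_behavior = c("disturbed sleep", "wakes at night",
                          "daytime drowsiness"),
    eating_behavior = c("decreased appetite", "eats excessively",
                        "altered food preference"),
    nps_general = c("behavioural changes", "challenging behaviour",
                    "personality change")
  )
}

#' Negation cue words used by the generator and the preprocessor
#' @return character vector of negation cues.
#' @export
default_negation_cues <- function() {
  c("no", "not", "denies", "without", "never")
}

# Neutral clinical boilerplate; free of cue-lexicon and negation tokens.
boilerplate_sentences <- function() {
  c("patient visited the memory clinic with partner.",
    "neurological examination was unremarkable.",
    "mmse 21 of 30.",
    "mri showed mild global atrophy.",
    "medication reviewed during consultation.",
    "history taking performed with caregiver present.",
    "laboratory results within normal limits.",
    "follow up planned in six months.")
}

#' Generate a synthetic clinical note corpus with known gold labels
#'
#' For each patient one document (a cluster of `notes_per_patient` note
#' sections dated within `note_span_days`) is generated. Per category the
#' gold label is drawn Bernoulli(true prevalence); gold-positive documents
#' receive at least one non-negated cue phrase, gold-negative documents may
#' receive a negated cue ("no" + cue) with probability `negation_rate` and
#' never a non-negated one. Background text is sampled from a synthetic
#' vocabulary plus neutral boilerplate, so cue/background separation is
#' fully controlled.
#'
#' @param config a [synthetic_config()].
#' @return A list with `documents` (data.frame: doc_id, patient_id, center,
#'   text, and a list-column note_dates) and `gold` (binary matrix,
#'   documents x 13 categories, rownames = doc_id).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  cats <- nps_categories()
  with_rng(child_seed(config$seed, 1L), {
    gold <- matrix(0L, nrow = n, ncol = length(cats),
                   dimnames = list(NULL, cats))
    for (cc in cats) {
      gold[, cc] <- stats::rbinom(n, 1L, config$true_prevalence[[cc]])
    }
    pid <- sprintf("%s%04d", config$center, seq_len(n))
    did <- sprintf("doc_%s", pid)
    rownames(gold) <- did

    vocab <- sprintf("w%04d", seq_len(config$background_vocab_size))
    boiler <- boilerplate_sentences()
    neg_cues <- default_negation_cues()
    base_date <- as.Date("2015-01-01")

    texts <- character(n)
    dates <- vector("list", n)
    for (i in seq_len(n)) {
      sentences <- character(0)
      for (s in seq_len(config$notes_per_patient)) {
        nbg <- sample(4:8, 1)
        bg <- paste(sample(vocab, nbg, replace = TRUE), collapse = " ")
        sentences <- c(sentences, sample(boiler, 1), paste0(bg, "."))
      }
      for (cc in cats) {
        if (!config$cue_insertion) {
          break
        } else if (gold[i, cc] == 1L) {
          k <- sample(1:2, 1)
          cues <- sample(config$cue_lexicon[[cc]], k, replace = TRUE)
          sentences <- c(sentences, paste0(cues, "."))
        } else if (length(config$cue_lexicon[[cc]]) > 0 &&
                   stats::runif(1) < config$negation_rate) {
          cue <- sample(config$cue_lexicon[[cc]], 1)
          sentences <- c(sentences, paste0(sample(neg_cues, 1), " ", cue, "."))
        }
      }
      texts[i] <- paste(sample(sentences), collapse = " ")
      start <- base_date + sample(0:3650, 1)
      offs <- sort(sample(0:config$note_span_days,
                          config$notes_per_patient, replace = TRUE))
      dates[[i]] <- start + (offs - min(offs))
    }

    documents <- data.frame(doc_id = did, patient_id = pid,
                            center = config$center, text = texts,
                            stringsAsFactors = FALSE)
    documents$note_dates <- dates
    list(documents = documents, gold = gold)
  })
}

#' Simulate two imperfect annotators from gold labels
#'
#' Each rater's document-level label is the gold label flipped independently
#' per document and category: a true positive is kept with the rater's
#' sensitivity, a true negative with the rater's specificity. Raters are
#' conditionally independent given gold. Noise acts at the document-category
#' level, not at span level, matching how downstream agreement statistics
#' are computed.
#'
#' @param gold binary gold label matrix (documents x categories).
#' @param config a [synthetic_config()] supplying the two raters' rates.
#' @return list of two binary matrices, `rater1` and `rater2`.
#' @export
generate_annotator_views <- function(gold, config) {
  stopifnot(inherits(config, "synthetic_config"), is.matrix(gold))
  with_rng(child_seed(config$seed, 2L), {
    views <- lapply(1:2, function(r) {
      sens <- config$annotator_sensitivity[r]
      spec <- config$annotator_specificity[r]
      u <- matrix(stats::runif(length(gold)), nrow = nrow(gold))
      v <- ifelse(gold == 1L, as.integer(u < sens), as.integer(u >= spec))
      dimnames(v) <- dimnames(gold)
      v
    })
    names(views) <- c("rater1", "rater2")
    views
  })
}

#' Simulate NPI/NPI-Q assessments imperfectly tied to note content
#'
#' For each patient and each of the 12 NPI domains, the domain score is
#' positive with probability `npi_report_prob_given_present` when the gold
#' label is 1 and `npi_report_prob_given_absent` when it is 0; positive
#' scores are drawn uniformly from 1..12 (NPI-Q-like range, presence is
#' defined downstream by threshold). A per-patient availability flag allows
#' simulating partial NPI coverage.
#'
#' @param gold binary gold label matrix with doc_id rownames; the 12 NPI
#'   domain columns are used.
#' @param config a [synthetic_config()].
#' @param patient_ids character vector aligning rows of `gold` to patients;
#'   defaults to rownames with the "doc_" prefix stripped.
#' @return data.frame with columns patient_id, domain, score, available.
#' @export
generate_npi_assessments <- function(gold, config, patient_ids = NULL) {
  stopifnot(inherits(config, "synthetic_config"), is.matrix(gold))
  doms <- npi_domains()
  stopifnot(all(doms %in% colnames(gold)))
  if (is.null(patient_ids)) patient_ids <- sub("^doc_", "", rownames(gold))
  n <- nrow(gold)
  with_rng(child_seed(config$seed, 3L), {
    available <- stats::runif(n) < config$npi_availability
    long <- expand.grid(patient_id = patient_ids, domain = doms,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- as.vector(gold[, doms])
    p <- ifelse(g == 1L, config$npi_report_prob_given_present,
                config$npi_report_prob_given_absent)
    reported <- stats::runif(length(p)) < p
    long$score <- ifelse(reported, sample(1:12, length(p), replace = TRUE), 0L)
    long$available <- rep(available, times = length(doms))
    long[order(match(long$patient_id, patient_ids), match(long$domain, doms)), ,
         drop = FALSE] -> long
    rownames(long) <- NULL
    long
  })
}

#' Write a synthetic corpus to disk
#'
#' One UTF-8 `.txt` file per document, a delimited gold-label table
#' (`gold_labels.csv`), and optionally an NPI table (`npi.csv`).
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @param npi optional data.frame from [generate_npi_assessments()].
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, npi = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus$documents))) {
    writeLines(corpus$documents$text[i],
               file.path(dir, paste0(corpus$documents$doc_id[i], ".txt")),
               useBytes = TRUE)
  }
  gold_df <- data.frame(doc_id = rownames(corpus$gold), corpus$gold,
                        check.names = FALSE)
  utils::write.csv(gold_df, file.path(dir, "gold_labels.csv"),
                   row.names = FALSE)
  if (!is.null(npi)) {
    utils::write.csv(npi, file.path(dir, "npi.csv"), row.names = FALSE)
  }
  invisible(dir)
}
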