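#' Assemble a run configuration
#'
#' @param mode `"synthetic"` (generate both cohorts) or `"from_files"`
#'   (read .txt/.ann corpora and an NPI table from disk).
#' @param train,external in synthetic mode, argument lists for
#'   [synthetic_config()] for the training (center A) and external
#'   (center B) cohorts; in from_files mode, lists with `corpus_dir` and
#'   optionally `npi_csv`.
#' @param preprocess argument list for [preprocess_config()].
#' @param k cross-validation folds (default 10).
#' @param alpha_grid elastic-net mixing grid.
#' @param gate minimum external-validation AUC for a classifier to be used
#'   in prevalence and NPI comparisons (default 0.80).
#' @param npi_thresholds NPI presence thresholds (default 1 and 4).
#' @param seed master seed for fold assignment.
#' @param output_dir where tables, models and the manifest are written;
#'   NULL for no output.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "from_files"),
                       train = list(), external = list(),
                       preprocess = list(stemmer = "porter",
                                         min_document_frequency = 2),
                       k = 10, alpha_grid = c(0.1, 0.55, 1.0),
                       gate = 0.80, npi_thresholds = c(1, 4),
                       seed = 13, output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "from_files") {
    for (side in list(train, external)) {
      if (is.null(side$corpus_dir) || !dir.exists(side$corpus_dir)) {
        stop("from_files mode requires existing `corpus_dir` for both ",
             "cohorts", call. = FALSE)
      }
    }
  }
  structure(list(mode = mode, train = train, external = external,
                 preprocess = preprocess, k = k, alpha_grid = alpha_grid,
                 gate = gate, npi_thresholds = npi_thresholds,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; top-level keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# load one cohort in from_files mode
load_cohort <- function(side) {
  anns <- read_brat_dir(side$corpus_dir)
  doc_ids <- names(anns)
  texts <- vapply(doc_ids, function(d) {
    paste(readLines(file.path(side$corpus_dir, paste0(d, ".txt")),
                    warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }, character(1))
  documents <- data.frame(doc_id = doc_ids,
                          patient_id = sub("^doc_", "", doc_ids),
                          center = side$center %||% "A",
                          text = unname(texts), stringsAsFactors = FALSE)
  gold <- labels_from_spans(anns, doc_ids)
  npi <- if (!is.null(side$npi_csv)) {
    utils::read.csv(side$npi_csv, stringsAsFactors = FALSE)
  }
  list(documents = documents, gold = gold, npi = npi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full NPS classification experiment
#'
#' Stages, in order: build/load the training (A) and external (B) cohorts;
#' featurize A and freeze its vocabulary; per category, stratified tenfold
#' cross-validation over the elastic-net grid, Youden cutoff selection on
#' out-of-fold scores, refit on all of A, frozen evaluation on B; gate on
#' external AUC; observed and misclassification-adjusted prevalence per
#' cohort with confidence intervals; between-cohort prevalence comparison
#' with FDR control; and EHR-vs-NPI agreement at each NPI threshold.
#' Categories with too few positives to stratify are recorded as
#' untrainable and skipped. All tables are deterministic given the
#' configuration (including its seeds).
#'
#' @param config a [run_config()].
#' @return list with elements `evaluations`, `untrainable`, `models`,
#'   `cutoffs`, `prevalence` (per cohort), `center_comparison`,
#'   `annotator_agreement`, `ehr_npi` (per threshold), `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_info <- function(...) message(sprintf(...))

  # --- stage: corpora -------------------------------------------------
  if (config$mode == "synthetic") {
    cfg_a <- do.call(synthetic_config,
                     utils::modifyList(list(center = "A",
                                            seed = config$seed),
                                       config$train))
    cfg_b <- do.call(synthetic_config,
                     utils::modifyList(list(center = "B",
                                            seed = child_seed(config$seed, 101L)),
                                       config$external))
    corpus_a <- generate_corpus(cfg_a)
    corpus_b <- generate_corpus(cfg_b)
    views_a <- generate_annotator_views(corpus_a$gold, cfg_a)
    npi_a <- generate_npi_assessments(corpus_a$gold, cfg_a)
  } else {
    a <- load_cohort(utils::modifyList(config$train, list(center = "A")))
    b <- load_cohort(utils::modifyList(config$external, list(center = "B")))
    corpus_a <- a[c("documents", "gold")]
    corpus_b <- b[c("documents", "gold")]
    views_a <- NULL
    npi_a <- a$npi
  }
  log_info("cohort A: %d documents; cohort B: %d documents",
           nrow(corpus_a$documents), nrow(corpus_b$documents))

  # --- stage: features ------------------------------------------------
  pp <- do.call(preprocess_config, config$preprocess)
  dtm_a <- build_doc_term_matrix(corpus_a$documents, pp)
  vocab <- colnames(dtm_a)
  dtm_b <- build_doc_term_matrix(corpus_b$documents, pp, vocabulary = vocab)
  log_info("vocabulary: %d features (frozen from cohort A)", length(vocab))

  # --- stage: per-category training ----------------------------------
  cats <- nps_categories()
  evaluations <- list()
  models <- list()
  cutoffs <- numeric(0)
  untrainable <- character(0)
  counts_int <- list()
  counts_ext <- list()
  class_a <- matrix(NA_integer_, nrow(dtm_a), length(cats),
                    dimnames = list(rownames(dtm_a), cats))
  class_b <- matrix(NA_integer_, nrow(dtm_b), length(cats),
                    dimnames = list(rownames(dtm_b), cats))
  for (cc in cats) {
    y <- corpus_a$gold[, cc]
    npos <- sum(y == 1)
    log_info("category %s: %d positive documents", cc, npos)
    cv <- tryCatch(
      cross_validate(dtm_a, y, k = config$k, alpha_grid = config$alpha_grid,
                     seed = child_seed(config$seed, match(cc, cats)),
                     category = cc),
      error = function(e) e)
    if (inherits(cv, "error")) {
      log_info("  skipped: %s", conditionMessage(cv))
      untrainable <- c(untrainable, cc)
      next
    }
    sel <- select_youden_cutoff(cv$oof, y, category = cc,
                                split = "internal_cv")
    ext <- evaluate_external(cv$model, sel$cutoff, dtm_b,
                             corpus_b$gold[, cc])
    evaluations[[cc]] <- rbind(sel$evaluation, ext$evaluation)
    models[[cc]] <- cv$model
    cutoffs[cc] <- sel$cutoff
    counts_int[[cc]] <- data.frame(category = cc,
                                   t(confusion_counts(cv$oof, y, sel$cutoff)))
    counts_ext[[cc]] <- data.frame(
      category = cc,
      t(confusion_counts(ext$scores, corpus_b$gold[, cc], sel$cutoff)))
    class_a[, cc] <- as.integer(predict(cv$model, dtm_a) >= sel$cutoff)
    class_b[, cc] <- as.integer(ext$scores >= sel$cutoff)
  }
  if (length(evaluations) == 0) {
    stop("stage training: no category was trainable", call. = FALSE)
  }
  evaluations <- do.call(rbind, evaluations)
  rownames(evaluations) <- NULL
  counts_int <- do.call(rbind, counts_int)
  counts_ext <- do.call(rbind, counts_ext)

  # --- stage: gate + prevalence --------------------------------------
  ev_int <- evaluations[evaluations$split == "internal_cv", ]
  ev_ext <- evaluations[evaluations$split == "external", ]
  trained <- ev_int$category
  # cohort A is evaluated with internal CV operating characteristics,
  # cohort B with the external-validation ones; gating uses each split's AUC
  prev_a <- estimate_all(class_a[, trained, drop = FALSE], ev_int,
                         counts_int, gate = config$gate)
  prev_b <- estimate_all(class_b[, trained, drop = FALSE], ev_ext,
                         counts_ext, gate = config$gate)
  gate_failed <- ev_ext$category[ev_ext$auc < config$gate]
  if (length(gate_failed) > 0) {
    log_info("gate (external AUC >= %.2f) excludes: %s", config$gate,
             paste(gate_failed, collapse = ", "))
  }

  # --- stage: cohort comparison --------------------------------------
  both <- rbind(class_a[, trained, drop = FALSE],
                class_b[, trained, drop = FALSE])
  center_cmp <- compare_groups(
    both, c(rep("A", nrow(class_a)), rep("B", nrow(class_b))),
    categories = trained)

  # --- stage: agreement ----------------------------------------------
  annotator_agreement <- if (!is.null(views_a)) {
    pairwise_annotation_agreement(views_a$rater1, views_a$rater2)
  }
  ehr_npi <- NULL
  if (!is.null(npi_a)) {
    ehr_pat <- class_a[, trained, drop = FALSE]
    rownames(ehr_pat) <- corpus_a$documents$patient_id[
      match(rownames(class_a), corpus_a$documents$doc_id)]
    ok_cats <- setdiff(intersect(trained, npi_domains()),
                       union(gate_failed, untrainable))
    ehr_npi <- lapply(config$npi_thresholds, function(th) {
      compare_ehr_npi(ehr_pat, npi_presence(npi_a, threshold = th),
                      categories = ok_cats)
    })
    names(ehr_npi) <- paste0("threshold_", config$npi_thresholds)
  }

  cfg_sem <- unclass(config)
  cfg_sem$output_dir <- NULL   # where results land is not part of the run
  manifest <- list(config_hash = vocab_hash(utils::capture.output(
                     utils::str(cfg_sem))),
                   seed = config$seed, mode = config$mode,
                   n_documents_a = nrow(corpus_a$documents),
                   n_documents_b = nrow(corpus_b$documents),
                   n_features = length(vocab),
                   vocabulary_hash = vocab_hash(vocab),
                   untrainable = untrainable,
                   gate_failed = gate_failed)

  report <- list(evaluations = evaluations, untrainable = untrainable,
                 models = models, cutoffs = cutoffs,
                 prevalence = list(A = prev_a, B = prev_b),
                 center_comparison = center_cmp,
                 annotator_agreement = annotator_agreement,
                 ehr_npi = ehr_npi, manifest = manifest)

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# write all report tables; file set is stable, contents deterministic
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(dir, name),
                                       row.names = FALSE)
  }
  wr(report$evaluations, "evaluations.csv")
  wr(report$prevalence$A, "prevalence_A.csv")
  wr(report$prevalence$B, "prevalence_B.csv")
  wr(report$center_comparison, "center_comparison.csv")
  wr(report$annotator_agreement, "annotator_agreement.csv")
  for (nm in names(report$ehr_npi)) {
    wr(report$ehr_npi[[nm]], paste0("ehr_npi_", nm, ".csv"))
  }
  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (cc in names(report$models)) {
    write_model(report$models[[cc]], file.path(mdir, paste0(cc, ".json")))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Grouped-bar plot of observed vs adjusted prevalence
#'
#' @param prevalence data.frame from [estimate_all()].
#' @param main plot title.
#' @return invisibly, the matrix plotted.
#' @export
plot_prevalence <- function(prevalence, main = "Adjusted NPS prevalence") {
  keep <- prevalence[prevalence$gate_passed, ]
  m <- t(as.matrix(keep[, c("observed", "adjusted_clamped")]))
  colnames(m) <- keep$category
  graphics::barplot(m, beside = TRUE, las = 2, main = main,
                    legend.text = c("observed", "adjusted"),
                    col = c("grey70", "steelblue"), ylim = c(0, 1))
  invisible(m)
}

#' Command-line entry point
#'
#' Subcommands: `run --config run.yaml [--out dir]`,
#' `simulate --config synth.yaml --out dir`,
#' `agree --ann-a dirA --ann-b dirB`. Installed as `exec/nps-ehr`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
nps_ehr_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, required = TRUE) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) return(args[i + 1])
    if (required) stop("missing required option ", flag, call. = FALSE)
    NULL
  }
  if (length(args) == 0) {
    stop("usage: nps-ehr <run|simulate|agree> [options]", call. = FALSE)
  }
  cmd <- args[1]
  if (cmd == "run") {
    cfg <- run_config_from_yaml(get_opt("--config"))
    out <- get_opt("--out", required = FALSE)
    if (!is.null(out)) cfg$output_dir <- out
    run_experiment(cfg)
  } else if (cmd == "simulate") {
    sc <- do.call(synthetic_config, yaml::read_yaml(get_opt("--config")))
    out <- get_opt("--out")
    corpus <- generate_corpus(sc)
    npi <- generate_npi_assessments(corpus$gold, sc)
    write_corpus(corpus, out, npi = npi)
    message("wrote ", nrow(corpus$documents), " documents to ", out)
  } else if (cmd == "agree") {
    da <- read_brat_dir(get_opt("--ann-a"))
    db <- read_brat_dir(get_opt("--ann-b"))
    ids <- sort(union(names(da), names(db)))
    res <- pairwise_annotation_agreement(labels_from_spans(da, ids),
                                         labels_from_spans(db, ids))
    utils::write.csv(res, stdout(), row.names = FALSE)
  } else {
    stop("unknown command ", dQuote(cmd), call. = FALSE)
  }
  invisible(0L)
}
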