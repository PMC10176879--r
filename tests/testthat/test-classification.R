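# small dense-ish design used across fit tests
make_design <- function(n = 200, p = 5, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("d%03d", 1:n),
                                sprintf("f%d", 1:p)))
    eta <- X %*% c(1.5, -1, 0.5, 0, 0) - 0.2
    y <- rbinom(n, 1, plogis(eta))
    list(X = methods::as(X, "CsparseMatrix"), y = y)
  })
}

test_that("huge lambda shrinks all coefficients; intercept = logit base rate", {
  d <- make_design()
  m <- fit_elastic_net_logistic(d$X, d$y, mixing_alpha = 0.5, lambda = 1e6)
  expect_length(m$coefficients, 0)
  expect_equal(m$intercept, qlogis(mean(d$y)), tolerance = 1e-6)
})

test_that("lambda = 0 matches the unpenalized ML fit from glm", {
  d <- make_design()
  m <- fit_elastic_net_logistic(d$X, d$y, mixing_alpha = 1, lambda = 0)
  oracle <- stats::glm.fit(cbind(1, as.matrix(d$X)), d$y,
                           family = stats::binomial())
  cf <- stats::setNames(rep(0, ncol(d$X)), colnames(d$X))
  cf[names(m$coefficients)] <- m$coefficients
  expect_equal(unname(c(m$intercept, cf)), unname(oracle$coefficients),
               tolerance = 1e-4)
})

test_that("L1 norm of coefficients is non-increasing in lambda", {
  d <- make_design()
  lambdas <- 10^seq(-3, 0, length.out = 8)
  l1 <- vapply(lambdas, function(l) {
    sum(abs(fit_elastic_net_logistic(d$X, d$y, 0.8, l)$coefficients))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("single-class labels are refused", {
  d <- make_design()
  expect_error(fit_elastic_net_logistic(d$X, rep(1, nrow(d$X)), 0.5, 0.1),
               "single class")
})

test_that("models serialize to JSON with identical predictions", {
  d <- make_design()
  m <- fit_elastic_net_logistic(d$X, d$y, 0.55, 0.01, category = "apathy")
  path <- file.path(withr::local_tempdir(), "m.json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(predict(m2, d$X), predict(m, d$X))
  expect_identical(m2$vocabulary_hash, m$vocabulary_hash)
})

test_that("compute_auc equals the Mann-Whitney pair statistic", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(compute_auc(c(0.1, 0.2), c(1, 1)), "single class")
  # brute-force equivalence on random sets, exactly
  withr::with_seed(9, {
    for (i in 1:25) {
      n <- sample(4:50, 1)
      s <- round(runif(n), 2)  # force ties
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      expect_identical(compute_auc(s, y), auc_brute(s, y))
    }
  })
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(10, {
    s <- runif(60)
    y <- rbinom(60, 1, 0.4)
    if (sum(y) %in% c(0, 60)) y[1:2] <- c(0, 1)
    a0 <- compute_auc(s, y)
    expect_equal(compute_auc(qlogis(s * 0.98 + 0.01), y), a0)
    expect_equal(compute_auc(s^3, y), a0)
    expect_equal(compute_auc(100 * s - 3, y), a0)
  })
})

test_that("confusion_at_cutoff computes the stated operating points", {
  s <- c(0.1, 0.4, 0.6, 0.9)
  y <- c(0, 1, 0, 1)
  expect_equal(confusion_at_cutoff(s, y, 0.05),
               c(sensitivity = 1, specificity = 0))
  expect_equal(confusion_at_cutoff(s, y, 0.95),
               c(sensitivity = 0, specificity = 1))
  # the depression training operating point: TP=71 FN=29 TN=97 FP=3
  d <- scores_for_counts(71, 29, 97, 3)
  cs <- confusion_at_cutoff(d$scores, d$labels, 0.5)
  expect_equal(unname(cs["sensitivity"]), 0.71)
  expect_equal(unname(cs["specificity"]), 0.97)
  expect_equal(youden_index(cs[["sensitivity"]], cs[["specificity"]]), 0.68)
  expect_error(confusion_at_cutoff(c(0.2, 0.8), c(0, 0), 0.5),
               "no positive")
})

test_that("youden cutoff maximizes J over midpoints (brute-force oracle)", {
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- 40
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- round(plogis(rnorm(n) + y), 2)
      sel <- select_youden_cutoff(s, y)
      # exhaustive scan oracle
      u <- sort(unique(s))
      mids <- (u[-length(u)] + u[-1]) / 2
      mids <- mids[mids > 0 & mids < 1]
      js <- vapply(mids, function(cc) {
        p <- as.integer(s >= cc)
        sum(p & y) / sum(y) + sum(!p & !y) / sum(!y) - 1
      }, numeric(1))
      expect_equal(sel$cutoff, mids[which.max(js)])
      expect_equal(sel$evaluation$youden, max(js))
      # identity J = se + sp - 1 within 1e-12
      expect_equal(sel$evaluation$youden,
                   sel$evaluation$sensitivity +
                     sel$evaluation$specificity - 1,
                   tolerance = 1e-12)
    }
  })
  # perfect separation gives J = 1 at the separating midpoint
  sel <- select_youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sel$cutoff, 0.5)
  expect_equal(sel$evaluation$youden, 1)
})

test_that("cross_validate partitions, stratifies and is deterministic", {
  d <- make_design(n = 100, seed = 3)
  cv <- cross_validate(d$X, d$y, k = 10, seed = 5, category = "anxiety")
  expect_false(anyNA(cv$oof))               # every doc scored once
  expect_true(all(table(cv$folds) %in% 9:11))
  # stratification: every fold contains both classes
  expect_true(all(tapply(d$y, cv$folds, function(v) length(unique(v))) == 2))
  cv2 <- cross_validate(d$X, d$y, k = 10, seed = 5, category = "anxiety")
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$best_alpha, cv2$best_alpha)
  expect_identical(cv$best_lambda, cv2$best_lambda)
  expect_identical(cv$oof, cv2$oof)
})

test_that("too few positives gives the explicit untrainable error", {
  d <- make_design(n = 500, seed = 4)
  y <- rep(0L, 500)
  y[1:5] <- 1L
  expect_error(cross_validate(d$X, y, k = 10, category = "euphoria"),
               "euphoria untrainable")
})

test_that("external evaluation refuses mismatched vocabularies", {
  d <- make_design()
  m <- fit_elastic_net_logistic(d$X, d$y, 0.55, 0.01)
  X_bad <- d$X
  colnames(X_bad) <- paste0("g", seq_len(ncol(X_bad)))
  expect_error(predict(m, X_bad), "vocabulary hash mismatch")
  expect_error(evaluate_external(m, 0.5, X_bad, d$y), "hash mismatch")
})

test_that("external evaluation is frozen: same data gives same operating point", {
  d <- make_design()
  cv <- cross_validate(d$X, d$y, k = 10, seed = 1, category = "apathy")
  sel <- select_youden_cutoff(cv$oof, d$y, category = "apathy")
  ext <- evaluate_external(cv$model, sel$cutoff, d$X, d$y)
  # refit scores on the training data itself: same cutoff, consistent youden
  expect_equal(ext$evaluation$youden,
               ext$evaluation$sensitivity + ext$evaluation$specificity - 1,
               tolerance = 1e-12)
  expect_equal(ext$evaluation$cutoff, sel$cutoff)
  expect_s3_class(ext$evaluation, "data.frame")
  expect_equal(ext$evaluation$split, "external")
})

test_that("distribution shift reduces external AUC (direction only)", {
  cfg_a <- synthetic_config(n_patients = 150, seed = 21,
                            true_prevalence = c(depression = 0.4),
                            negation_rate = 0)
  shifted_lex <- default_cue_lexicon()
  shifted_lex$depression <- c("dysthymic affect", "tearful presentation")
  cfg_b <- synthetic_config(n_patients = 150, seed = 22, center = "B",
                            true_prevalence = c(depression = 0.4),
                            cue_lexicon = shifted_lex, negation_rate = 0)
  a <- generate_corpus(cfg_a)
  b <- generate_corpus(cfg_b)
  pp <- preprocess_config(min_document_frequency = 2)
  Xa <- build_doc_term_matrix(a$documents, pp)
  Xb <- build_doc_term_matrix(b$documents, pp, vocabulary = colnames(Xa))
  cv <- cross_validate(Xa, a$gold[, "depression"], k = 10, seed = 2,
                       category = "depression")
  sel <- select_youden_cutoff(cv$oof, a$gold[, "depression"])
  ext <- evaluate_external(cv$model, sel$cutoff, Xb, b$gold[, "depression"])
  expect_lt(ext$evaluation$auc, sel$evaluation$auc)
})
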