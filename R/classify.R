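# Stable content hash of a vocabulary (pure R, polynomial rolling hash).
# Used to refuse scoring a matrix whose feature space differs from the one
# a model was trained on.
vocab_hash <- function(vocabulary) {
  s <- paste(vocabulary, collapse = "\x1f")
  h <- 0
  m <- 2147483647
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
  sprintf("%d:%d", length(vocabulary), as.integer(h))
}

# largest penalty with all coefficients zero, glmnet convention
# (columns standardized with 1/n variance)
lambda_max <- function(X, y, alpha) {
  n <- nrow(X)
  mu <- Matrix::colMeans(X)
  sd_n <- sqrt(Matrix::colMeans(X^2) - mu^2)
  sd_n[sd_n == 0] <- Inf
  r <- y - mean(y)
  g <- abs(as.numeric(Matrix::crossprod(X, r)) - mu * sum(r)) / sd_n
  max(g) / (n * max(alpha, 1e-3))
}

#' Fit one elastic-net regularized logistic classifier
#'
#' Minimizes the mean logistic deviance plus
#' `lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)` with an
#' unpenalized intercept. Features are standardized internally for
#' penalization; coefficients are reported on the original count scale.
#'
#' @param X sparse document-term matrix (rows align with `y`).
#' @param y binary 0/1 labels containing both classes.
#' @param mixing_alpha elastic-net mixing in `[0, 1]` (0 ridge, 1 lasso).
#' @param lambda penalty strength `>= 0`.
#' @param category optional category name carried in the model.
#' @return object of class `enet_model`: intercept, sparse coefficient map,
#'   hyperparameters, vocabulary and its hash.
#' @export
fit_elastic_net_logistic <- function(X, y, mixing_alpha = 0.55, lambda = 0.01,
                                     category = NA_character_) {
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1),
            mixing_alpha >= 0, mixing_alpha <= 1, lambda >= 0)
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; classifier untrainable",
         call. = FALSE)
  }
  lmax <- max(lambda_max(X, y, mixing_alpha), lambda * 1.01, 1e-4)
  path <- exp(seq(log(lmax), log(max(lambda, lmax * 1e-6)), length.out = 25))
  if (lambda < min(path)) path <- c(path, lambda)
  fit <- withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = mixing_alpha,
                   lambda = path, standardize = TRUE, thresh = 1e-9,
                   maxit = 1e6),
    warning = function(w) {
      if (grepl("Convergence", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  # suppress the benign stats::approx tie warning from path interpolation
  cf <- suppressWarnings(
    as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE)))
  beta <- stats::setNames(cf[-1], colnames(X))
  structure(list(category = category,
                 intercept = cf[1],
                 coefficients = beta[beta != 0],
                 mixing_alpha = mixing_alpha,
                 lambda = lambda,
                 vocabulary = colnames(X),
                 vocabulary_hash = vocab_hash(colnames(X))),
            class = "enet_model")
}

#' Predict positive-class probabilities from an `enet_model`
#'
#' @param object an `enet_model`.
#' @param newdata document-term matrix built with the model's vocabulary.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.enet_model <- function(object, newdata, ...) {
  if (vocab_hash(colnames(newdata)) != object$vocabulary_hash) {
    stop("vocabulary hash mismatch: matrix was not built with the model's ",
         "training vocabulary", call. = FALSE)
  }
  eta <- rep(object$intercept, nrow(newdata))
  if (length(object$coefficients) > 0) {
    j <- match(names(object$coefficients), colnames(newdata))
    eta <- eta + as.numeric(newdata[, j, drop = FALSE] %*%
                              object$coefficients)
  }
  stats::plogis(eta)
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf("<enet_model> category=%s alpha=%.2f lambda=%.4g nonzero=%d/%d\n",
              x$category, x$mixing_alpha, x$lambda,
              length(x$coefficients), length(x$vocabulary)))
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' Round-trips with bit-identical predictions (numbers written at full
#' precision).
#' @param model an `enet_model`.
#' @param path file path.
#' @return `path` invisibly / the restored model.
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  # doubles are stored as %.17g strings: decimal JSON numbers lose the last
  # ulp, which would break the bit-identical-predictions contract
  obj$intercept <- sprintf("%.17g", obj$intercept)
  obj$coefficients <- as.list(stats::setNames(
    sprintf("%.17g", obj$coefficients), names(obj$coefficients)))
  obj$lambda <- sprintf("%.17g", obj$lambda)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$intercept <- as.numeric(obj$intercept)
  obj$lambda <- as.numeric(obj$lambda)
  cf <- unlist(obj$coefficients)
  obj$coefficients <- if (is.null(cf)) numeric(0) else {
    stats::setNames(as.numeric(cf), names(cf))
  }
  structure(obj[c("category", "intercept", "coefficients", "mixing_alpha",
                  "lambda", "vocabulary", "vocabulary_hash")],
            class = "enet_model")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Equals the probability that a random positive outscores a random
#' negative, ties counted half:
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)`.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Sensitivity and specificity at a probability cutoff
#'
#' Prediction is positive iff `score >= cutoff`.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @param cutoff threshold in `(0, 1)`.
#' @return named numeric: sensitivity, specificity.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), cutoff > 0, cutoff < 1)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0) stop("no positive labels: sensitivity undefined",
                      call. = FALSE)
  if (nneg == 0) stop("no negative labels: specificity undefined",
                      call. = FALSE)
  pred <- as.integer(scores >= cutoff)
  c(sensitivity = sum(pred == 1 & labels == 1) / npos,
    specificity = sum(pred == 0 & labels == 0) / nneg)
}

#' Select the probability cutoff maximizing the Youden index
#'
#' Scans every midpoint between adjacent distinct scores and maximizes
#' `J(c) = sensitivity(c) + specificity(c) - 1`; ties are broken by the
#' smallest cutoff. Designed to run on *out-of-fold* scores so the
#' operating point is not optimistic.
#'
#' @param scores out-of-fold probabilities.
#' @param labels binary 0/1 labels.
#' @param category category name carried into the evaluation.
#' @param split `"internal_cv"` or `"external"`.
#' @return list with `cutoff` and `evaluation` (one-row data.frame:
#'   category, auc, sensitivity, specificity, youden, cutoff, split).
#' @export
select_youden_cutoff <- function(scores, labels, category = NA_character_,
                                 split = "internal_cv") {
  s <- sort(unique(scores))
  if (length(s) < 2) {
    stop("cannot select a cutoff: all scores identical", call. = FALSE)
  }
  cands <- (s[-length(s)] + s[-1]) / 2
  cands <- cands[cands > 0 & cands < 1]
  if (length(cands) == 0) {
    stop("no admissible cutoff in (0, 1)", call. = FALSE)
  }
  js <- vapply(cands, function(cc) {
    ss <- confusion_at_cutoff(scores, labels, cc)
    unname(ss[1] + ss[2] - 1)
  }, numeric(1))
  best <- cands[which.max(js)]   # which.max takes the first, i.e. smallest
  ss <- confusion_at_cutoff(scores, labels, best)
  ev <- data.frame(category = category,
                   auc = compute_auc(scores, labels),
                   sensitivity = unname(ss["sensitivity"]),
                   specificity = unname(ss["specificity"]),
                   youden = unname(ss["sensitivity"] + ss["specificity"] - 1),
                   cutoff = best, split = split,
                   stringsAsFactors = FALSE)
  list(cutoff = best, evaluation = ev)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, k, seed) {
  with_rng(seed, {
    fold <- integer(length(y))
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validation over an elastic-net grid
#'
#' Folds are stratified by label; every document is scored exactly once
#' out-of-fold. The hyperparameter pair (mixing alpha, lambda) maximizing
#' out-of-fold AUC is selected; lambda ranges over a 10-point log grid from
#' the smallest all-zero penalty down by factor 1e-4, per alpha. A final
#' model is refit on all data at the selected pair.
#'
#' @param X document-term matrix.
#' @param y binary 0/1 labels.
#' @param k folds (default 10).
#' @param alpha_grid elastic-net mixing values.
#' @param n_lambda points on the lambda grid.
#' @param seed integer; fixes fold assignment.
#' @param category category name (used in error messages and the model).
#' @return list: `oof` (out-of-fold probabilities at the selected pair),
#'   `best_alpha`, `best_lambda`, `oof_auc`, `folds`, `model`.
#' @export
cross_validate <- function(X, y, k = 10, alpha_grid = c(0.1, 0.55, 1.0),
                           n_lambda = 10, seed = 1,
                           category = NA_character_) {
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos < k || nneg < k) {
    stop(sprintf(
      "category %s untrainable: %d positive and %d negative documents cannot be stratified into %d folds",
      category, npos, nneg, k), call. = FALSE)
  }
  folds <- stratified_folds(y, k, seed)

  grids <- lapply(alpha_grid, function(a) {
    lmax <- lambda_max(X, y, a)
    exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
  })

  n <- length(y)
  oof <- lapply(seq_along(alpha_grid), function(a) {
    matrix(NA_real_, nrow = n, ncol = n_lambda)
  })
  # On cleanly separable data the lower end of the pinned grid (lambda_max
  # down to 1e-4 * lambda_max) lies past the separation point, where
  # coordinate descent diverges; iterations are capped and the deepest
  # converged solution stands in for deeper penalties (glmnet's own
  # early-stopping behaviour), with the advisory warning muffled.
  quiet_glmnet <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("Convergence|collapsing", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  for (f in seq_len(k)) {
    test <- folds == f
    for (a in seq_along(alpha_grid)) {
      quiet_glmnet({
        fit <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                              family = "binomial", alpha = alpha_grid[a],
                              lambda = grids[[a]], standardize = TRUE,
                              thresh = 1e-7, maxit = 1e5)
        p <- stats::predict(fit, X[test, , drop = FALSE], s = grids[[a]],
                            type = "response", exact = FALSE)
      })
      oof[[a]][test, ] <- as.matrix(p)
    }
  }

  aucs <- sapply(seq_along(alpha_grid), function(a) {
    apply(oof[[a]], 2, compute_auc, labels = y)
  })  # n_lambda x n_alpha
  best <- arrayInd(which.max(aucs), dim(aucs))
  best_alpha <- alpha_grid[best[2]]
  best_lambda <- grids[[best[2]]][best[1]]

  model <- fit_elastic_net_logistic(X, y, best_alpha, best_lambda, category)
  list(oof = oof[[best[2]]][, best[1]],
       best_alpha = best_alpha, best_lambda = best_lambda,
       oof_auc = max(aucs), folds = folds, model = model)
}

#' Evaluate a frozen model on an external corpus
#'
#' No refitting and no cutoff re-selection: the model and the cutoff chosen
#' on internal cross-validation are applied as-is. The external matrix must
#' have been built with the training vocabulary (checked by hash).
#'
#' @param model an `enet_model`.
#' @param cutoff probability cutoff fixed from internal CV.
#' @param X_ext external document-term matrix (training vocabulary).
#' @param y_ext binary 0/1 labels for the external documents.
#' @return list with `scores` and `evaluation` (one-row data.frame,
#'   split = "external").
#' @export
evaluate_external <- function(model, cutoff, X_ext, y_ext) {
  scores <- predict(model, X_ext)
  y_ext <- as.integer(y_ext)
  ss <- confusion_at_cutoff(scores, y_ext, cutoff)
  ev <- data.frame(category = model$category,
                   auc = compute_auc(scores, y_ext),
                   sensitivity = unname(ss["sensitivity"]),
                   specificity = unname(ss["specificity"]),
                   youden = unname(ss["sensitivity"] + ss["specificity"] - 1),
                   cutoff = cutoff, split = "external",
                   stringsAsFactors = FALSE)
  list(scores = scores, evaluation = ev)
}

#' Youden's J from sensitivity and specificity
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return `sensitivity + specificity - 1`.
#' @export
youden_index <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}
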