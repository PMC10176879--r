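#' Rogan-Gladen misclassification-corrected prevalence
#'
#' Corrects an observed (apparent) prevalence for the imperfect sensitivity
#' and specificity of the classifier that produced it:
#' `(observed + specificity - 1) / (sensitivity + specificity - 1)`.
#' The raw estimate can fall outside `[0, 1]` when the observed rate is not
#' compatible with the assumed error rates; both the raw and the clamped
#' value are returned.
#'
#' @param observed apparent prevalence in `[0, 1]`.
#' @param sensitivity,specificity classifier rates; must sum to more than 1
#'   (an uninformative classifier has no defined correction).
#' @return list with `raw` and `clamped` estimates.
#' @export
#' @examples
#' rogan_gladen(0.5, 0.8, 0.9)$raw  # 0.5714...
rogan_gladen <- function(observed, sensitivity, specificity) {
  check_prob(observed, "observed")
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  if (sensitivity + specificity <= 1) {
    stop("sensitivity + specificity <= 1: estimator undefined for an ",
         "uninformative classifier", call. = FALSE)
  }
  raw <- (observed + specificity - 1) / (sensitivity + specificity - 1)
  list(raw = raw, clamped = min(max(raw, 0), 1))
}

# confusion counts of a scored validation set at a fixed cutoff
#' Confusion counts at a cutoff
#' @param scores numeric scores; positive iff `score >= cutoff`.
#' @param labels binary 0/1 labels.
#' @param cutoff threshold.
#' @return named integer vector: tp, fn, tn, fp.
#' @export
confusion_counts <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= cutoff)
  c(tp = sum(pred == 1 & labels == 1), fn = sum(pred == 0 & labels == 1),
    tn = sum(pred == 0 & labels == 0), fp = sum(pred == 1 & labels == 0))
}

#' Confidence interval for misclassification-corrected prevalence
#'
#' Adjusted-Wald (Agresti-Coull style) interval for the Rogan-Gladen
#' estimate, propagating the sampling uncertainty of sensitivity and
#' specificity from the validation-set confusion counts they were estimated
#' from. The apparent prevalence is centre-adjusted by `z^2/2` successes and
#' failures; the variance combines, on the corrected scale,
#' the apparent-prevalence binomial term with delta-method terms
#' `pi^2 Var(Se)` and `(1 - pi)^2 Var(Sp)`. The interval is *not* clamped to
#' `[0, 1]` by default, so bounds such as 103.3% are reported as-is.
#'
#' @param positives,n positive classifications and total documents.
#' @param sens_tp,sens_fn validation true positives / false negatives from
#'   which sensitivity was estimated.
#' @param spec_tn,spec_fp validation true negatives / false positives.
#' @param level confidence level (default 0.95).
#' @param clamp clamp the interval to `[0, 1]`.
#' @return named numeric: ci_low, ci_high.
#' @export
adjusted_prevalence_ci <- function(positives, n, sens_tp, sens_fn,
                                   spec_tn, spec_fp, level = 0.95,
                                   clamp = FALSE) {
  stopifnot(n > 0, positives >= 0, positives <= n,
            sens_tp + sens_fn > 0, spec_tn + spec_fp > 0,
            level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sens_tp / (sens_tp + sens_fn)
  sp <- spec_tn / (spec_tn + spec_fp)
  j <- se + sp - 1
  if (j <= 0) {
    stop("sensitivity + specificity <= 1: estimator undefined", call. = FALSE)
  }
  n_se <- sens_tp + sens_fn
  n_sp <- spec_tn + spec_fp
  nt <- n + z^2
  pt <- (positives + z^2 / 2) / nt
  pi_hat <- (pt + sp - 1) / j
  v <- (pt * (1 - pt) / nt +
          pi_hat^2 * se * (1 - se) / n_se +
          (1 - pi_hat)^2 * sp * (1 - sp) / n_sp) / j^2
  half <- z * sqrt(v)
  ci <- c(ci_low = pi_hat - half, ci_high = pi_hat + half)
  if (clamp) ci <- pmin(pmax(ci, 0), 1)
  ci
}

#' Prevalence estimates for all categories, with AUC gating
#'
#' Categories whose evaluation AUC falls below `gate` (default 0.80) are
#' flagged `gate_passed = FALSE` and receive no adjusted estimate, mirroring
#' the exclusion of unreliable classifiers from downstream reporting.
#' Adjusted point estimates use Rogan-Gladen with the evaluation's
#' sensitivity/specificity; intervals propagate validation-count
#' uncertainty via [adjusted_prevalence_ci()].
#'
#' @param labels binary matrix (documents x categories) of classifier
#'   decisions on the cohort of interest.
#' @param evaluations data.frame with columns category, auc, sensitivity,
#'   specificity (one row per category, one split).
#' @param validation_counts data.frame with columns category, tp, fn, tn,
#'   fp: the confusion counts behind each evaluation.
#' @param gate minimum AUC for adjusted reporting.
#' @param level confidence level.
#' @return data.frame: category, n, positives, observed, adjusted,
#'   adjusted_clamped, ci_low, ci_high, sensitivity_used, specificity_used,
#'   gate_passed.
#' @export
estimate_all <- function(labels, evaluations, validation_counts,
                         gate = 0.80, level = 0.95) {
  stopifnot(is.matrix(labels),
            all(c("category", "auc", "sensitivity", "specificity") %in%
                  names(evaluations)))
  out <- lapply(seq_len(nrow(evaluations)), function(i) {
    ev <- evaluations[i, ]
    cc <- ev$category
    if (!cc %in% colnames(labels)) return(NULL)
    x <- sum(labels[, cc] == 1)
    n <- nrow(labels)
    row <- data.frame(category = cc, n = n, positives = x, observed = x / n,
                      adjusted = NA_real_, adjusted_clamped = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      sensitivity_used = ev$sensitivity,
                      specificity_used = ev$specificity,
                      gate_passed = ev$auc >= gate,
                      stringsAsFactors = FALSE)
    if (row$gate_passed) {
      rg <- rogan_gladen(row$observed, ev$sensitivity, ev$specificity)
      if (rg$raw > 1 || rg$raw < 0) {
        warning(sprintf(
          "adjusted prevalence for %s is %.3f before clamping; classifier error rates are incompatible with the observed rate",
          cc, rg$raw), call. = FALSE)
      }
      row$adjusted <- rg$raw
      row$adjusted_clamped <- rg$clamped
      vc <- validation_counts[validation_counts$category == cc, ]
      if (nrow(vc) == 1) {
        ci <- adjusted_prevalence_ci(x, n, vc$tp, vc$fn, vc$tn, vc$fp,
                                     level = level)
        row$ci_low <- ci[["ci_low"]]
        row$ci_high <- ci[["ci_high"]]
      }
    }
    row
  })
  do.call(rbind, out)
}

#' Compare category prevalences between two groups
#'
#' Per category, a two-proportion chi-square test (without continuity
#' correction) on the 2x2 table of group by label; Fisher's exact test is
#' substituted when any expected cell count is below 5. P-values are
#' Benjamini-Hochberg adjusted across the category family of this one
#' comparison.
#'
#' @param labels binary matrix (documents x categories).
#' @param grouping factor/character of length `nrow(labels)` with exactly
#'   two levels; every group must be nonempty.
#' @param categories categories to compare (default: all columns).
#' @return data.frame: category, group_a, group_b, prevalence_a,
#'   prevalence_b, test, p_raw, p_fdr.
#' @export
compare_groups <- function(labels, grouping, categories = colnames(labels)) {
  grouping <- as.factor(as.character(grouping))
  stopifnot(length(grouping) == nrow(labels))
  lv <- levels(grouping)
  if (length(lv) != 2 || any(table(grouping) == 0)) {
    stop("exactly two nonempty groups required", call. = FALSE)
  }
  rows <- lapply(categories, function(cc) {
    pos <- vapply(lv, function(g) sum(labels[grouping == g, cc] == 1),
                  numeric(1))
    tot <- vapply(lv, function(g) sum(grouping == g), numeric(1))
    tab <- rbind(pos, tot - pos)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      test <- "chisq"
    }
    data.frame(category = cc, group_a = lv[1], group_b = lv[2],
               prevalence_a = pos[1] / tot[1], prevalence_b = pos[2] / tot[2],
               test = test, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  rownames(out) <- NULL
  out
}
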