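#' Cohen's kappa for two binary labelings
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement from product
#' marginals. Degenerate conventions are made explicit: when both raters
#' are constant and identical (`p_e = 1`, `p_o = 1`) kappa is defined as 1;
#' when `p_e = 1` with disagreement (impossible for product marginals) or a
#' single rater is constant so that `p_o = p_e`, kappa is 0.
#'
#' @param labels_a,labels_b equal-length binary 0/1 vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  n <- length(labels_a)
  stopifnot(n > 0)
  a <- as.integer(labels_a)
  b <- as.integer(labels_b)
  stopifnot(all(a %in% 0:1), all(b %in% 0:1))
  po <- mean(a == b)
  pa <- mean(a)
  pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (abs(1 - pe) < 1e-15) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Observed agreement (accuracy) between two binary labelings
#' @inheritParams cohen_kappa
#' @return proportion of agreement in `[0, 1]`.
#' @export
agreement_accuracy <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  mean(as.integer(labels_a) == as.integer(labels_b))
}

#' Document-level inter-annotator agreement per category
#'
#' Accuracy and Cohen's kappa per NPS category between two annotator views,
#' plus a summary row: median accuracy and median kappa across categories
#' and the micro-averaged accuracy over all document-category cells.
#'
#' @param view_a,view_b binary matrices (documents x categories) with
#'   identical dimnames.
#' @return data.frame: category, accuracy, kappa, n; last row is
#'   `"overall"` (medians; accuracy column additionally reported in
#'   `micro_accuracy`).
#' @export
pairwise_annotation_agreement <- function(view_a, view_b) {
  if (!identical(dim(view_a), dim(view_b)) ||
      !identical(rownames(view_a), rownames(view_b))) {
    stop("annotator views cover different document sets", call. = FALSE)
  }
  cats <- colnames(view_a)
  per <- lapply(cats, function(cc) {
    data.frame(category = cc,
               accuracy = agreement_accuracy(view_a[, cc], view_b[, cc]),
               kappa = cohen_kappa(view_a[, cc], view_b[, cc]),
               n = nrow(view_a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  overall <- data.frame(category = "overall",
                        accuracy = stats::median(out$accuracy),
                        kappa = stats::median(out$kappa),
                        n = nrow(view_a), stringsAsFactors = FALSE)
  out <- rbind(out, overall)
  attr(out, "micro_accuracy") <- mean(view_a == view_b)
  out
}

#' NPI domain presence at a score threshold
#'
#' Presence of a domain is `score >= threshold`; threshold 1 is the default
#' presence rule, threshold 4 marks clinically relevant symptoms and is
#' used as a sensitivity analysis.
#'
#' @param npi long data.frame with columns patient_id, domain, score,
#'   available (as from [generate_npi_assessments()]).
#' @param threshold minimum score counting as present (default 1).
#' @return binary matrix (patients with available NPI x 12 domains).
#' @export
npi_presence <- function(npi, threshold = 1) {
  stopifnot(all(c("patient_id", "domain", "score", "available") %in%
                  names(npi)), threshold >= 1)
  npi <- npi[npi$available, , drop = FALSE]
  if (nrow(npi) == 0) {
    stop("no available NPI assessments", call. = FALSE)
  }
  doms <- npi_domains()
  pats <- unique(npi$patient_id)
  m <- matrix(0L, nrow = length(pats), ncol = length(doms),
              dimnames = list(pats, doms))
  m[cbind(match(npi$patient_id, pats), match(npi$domain, doms))] <-
    as.integer(npi$score >= threshold)
  m
}

#' Intra-individual agreement between note-derived and NPI-reported NPS
#'
#' Per NPI-mappable category: Cohen's kappa between the EHR label and NPI
#' presence, the proportion of EHR-positive patients whose NPS is not
#' endorsed on the NPI (`EHR+NPI-` over all EHR+), and the proportion of
#' NPI-positive patients without the NPS in their notes (`EHR-NPI+` over
#' all NPI+). Zero denominators yield `NA`, not zero. Restricted to
#' patients present in both inputs; `nps_general` has no NPI counterpart
#' and is never compared.
#'
#' @param ehr_labels binary matrix (patients x categories), rownames =
#'   patient_id.
#' @param npi_presence_matrix binary matrix from [npi_presence()].
#' @param categories categories to compare; default all 12 NPI domains.
#'   Gate-failed categories should be excluded by the caller.
#' @return data.frame: category, kappa, prop_ehr_pos_npi_neg,
#'   prop_ehr_neg_npi_pos, n; with attributes `median_prevalence_ehr` and
#'   `median_prevalence_npi`.
#' @export
compare_ehr_npi <- function(ehr_labels, npi_presence_matrix,
                            categories = npi_domains()) {
  categories <- setdiff(categories, "nps_general")
  pats <- intersect(rownames(ehr_labels), rownames(npi_presence_matrix))
  if (length(pats) == 0) {
    stop("no patients shared between EHR labels and NPI assessments",
         call. = FALSE)
  }
  e <- ehr_labels[pats, , drop = FALSE]
  q <- npi_presence_matrix[pats, , drop = FALSE]
  if (length(categories) == 0) {
    out <- data.frame(category = character(0), kappa = numeric(0),
                      prop_ehr_pos_npi_neg = numeric(0),
                      prop_ehr_neg_npi_pos = numeric(0), n = integer(0))
    attr(out, "median_prevalence_ehr") <- NA_real_
    attr(out, "median_prevalence_npi") <- NA_real_
    return(out)
  }
  rows <- lapply(categories, function(cc) {
    ev <- as.integer(e[, cc])
    nv <- as.integer(q[, cc])
    n_ehr_pos <- sum(ev == 1)
    n_npi_pos <- sum(nv == 1)
    data.frame(
      category = cc,
      kappa = cohen_kappa(ev, nv),
      prop_ehr_pos_npi_neg =
        if (n_ehr_pos > 0) sum(ev == 1 & nv == 0) / n_ehr_pos else NA_real_,
      prop_ehr_neg_npi_pos =
        if (n_npi_pos > 0) sum(ev == 0 & nv == 1) / n_npi_pos else NA_real_,
      n = length(pats), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "median_prevalence_ehr") <-
    stats::median(colMeans(e[, categories, drop = FALSE]))
  attr(out, "median_prevalence_npi") <-
    stats::median(colMeans(q[, categories, drop = FALSE]))
  out
}
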