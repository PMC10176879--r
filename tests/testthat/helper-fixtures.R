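# Shared fixtures, all built in code.

# tiny fast synthetic config (invalid-free defaults, small n)
tiny_config <- function(...) {
  defaults <- list(n_patients = 40, notes_per_patient = 2,
                   background_vocab_size = 60, seed = 7)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# a gold matrix drawn directly (no text), for annotator/NPI oracles
random_gold <- function(n, prevalence = 0.5, seed = 1) {
  cats <- nps_categories()
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * length(cats), 1L, prevalence), nrow = n,
                dimnames = list(sprintf("doc_A%04d", seq_len(n)), cats))
    m
  })
}

# brute-force AUC by pair enumeration (independent oracle)
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# expected kappa for two conditionally independent imperfect raters
expected_kappa_two_raters <- function(prev, se1, sp1, se2, sp2) {
  p11 <- prev * se1 * se2 + (1 - prev) * (1 - sp1) * (1 - sp2)
  p00 <- prev * (1 - se1) * (1 - se2) + (1 - prev) * sp1 * sp2
  po <- p11 + p00
  p1 <- prev * se1 + (1 - prev) * (1 - sp1)
  p2 <- prev * se2 + (1 - prev) * (1 - sp2)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  (po - pe) / (1 - pe)
}

# construct a score/label vector realizing given confusion counts at 0.5
scores_for_counts <- function(tp, fn, tn, fp) {
  list(scores = c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp)),
       labels = c(rep(1, tp + fn), rep(0, tn + fp)))
}
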