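#' The 13 neuropsychiatric symptom (NPS) categories
#'
#' Twelve categories correspond one-to-one to the domains of the
#' Neuropsychiatric Inventory (NPI); the 13th, `nps_general`, collects
#' non-specific descriptions of behavioural change and has no NPI
#' counterpart.
#'
#' @return Character vector of 13 category names, in canonical order.
#' @export
#' @examples
#' nps_categories()
nps_categories <- function() {
  c("delusions", "hallucinations", "agitation", "depression", "anxiety",
    "euphoria", "apathy", "disinhibition", "irritability",
    "aberrant_motor_behavior", "sleeping_behavior", "eating_behavior",
    "nps_general")
}

#' The 12 categories with an NPI domain counterpart
#'
#' @return Character vector of 12 category names (all except `nps_general`).
#' @export
npi_domains <- function() {
  setdiff(nps_categories(), "nps_general")
}

# Synonyms used by annotation guidelines; extended via the `synonyms`
# argument of read_brat().
default_category_synonyms <- function() {
  c(amb               = "aberrant_motor_behavior",
    motor             = "aberrant_motor_behavior",
    sleep             = "sleeping_behavior",
    sleeping          = "sleeping_behavior",
    eating            = "eating_behavior",
    appetite          = "eating_behavior",
    elation           = "euphoria",
    dysphoria         = "depression",
    general           = "nps_general",
    nps               = "nps_general")
}

#' Map a raw label onto a canonical NPS category
#'
#' Matching is case-insensitive; spaces and hyphens are treated as
#' underscores. A synonym table (guideline label -> canonical name) can be
#' supplied on top of the built-in one.
#'
#' @param label character vector of raw labels.
#' @param synonyms named character vector mapping lowercase raw labels to
#'   canonical category names; merged over the built-in table.
#' @return character vector of canonical category names.
#' @export
match_category <- function(label, synonyms = NULL) {
  syn <- default_category_synonyms()
  if (!is.null(synonyms)) syn[tolower(names(synonyms))] <- unname(synonyms)
  key <- gsub("[ -]+", "_", tolower(trimws(label)))
  out <- ifelse(key %in% nps_categories(), key, unname(syn[key]))
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown NPS category label(s): ",
         paste(unique(label[bad]), collapse = ", "),
         "; valid names: ", paste(nps_categories(), collapse = ", "),
         call. = FALSE)
  }
  out
}

# Internal: validate a probability (scalar or vector), with a name for errors
check_prob <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1) ||
      (!allow_zero && any(x == 0))) {
    stop(sprintf("`%s` must be probability in %s", name,
                 if (allow_zero) "[0, 1]" else "(0, 1]"), call. = FALSE)
  }
  invisible(x)
}

# Internal: derive a child seed from a base seed, kept inside 32-bit range
child_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}

# Internal: evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
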