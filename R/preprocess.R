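#' Sentence-boundary marker token
#'
#' Tokenization keeps sentence boundaries as internal marker tokens so that
#' negation windows and bigrams never cross a sentence. The marker contains
#' punctuation, so it can never collide with a real (alphanumeric) token.
#'
#' @return the marker string.
#' @export
sentence_boundary <- function() "<.>"

#' Preprocessing configuration
#'
#' @param stopword_list character vector of stop-word tokens (lowercase).
#' @param stemmer `"identity"` or `"porter"` (snowball-style English).
#' @param negation_cues tokens that open a negated phrase.
#' @param negation_window tokens removed after a negation cue (>= 1,
#'   truncated at a sentence boundary); default 3.
#' @param lowercase lowercase text before tokenization.
#' @param min_document_frequency features occurring in fewer documents are
#'   pruned from the vocabulary (computed on the training corpus only).
#' @param binary if TRUE the document-term matrix holds presence (0/1)
#'   instead of counts.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(stopword_list = default_stopwords(),
                              stemmer = "identity",
                              negation_cues = default_negation_cues(),
                              negation_window = 3,
                              lowercase = TRUE,
                              min_document_frequency = 2,
                              binary = FALSE) {
  if (!stemmer %in% c("identity", "porter")) {
    stop("unknown stemmer ", dQuote(stemmer),
         "; available: identity, porter", call. = FALSE)
  }
  stopifnot(negation_window >= 1, min_document_frequency >= 1)
  structure(list(stopword_list = tolower(stopword_list), stemmer = stemmer,
                 negation_cues = tolower(negation_cues),
                 negation_window = as.integer(negation_window),
                 lowercase = isTRUE(lowercase),
                 min_document_frequency = as.integer(min_document_frequency),
                 binary = isTRUE(binary)),
            class = "preprocess_config")
}

#' A small default English stop-word list
#'
#' Deliberately excludes negation cues ("no", "not", ...), which are handled
#' by negation-phrase removal before stop words are stripped.
#' @return character vector.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "of", "in", "on", "at", "to",
    "for", "with", "by", "from", "as", "is", "are", "was", "were", "be",
    "been", "being", "has", "have", "had", "do", "does", "did", "he", "she",
    "it", "they", "them", "his", "her", "its", "their", "this", "that",
    "these", "those", "there", "here", "which", "who", "whom", "what",
    "when", "where", "how", "than", "then", "so", "such", "very", "can",
    "could", "will", "would", "shall", "should", "may", "might", "must",
    "am", "i", "we", "you", "your", "our", "my", "me", "us")
}

#' Tokenize text into word tokens with sentence-boundary markers
#'
#' Tokens are maximal runs of letters/digits, lowercased when configured.
#' Sentence-ending punctuation (`. ! ? ; :` and newline) becomes a boundary
#' marker; consecutive, leading and trailing markers are collapsed away.
#' Other punctuation merely separates tokens.
#'
#' @param text character scalar.
#' @param lowercase lowercase before tokenizing.
#' @return character vector of tokens and boundary markers.
#' @export
#' @examples
#' tokenize("No depressive symptoms.")
#' tokenize("MMSE 21/30")
tokenize <- function(text, lowercase = TRUE) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(character(0))
  if (lowercase) text <- tolower(text)
  raw <- regmatches(text, gregexpr("[[:alnum:]]+|[.!?;:\n]", text))[[1]]
  b <- sentence_boundary()
  toks <- ifelse(grepl("^[[:alnum:]]", raw), raw, b)
  normalize_boundaries(toks)
}

# drop leading/trailing boundary markers and collapse runs
normalize_boundaries <- function(tokens) {
  b <- sentence_boundary()
  if (length(tokens) == 0) return(tokens)
  keep <- !(tokens == b & c(TRUE, tokens[-length(tokens)] == b))
  tokens <- tokens[keep]
  while (length(tokens) > 0 && tokens[length(tokens)] == b) {
    tokens <- tokens[-length(tokens)]
  }
  tokens
}

#' Remove negated phrases from a token stream
#'
#' Each negation cue is removed together with up to `negation_window`
#' following tokens; removal stops at a sentence boundary. This is
#' cue-plus-window removal, not full scope detection.
#'
#' @param tokens token vector from [tokenize()].
#' @param negation_cues cue tokens.
#' @param negation_window maximum tokens removed after a cue.
#' @return token vector with negated phrases removed.
#' @export
#' @examples
#' remove_negated_phrases(c("no", "depressive", "symptoms"))
remove_negated_phrases <- function(tokens,
                                   negation_cues = default_negation_cues(),
                                   negation_window = 3) {
  b <- sentence_boundary()
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (tokens[i] %in% negation_cues) {
      j <- i + 1L
      taken <- 0L
      while (j <= n && taken < negation_window && tokens[j] != b) {
        j <- j + 1L
        taken <- taken + 1L
      }
      i <- j
    } else {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  normalize_boundaries(out)
}

#' Remove stop words, then stem
#'
#' @param tokens token vector (boundary markers pass through untouched).
#' @param stopword_list stop words to drop.
#' @param stemmer `"identity"` or `"porter"`.
#' @return filtered, stemmed token vector.
#' @export
stem_and_filter <- function(tokens, stopword_list = default_stopwords(),
                            stemmer = "identity") {
  b <- sentence_boundary()
  tokens <- tokens[!(tokens %in% stopword_list)]
  if (stemmer == "porter") {
    w <- tokens != b
    tokens[w] <- porter_stem(tokens[w])
  } else if (stemmer != "identity") {
    stop("unknown stemmer ", dQuote(stemmer), call. = FALSE)
  }
  normalize_boundaries(tokens)
}

#' Extract unigram and bigram features
#'
#' All unigrams plus all bigrams of adjacent tokens that do not span a
#' sentence boundary; bigrams are underscore-joined.
#'
#' @param tokens token vector.
#' @return character vector (multiset) of features.
#' @export
#' @examples
#' extract_ngrams(c("a", "b", "c"))
extract_ngrams <- function(tokens) {
  b <- sentence_boundary()
  uni <- tokens[tokens != b]
  if (length(tokens) >= 2) {
    left <- tokens[-length(tokens)]
    right <- tokens[-1]
    ok <- left != b & right != b
    big <- paste(left[ok], right[ok], sep = "_")
  } else {
    big <- character(0)
  }
  c(uni, big)
}

# full per-document pipeline: text -> feature multiset
featurize_text <- function(text, config) {
  toks <- tokenize(text, lowercase = config$lowercase)
  toks <- remove_negated_phrases(toks, config$negation_cues,
                                 config$negation_window)
  toks <- stem_and_filter(toks, config$stopword_list, config$stemmer)
  extract_ngrams(toks)
}

#' Build a document-term matrix
#'
#' Pipeline order: tokenize, negation-phrase removal, stop-word removal and
#' stemming, n-gram extraction, counting. When `vocabulary` is NULL the
#' vocabulary is all features with document frequency >=
#' `min_document_frequency` in *this* corpus; when a training vocabulary is
#' supplied (featurizing an external corpus) it is reused as-is and
#' out-of-vocabulary features are dropped, so no information flows from the
#' external corpus into the feature space.
#'
#' @param corpus data.frame with `doc_id` and `text` columns (as produced by
#'   [generate_corpus()]), or a named character vector of texts.
#' @param config a [preprocess_config()].
#' @param vocabulary optional character vector fixing the feature space.
#' @return sparse `dgCMatrix` (documents x features) with doc_id rownames;
#'   the vocabulary is `colnames()`.
#' @export
build_doc_term_matrix <- function(corpus, config = preprocess_config(),
                                  vocabulary = NULL) {
  if (is.data.frame(corpus)) {
    texts <- stats::setNames(corpus$text, corpus$doc_id)
  } else {
    texts <- corpus
  }
  if (length(texts) == 0) stop("empty corpus", call. = FALSE)
  if (is.null(names(texts)) || anyDuplicated(names(texts))) {
    stop("corpus must carry unique doc_ids", call. = FALSE)
  }

  counts <- lapply(texts, function(tx) table(featurize_text(tx, config)))

  if (is.null(vocabulary)) {
    df <- table(unlist(lapply(counts, names), use.names = FALSE))
    vocabulary <- sort(names(df)[df >= config$min_document_frequency])
    if (length(vocabulary) == 0) {
      stop("vocabulary empty after pruning at min_document_frequency = ",
           config$min_document_frequency,
           "; lower the threshold or supply more documents", call. = FALSE)
    }
  }

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(counts)) {
    tb <- counts[[d]]
    j <- match(names(tb), vocabulary)
    keep <- !is.na(j)
    if (any(keep)) {
      ii <- c(ii, rep.int(d, sum(keep)))
      jj <- c(jj, j[keep])
      xx <- c(xx, as.numeric(tb[keep]))
    }
  }
  if (config$binary) xx <- pmin(xx, 1)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(texts), length(vocabulary)),
                       dimnames = list(names(texts), vocabulary))
}

#' Serialize a document-term matrix as MTX plus sidecar files
#'
#' Writes `<stem>.mtx` (sparse coordinate), `<stem>.vocab.txt` (one feature
#' per line, column order) and `<stem>.docs.txt` (one doc_id per line, row
#' order).
#'
#' @param dtm matrix from [build_doc_term_matrix()].
#' @param stem path prefix.
#' @return `stem`, invisibly.
#' @export
write_dtm <- function(dtm, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dtm, paste0(stem, ".mtx"))
  writeLines(colnames(dtm), paste0(stem, ".vocab.txt"))
  writeLines(rownames(dtm), paste0(stem, ".docs.txt"))
  invisible(stem)
}

#' Read a document-term matrix written by [write_dtm()]
#' @param stem path prefix.
#' @return sparse `dgCMatrix` with dimnames restored.
#' @export
read_dtm <- function(stem) {
  m <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  # writeMM stores an all-ones matrix as a pattern matrix; restore numeric
  if (methods::is(m, "nMatrix")) m <- m * 1
  dimnames(m) <- list(readLines(paste0(stem, ".docs.txt")),
                      readLines(paste0(stem, ".vocab.txt")))
  m
}
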