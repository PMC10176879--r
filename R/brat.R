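#' Parse brat standoff annotations
#'
#' Reads the text-bound ("T") lines of a brat `.ann` file into an annotation
#' set. Offsets are 0-based, end-exclusive, counted in Unicode code points;
#' every span's surface text is verified against the document. Discontinuous
#' spans (semicolon-separated fragments) are collapsed to their minimal
#' covering interval, which is immaterial for document-level label
#' reduction. Relation, event and attribute lines (R/E/A/M/N/#) are ignored
#' with a warning.
#'
#' @param ann_content character scalar (or vector of lines) with the `.ann`
#'   file content.
#' @param doc_text the document text the annotations refer to.
#' @param doc_id document identifier attached to each span.
#' @param synonyms optional category synonym table, see [match_category()].
#' @return A list of class `annotation_set` with fields `rater_id` (NA until
#'   set) and `spans` (data.frame: span_id, doc_id, category, start, end,
#'   surface_text).
#' @export
read_brat <- function(ann_content, doc_text, doc_id, synonyms = NULL) {
  stopifnot(is.character(ann_content), length(doc_text) == 1)
  lines <- unlist(strsplit(ann_content, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]

  is_t <- grepl("^T", lines)
  other <- lines[!is_t]
  if (length(other) > 0) {
    warning(sprintf("ignoring %d non-text-bound annotation line(s) in %s",
                    length(other), doc_id), call. = FALSE)
  }

  spans <- data.frame(span_id = character(0), doc_id = character(0),
                      category = character(0), start = integer(0),
                      end = integer(0), surface_text = character(0),
                      stringsAsFactors = FALSE)
  nchar_doc <- nchar(doc_text, type = "chars")
  for (ln in lines[is_t]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed brat line (expected 3 tab-separated fields): ", ln,
           call. = FALSE)
    }
    span_id <- parts[1]
    surface <- paste(parts[-(1:2)], collapse = "\t")
    mid <- strsplit(trimws(parts[2]), " ", fixed = TRUE)[[1]]
    if (length(mid) < 3) {
      stop("malformed brat line (expected 'Category start end'): ", ln,
           call. = FALSE)
    }
    category <- match_category(mid[1], synonyms)
    # discontinuous fragments: "start end;start end" -> covering interval
    offs <- suppressWarnings(
      as.integer(unlist(strsplit(paste(mid[-1], collapse = " "), "[ ;]+"))))
    if (anyNA(offs)) {
      stop("malformed brat offsets in line: ", ln, call. = FALSE)
    }
    start <- min(offs); end <- max(offs)
    if (start < 0 || start >= end || end > nchar_doc) {
      stop(sprintf("offsets [%d, %d) outside document %s (length %d): %s",
                   start, end, doc_id, nchar_doc, ln), call. = FALSE)
    }
    got <- substr(doc_text, start + 1L, end)
    if (got != surface) {
      stop(sprintf(
        "surface text mismatch in %s for %s: annotation says %s, document has %s",
        doc_id, span_id, dQuote(surface), dQuote(got)), call. = FALSE)
    }
    spans <- rbind(spans, data.frame(
      span_id = span_id, doc_id = doc_id, category = category,
      start = start, end = end, surface_text = surface,
      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(spans$span_id)) {
    stop("duplicate span ids in ", doc_id, call. = FALSE)
  }
  structure(list(rater_id = NA_character_, spans = spans),
            class = "annotation_set")
}

#' Serialize an annotation set to brat standoff format
#'
#' Inverse of [read_brat()]: emits one text-bound line per span, in span-id
#' order (numeric part of the `T` id) regardless of insertion order, so
#' output is stable. Refuses to serialize spans whose surface text does not
#' match the document.
#'
#' @param annotations an `annotation_set`.
#' @param doc_text the document text, used to re-verify every span.
#' @return character scalar with the `.ann` file content.
#' @export
write_brat <- function(annotations, doc_text) {
  stopifnot(inherits(annotations, "annotation_set"))
  sp <- annotations$spans
  if (nrow(sp) == 0) return("")
  if (anyDuplicated(sp$span_id)) {
    stop("duplicate span ids; refusing to serialize", call. = FALSE)
  }
  nchar_doc <- nchar(doc_text, type = "chars")
  bad <- sp$start < 0 | sp$start >= sp$end | sp$end > nchar_doc
  if (any(bad)) {
    stop("span offsets violate invariants; refusing to serialize",
         call. = FALSE)
  }
  got <- substr(rep(doc_text, nrow(sp)), sp$start + 1L, sp$end)
  if (any(got != sp$surface_text)) {
    stop("surface text does not match document; refusing to serialize",
         call. = FALSE)
  }
  ord <- order(as.integer(sub("^T", "", sp$span_id)))
  sp <- sp[ord, , drop = FALSE]
  paste0(sp$span_id, "\t",
         vapply(sp$category, brat_label, character(1)), " ",
         sp$start, " ", sp$end, "\t", sp$surface_text,
         collapse = "\n")
}

# Canonical label spelling used when writing .ann files
brat_label <- function(category) {
  parts <- strsplit(category, "_", fixed = TRUE)[[1]]
  paste(toupper(substring(parts, 1, 1)), substring(parts, 2),
        sep = "", collapse = "_")
}

#' Reduce span annotations to a document-level label matrix
#'
#' Cell (d, c) is 1 iff at least one span of category c exists in document
#' d; documents with no spans get all-zero rows. Idempotent under span
#' duplication.
#'
#' @param annotations an `annotation_set`, or a list of them (pooled).
#' @param doc_ids character vector of all document ids (defines rows).
#' @return binary matrix, `length(doc_ids)` x 13, rownames = doc_ids.
#' @export
labels_from_spans <- function(annotations, doc_ids) {
  if (inherits(annotations, "annotation_set")) annotations <- list(annotations)
  spans <- do.call(rbind, lapply(annotations, `[[`, "spans"))
  cats <- nps_categories()
  m <- matrix(0L, nrow = length(doc_ids), ncol = length(cats),
              dimnames = list(doc_ids, cats))
  if (!is.null(spans) && nrow(spans) > 0) {
    orphan <- setdiff(unique(spans$doc_id), doc_ids)
    if (length(orphan) > 0) {
      stop("spans reference unknown doc_id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    m[cbind(match(spans$doc_id, doc_ids), match(spans$category, cats))] <- 1L
  }
  m
}

#' Read a directory of paired .txt/.ann files
#'
#' @param dir directory containing `<doc_id>.txt` and `<doc_id>.ann` pairs.
#' @param synonyms optional category synonym table.
#' @return list of `annotation_set` objects, named by doc_id. Documents
#'   without an `.ann` file get an empty set.
#' @export
read_brat_dir <- function(dir, synonyms = NULL) {
  txts <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  out <- list()
  for (tf in txts) {
    doc_id <- sub("\\.txt$", "", basename(tf))
    doc_text <- paste(readLines(tf, warn = FALSE, encoding = "UTF-8"),
                      collapse = "\n")
    af <- sub("\\.txt$", ".ann", tf)
    ann <- if (file.exists(af)) {
      paste(readLines(af, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    } else ""
    out[[doc_id]] <- read_brat(ann, doc_text, doc_id, synonyms)
  }
  out
}
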