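# Porter stemming algorithm (1980), self-contained.
# Operates on lowercase words; words of length <= 2 are left unchanged.

pt_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

# consonant test: not aeiou; 'y' is a consonant at position 1 or after a vowel
pt_cons <- function(ch, i) {
  c <- ch[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1L) return(TRUE)
    return(!pt_cons(ch, i - 1L))
  }
  TRUE
}

pt_types <- function(stem) {
  ch <- pt_chars(stem)
  vapply(seq_along(ch), function(i) pt_cons(ch, i), logical(1))
}

# measure m of [C](VC)^m[V]
pt_m <- function(stem) {
  if (nchar(stem) == 0) return(0L)
  runs <- rle(pt_types(stem))$values
  if (length(runs) < 2) return(0L)
  sum(!runs[-length(runs)] & runs[-1])
}

pt_has_vowel <- function(stem) {
  nchar(stem) > 0 && any(!pt_types(stem))
}

# *d: ends with a double consonant
pt_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2) return(FALSE)
  ch <- pt_chars(stem)
  ch[n] == ch[n - 1] && pt_cons(ch, n)
}

# *o: ends cvc where the final c is not w, x or y
pt_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3) return(FALSE)
  ch <- pt_chars(stem)
  pt_cons(ch, n - 2) && !pt_cons(ch, n - 1) && pt_cons(ch, n) &&
    !(ch[n] %in% c("w", "x", "y"))
}

pt_ends <- function(w, suf) {
  n <- nchar(w); k <- nchar(suf)
  n >= k && substring(w, n - k + 1, n) == suf
}

pt_trim <- function(w, k) substring(w, 1, nchar(w) - k)

# apply the first matching rule from a list of c(suffix, replacement, min_m)
pt_rule_set <- function(w, rules) {
  for (r in rules) {
    suf <- r[[1]]
    if (pt_ends(w, suf)) {
      stem <- pt_trim(w, nchar(suf))
      if (pt_m(stem) > r[[3]]) return(paste0(stem, r[[2]]))
      return(w)
    }
  }
  w
}

porter1 <- function(w) {
  if (nchar(w) <= 2) return(w)

  # step 1a
  if (pt_ends(w, "sses")) w <- pt_trim(w, 2)
  else if (pt_ends(w, "ies")) w <- paste0(pt_trim(w, 3), "i")
  else if (pt_ends(w, "ss")) w <- w
  else if (pt_ends(w, "s")) w <- pt_trim(w, 1)

  # step 1b
  cleanup <- FALSE
  if (pt_ends(w, "eed")) {
    if (pt_m(pt_trim(w, 3)) > 0) w <- pt_trim(w, 1)
  } else if (pt_ends(w, "ed") && pt_has_vowel(pt_trim(w, 2))) {
    w <- pt_trim(w, 2); cleanup <- TRUE
  } else if (pt_ends(w, "ing") && pt_has_vowel(pt_trim(w, 3))) {
    w <- pt_trim(w, 3); cleanup <- TRUE
  }
  if (cleanup) {
    if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (pt_double_cons(w) &&
               !pt_ends(w, "l") && !pt_ends(w, "s") && !pt_ends(w, "z")) {
      w <- pt_trim(w, 1)
    } else if (pt_m(w) == 1 && pt_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (pt_ends(w, "y") && pt_has_vowel(pt_trim(w, 1))) {
    w <- paste0(pt_trim(w, 1), "i")
  }

  # step 2 (m > 0)
  w <- pt_rule_set(w, list(
    list("ational", "ate", 0), list("tional", "tion", 0),
    list("enci", "ence", 0), list("anci", "ance", 0),
    list("izer", "ize", 0), list("abli", "able", 0),
    list("alli", "al", 0), list("entli", "ent", 0), list("eli", "e", 0),
    list("ousli", "ous", 0), list("ization", "ize", 0),
    list("ation", "ate", 0), list("ator", "ate", 0), list("alism", "al", 0),
    list("iveness", "ive", 0), list("fulness", "ful", 0),
    list("ousness", "ous", 0), list("aliti", "al", 0),
    list("iviti", "ive", 0), list("biliti", "ble", 0)))

  # step 3 (m > 0)
  w <- pt_rule_set(w, list(
    list("icate", "ic", 0), list("ative", "", 0), list("alize", "al", 0),
    list("iciti", "ic", 0), list("ical", "ic", 0), list("ful", "", 0),
    list("ness", "", 0)))

  # step 4 (m > 1); "ion" needs a preceding s or t
  for (suf in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")) {
    if (pt_ends(w, suf)) {
      stem <- pt_trim(w, nchar(suf))
      ok <- pt_m(stem) > 1 &&
        (suf != "ion" || pt_ends(stem, "s") || pt_ends(stem, "t"))
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (pt_ends(w, "e")) {
    stem <- pt_trim(w, 1)
    m <- pt_m(stem)
    if (m > 1 || (m == 1 && !pt_cvc(stem))) w <- stem
  }
  # step 5b
  if (pt_m(w) > 1 && pt_double_cons(w) && pt_ends(w, "l")) w <- pt_trim(w, 1)

  w
}

#' Stem words with the built-in Porter (snowball-style English) stemmer
#'
#' @param words character vector of lowercase tokens. Tokens containing
#'   non-letters are returned unchanged.
#' @return character vector of stems.
#' @export
#' @examples
#' porter_stem(c("symptoms", "agitated", "hallucinations"))
porter_stem <- function(words) {
  out <- words
  idx <- grepl("^[a-z]+$", words)
  out[idx] <- vapply(words[idx], porter1, character(1), USE.NAMES = FALSE)
  out
}
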