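# Porter (1980) stemming algorithm, implemented directly from the published
# step tables. Operates on lowercase alphabetic words; any token containing
# a non-letter is returned unchanged. Used as the morphology feature for
# Model 2 and as the default lemmatizer stand-in for Model 1.

porter_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_cons(chars, i - 1L)) # y after consonant is a vowel
  }
  TRUE
}

porter_shape <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  vapply(seq_along(chars), function(i) porter_cons(chars, i), logical(1))
}

# m = number of VC blocks in [C](VC){m}[V]
porter_m <- function(word) {
  cons <- porter_shape(word)
  if (length(cons) == 0) return(0L)
  runs <- rle(cons)$values
  # VC pairs: a vowel run immediately followed by a consonant run
  sum(!runs & c(runs[-1], FALSE))
}

porter_has_vowel <- function(word) {
  any(!porter_shape(word))
}

porter_ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1); b <- substr(word, n, n)
  a == b && porter_shape(word)[n]
}

# *o: stem ends cvc where final c is not w, x or y
porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  cons <- porter_shape(word)
  if (!(cons[n] && !cons[n - 1] && cons[n - 2])) return(FALSE)
  !substr(word, n, n) %in% c("w", "x", "y")
}

ends_with <- function(word, suf) {
  n <- nchar(word); k <- nchar(suf)
  n >= k && substr(word, n - k + 1, n) == suf
}

chop <- function(word, k) substr(word, 1, nchar(word) - k)

# try rules in order: list of c(suffix, replacement, min_m); first suffix
# that matches fires (whether or not the m condition passes)
porter_rule_set <- function(word, rules, cond = NULL) {
  for (r in rules) {
    suf <- r[[1]]
    if (ends_with(word, suf)) {
      stem <- chop(word, nchar(suf))
      ok <- if (is.null(cond)) porter_m(stem) > as.integer(r[[3]]) else cond(stem)
      if (ok) return(paste0(stem, r[[2]]))
      return(word)
    }
  }
  word
}

porter_step1 <- function(word) {
  # 1a
  if (ends_with(word, "sses")) word <- paste0(chop(word, 4), "ss")
  else if (ends_with(word, "ies")) word <- paste0(chop(word, 3), "i")
  else if (ends_with(word, "ss")) word <- word
  else if (ends_with(word, "s")) word <- chop(word, 1)
  # 1b
  flag <- FALSE
  if (ends_with(word, "eed")) {
    if (porter_m(chop(word, 3)) > 0) word <- chop(word, 1)
  } else if (ends_with(word, "ed") && porter_has_vowel(chop(word, 2))) {
    word <- chop(word, 2); flag <- TRUE
  } else if (ends_with(word, "ing") && porter_has_vowel(chop(word, 3))) {
    word <- chop(word, 3); flag <- TRUE
  }
  if (flag) {
    if (ends_with(word, "at") || ends_with(word, "bl") || ends_with(word, "iz")) {
      word <- paste0(word, "e")
    } else if (porter_ends_double_cons(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- chop(word, 1)
    } else if (porter_m(word) == 1 && porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }
  # 1c
  if (ends_with(word, "y") && porter_has_vowel(chop(word, 1))) {
    word <- paste0(chop(word, 1), "i")
  }
  word
}

porter_step2 <- function(word) {
  porter_rule_set(word, list(
    list("ational", "ate", 0), list("tional", "tion", 0),
    list("enci", "ence", 0), list("anci", "ance", 0),
    list("izer", "ize", 0), list("abli", "able", 0),
    list("alli", "al", 0), list("entli", "ent", 0),
    list("eli", "e", 0), list("ousli", "ous", 0),
    list("ization", "ize", 0), list("ation", "ate", 0),
    list("ator", "ate", 0), list("alism", "al", 0),
    list("iveness", "ive", 0), list("fulness", "ful", 0),
    list("ousness", "ous", 0), list("aliti", "al", 0),
    list("iviti", "ive", 0), list("biliti", "ble", 0)
  ))
}

porter_step3 <- function(word) {
  porter_rule_set(word, list(
    list("icate", "ic", 0), list("ative", "", 0), list("alize", "al", 0),
    list("iciti", "ic", 0), list("ical", "ic", 0), list("ful", "", 0),
    list("ness", "", 0)
  ))
}

porter_step4 <- function(word) {
  rules <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ou", "ism", "ate", "iti", "ous",
             "ive", "ize")
  for (suf in rules) {
    if (ends_with(word, suf)) {
      stem <- chop(word, nchar(suf))
      if (porter_m(stem) > 1) return(stem)
      return(word)
    }
  }
  if (ends_with(word, "ion")) {
    stem <- chop(word, 3)
    last <- substr(stem, nchar(stem), nchar(stem))
    if (porter_m(stem) > 1 && last %in% c("s", "t")) return(stem)
  }
  word
}

porter_step5 <- function(word) {
  if (ends_with(word, "e")) {
    stem <- chop(word, 1)
    m <- porter_m(stem)
    if (m > 1 || (m == 1 && !porter_cvc(stem))) word <- stem
  }
  if (porter_m(word) > 1 && porter_ends_double_cons(word) &&
      ends_with(word, "l")) {
    word <- chop(word, 1)
  }
  word
}

porter_one <- function(word) {
  if (nchar(word) <= 2) return(word)
  w <- porter_step1(word)
  w <- porter_step2(w)
  w <- porter_step3(w)
  w <- porter_step4(w)
  porter_step5(w)
}

#' Porter stems
#'
#' Classic suffix-stripping stemmer for English. Tokens containing
#' characters other than ASCII letters are returned unchanged; input is
#' lowercased before stemming.
#'
#' @param x character vector of tokens.
#' @return Character vector of stems, same length as `x`.
#' @export
porter_stem <- function(x) {
  lower <- tolower(x)
  out <- lower
  idx <- grepl("^[a-z]+$", lower)
  out[idx] <- vapply(lower[idx], porter_one, character(1), USE.NAMES = FALSE)
  out
}
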