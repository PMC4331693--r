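# Model 1 feature set (BANNER-style): token identity, lemma, word shape,
# capitalization patterns, Roman numeral / Greek letter flags, character
# n-grams of length 2-4, element and amino-acid lexicon flags, whole-token
# chemical-formula flag, cross-token amino-acid-sequence flag, optional
# part-of-speech and external-tagger flags, all copied over a +/-2 window.

#' Word shape of a token
#'
#' Uppercase letters become `"A"`, lowercase `"a"`, digits `"0"`, everything
#' else `"x"`: `"Cu(2+"` has shape `"Aax0x"`.
#'
#' @param x character vector of tokens.
#' @return Character vector of shapes.
#' @export
word_shape <- function(x) {
  y <- gsub("\\p{Lu}", "A", x, perl = TRUE)
  y <- gsub("\\p{Ll}", "a", y, perl = TRUE)
  y <- gsub("[0-9]", "0", y)
  gsub("[^Aa0]", "x", y)
}

#' Character n-grams of a token
#'
#' All contiguous substrings of length `nmin` to `nmax` (with repeats, in
#' left-to-right order).
#'
#' @param token a single token.
#' @param nmin,nmax inclusive length range.
#' @return Character vector of n-grams (possibly empty).
#' @export
char_ngrams <- function(token, nmin = 2L, nmax = 4L) {
  n <- str_length(token)
  if (n < nmin) return(character())
  out <- character()
  for (k in nmin:min(nmax, n)) {
    out <- c(out, str_sub(token, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  }
  out
}

#' Can a token be segmented into element symbols?
#'
#' True iff the whole token is a concatenation of case-sensitive element
#' symbols (`"FCH"` = F, C, H). The backtracking search prefers two-letter
#' symbols at each step.
#'
#' @param token a single token.
#' @param lexicons a [chem_lexicons()] object (uses `element_symbols`).
#' @return Logical flag.
#' @export
is_formula_token <- function(token, lexicons) {
  symbols <- lexicons$element_symbols
  n <- nchar(token)
  if (n == 0) return(FALSE)
  memo <- rep(NA, n + 1L)
  parses <- function(i) { # can token[i..n] (1-based) be segmented?
    if (i > n) return(TRUE)
    if (!is.na(memo[i])) return(memo[i])
    ok <- FALSE
    for (k in c(2L, 1L)) { # prefer 2-letter symbols
      if (i + k - 1L <= n && substr(token, i, i + k - 1L) %in% symbols) {
        if (parses(i + k)) { ok <- TRUE; break }
      }
    }
    memo[i] <<- ok
    ok
  }
  parses(1L)
}

#' Roman numeral test
#'
#' Uppercase-only, standard subtractive validity over I, V, X, L, C, D, M.
#'
#' @param x character vector.
#' @return Logical vector.
#' @export
is_roman_numeral <- function(x) {
  nzchar(x) &
    grepl("^M{0,3}(CM|CD|D?C{0,3})(XC|XL|L?X{0,3})(IX|IV|V?I{0,3})$", x)
}

#' Flag tokens inside hyphenated amino-acid sequences
#'
#' A token is flagged when it lies inside a run of at least two
#' three-letter amino-acid abbreviations joined by hyphens with no
#' intervening whitespace (`"Phe-Cys-Tyr"`), and the token itself is one of
#' the abbreviations.
#'
#' @param tokens token tibble from a tokenizer (columns `text`, `start`,
#'   `end`).
#' @param source_text the text the tokens were cut from.
#' @param lexicons a [chem_lexicons()] object.
#' @return Logical vector, one element per token row.
#' @export
amino_acid_sequence_flags <- function(tokens, source_text, lexicons) {
  if (nrow(tokens) == 0) return(logical())
  aa3 <- lexicons$amino_acid_3char
  alt <- paste(aa3, collapse = "|")
  pat <- sprintf("(?i)(?<![\\p{L}\\p{N}])(?:%s)(?:-(?:%s))+(?![\\p{L}\\p{N}])",
                 alt, alt)
  locs <- str_locate_all(source_text, stringr::regex(pat))[[1]]
  flags <- rep(FALSE, nrow(tokens))
  if (nrow(locs) == 0) return(flags)
  for (r in seq_len(nrow(locs))) {
    s <- locs[r, 1] - 1L; e <- locs[r, 2] # 0-based half-open
    inside <- tokens$start >= s & tokens$end <= e
    flags <- flags | (inside & tolower(tokens$text) %in% aa3)
  }
  flags
}

the_irregular_nouns <- c(
  children = "child", mice = "mouse", men = "man", women = "woman",
  feet = "foot", teeth = "tooth", geese = "goose", media = "medium",
  criteria = "criterion", phenomena = "phenomenon", analyses = "analysis",
  hypotheses = "hypothesis", indices = "index", matrices = "matrix"
)

#' Lemmatize tokens
#'
#' Default morphology for Model 1: a small irregular-noun table backed by
#' Porter stems. Pluggable — pass any `function(character) character` as the
#' `lemmatizer` argument of [extract_features_m1()] to substitute a real
#' lemmatizer.
#'
#' @param x character vector of tokens.
#' @return Character vector of lemmas.
#' @export
default_lemmatizer <- function(x) {
  lower <- tolower(x)
  hit <- lower %in% names(the_irregular_nouns)
  out <- porter_stem(lower)
  out[hit] <- the_irregular_nouns[lower[hit]]
  out
}

#' Extract Model 1 features
#'
#' Produces, for every token, a character vector of feature strings:
#' identity, lemma, optional part of speech, word shape, capitalization
#' pattern, Roman-numeral and Greek-letter flags, character 2-4-grams,
#' optional external chemical-tagger overlap flag, element symbol/name
#' flags, three amino-acid flags, formula-token flag and the cross-token
#' amino-acid-sequence flag, plus copies of every neighbor's features for
#' context offsets -2..2 tagged with the offset (a `BND` sentinel marks
#' positions beyond the sequence boundary).
#'
#' @param tokens token tibble from [tokenize_m1()].
#' @param source_text the sentence/section text the tokens came from.
#' @param lexicons a [chem_lexicons()] object.
#' @param pos_tagger optional `function(tokens) character` returning one
#'   part-of-speech tag per token; the feature is omitted when `NULL`.
#' @param external_tagger optional `function(source_text) tibble(start,end)`
#'   proposing chemical spans (an external recognizer adapter); the overlap
#'   flag is omitted when `NULL`.
#' @param lemmatizer morphology function, [default_lemmatizer()] by default.
#' @param window context half-width (2 for Model 1).
#' @return List of character vectors, one per token.
#' @export
extract_features_m1 <- function(tokens, source_text, lexicons,
                                pos_tagger = NULL, external_tagger = NULL,
                                lemmatizer = default_lemmatizer,
                                window = 2L) {
  n <- nrow(tokens)
  if (n == 0) return(list())
  txt <- tokens$text
  lower <- tolower(txt)
  shapes <- word_shape(txt)
  cap <- dplyr::case_when(
    grepl("^\\p{Lu}+$", txt, perl = TRUE) ~ "ALLCAPS",
    grepl("^\\p{Lu}[\\p{Ll}]+$", txt, perl = TRUE) ~ "INITCAP",
    grepl("^\\p{Ll}+$", txt, perl = TRUE) ~ "ALLLOWER",
    TRUE ~ "MIXED"
  )
  lemmas <- lemmatizer(txt)
  pos <- if (!is.null(pos_tagger)) pos_tagger(txt) else NULL
  ext_flag <- NULL
  if (!is.null(external_tagger)) {
    spans <- external_tagger(source_text)
    ext_flag <- rep(FALSE, n)
    if (!is.null(spans) && nrow(spans) > 0) {
      for (r in seq_len(nrow(spans))) {
        ext_flag <- ext_flag |
          (tokens$start < spans$end[r] & tokens$end > spans$start[r])
      }
    }
  }
  aaseq <- amino_acid_sequence_flags(tokens, source_text, lexicons)
  roman <- is_roman_numeral(txt)
  greek <- lower %in% lexicons$greek_letter_names
  el_sym <- txt %in% lexicons$element_symbols
  el_name <- lower %in% lexicons$element_names
  aa_name <- lower %in% lexicons$amino_acid_names
  aa3 <- lower %in% lexicons$amino_acid_3char
  aa1 <- lower %in% lexicons$amino_acid_1char
  base <- lapply(seq_len(n), function(i) {
    f <- c(paste0("W=", txt[i]),
           paste0("L=", lemmas[i]),
           paste0("SH=", shapes[i]),
           paste0("CAP=", cap[i]))
    if (!is.null(pos)) f <- c(f, paste0("POS=", pos[i]))
    if (roman[i]) f <- c(f, "ROMAN")
    if (greek[i]) f <- c(f, "GREEK")
    grams <- char_ngrams(txt[i])
    if (length(grams) > 0) f <- c(f, paste0("NG=", grams))
    if (!is.null(ext_flag)) f <- c(f, paste0("EXT=", as.integer(ext_flag[i])))
    if (el_sym[i]) f <- c(f, "ELSYM")
    if (el_name[i]) f <- c(f, "ELNAME")
    if (aa_name[i]) f <- c(f, "AANAME")
    if (aa3[i]) f <- c(f, "AA3")
    if (aa1[i]) f <- c(f, "AA1")
    if (is_formula_token(txt[i], lexicons)) f <- c(f, "FORMULA")
    if (aaseq[i]) f <- c(f, "AASEQ")
    f
  })
  add_context(base, window)
}

# copies of neighboring feature vectors tagged with their relative offset;
# positions beyond the boundary contribute a sentinel feature
add_context <- function(base, window) {
  n <- length(base)
  lapply(seq_len(n), function(i) {
    out <- base[[i]]
    for (d in setdiff(seq.int(-window, window), 0L)) {
      j <- i + d
      tag <- paste0("@", d, "|")
      if (j < 1L || j > n) {
        out <- c(out, paste0(tag, "BND"))
      } else {
        out <- c(out, paste0(tag, base[[j]]))
      }
    }
    out
  })
}
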