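# Model 2 feature set (tmVar-style): token identity, Porter stem, prefixes
# and suffixes of length 1-5, binned character counts, Roman numeral and
# Greek letter flags, semantic affix flags (chemical suffixes, alkane stems,
# trivial rings, simple multipliers), element-name flag, and full + merged
# case patterns, copied over a +/-3 window. Input is expected to be
# transliterated text tokenized with tokenize_m2().

#' Prefixes and suffixes of a token
#'
#' All prefixes and suffixes of length `lmin` to `min(lmax, nchar(token))`.
#'
#' @param token a single token.
#' @param lmin,lmax inclusive length range (1 and 5 by default).
#' @return Tibble with columns `kind` (`"prefix"`/`"suffix"`) and `value`.
#' @export
affixes <- function(token, lmin = 1L, lmax = 5L) {
  n <- str_length(token)
  hi <- min(lmax, n)
  if (n == 0 || hi < lmin) {
    return(tibble(kind = character(), value = character()))
  }
  ks <- lmin:hi
  tibble(
    kind = rep(c("prefix", "suffix"), each = length(ks)),
    value = c(str_sub(token, 1L, ks), str_sub(token, n - ks + 1L, n))
  )
}

#' Character-class counts of a token
#'
#' Total characters, digits, uppercase and lowercase letters. As features
#' these are binned into 0, 1, 2, 3 and 4+.
#'
#' @param token a single token.
#' @return Named integer vector `n_chars`, `n_digits`, `n_upper`, `n_lower`.
#' @export
char_counts <- function(token) {
  chars <- strsplit(token, "", fixed = FALSE)[[1]]
  c(n_chars = length(chars),
    n_digits = sum(grepl("[0-9]", chars)),
    n_upper = sum(grepl("\\p{Lu}", chars, perl = TRUE)),
    n_lower = sum(grepl("\\p{Ll}", chars, perl = TRUE)))
}

count_bin <- function(k) ifelse(k >= 4L, "4+", as.character(k))

#' Case pattern of a token
#'
#' The full pattern replaces uppercase letters with `"A"`, lowercase with
#' `"a"` and digits with `"0"`, keeping all other characters verbatim; the
#' merged pattern collapses consecutive identical pattern symbols
#' (`"CD40"` gives `"AA00"` and `"A0"`).
#'
#' @param token a single token.
#' @return Named character vector with elements `full` and `merged`.
#' @export
case_pattern <- function(token) {
  full <- gsub("\\p{Lu}", "A", token, perl = TRUE)
  full <- gsub("\\p{Ll}", "a", full, perl = TRUE)
  full <- gsub("[0-9]", "0", full)
  chars <- strsplit(full, "", fixed = FALSE)[[1]]
  keep <- c(TRUE, chars[-1] != chars[-length(chars)])
  if (length(chars) == 0) keep <- logical()
  c(full = full, merged = paste(chars[keep], collapse = ""))
}

#' Extract Model 2 features
#'
#' Produces per token: identity, Porter stem, prefixes/suffixes of length
#' 1-5, binned character counts, Roman-numeral and Greek-letter flags,
#' semantic flags (chemical suffix matched at token end, alkane stem and
#' simple multiplier at token start, trivial ring as whole token),
#' element-name flag, and the full and merged case patterns, plus copies
#' for context offsets -3..3.
#'
#' @param tokens token tibble from [tokenize_m2()] over transliterated text.
#' @param lexicons a [chem_lexicons()] object.
#' @param lmin,lmax affix length range.
#' @param window context half-width (3 for Model 2).
#' @return List of character vectors, one per token.
#' @export
extract_features_m2 <- function(tokens, lexicons, lmin = 1L, lmax = 5L,
                                window = 3L) {
  n <- nrow(tokens)
  if (n == 0) return(list())
  txt <- tokens$text
  lower <- tolower(txt)
  stems <- porter_stem(txt)
  roman <- is_roman_numeral(txt)
  greek <- lower %in% lexicons$greek_letter_names
  el_name <- lower %in% lexicons$element_names
  suf_re <- paste0("(", paste(lexicons$chemical_suffixes, collapse = "|"), ")$")
  stem_re <- paste0("^(", paste(lexicons$alkane_stems, collapse = "|"), ")")
  mult_re <- paste0("^(", paste(lexicons$simple_multipliers, collapse = "|"), ")")
  has_suf <- grepl(suf_re, lower)
  has_stem <- grepl(stem_re, lower)
  has_mult <- grepl(mult_re, lower)
  is_ring <- lower %in% lexicons$trivial_rings
  base <- lapply(seq_len(n), function(i) {
    f <- c(paste0("W=", txt[i]), paste0("ST=", stems[i]))
    af <- affixes(txt[i], lmin, lmax)
    if (nrow(af) > 0) {
      pre <- af$value[af$kind == "prefix"]
      suf <- af$value[af$kind == "suffix"]
      f <- c(f, paste0("P", str_length(pre), "=", pre),
             paste0("S", str_length(suf), "=", suf))
    }
    cc <- char_counts(txt[i])
    f <- c(f, paste0("NC=", count_bin(cc[["n_chars"]])),
           paste0("ND=", count_bin(cc[["n_digits"]])),
           paste0("NU=", count_bin(cc[["n_upper"]])),
           paste0("NL=", count_bin(cc[["n_lower"]])))
    if (roman[i]) f <- c(f, "ROMAN")
    if (greek[i]) f <- c(f, "GREEK")
    if (has_suf[i]) f <- c(f, "CHEMSUF")
    if (has_stem[i]) f <- c(f, "ALKSTEM")
    if (is_ring[i]) f <- c(f, "RING")
    if (has_mult[i]) f <- c(f, "MULT")
    if (el_name[i]) f <- c(f, "ELNAME")
    cp <- case_pattern(txt[i])
    c(f, paste0("CPF=", cp[["full"]]), paste0("CPM=", cp[["merged"]]))
  })
  add_context(base, window)
}
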