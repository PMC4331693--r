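the_translit <- new.env(parent = emptyenv())

load_translit_table <- function() {
  if (is.null(the_translit$tab)) {
    lines <- read_utf8_lines(extdata_path("transliteration.tsv"))
    f <- strsplit(lines, "\t", fixed = TRUE)
    tab <- tibble(from = map_chr(f, 1), to = map_chr(f, 2))
    chem_stopifnot(all(str_length(tab$from) == 1L & str_length(tab$to) == 1L),
                   "transliteration entries must be single characters")
    the_translit$tab <- tab
  }
  the_translit$tab
}

#' Transliterate non-ASCII characters to ASCII equivalents
#'
#' Applies a bundled single-character table (Greek letters, typographic
#' dashes and quotes, multiplication sign, plus-minus, accented Latin
#' letters, sub/superscript digits, ...). Non-ASCII whitespace becomes a
#' plain space and any remaining unmapped non-ASCII character becomes `"?"`.
#' Because every replacement is exactly one character, transliterated
#' offsets coincide with source offsets; the returned `map` (0-based, one
#' entry per output character) makes that explicit so downstream mention
#' offsets are reported in source coordinates.
#'
#' @param text a single string.
#' @return A list with elements `text` (the ASCII string) and `map`
#'   (integer vector: source offset of each output character).
#' @seealso [translit_ascii()] for the vectorized text-only variant.
#' @export
transliterate <- function(text) {
  out <- translit_ascii(text)
  list(text = out, map = seq_len(str_length(out)) - 1L)
}

#' @rdname transliterate
#' @param x character vector.
#' @export
translit_ascii <- function(x) {
  tab <- load_translit_table()
  y <- x
  needs <- !is.na(y) & grepl("[^\\x00-\\x7F]", y, perl = TRUE)
  y[needs] <- vapply(y[needs], function(s) {
    chars <- strsplit(s, "", fixed = FALSE)[[1]]
    idx <- match(chars, tab$from)
    hit <- !is.na(idx)
    chars[hit] <- tab$to[idx[hit]]
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  uni_space <- intToUtf8(c(0xa0, 0x1680, 0x2000:0x200b, 0x2028, 0x2029,
                           0x202f, 0x205f, 0x3000, 0xfeff))
  y <- gsub(paste0("[", uni_space, "]"), " ", y, perl = TRUE)
  gsub("[^\\x00-\\x7F]", "?", y, perl = TRUE)
}

#' Segment a section into sentences
#'
#' Deterministic rule-based splitter used by Model 1 only (Model 2 tags a
#' whole section as one sequence). A sentence ends after `.`, `!` or `?`
#' when the terminator is followed by whitespace and then an uppercase
#' letter or digit — except when a period sits between digits or follows a
#' single uppercase letter (initials). Returned spans are 0-based,
#' half-open, trimmed of surrounding whitespace.
#'
#' @param text section text.
#' @return Tibble with columns `start`, `end`.
#' @export
segment_sentences <- function(text) {
  n <- str_length(text)
  if (n == 0 || !nzchar(trimws(text))) {
    return(tibble(start = integer(), end = integer()))
  }
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  breaks <- integer() # positions AFTER which a sentence ends (1-based char idx)
  for (i in seq_len(n - 1L)) {
    ch <- chars[i]
    if (!ch %in% c(".", "!", "?")) next
    if (!grepl("[[:space:]]", chars[i + 1L])) next
    j <- i + 1L
    while (j <= n && grepl("[[:space:]]", chars[j])) j <- j + 1L
    if (j > n) next
    if (!grepl("[[:upper:][:digit:]]", chars[j])) next
    if (ch == ".") {
      prev <- if (i > 1L) chars[i - 1L] else ""
      nxt_immediate <- chars[i + 1L]
      if (grepl("[[:digit:]]", prev) && grepl("[[:digit:]]", nxt_immediate)) next
      # single uppercase letter before the period (an initial)
      if (grepl("[[:upper:]]", prev) &&
          (i == 2L || (i > 2L && grepl("[^[:alpha:]]", chars[i - 2L])))) next
    }
    breaks <- c(breaks, i)
  }
  starts0 <- c(1L, breaks + 1L)
  ends0 <- c(breaks, n)
  spans <- map2(starts0, ends0, function(s, e) {
    while (s <= e && grepl("[[:space:]]", chars[s])) s <- s + 1L
    while (e >= s && grepl("[[:space:]]", chars[e])) e <- e - 1L
    if (s > e) NULL else c(s - 1L, e)
  })
  spans <- spans[!vapply(spans, is.null, logical(1))]
  tibble(start = map_int(spans, 1), end = map_int(spans, 2))
}

token_tibble <- function(text, locs) {
  if (nrow(locs) == 0) {
    return(tibble(text = character(), start = integer(), end = integer()))
  }
  tibble(
    text = str_sub(text, locs[, 1], locs[, 2]),
    start = as.integer(locs[, 1]) - 1L,
    end = as.integer(locs[, 2])
  )
}

# base segmentation shared by both tokenizers: letter runs, digit runs,
# single punctuation characters; whitespace discarded
base_token_locs <- function(text) {
  str_locate_all(text, "\\p{L}+|\\p{N}+|[^\\p{L}\\p{N}\\s]")[[1]]
}

split_run <- function(token, boundary_re) {
  # returns relative 0-based cut positions inside the token
  m <- gregexpr(boundary_re, token, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m) - 1L
}

tokenize_runs <- function(text, boundary_re) {
  locs <- base_token_locs(text)
  toks <- token_tibble(text, locs)
  if (nrow(toks) == 0) return(toks)
  pieces <- pmap(toks, function(text, start, end) {
    cuts <- split_run(text, boundary_re)
    if (length(cuts) == 0) {
      return(tibble(text = text, start = start, end = end))
    }
    s_rel <- c(0L, cuts)
    e_rel <- c(cuts, str_length(text))
    abs_start <- start + s_rel
    abs_end <- start + e_rel
    tibble(text = str_sub(text, s_rel + 1L, e_rel),
           start = abs_start, end = abs_end)
  })
  bind_rows(pieces)
}

#' Tokenize for Model 1
#'
#' Splits at whitespace (discarded), emits every punctuation character as
#' its own token, breaks between a letter and a digit in both directions,
#' and breaks between a lowercase letter and a following uppercase letter.
#' `"FCH2CH2N3"` becomes `FCH / 2 / CH / 2 / N / 3`.
#'
#' @param text a single string.
#' @return Tibble with columns `text`, `start`, `end` (0-based half-open
#'   offsets into `text`); tokens are non-overlapping and sorted.
#' @export
tokenize_m1 <- function(text) {
  tokenize_runs(text, "(?<=\\p{Ll})(?=\\p{Lu})")
}

#' Tokenize for Model 2
#'
#' Finer than [tokenize_m1()]: digits, lowercase letters and uppercase
#' letters form separate tokens (maximal single-class runs), so `"NaCl"`
#' becomes `N / a / C / l`. Every Model 1 boundary is also a Model 2
#' boundary.
#'
#' @inheritParams tokenize_m1
#' @return Tibble with columns `text`, `start`, `end`.
#' @export
tokenize_m2 <- function(text) {
  tokenize_runs(text, "(?<=\\p{Ll})(?=\\p{Lu})|(?<=\\p{Lu})(?=\\p{Ll})")
}
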