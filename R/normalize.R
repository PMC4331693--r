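# Lexical normalization: map recognized mentions to chemical vocabulary
# identifiers by case- and punctuation-stripped key lookup, with
# primary-vocabulary (MeSH-style) priority over the secondary (ChEBI-style)
# vocabulary and abbreviation linking to long forms.

#' Normalization key of a mention text
#'
#' Lowercases and removes all whitespace and punctuation (any character
#' that is neither letter nor digit): `"flavone-C-glycoside"` becomes
#' `"flavonecglycoside"`. Idempotent. An empty key means the lookup is
#' skipped.
#'
#' @param text character vector.
#' @return Character vector of keys.
#' @export
normalization_key <- function(text) {
  gsub("[^\\p{L}\\p{N}]", "", tolower(text), perl = TRUE)
}

#' Build a normalization lexicon from two vocabulary tables
#'
#' Each input is a `name<TAB>identifier` TSV (or an equivalent data frame
#' with columns `name`, `identifier`). Keys are computed with
#' [normalization_key()]; on a key collision within one source the first
#' entry is retained; entries from the primary vocabulary shadow the
#' secondary one, so a mention found in both receives the primary
#' identifier.
#'
#' @param primary,secondary paths or data frames (primary = the vocabulary
#'   whose identifiers win, e.g. MeSH; secondary e.g. ChEBI).
#' @return Tibble of class `chem_norm_lexicon` with columns `key`,
#'   `identifier`, `source` (`"PRIMARY_VOCAB"` / `"SECONDARY_VOCAB"`).
#' @export
build_lexicon <- function(primary, secondary = NULL) {
  read_vocab <- function(x, source) {
    if (is.null(x)) return(tibble(key = character(), identifier = character(),
                                  source = character()))
    df <- if (is.character(x) && length(x) == 1) {
      cols <- read_tsv_cols(x, 2)
      tibble(name = cols[[1]], identifier = cols[[2]])
    } else {
      as_tibble(x)
    }
    df$key <- normalization_key(df$name)
    df <- df[nzchar(df$key), ]
    df <- df[!duplicated(df$key), ] # first entry wins within one source
    tibble(key = df$key, identifier = df$identifier, source = source)
  }
  prim <- read_vocab(primary, "PRIMARY_VOCAB")
  sec <- read_vocab(secondary, "SECONDARY_VOCAB")
  if (nrow(prim) == 0 && nrow(sec) == 0) {
    warn("both vocabulary files are empty; the lexicon maps nothing")
  }
  sec <- sec[!sec$key %in% prim$key, ] # primary shadows secondary
  structure(bind_rows(prim, sec), class = c("chem_norm_lexicon",
                                            class(prim)))
}

#' Normalize mentions to vocabulary identifiers
#'
#' Each mention is looked up by its normalization key. A mention whose
#' direct lookup fails but whose text equals a detected abbreviation's
#' short form inherits the identifier of the abbreviation's long form.
#' Every input row is returned; unmapped mentions carry `NA` identifiers.
#'
#' @param mentions mention tibble.
#' @param lexicon a [build_lexicon()] result.
#' @param abbrev_pairs optional abbreviation table from
#'   [detect_abbreviations()].
#' @return The mention tibble with `identifier` and `source` columns added.
#' @export
normalize_mentions <- function(mentions, lexicon, abbrev_pairs = NULL) {
  m <- as_mentions(mentions)
  keys <- normalization_key(m$text)
  idx <- match(keys, lexicon$key)
  idx[!nzchar(keys)] <- NA_integer_
  identifier <- lexicon$identifier[idx]
  source <- lexicon$source[idx]
  if (!is.null(abbrev_pairs) && nrow(abbrev_pairs) > 0) {
    need <- which(is.na(identifier))
    for (i in need) {
      hit <- abbrev_pairs[abbrev_pairs$doc_id == m$doc_id[i] &
                            abbrev_pairs$short_form == m$text[i], ]
      if (nrow(hit) == 0) next
      lf_key <- normalization_key(hit$long_form[1])
      j <- match(lf_key, lexicon$key)
      if (!is.na(j)) {
        identifier[i] <- lexicon$identifier[j]
        source[i] <- lexicon$source[j]
      }
    }
  }
  m$identifier <- identifier
  m$source <- source
  m
}

#' Write normalized mentions as TSV
#'
#' Columns: doc_id, section, start, end, text, identifier (or `-`), source
#' (or `-`).
#'
#' @param normalized tibble from [normalize_mentions()].
#' @param path output path.
#' @return `normalized`, invisibly.
#' @export
write_normalized <- function(normalized, path) {
  writeLines(paste(
    normalized$doc_id, normalized$section, normalized$start, normalized$end,
    normalized$text,
    ifelse(is.na(normalized$identifier), "-", normalized$identifier),
    ifelse(is.na(normalized$source), "-", normalized$source),
    sep = "\t"), path)
  invisible(normalized)
}
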