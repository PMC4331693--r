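# Rule-based correction passes applied to CRF output, per document:
# tagging consistency (Model 1 only), abbreviation propagation/removal,
# bracket balancing, identifier-lexicon matching, then overlap resolution.

# word-boundary-delimited occurrences of `needle` in `haystack`;
# boundaries require that the neighbors are not letters or digits
find_occurrences <- function(haystack, needle) {
  if (!nzchar(needle)) return(tibble(start = integer(), end = integer()))
  locs <- str_locate_all(haystack, fixed(needle))[[1]]
  if (nrow(locs) == 0) return(tibble(start = integer(), end = integer()))
  n <- str_length(haystack)
  ok <- vapply(seq_len(nrow(locs)), function(i) {
    s <- locs[i, 1]; e <- locs[i, 2]
    left_ok <- s == 1 || !grepl("[\\p{L}\\p{N}]", str_sub(haystack, s - 1, s - 1), perl = TRUE)
    right_ok <- e == n || !grepl("[\\p{L}\\p{N}]", str_sub(haystack, e + 1, e + 1), perl = TRUE)
    left_ok && right_ok
  }, logical(1))
  tibble(start = as.integer(locs[ok, 1]) - 1L, end = as.integer(locs[ok, 2]))
}

overlaps_any <- function(start, end, section, existing) {
  if (nrow(existing) == 0) return(FALSE)
  any(existing$section == section & existing$start < end & existing$end > start)
}

#' Enforce document-level tagging consistency
#'
#' Every character sequence tagged at least twice within a document gets
#' all of its remaining word-boundary-delimited occurrences (in title and
#' abstract) added as mentions, unless a new span would overlap an existing
#' mention. Existing mentions are never removed; added mentions inherit the
#' maximum probability of their source mentions. Matching is
#' case-sensitive. The pass is monotone and idempotent.
#'
#' @param mentions mention tibble for one document.
#' @param doc one-row document tibble (`doc_id`, `title`, `abstract`).
#' @return The augmented mention tibble.
#' @export
enforce_consistency <- function(mentions, doc) {
  m <- as_mentions(mentions)
  chem_stopifnot(all(m$doc_id == doc$doc_id), "mentions must belong to doc")
  tallies <- m |> count(.data$text) |> filter(n >= 2) |> arrange(.data$text)
  if (nrow(tallies) == 0) return(m)
  out <- m
  for (txt in tallies$text) {
    src_prob <- suppressWarnings(max(m$probability[m$text == txt], na.rm = TRUE))
    if (!is.finite(src_prob)) src_prob <- NA_real_
    for (sec in c("T", "A")) {
      hay <- section_text(doc, sec)
      occ <- find_occurrences(hay, txt)
      for (i in seq_len(nrow(occ))) {
        s <- occ$start[i]; e <- occ$end[i]
        if (overlaps_any(s, e, sec, out)) next
        out <- bind_rows(out, tibble(
          doc_id = doc$doc_id, section = sec, start = s, end = e,
          text = txt, subtype = NA_character_, probability = src_prob
        ))
      }
    }
  }
  arrange(out, .data$section, .data$start, .data$end)
}

#' Detect local abbreviation definitions
#'
#' Finds parenthesized short-form definitions of the form
#' `long form (SF)` with a Schwartz-Hearst-style right-to-left initial
#' character alignment. The built-in aligner is tolerant of digits and
#' punctuation in the short form and of leading non-alphabetic material in
#' the long form; when character alignment fails but the short form parses
#' as a chemical formula (element symbols and digits), the immediately
#' preceding word group is accepted as the long form. The detector is
#' pluggable: any `function(doc) tibble(...)` with the same columns can
#' replace it downstream.
#'
#' @param doc one-row document tibble.
#' @param lexicons a [chem_lexicons()] (used for the formula fallback).
#' @return Tibble with columns `doc_id`, `section`, `short_form`,
#'   `long_form`, `short_start`, `short_end`, `long_start`, `long_end`.
#' @export
detect_abbreviations <- function(doc, lexicons = chem_lexicons()) {
  out <- list()
  for (sec in c("T", "A")) {
    text <- section_text(doc, sec)
    locs <- str_locate_all(text, "\\(([^()]{1,10})\\)")[[1]]
    for (i in seq_len(nrow(locs))) {
      sf_start <- locs[i, 1] + 1L # inside the parens, 1-based
      sf_end <- locs[i, 2] - 1L
      sf <- str_sub(text, sf_start, sf_end)
      if (!grepl("\\p{L}", sf, perl = TRUE)) next
      if (str_length(sf) < 1 || lengths(gregexpr("\\S+", sf)) > 2) next
      before <- str_sub(text, 1L, locs[i, 1] - 1L)
      lf <- find_long_form(before, sf, lexicons)
      if (is.null(lf)) next
      out[[length(out) + 1L]] <- tibble(
        doc_id = doc$doc_id, section = sec,
        short_form = sf, long_form = lf$text,
        short_start = sf_start - 1L, short_end = sf_end,
        long_start = lf$start, long_end = lf$end
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(doc_id = character(), section = character(),
                  short_form = character(), long_form = character(),
                  short_start = integer(), short_end = integer(),
                  long_start = integer(), long_end = integer()))
  }
  bind_rows(out)
}

# candidate long form: up to min(|sf| + 5, 2 * |sf|) words before the paren
find_long_form <- function(before, sf, lexicons) {
  before <- sub("\\s+$", "", before)
  if (!nzchar(before)) return(NULL)
  word_locs <- str_locate_all(before, "\\S+")[[1]]
  if (nrow(word_locs) == 0) return(NULL)
  max_words <- min(str_length(sf) + 5L, 2L * str_length(sf))
  n_words <- min(nrow(word_locs), max_words)
  cand_start <- word_locs[nrow(word_locs) - n_words + 1L, 1]
  candidate <- str_sub(before, cand_start, str_length(before))
  aligned <- align_short_form(candidate, sf)
  if (!is.null(aligned)) {
    abs_start <- cand_start + aligned - 2L # 0-based offset of the long form
    lf_text <- str_sub(before, cand_start + aligned - 1L, str_length(before))
    return(list(text = lf_text, start = as.integer(abs_start),
                end = str_length(before)))
  }
  # chemical-formula fallback: "water (H2O)"
  core <- gsub("[^A-Za-z]", "", sf)
  sf_is_formula <- nzchar(core) && is_formula_token(core, lexicons)
  if (sf_is_formula) {
    # the immediately preceding word serves as the long form
    s <- word_locs[nrow(word_locs), 1]
    return(list(text = str_sub(before, s, str_length(before)),
                start = as.integer(s - 1L), end = str_length(before)))
  }
  NULL
}

# Schwartz-Hearst right-to-left alignment; returns the 1-based index into
# `candidate` where the long form starts, or NULL. Digits/punctuation in
# the short form may be skipped when unmatched; the first short-form letter
# must align to the first character of a word (leading digits/punctuation
# of that word are tolerated).
align_short_form <- function(candidate, sf) {
  cand <- tolower(candidate)
  sfl <- tolower(sf)
  ci <- str_length(cand)
  si <- str_length(sfl)
  while (si > 0) {
    sch <- str_sub(sfl, si, si)
    is_first_letter <- si == 1 ||
      !grepl("\\p{L}", str_sub(sfl, 1, si - 1), perl = TRUE)
    while (ci > 0) {
      cch <- str_sub(cand, ci, ci)
      if (cch == sch &&
          (!is_first_letter || at_word_start(cand, ci))) break
      ci <- ci - 1L
    }
    if (ci == 0) {
      # tolerate unmatched digits / punctuation in the short form
      if (!grepl("\\p{L}", sch, perl = TRUE)) {
        ci <- str_length(cand)
        si <- si - 1L
        next
      }
      return(NULL)
    }
    si <- si - 1L
    if (si > 0) ci <- ci - 1L
  }
  as.integer(ci)
}

# word start for alignment purposes: anything but a letter may precede,
# which tolerates leading digits and punctuation in the long form
at_word_start <- function(text, i) {
  i == 1 || !grepl("\\p{L}", str_sub(text, i - 1L, i - 1L), perl = TRUE)
}

#' Propagate abbreviations through a document's mentions
#'
#' In both modes, if any mention covers a defined long form (or matches its
#' text), every non-overlapping word-boundary occurrence of the short form
#' is tagged. Mode `"M2"` adds two rules: if both short and long form were
#' tagged, all occurrences of the long form are tagged too; if the long
#' form was not tagged, mentions exactly matching the short form are
#' removed.
#'
#' @param mentions mention tibble for one document.
#' @param doc one-row document tibble.
#' @param pairs abbreviation table from [detect_abbreviations()].
#' @param mode `"M1"` or `"M2"`.
#' @return Updated mention tibble.
#' @export
propagate_abbreviations <- function(mentions, doc, pairs, mode = c("M1", "M2")) {
  mode <- match.arg(mode)
  out <- as_mentions(mentions)
  if (nrow(pairs) == 0) return(out)
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    long_tagged <- any(out$text == p$long_form) ||
      any(out$section == p$section & out$start <= p$long_start &
            out$end >= p$long_end)
    short_tagged <- any(out$text == p$short_form)
    if (long_tagged) {
      src <- out$probability[out$text == p$long_form |
                               (out$section == p$section &
                                  out$start <= p$long_start &
                                  out$end >= p$long_end)]
      prob <- suppressWarnings(max(src, na.rm = TRUE))
      if (!is.finite(prob)) prob <- NA_real_
      out <- add_occurrences(out, doc, p$short_form, prob)
      if (mode == "M2" && short_tagged) {
        out <- add_occurrences(out, doc, p$long_form, prob)
      }
    } else if (mode == "M2") {
      out <- filter(out, .data$text != p$short_form)
    }
  }
  arrange(out, .data$section, .data$start, .data$end)
}

add_occurrences <- function(mentions, doc, txt, prob) {
  for (sec in c("T", "A")) {
    occ <- find_occurrences(section_text(doc, sec), txt)
    for (i in seq_len(nrow(occ))) {
      if (overlaps_any(occ$start[i], occ$end[i], sec, mentions)) next
      mentions <- bind_rows(mentions, tibble(
        doc_id = doc$doc_id, section = sec,
        start = occ$start[i], end = occ$end[i], text = txt,
        subtype = NA_character_, probability = prob
      ))
    }
  }
  mentions
}

brackets_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  open <- c("(" = ")", "[" = "]", "{" = "}")
  stack <- character()
  for (ch in chars) {
    if (ch %in% names(open)) {
      stack <- c(stack, open[[ch]])
    } else if (ch %in% open) {
      if (length(stack) == 0 || stack[length(stack)] != ch) return(FALSE)
      stack <- stack[-length(stack)]
    }
  }
  length(stack) == 0
}

#' Balance brackets of predicted mentions
#'
#' A mention whose text has balanced `()`, `[]`, `{}` is kept unchanged.
#' Otherwise four single-character edits are tried in a fixed order —
#' extend right, extend left, trim right, trim left — and the first edit
#' producing balance wins; extensions must take in a bracket character. If
#' no edit balances the mention it is dropped. The paper's worked case:
#' `"Cu(2+"` followed by `")"` in the source extends to `"Cu(2+)"`.
#'
#' @param mentions mention tibble for one document.
#' @param doc one-row document tibble.
#' @return Mention tibble with revised or dropped rows.
#' @export
balance_brackets <- function(mentions, doc) {
  m <- as_mentions(mentions)
  if (nrow(m) == 0) return(m)
  keep <- map(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    if (brackets_balanced(row$text)) return(row)
    src <- section_text(doc, row$section)
    n <- str_length(src)
    bracket_chars <- c("(", ")", "[", "]", "{", "}")
    # extend right
    if (row$end < n) {
      nxt <- str_slice(src, row$end, row$end + 1L)
      if (nxt %in% bracket_chars &&
          brackets_balanced(paste0(row$text, nxt))) {
        row$end <- row$end + 1L
        row$text <- str_slice(src, row$start, row$end)
        return(row)
      }
    }
    # extend left
    if (row$start > 0) {
      prv <- str_slice(src, row$start - 1L, row$start)
      if (prv %in% bracket_chars &&
          brackets_balanced(paste0(prv, row$text))) {
        row$start <- row$start - 1L
        row$text <- str_slice(src, row$start, row$end)
        return(row)
      }
    }
    # trim right
    if (str_length(row$text) > 1 &&
        brackets_balanced(str_sub(row$text, 1, -2))) {
      row$end <- row$end - 1L
      row$text <- str_slice(src, row$start, row$end)
      return(row)
    }
    # trim left
    if (str_length(row$text) > 1 &&
        brackets_balanced(str_sub(row$text, 2, -1))) {
      row$start <- row$start + 1L
      row$text <- str_slice(src, row$start, row$end)
      return(row)
    }
    NULL
  })
  keep <- keep[!vapply(keep, is.null, logical(1))]
  if (length(keep) == 0) return(empty_mentions())
  bind_rows(keep)
}

#' Compile an identifier lexicon into match patterns
#'
#' Keeps names shaped as 2-5 letters, up to two `-`/`_`/space separator
#' characters, then at least two digits, and turns each into a pattern that
#' lets the separator vary: `"NSC-114792"` becomes
#' `"NSC[\-\_ ]{0,2}114792"`. Letter matching is case-sensitive.
#'
#' @param names character vector of chemical names (e.g. a database export).
#' @return Tibble with columns `source_name`, `pattern`.
#' @export
compile_identifier_lexicon <- function(names) {
  m <- stringr::str_match(names, "^([A-Za-z]{2,5})([-_ ]{0,2})([0-9]{2,})$")
  ok <- !is.na(m[, 1])
  tibble(
    source_name = names[ok],
    pattern = paste0(m[ok, 2], "[\\-\\_ ]{0,2}", m[ok, 4])
  )
}

#' Match identifier patterns in a document
#'
#' All word-boundary-delimited matches of the compiled patterns in title
#' and abstract become mentions with subtype `IDENTIFIER` and a fixed
#' configurable probability. `"NSC1147920"` does not match the
#' `NSC...114792` pattern because the trailing digit breaks the right word
#' boundary.
#'
#' @param doc one-row document tibble.
#' @param patterns tibble from [compile_identifier_lexicon()].
#' @param probability probability assigned to lexicon matches.
#' @return Mention tibble (possibly empty); deduplication against existing
#'   spans is the caller's job.
#' @export
match_identifiers <- function(doc, patterns, probability = 0.9) {
  if (is.null(patterns) || nrow(patterns) == 0) return(empty_mentions())
  out <- list()
  for (sec in c("T", "A")) {
    text <- section_text(doc, sec)
    for (pat in patterns$pattern) {
      guarded <- paste0("(?<![\\p{L}\\p{N}])(?:", pat, ")(?![\\p{L}\\p{N}])")
      locs <- str_locate_all(text, stringr::regex(guarded))[[1]]
      for (i in seq_len(nrow(locs))) {
        out[[length(out) + 1L]] <- tibble(
          doc_id = doc$doc_id, section = sec,
          start = as.integer(locs[i, 1]) - 1L, end = as.integer(locs[i, 2]),
          text = str_sub(text, locs[i, 1], locs[i, 2]),
          subtype = "IDENTIFIER", probability = probability
        )
      }
    }
  }
  if (length(out) == 0) return(empty_mentions())
  distinct(bind_rows(out), .data$doc_id, .data$section, .data$start,
           .data$end, .keep_all = TRUE)
}

#' Resolve overlapping mentions
#'
#' Within each document section, exact duplicate spans are merged keeping
#' the maximum probability; among overlapping distinct spans the longer
#' span wins, ties broken by higher probability then left position.
#'
#' @param mentions mention tibble (any number of documents).
#' @return Non-overlapping mention tibble.
#' @export
resolve_overlaps <- function(mentions) {
  m <- as_mentions(mentions)
  if (nrow(m) == 0) return(m)
  m <- m |>
    group_by(.data$doc_id, .data$section, .data$start, .data$end) |>
    arrange(desc(.data$probability), .by_group = TRUE) |>
    summarise(text = first(.data$text), subtype = first(.data$subtype),
              probability = suppressWarnings(
                if (all(is.na(.data$probability))) NA_real_
                else max(.data$probability, na.rm = TRUE)),
              .groups = "drop")
  m <- m |>
    mutate(len = .data$end - .data$start) |>
    arrange(.data$doc_id, .data$section, desc(.data$len),
            desc(ifelse(is.na(.data$probability), -Inf, .data$probability)),
            .data$start)
  kept <- m[0, ]
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    clash <- kept$doc_id == row$doc_id & kept$section == row$section &
      kept$start < row$end & kept$end > row$start
    if (!any(clash)) kept <- bind_rows(kept, row)
  }
  kept |>
    select(-"len") |>
    arrange(.data$doc_id, .data$section, .data$start, .data$end) |>
    as_mentions()
}

#' Apply the full post-processing cascade to one document
#'
#' Order of passes: consistency (Model 1 only), abbreviation rules, bracket
#' balancing, identifier matching, overlap resolution.
#'
#' @param mentions mention tibble for one document.
#' @param doc one-row document tibble.
#' @param mode `"M1"` or `"M2"` (selects the consistency pass and the
#'   abbreviation rule set).
#' @param identifier_patterns optional tibble from
#'   [compile_identifier_lexicon()].
#' @param lexicons a [chem_lexicons()].
#' @param abbrev_detector pluggable detector, [detect_abbreviations()] by
#'   default.
#' @param identifier_probability probability for identifier-lexicon matches.
#' @return Post-processed mention tibble.
#' @export
postprocess_mentions <- function(mentions, doc, mode = c("M1", "M2"),
                                 identifier_patterns = NULL,
                                 lexicons = chem_lexicons(),
                                 abbrev_detector = NULL,
                                 identifier_probability = 0.9) {
  mode <- match.arg(mode)
  m <- as_mentions(mentions)
  if (mode == "M1") m <- enforce_consistency(m, doc)
  pairs <- if (is.null(abbrev_detector)) {
    detect_abbreviations(doc, lexicons)
  } else {
    abbrev_detector(doc)
  }
  m <- propagate_abbreviations(m, doc, pairs, mode)
  m <- balance_brackets(m, doc)
  if (!is.null(identifier_patterns)) {
    ids <- match_identifiers(doc, identifier_patterns, identifier_probability)
    m <- bind_rows(m, ids)
  }
  resolve_overlaps(m)
}
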