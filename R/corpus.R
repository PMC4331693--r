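#' Construct a corpus object
#'
#' A corpus bundles a table of documents (abstracts with titles) and a table
#' of chemical mention annotations in standoff form. Offsets are 0-based,
#' half-open, counted in Unicode code points within the title or abstract
#' separately; the `section` flag is `"T"` (title) or `"A"` (abstract).
#'
#' @param documents tibble with columns `doc_id`, `title`, `abstract`.
#' @param mentions tibble with columns `doc_id`, `section`, `start`, `end`,
#'   `text`, and optionally `subtype` and `probability`.
#' @return An object of class `chem_corpus`: a list with elements
#'   `documents` and `mentions`, both tibbles.
#' @export
chem_corpus <- function(documents, mentions = empty_mentions()) {
  documents <- as_tibble(documents)
  mentions <- as_mentions(mentions)
  corpus <- structure(list(documents = documents, mentions = mentions),
                      class = "chem_corpus")
  validate_corpus(corpus)
  corpus
}

#' @export
print.chem_corpus <- function(x, ...) {
  cat(sprintf("<chem_corpus: %d documents, %d mentions>\n",
              nrow(x$documents), nrow(x$mentions)))
  invisible(x)
}

validate_corpus <- function(corpus) {
  docs <- corpus$documents
  men <- corpus$mentions
  chem_stopifnot(all(nzchar(docs$doc_id)), "empty doc_id in documents")
  chem_stopifnot(!anyDuplicated(docs$doc_id), "duplicate doc_id in documents")
  chem_stopifnot(!any(grepl("[\t\n]", docs$title)) &&
                   !any(grepl("[\t\n]", docs$abstract)),
                 "document text contains tab or newline")
  if (nrow(men) > 0) {
    chem_stopifnot(all(men$doc_id %in% docs$doc_id),
                   "annotation doc_id not present among documents")
    chem_stopifnot(all(men$section %in% c("T", "A")), "section must be T or A")
    validate_mention_slices(docs, men)
    dup <- duplicated(men[, c("doc_id", "section", "start", "end")])
    chem_stopifnot(!any(dup), "duplicate (doc, section, start, end) annotation")
  }
  invisible(corpus)
}

# The slice invariant: mention text equals the substring of the section text
# at [start, end). Raised as an offset-convention error naming the mention.
validate_mention_slices <- function(docs, mentions) {
  idx <- match(mentions$doc_id, docs$doc_id)
  src <- ifelse(mentions$section == "T", docs$title[idx], docs$abstract[idx])
  len <- str_length(src)
  bad_rng <- !(mentions$start >= 0L & mentions$start < mentions$end &
                 mentions$end <= len)
  sliced <- str_slice(src, mentions$start, mentions$end)
  bad_txt <- !bad_rng & sliced != mentions$text
  if (any(bad_rng | bad_txt)) {
    i <- which(bad_rng | bad_txt)[1]
    abort(sprintf(
      paste0("offset-convention error for mention %s %s:%d:%d: ",
             "annotated text %s does not equal source slice %s"),
      mentions$doc_id[i], mentions$section[i], mentions$start[i],
      mentions$end[i], dQuote(mentions$text[i], q = FALSE),
      dQuote(if (bad_rng[i]) "<out of range>" else sliced[i], q = FALSE)),
      class = "chemtagger_offset_error")
  }
  invisible(TRUE)
}

#' Read a tab-separated abstracts + annotations corpus
#'
#' The abstracts file holds one document per line:
#' `doc_id<TAB>title<TAB>abstract`. The optional annotations file holds one
#' mention per line: `doc_id<TAB>T|A<TAB>start<TAB>end<TAB>text<TAB>subtype`,
#' with 0-based half-open code-point offsets into the flagged section. Every
#' mention's text column is cross-checked against the corresponding slice of
#' the section text; a mismatch is an offset-convention error. Files must be
#' valid UTF-8; a decode failure is an error.
#'
#' @param abstracts_path path to the abstracts TSV.
#' @param annotations_path optional path to the annotations TSV.
#' @return A [chem_corpus()] object.
#' @export
read_chemdner <- function(abstracts_path, annotations_path = NULL) {
  doc_lines <- read_utf8_lines(abstracts_path)
  doc_fields <- strsplit(doc_lines, "\t", fixed = TRUE)
  nf <- lengths(doc_fields)
  if (any(nf != 3L)) {
    abort(sprintf("malformed abstracts record at line %d of %s (%d fields, expected 3)",
                  which(nf != 3L)[1], abstracts_path, nf[which(nf != 3L)[1]]),
          class = "chemtagger_parse_error")
  }
  documents <- tibble(
    doc_id = map_chr(doc_fields, 1),
    title = map_chr(doc_fields, 2),
    abstract = map_chr(doc_fields, 3)
  )
  mentions <- empty_mentions()
  if (!is.null(annotations_path)) {
    ann_lines <- read_utf8_lines(annotations_path)
    if (length(ann_lines) > 0) {
      ann_fields <- strsplit(ann_lines, "\t", fixed = TRUE)
      nf <- lengths(ann_fields)
      if (any(nf != 6L)) {
        abort(sprintf("malformed annotations record at line %d of %s (%d fields, expected 6)",
                      which(nf != 6L)[1], annotations_path, nf[which(nf != 6L)[1]]),
              class = "chemtagger_parse_error")
      }
      mentions <- tibble(
        doc_id = map_chr(ann_fields, 1),
        section = map_chr(ann_fields, 2),
        start = as.integer(map_chr(ann_fields, 3)),
        end = as.integer(map_chr(ann_fields, 4)),
        text = map_chr(ann_fields, 5),
        subtype = map_chr(ann_fields, 6),
        probability = NA_real_
      )
    }
  }
  chem_corpus(documents, mentions)
}

read_utf8_lines <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    abort(paste0("file is not valid UTF-8: ", path),
          class = "chemtagger_parse_error")
  }
  lines <- strsplit(gsub("\r\n", "\n", txt, fixed = TRUE), "\n", fixed = TRUE)[[1]]
  lines[nzchar(lines) | seq_along(lines) < length(lines)]
}

#' Write a corpus back to abstracts + annotations TSV files
#'
#' Inverse of [read_chemdner()]; reading the written pair reproduces the
#' corpus field-for-field (probabilities are not serialized in the
#' annotation dialect).
#'
#' @param corpus a [chem_corpus()].
#' @param abstracts_path,annotations_path output paths.
#' @return `corpus`, invisibly.
#' @export
write_chemdner <- function(corpus, abstracts_path, annotations_path = NULL) {
  docs <- corpus$documents
  writeLines(paste(docs$doc_id, docs$title, docs$abstract, sep = "\t"),
             abstracts_path, useBytes = FALSE)
  if (!is.null(annotations_path)) {
    m <- corpus$mentions
    sub <- ifelse(is.na(m$subtype), "NONE", m$subtype)
    writeLines(paste(m$doc_id, m$section, m$start, m$end, m$text, sub,
                     sep = "\t"), annotations_path, useBytes = FALSE)
  }
  invisible(corpus)
}

rank_within_doc <- function(df, order_cols) {
  df |>
    group_by(.data$doc_id) |>
    arrange(!!!order_cols, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Write mention-level (CEM) predictions
#'
#' One line per mention: `doc_id<TAB>T:start:end<TAB>rank<TAB>probability`.
#' Ranks are recomputed at write time per document by descending probability,
#' ties broken by (section, start, end); any pre-existing rank is ignored.
#'
#' @param mentions mention tibble; every row must carry a probability.
#' @param path output path.
#' @return The written tibble (with `rank`), invisibly.
#' @export
write_cem_predictions <- function(mentions, path) {
  m <- as_mentions(mentions)
  chem_stopifnot(all(!is.na(m$probability)),
                 "every CEM prediction must carry a probability")
  m <- rank_within_doc(m, rlang::quos(desc(.data$probability), .data$section,
                                      .data$start, .data$end))
  writeLines(paste(m$doc_id,
                   paste(m$section, m$start, m$end, sep = ":"),
                   m$rank, format_prob(m$probability), sep = "\t"),
             path)
  invisible(m)
}

#' Write document-level (CDI) predictions
#'
#' One line per (document, mention text):
#' `doc_id<TAB>text<TAB>rank<TAB>probability`. Texts must be unique within a
#' document; ranks are recomputed by descending probability, ties broken by
#' text order.
#'
#' @param terms tibble with columns `doc_id`, `text`, `probability`.
#' @param path output path.
#' @return The written tibble (with `rank`), invisibly.
#' @export
write_cdi_predictions <- function(terms, path) {
  terms <- as_tibble(terms)
  chem_stopifnot(all(c("doc_id", "text", "probability") %in% names(terms)),
                 "CDI terms need doc_id, text, probability")
  chem_stopifnot(all(!is.na(terms$probability)),
                 "every CDI prediction must carry a probability")
  dup <- terms |> count(.data$doc_id, .data$text) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate CDI text %s in document %s",
                  dQuote(dup$text[1], q = FALSE), dup$doc_id[1]),
          class = "chemtagger_contract_error")
  }
  terms <- rank_within_doc(terms, rlang::quos(desc(.data$probability), .data$text))
  writeLines(paste(terms$doc_id, terms$text, terms$rank,
                   format_prob(terms$probability), sep = "\t"), path)
  invisible(terms)
}

format_prob <- function(p) {
  sprintf("%.15g", p)
}

#' Read back CEM / CDI prediction files
#'
#' @param path prediction file written by [write_cem_predictions()] or
#'   [write_cdi_predictions()].
#' @return A tibble (spans or texts with probabilities). The rank column is
#'   read but ignored by all downstream code.
#' @export
read_cem_predictions <- function(path) {
  lines <- read_utf8_lines(path)
  if (length(lines) == 0) {
    return(tibble(doc_id = character(), section = character(),
                  start = integer(), end = integer(), probability = double()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  span <- strsplit(map_chr(f, 2), ":", fixed = TRUE)
  tibble(
    doc_id = map_chr(f, 1),
    section = map_chr(span, 1),
    start = as.integer(map_chr(span, 2)),
    end = as.integer(map_chr(span, 3)),
    probability = as.numeric(map_chr(f, 4))
  )
}

#' @rdname read_cem_predictions
#' @export
read_cdi_predictions <- function(path) {
  lines <- read_utf8_lines(path)
  if (length(lines) == 0) {
    return(tibble(doc_id = character(), text = character(),
                  probability = double()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    doc_id = map_chr(f, 1),
    text = map_chr(f, 2),
    probability = as.numeric(map_chr(f, 4))
  )
}
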