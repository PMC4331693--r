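#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 pmap map_chr map_int map_dbl map_lgl imap
#' @importFrom stringr str_sub str_length str_detect str_split str_locate_all
#'   str_to_lower str_replace_all fixed coll
#' @useDynLib chemtagger, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# All character offsets in this package are 0-based, half-open, counted in
# Unicode code points within one section (title or abstract).

str_slice <- function(text, start, end) {
  stringr::str_sub(text, start + 1L, end)
}

# punctuation = neither letter, digit, nor whitespace (shared definition)
is_punct_char <- function(ch) {
  !grepl("[[:alpha:][:digit:][:space:]]", ch) & nzchar(ch)
}

chem_stopifnot <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "chemtagger_contract_error")
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "chemtagger")
  if (!nzchar(path)) {
    # during development (pkgload) system.file resolves differently
    abort(paste0("bundled data file not found: ", file))
  }
  path
}

empty_mentions <- function() {
  tibble(
    doc_id = character(), section = character(),
    start = integer(), end = integer(), text = character(),
    subtype = character(), probability = double()
  )
}

# Coerce a mention tibble to the canonical column set, filling optional cols.
as_mentions <- function(x) {
  x <- as_tibble(x)
  if (!"subtype" %in% names(x)) x$subtype <- NA_character_
  if (!"probability" %in% names(x)) x$probability <- NA_real_
  need <- c("doc_id", "section", "start", "end", "text", "subtype", "probability")
  missing <- setdiff(setdiff(need, c("subtype", "probability")), names(x))
  if (length(missing) > 0) {
    abort(paste0("mention table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x[, c(need, setdiff(names(x), need))]
}

section_text <- function(doc, section) {
  ifelse(section == "T", doc$title, doc$abstract)
}
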