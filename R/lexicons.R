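#' Load the bundled chemical lexicons
#'
#' Reads the element table (118 symbols and names), the 20 amino acids
#' (name, 3-character and 1-character abbreviations), the Greek letter
#' names, and the semantic affix lists (chemical suffixes, alkane stems,
#' trivial ring names, simple multipliers). Any component can be overridden
#' with a user file in the same TSV dialect.
#'
#' Matching conventions: element symbols are case-sensitive (`"Co"` is
#' cobalt, `"CO"` is not); element names, amino-acid entries, Greek letter
#' names and all semantic affixes match case-insensitively (stored
#' lowercase).
#'
#' @param elements_path,amino_acids_path,greek_path,affixes_path optional
#'   replacement files (`symbol<TAB>name`; `name<TAB>3char<TAB>1char`; one
#'   name per line; `kind<TAB>string`).
#' @return A list of class `chem_lexicons` with character-vector components
#'   `element_symbols`, `element_names`, `amino_acid_names`,
#'   `amino_acid_3char`, `amino_acid_1char`, `greek_letter_names`,
#'   `chemical_suffixes`, `alkane_stems`, `trivial_rings`,
#'   `simple_multipliers`.
#' @export
chem_lexicons <- function(elements_path = NULL, amino_acids_path = NULL,
                          greek_path = NULL, affixes_path = NULL) {
  el <- read_tsv_cols(elements_path %||% extdata_path("elements.tsv"), 2)
  aa <- read_tsv_cols(amino_acids_path %||% extdata_path("amino_acids.tsv"), 3)
  greek <- read_utf8_lines(greek_path %||% extdata_path("greek_letters.txt"))
  aff <- read_tsv_cols(affixes_path %||% extdata_path("semantic_affixes.tsv"), 2)
  kind <- aff[[1]]
  structure(list(
    element_symbols = el[[1]],
    element_names = tolower(el[[2]]),
    amino_acid_names = tolower(aa[[1]]),
    amino_acid_3char = tolower(aa[[2]]),
    amino_acid_1char = tolower(aa[[3]]),
    greek_letter_names = tolower(greek),
    chemical_suffixes = unique(tolower(aff[[2]][kind == "chemical_suffix"])),
    alkane_stems = unique(tolower(aff[[2]][kind == "alkane_stem"])),
    trivial_rings = unique(tolower(aff[[2]][kind == "trivial_ring"])),
    simple_multipliers = unique(tolower(aff[[2]][kind == "simple_multiplier"]))
  ), class = "chem_lexicons")
}

read_tsv_cols <- function(path, ncol) {
  lines <- read_utf8_lines(path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) != ncol
  if (any(bad)) {
    abort(sprintf("malformed lexicon record at line %d of %s",
                  which(bad)[1], path), class = "chemtagger_parse_error")
  }
  lapply(seq_len(ncol), function(i) map_chr(f, i))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
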