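lex <- chem_lexicons()

test_that("word shape and capitalization abstractions", {
  expect_equal(word_shape(c("Cu(2+", "AAA", "mg")), c("Aax0x", "AAA", "aa"))
})

test_that("character n-grams enumerate substrings of length 2-4", {
  expect_setequal(char_ngrams("meth"),
                  c("me", "et", "th", "met", "eth", "meth"))
  expect_equal(char_ngrams("ab"), "ab")
  expect_equal(char_ngrams("a"), character())
  # multiset: repeats preserved
  expect_equal(sum(char_ngrams("aaa") == "aa"), 2)
})

test_that("formula-token segmentation agrees with exhaustive enumeration", {
  expect_true(is_formula_token("FCH", lex))
  expect_true(is_formula_token("He", lex))
  expect_false(is_formula_token("Qx", lex))
  # brute force over a 10-element toy table, all tokens of length <= 6
  toy <- lex
  toy$element_symbols <- c("H", "He", "C", "Ca", "N", "Na", "O", "S", "Sn", "F")
  alphabet <- c("H", "e", "C", "a", "N", "O", "S", "n", "F", "x")
  enumerate_parse <- function(token) {
    n <- nchar(token)
    if (n == 0) return(TRUE)
    for (k in 1:2) {
      if (k <= n && substr(token, 1, k) %in% toy$element_symbols &&
          enumerate_parse(substr(token, k + 1, n))) {
        return(TRUE)
      }
    }
    FALSE
  }
  set.seed(5)
  tokens <- vapply(1:250, function(i) {
    paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
  }, character(1))
  expect_equal(vapply(tokens, is_formula_token, logical(1), lexicons = toy,
                      USE.NAMES = FALSE),
               vapply(tokens, enumerate_parse, logical(1), USE.NAMES = FALSE))
})

test_that("Roman numerals follow subtractive validity, uppercase only", {
  expect_true(all(is_roman_numeral(c("III", "IV", "MCMXCIV", "X"))))
  expect_false(any(is_roman_numeral(c("IIII", "VX", "iii", "", "ABC"))))
})

test_that("amino-acid sequences are flagged across hyphenated tokens", {
  toks <- tokenize_m1("Phe-Cys-Tyr")
  flags <- amino_acid_sequence_flags(toks, "Phe-Cys-Tyr", lex)
  expect_equal(flags, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  toks1 <- tokenize_m1("Phe alone")
  expect_false(any(amino_acid_sequence_flags(toks1, "Phe alone", lex)))
  toks2 <- tokenize_m1("Phe-Xyz")
  expect_false(any(amino_acid_sequence_flags(toks2, "Phe-Xyz", lex)))
})

test_that("Model 1 feature extraction emits the documented flags", {
  toks <- tokenize_m1("alpha III chain")
  fv <- extract_features_m1(toks, "alpha III chain", lex)
  expect_true("GREEK" %in% fv[[1]])
  expect_true("ROMAN" %in% fv[[2]])
  # boundary sentinels at the sequence edges
  expect_true("@-1|BND" %in% fv[[1]])
  expect_true("@-2|BND" %in% fv[[2]])
  expect_true("@2|BND" %in% fv[[2]])
  # context copies carry the neighbor's features
  expect_true("@1|ROMAN" %in% fv[[1]])
  # part-of-speech omitted without a tagger, present with one
  expect_false(any(grepl("^POS=", unlist(fv))))
  fv_pos <- extract_features_m1(toks, "alpha III chain", lex,
                                pos_tagger = function(x) rep("NN", length(x)))
  expect_true("POS=NN" %in% fv_pos[[1]])
  # external tagger overlap flag only when an adapter is supplied
  expect_false(any(grepl("^EXT=", unlist(fv))))
  fv_ext <- extract_features_m1(
    toks, "alpha III chain", lex,
    external_tagger = function(text) tibble::tibble(start = 0L, end = 5L))
  expect_true("EXT=1" %in% fv_ext[[1]])
  expect_true("EXT=0" %in% fv_ext[[2]])
})

test_that("feature extraction is deterministic", {
  toks <- tokenize_m1("NaCl and 2-meth-yl-benzene")
  a <- extract_features_m1(toks, "NaCl and 2-meth-yl-benzene", lex)
  b <- extract_features_m1(toks, "NaCl and 2-meth-yl-benzene", lex)
  expect_identical(a, b)
  toks2 <- tokenize_m2("NaCl and 2-meth-yl-benzene")
  expect_identical(extract_features_m2(toks2, lex),
                   extract_features_m2(toks2, lex))
})

test_that("affix enumeration respects the length range", {
  af <- affixes("benzene")
  expect_setequal(af$value[af$kind == "prefix"],
                  c("b", "be", "ben", "benz", "benze"))
  expect_setequal(af$value[af$kind == "suffix"],
                  c("e", "ne", "ene", "zene", "nzene"))
  expect_equal(affixes("a")$value, c("a", "a"))
  af2 <- affixes("di")
  expect_setequal(af2$value[af2$kind == "prefix"], c("d", "di"))
  af25 <- affixes("benzene", lmin = 2, lmax = 5)
  expect_false("b" %in% af25$value)
})

test_that("character counts and case patterns", {
  expect_equal(unname(char_counts("Cu2")), c(3L, 1L, 1L, 1L))
  expect_equal(unname(char_counts("AAAA")), c(4L, 0L, 4L, 0L))
  expect_equal(unname(char_counts("ab")), c(2L, 0L, 0L, 2L))
  expect_equal(case_pattern("CD40"), c(full = "AA00", merged = "A0"))
  expect_equal(case_pattern("a"), c(full = "a", merged = "a"))
  expect_equal(case_pattern("Abc-1"), c(full = "Aaa-0", merged = "Aa-0"))
})

test_that("merging a merged case pattern is a fixed point", {
  set.seed(31)
  for (s in random_strings(200, ascii_only = TRUE)) {
    if (!nzchar(s)) next
    cp <- case_pattern(s)
    expect_equal(unname(case_pattern(cp[["merged"]])[["merged"]]),
                 unname(cp[["merged"]]))
  }
})

test_that("Model 2 semantic flags anchor as specified", {
  toks <- tokenize_m2("tetracos pyridine di xylene")
  fv <- extract_features_m2(toks, lex)
  txt <- toks$text
  expect_true("ALKSTEM" %in% fv[[which(txt == "tetracos")]])
  expect_true("RING" %in% fv[[which(txt == "pyridine")]])
  expect_true("MULT" %in% fv[[which(txt == "di")]])
  # ring names match as whole token only
  expect_false("RING" %in% fv[[which(txt == "xylene")]])
  # chemical suffix matches at token end
  toks2 <- tokenize_m2("methanol")
  fv2 <- extract_features_m2(toks2, lex)
  expect_true("CHEMSUF" %in% fv2[[1]])
})

test_that("per-token feature counts stay bounded", {
  set.seed(13)
  for (s in random_strings(50, ascii_only = TRUE)) {
    toks <- tokenize_m2(s)
    if (nrow(toks) == 0) next
    fv <- extract_features_m2(toks, lex)
    # base features are bounded; each of the 6 context slots repeats them
    expect_true(all(lengths(fv) <= 7 * 30))
  }
})

test_that("Porter stems match published reference pairs", {
  expect_equal(
    porter_stem(c("caresses", "ponies", "ties", "caress", "cats", "feed",
                  "agreed", "plastered", "motoring", "sing", "happy",
                  "relational", "conditional", "rational", "oscillators",
                  "generalization", "triplicate", "formative", "electrical",
                  "hopeful", "goodness", "adjustable", "replacement",
                  "adoption", "probate", "cease", "controll", "roll")),
    c("caress", "poni", "ti", "caress", "cat", "feed",
      "agre", "plaster", "motor", "sing", "happi",
      "relat", "condit", "ration", "oscil",
      "gener", "triplic", "form", "electr",
      "hope", "good", "adjust", "replac",
      "adopt", "probat", "ceas", "control", "roll"))
  # non-alphabetic tokens pass through unchanged
  expect_equal(porter_stem(c("C6H12", "2-yl")), c("c6h12", "2-yl"))
})
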