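mk_doc <- function(abstract, title = "Untitled", doc_id = "D1") {
  tibble::tibble(doc_id = doc_id, title = title, abstract = abstract)
}

mk_mention <- function(doc, section, start, end, prob = 0.8, subtype = NA) {
  text <- stringr::str_sub(if (section == "T") doc$title else doc$abstract,
                           start + 1, end)
  tibble::tibble(doc_id = doc$doc_id, section = section,
                 start = as.integer(start), end = as.integer(end),
                 text = text, subtype = subtype, probability = prob)
}

test_that("consistency adds missed repeats without touching overlaps", {
  doc <- mk_doc(paste0("steroidal saponins appear. steroidal saponins recur.",
                       " finally steroidal saponins again."))
  m <- dplyr::bind_rows(mk_mention(doc, "A", 0, 18, 0.7),
                        mk_mention(doc, "A", 27, 45, 0.9))
  expect_equal(m$text, rep("steroidal saponins", 2))
  out <- enforce_consistency(m, doc)
  expect_equal(nrow(out), 3)
  added <- dplyr::anti_join(out, m, by = c("start", "end"))
  expect_equal(added$text, "steroidal saponins")
  expect_equal(added$probability, 0.9) # max of the source mentions
  # monotone and idempotent
  expect_true(all(paste(m$start, m$end) %in% paste(out$start, out$end)))
  expect_identical(enforce_consistency(out, doc), out)
})

test_that("consistency does not add a span inside an already-tagged span", {
  doc <- mk_doc("GO was added. GO again. the GO-PDEA composite was stable.")
  m <- dplyr::bind_rows(mk_mention(doc, "A", 0, 2),   # GO
                        mk_mention(doc, "A", 14, 16), # GO
                        mk_mention(doc, "A", 28, 35)) # GO-PDEA
  expect_equal(m$text, c("GO", "GO", "GO-PDEA"))
  out <- enforce_consistency(m, doc)
  # the "GO" inside "GO-PDEA" must not be added
  expect_equal(nrow(out), 3)
  # and no overlapping mentions were created
  ov <- dplyr::group_by(out, section) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(ok = all(start[-1] >= end[-dplyr::n()]) | dplyr::n() == 1)
  expect_true(all(ov$ok))
})

test_that("a text tagged once is not propagated", {
  doc <- mk_doc("benzene here. benzene there.")
  m <- mk_mention(doc, "A", 0, 7)
  expect_equal(nrow(enforce_consistency(m, doc)), 1)
})

test_that("abbreviation definitions are detected by alignment", {
  doc <- mk_doc("allopregnanolone (AP) was infused.")
  pairs <- detect_abbreviations(doc)
  expect_equal(pairs$short_form, "AP")
  expect_equal(pairs$long_form, "allopregnanolone")
  # formula fallback for a short form with no letter overlap
  doc2 <- mk_doc("the sample contained water (H2O) only.")
  pairs2 <- detect_abbreviations(doc2)
  expect_equal(pairs2$short_form, "H2O")
  expect_equal(pairs2$long_form, "water")
  expect_equal(nrow(detect_abbreviations(mk_doc("no parens here"))), 0)
})

test_that("abbreviation propagation follows the per-model rules", {
  doc <- mk_doc("allopregnanolone (AP) rose. AP fell. AP stabilized.")
  pairs <- detect_abbreviations(doc)
  long_m <- mk_mention(doc, "A", 0, 16, 0.7)
  out <- propagate_abbreviations(long_m, doc, pairs, "M1")
  expect_equal(sum(out$text == "AP"), 3)
  expect_true(all(out$probability[out$text == "AP"] == 0.7))
  # M1: long form untagged leaves mentions unchanged
  short_only <- mk_mention(doc, "A", 28, 30, 0.5)
  expect_equal(short_only$text, "AP")
  expect_identical(propagate_abbreviations(short_only, doc, pairs, "M1"),
                   short_only)
  # M2: long form untagged removes short-form mentions
  expect_equal(nrow(propagate_abbreviations(short_only, doc, pairs, "M2")), 0)
  # M2: both tagged tags all long-form occurrences
  doc3 <- mk_doc("benzene (BZ) reacted. BZ remained. benzene stayed.")
  pairs3 <- detect_abbreviations(doc3)
  both <- dplyr::bind_rows(mk_mention(doc3, "A", 0, 7, 0.9),
                           mk_mention(doc3, "A", 22, 24, 0.6))
  out3 <- propagate_abbreviations(both, doc3, pairs3, "M2")
  expect_equal(sum(out3$text == "benzene"), 2)
})

test_that("bracket balancing applies the paper's worked example", {
  doc <- mk_doc("binding of Cu(2+) was measured")
  m <- mk_mention(doc, "A", 11, 16) # "Cu(2+"
  expect_equal(m$text, "Cu(2+")
  out <- balance_brackets(m, doc)
  expect_equal(out$text, "Cu(2+)")
  expect_equal(out$end, 17)
  # already balanced mentions are untouched
  doc2 <- mk_doc("aspirin was given")
  m2 <- mk_mention(doc2, "A", 0, 7)
  expect_identical(balance_brackets(m2, doc2), m2)
  # unbalanceable mentions are dropped
  doc3 <- mk_doc("junk ((a here")
  m3 <- mk_mention(doc3, "A", 5, 8)
  expect_equal(m3$text, "((a")
  expect_equal(nrow(balance_brackets(m3, doc3)), 0)
})

test_that("surviving mentions of random bracket perturbations are balanced", {
  set.seed(77)
  pieces <- c("ab", "(cd)", "[ef]", "{gh}", "(i[j])", "kl", "(", ")")
  for (i in 1:200) {
    abstract <- paste(sample(pieces, 6, replace = TRUE), collapse = " ")
    doc <- mk_doc(abstract)
    n <- stringr::str_length(abstract)
    s <- sample(0:(n - 2), 1)
    e <- sample((s + 1):n, 1)
    m <- mk_mention(doc, "A", s, e)
    out <- balance_brackets(m, doc)
    if (nrow(out) > 0) {
      expect_true(counter_balanced(out$text))
      # slice invariant maintained
      expect_equal(out$text,
                   stringr::str_sub(abstract, out$start + 1, out$end))
    }
  }
})

test_that("identifier lexicon compilation reproduces the worked pattern", {
  pat <- compile_identifier_lexicon(c("NSC-114792", "X1", "ABCDEF123",
                                      "AB 1234", "XYZ99"))
  expect_equal(pat$pattern[pat$source_name == "NSC-114792"],
               "NSC[\\-\\_ ]{0,2}114792")
  expect_false("X1" %in% pat$source_name)      # 1 letter, 1 digit
  expect_false("ABCDEF123" %in% pat$source_name) # 6 letters
  expect_true(all(c("AB 1234", "XYZ99") %in% pat$source_name))
})

test_that("identifier matching respects word boundaries", {
  pat <- compile_identifier_lexicon("NSC-114792")
  doc <- mk_doc("treated with NSC 114792 daily")
  hits <- match_identifiers(doc, pat)
  expect_equal(hits$text, "NSC 114792")
  expect_equal(hits$subtype, "IDENTIFIER")
  # the regex itself matches all separator variants
  rx <- paste0("^(?:", pat$pattern, ")$")
  expect_true(all(grepl(rx, c("NSC114792", "NSC 114792", "NSC-114792"),
                        perl = TRUE)))
  # a trailing digit breaks the right word boundary
  expect_equal(nrow(match_identifiers(mk_doc("with NSC1147920 treatment"),
                                      pat)), 0)
  expect_equal(nrow(match_identifiers(doc, pat[0, ])), 0)
})

test_that("overlap resolution keeps the longer, then the likelier span", {
  doc <- mk_doc("abcdefghij")
  m <- dplyr::bind_rows(
    mk_mention(doc, "A", 0, 4, 0.9),
    mk_mention(doc, "A", 2, 9, 0.3),
    mk_mention(doc, "A", 2, 9, 0.8)) # duplicate span, higher prob
  out <- resolve_overlaps(m)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 2L)
  expect_equal(out$probability, 0.8)
})

test_that("the full cascade never emits overlapping mentions", {
  set.seed(21)
  fit <- shared_taggers()
  pred <- tag_corpus(fit$m1, fit$test, fit$lex, marginals = FALSE)
  bad <- pred |>
    dplyr::group_by(doc_id, section) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(ok = dplyr::n() <= 1 ||
                       all(start[-1] >= end[-dplyr::n()]), .groups = "drop")
  expect_true(all(bad$ok))
})
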