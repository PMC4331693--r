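test_that("noisy-or closed forms and bounds", {
  expect_equal(noisy_or(c(0.5, 0.5)), 0.75)
  expect_equal(noisy_or(numeric()), 0)
  expect_equal(noisy_or(c(1.0, 0.2)), 1.0)
  expect_error(noisy_or(c(0.5, 1.2)), class = "chemtagger_contract_error")
})

test_that("noisy-or is monotone in arguments and under extension", {
  set.seed(55)
  for (i in 1:200) {
    p <- runif(sample(1:6, 1))
    v <- noisy_or(p)
    expect_gte(v, 0); expect_lte(v, 1)
    j <- sample(length(p), 1)
    bumped <- p
    bumped[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_gte(noisy_or(bumped) + 1e-12, v)
    expect_gte(noisy_or(c(p, runif(1))) + 1e-12, v)
  }
})

test_that("mention marginals sum joint probabilities per exact span", {
  toks <- tokenize_m1("aa bb")
  nbest <- tibble::tibble(
    labels = list(c("B-CHEMICAL", "I-CHEMICAL"),
                  c("B-CHEMICAL", "I-CHEMICAL"),
                  c("B-CHEMICAL", "O")),
    probability = c(0.6, 0.3, 0.05))
  mm <- mention_marginals(nbest, toks, "aa bb")
  span_full <- mm[mm$start == 0 & mm$end == 5, ]
  span_aa <- mm[mm$start == 0 & mm$end == 2, ]
  expect_equal(span_full$marginal, 0.9)
  expect_equal(span_aa$marginal, 0.05)
})

test_that("n-best marginals equal exact enumeration marginals", {
  set.seed(23)
  nF <- 3L
  feat_names <- paste0("f", 1:nF)
  for (rep in 1:10) {
    T <- sample(2:6, 1)
    text <- paste(rep("x", T), collapse = " ")
    toks <- tokenize_m1(text)
    w <- rnorm(nF * 3 + 9 + 3)
    featids <- lapply(seq_len(T), function(t) sample(1:nF, sample(0:2, 1)))
    model <- toy_crf_model(w, feat_names)
    feats <- lapply(featids, function(ids) feat_names[ids])
    nb <- crf_nbest(model, feats, n = 3^T)
    mine <- mention_marginals(nb, toks, text)
    # oracle: decode every enumerated labeling, accumulate its probability
    oracle <- enumerate_labelings(w, featids, nF, 3L)
    acc <- list()
    for (i in seq_len(nrow(oracle$paths))) {
      labs <- model$config$labels[oracle$paths[i, ]]
      spans <- iob_decode(toks, labs, text, quiet = TRUE)
      for (k in seq_len(nrow(spans))) {
        key <- paste(spans$start[k], spans$end[k])
        prev <- if (is.null(acc[[key]])) 0 else acc[[key]]
        acc[[key]] <- prev + exp(oracle$logp[i])
      }
    }
    expect_equal(nrow(mine), length(acc))
    for (k in seq_len(nrow(mine))) {
      key <- paste(mine$start[k], mine$end[k])
      expect_equal(mine$marginal[k], acc[[key]], tolerance = 1e-9)
    }
  }
})

mk_m <- function(doc_id, section, start, end, text, prob) {
  tibble::tibble(doc_id = doc_id, section = section,
                 start = as.integer(start), end = as.integer(end),
                 text = text, subtype = NA_character_, probability = prob)
}

test_that("naive combination pools and keeps the max probability", {
  a <- mk_m("D1", "A", 0, 4, "abcd", 0.4)
  b <- mk_m("D1", "A", c(0, 10), c(4, 14), c("abcd", "wxyz"), c(0.7, 0.5))
  out <- combine_naive(a, b)
  expect_equal(nrow(out), 2)
  expect_equal(out$probability[out$start == 0], 0.7)
  expect_identical(combine_naive(a, a[0, ])[, 1:7], a)
  disjoint <- combine_naive(mk_m("D1", "A", 0, 2, "ab", .5),
                            mk_m("D1", "A", 5, 7, "cd", .6))
  expect_equal(nrow(disjoint), 2)
})

test_that("heuristic combination swaps the 5-15 character band", {
  short1 <- mk_m("D1", "A", 0, 4, "abcd", 0.9)          # length 4: kept
  mid1 <- mk_m("D1", "A", 10, 20, "abcdefghij", 0.9)    # length 10: dropped
  mid2 <- mk_m("D1", "A", 30, 40, "qrstuvwxyz", 0.8)    # length 10: added
  out <- combine_heuristic(dplyr::bind_rows(short1, mid1), mid2)
  expect_setequal(out$start, c(0L, 30L))
  # boundary lengths 5 and 15 are in-range (inclusive)
  b5 <- mk_m("D1", "A", 0, 5, "abcde", 0.9)
  b15 <- mk_m("D1", "A", 0, 15, strrep("x", 15), 0.9)
  expect_equal(nrow(combine_heuristic(dplyr::bind_rows(b5, b15),
                                      b5[0, ])), 0)
})

test_that("high-recall combination includes marginals at the threshold", {
  marg <- mk_m("D1", "A", c(0, 10), c(4, 14), c("abcd", "wxyz"), c(0.09, 0.10))
  marg$marginal <- marg$probability
  m2 <- mk_m("D1", "A", 20, 24, "mnop", 0.9)
  out <- combine_high_recall(marg, m2, threshold = 0.1)
  expect_setequal(out$start, c(10L, 20L)) # 0.09 excluded, 0.10 included
  expect_identical(combine_high_recall(marg[0, ], m2)[, 1:7], m2)
})

test_that("document-level conversion applies the noisy-or per text", {
  m <- mk_m("D1", "A", c(0, 10, 20), c(4, 14, 24),
            c("abcd", "abcd", "wxyz"), NA_real_)
  m$marginal <- c(0.5, 0.5, 0.8)
  cdi <- cem_to_cdi(m)
  expect_equal(cdi$probability[cdi$text == "abcd"], 0.75)
  expect_equal(cdi$probability[cdi$text == "wxyz"], 0.8)
  expect_equal(nrow(cdi), 2)
  # unscored occurrences use the fixed probability
  m2 <- mk_m("D2", "A", c(0, 10), c(4, 14), c("abcd", "abcd"), NA_real_)
  cdi2 <- cem_to_cdi(m2, fixed_probability = 0.1)
  expect_equal(cdi2$probability, 1 - 0.9^2)
})
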