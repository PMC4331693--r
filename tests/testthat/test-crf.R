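test_that("IOB encoding and decoding are inverse on clean spans", {
  toks <- tokenize_m1("NaCl")
  m <- tibble::tibble(doc_id = "D1", section = "A", start = 0L, end = 4L,
                      text = "NaCl", subtype = NA, probability = NA_real_)
  labs <- iob_encode(toks, m)
  expect_equal(labs, c("B-CHEMICAL", "I-CHEMICAL"))
  expect_equal(iob_encode(toks, m[0, ]), c("O", "O"))

  toks4 <- tokenize_m1("aa bb cc dd")
  m4 <- tibble::tibble(doc_id = "D1", section = "A", start = 3L, end = 8L,
                       text = "bb cc", subtype = NA, probability = NA_real_)
  expect_equal(iob_encode(toks4, m4), c("O", "B-CHEMICAL", "I-CHEMICAL", "O"))
  back <- iob_decode(toks4, iob_encode(toks4, m4), "aa bb cc dd")
  expect_equal(back$start, 3L)
  expect_equal(back$end, 8L)
  expect_equal(back$text, "bb cc")
})

test_that("a mention boundary strictly inside a token labels the whole token", {
  toks <- tokenize_m1("abcdef")
  m <- tibble::tibble(doc_id = "D1", section = "A", start = 2L, end = 4L,
                      text = "cd", subtype = NA, probability = NA_real_)
  expect_equal(iob_encode(toks, m), "B-CHEMICAL")
})

test_that("overlapping gold mentions are rejected", {
  toks <- tokenize_m1("aa bb cc")
  m <- tibble::tibble(doc_id = "D1", section = "A", start = c(0L, 3L),
                      end = c(5L, 8L), text = c("aa bb", "bb cc"),
                      subtype = NA, probability = NA_real_)
  expect_error(iob_encode(toks, m), class = "chemtagger_contract_error")
})

test_that("orphan I labels are repaired with a warning", {
  toks <- tokenize_m1("aa bb")
  expect_warning(out <- iob_decode(toks, c("O", "I-CHEMICAL"), "aa bb"),
                 "orphan")
  expect_equal(out$text, "bb")
  expect_silent(iob_decode(toks, c("O", "I-CHEMICAL"), "aa bb", quiet = TRUE))
})

test_that("decoding an empty sequence yields empty labels, probability 1", {
  m <- toy_crf_model(rep(0, 5 * 3 + 9 + 3), paste0("f", 1:5))
  out <- crf_decode(m, list())
  expect_equal(out$labels, character())
  expect_equal(out$probability, 1)
  nb <- crf_nbest(m, list(), n = 3)
  expect_equal(nrow(nb), 1)
  expect_equal(nb$probability, 1)
})

test_that("Viterbi and n-best agree with exhaustive enumeration", {
  set.seed(202)
  nF <- 4L
  feat_names <- paste0("f", 1:nF)
  for (rep in 1:20) {
    T <- sample(1:6, 1)
    w <- rnorm(nF * 3 + 9 + 3)
    featids <- lapply(seq_len(T), function(t) sample(1:nF, sample(0:2, 1)))
    oracle <- enumerate_labelings(w, featids, nF, 3L)
    model <- toy_crf_model(w, feat_names)
    feats <- lapply(featids, function(ids) feat_names[ids])
    dec <- crf_decode(model, feats)
    best <- which.max(oracle$logp)
    expect_equal(dec$probability, exp(oracle$logp[best]), tolerance = 1e-9)
    y <- match(dec$labels, model$config$labels)
    own <- which(apply(oracle$paths, 1, function(p) all(p == y)))
    expect_equal(exp(oracle$logp[own]), exp(oracle$logp[best]),
                 tolerance = 1e-9)
    nb <- crf_nbest(model, feats, n = 5)
    expect_true(all(diff(nb$probability) <= 1e-12))
    expect_lte(sum(nb$probability), 1 + 1e-9)
    expect_gte(dec$probability, nb$probability[2] - 1e-12)
    # every returned sequence's probability matches the enumeration
    for (k in seq_len(nrow(nb))) {
      y <- match(nb$labels[[k]], model$config$labels)
      idx <- which(apply(oracle$paths, 1, function(p) all(p == y)))
      expect_equal(nb$probability[k], exp(oracle$logp[idx]), tolerance = 1e-9)
    }
  }
})

test_that("n-best with n = 1 equals Viterbi decoding", {
  set.seed(17)
  nF <- 3L
  feat_names <- paste0("g", 1:nF)
  w <- rnorm(nF * 3 + 9 + 3)
  feats <- list(c("g1", "g2"), "g3", character(), "g1")
  model <- toy_crf_model(w, feat_names)
  dec <- crf_decode(model, feats)
  nb <- crf_nbest(model, feats, n = 1)
  expect_equal(nb$labels[[1]], dec$labels)
  expect_equal(nb$probability[1], dec$probability)
})

test_that("exact ties are broken lexicographically by label sequence", {
  # all-zero weights: every labeling equally likely
  m <- toy_crf_model(rep(0, 2 * 3 + 9 + 3), c("a", "b"))
  nb <- crf_nbest(m, list(character(), character()), n = 9)
  key <- vapply(nb$labels, paste, character(1), collapse = "|")
  expect_equal(key, sort(key, method = "radix"))
  expect_equal(nb$probability, rep(1 / 9, 9))
})

test_that("training separates a toy corpus perfectly", {
  set.seed(3)
  mkseq <- function() {
    labs <- sample(c("O", "O", "B-CHEMICAL"), 6, replace = TRUE)
    list(features = lapply(labs, function(l) {
      if (l == "B-CHEMICAL") c("CHEM", "X") else c("PLAIN", "X")
    }), labels = labs)
  }
  train <- lapply(1:25, function(i) mkseq())
  model <- crf_train(train, crf_config(order = 1, sigma = 1))
  test_labs <- c("O", "B-CHEMICAL", "O", "B-CHEMICAL")
  feats <- lapply(test_labs, function(l) {
    if (l == "B-CHEMICAL") c("CHEM", "X") else c("PLAIN", "X")
  })
  expect_equal(crf_decode(model, feats)$labels, test_labs)
  expect_error(crf_train(list(), crf_config()),
               class = "chemtagger_contract_error")
})

test_that("a cutoff above all counts leaves only structural weights", {
  train <- list(list(features = list("A", "B", "A"),
                     labels = c("O", "O", "O")),
                list(features = list("C", "A"),
                     labels = c("B-CHEMICAL", "O")))
  model <- crf_train(train, crf_config(cutoff = 99L))
  expect_equal(length(model$features), 0)
  dec <- crf_decode(model, list("NEW", "NEW", "NEW"))
  expect_equal(dec$labels, rep("O", 3))
})

test_that("weight norms shrink monotonically as sigma decreases", {
  set.seed(9)
  train <- lapply(1:10, function(i) {
    labs <- sample(c("O", "B-CHEMICAL"), 5, replace = TRUE)
    list(features = lapply(labs, function(l) {
      c(if (l == "O") "p" else "c", sample(c("u", "v"), 1))
    }), labels = labs)
  })
  norms <- vapply(c(0.01, 0.1, 1), function(s) {
    sqrt(sum(crf_train(train, crf_config(sigma = s))$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) > 0))
})

test_that("order-2 composition trains and decodes with valid projection", {
  set.seed(4)
  mkseq <- function() {
    labs <- c("O", "B-CHEMICAL", "I-CHEMICAL", "O",
              sample(c("O", "B-CHEMICAL"), 1))
    list(features = purrr::map2(labs, seq_along(labs), function(l, i) {
      c(paste0("t", i), if (l != "O") "CHEM" else "PLAIN")
    }), labels = labs)
  }
  train <- lapply(1:15, function(i) mkseq())
  model <- crf_train(train, crf_config(order = 2, sigma = 4, cutoff = 0))
  feats <- list(c("t1", "PLAIN"), c("t2", "CHEM"), c("t3", "CHEM"),
                c("t4", "PLAIN"), c("t5", "PLAIN"))
  dec <- crf_decode(model, feats)
  expect_equal(length(dec$labels), 5)
  expect_true(all(dec$labels %in% model$config$labels))
  expect_equal(dec$labels[2:3], c("B-CHEMICAL", "I-CHEMICAL"))
  nb <- crf_nbest(model, feats, n = 10)
  expect_lte(sum(nb$probability), 1 + 1e-9)
  expect_false(anyDuplicated(vapply(nb$labels, paste, character(1),
                                    collapse = "|")) > 0)
})

test_that("models serialize and reload with identical decoding", {
  set.seed(12)
  train <- lapply(1:8, function(i) {
    labs <- sample(c("O", "B-CHEMICAL"), 4, replace = TRUE)
    list(features = lapply(labs, function(l) {
      if (l == "O") c("p", "q") else c("c", "q")
    }), labels = labs)
  })
  model <- crf_train(train, crf_config(order = 2, sigma = 2, cutoff = 1))
  path <- withr::local_tempfile()
  write_crf_model(model, path)
  back <- read_crf_model(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$features, model$features)
  feats <- list(c("p", "q"), c("c", "q"), "p")
  expect_identical(crf_decode(back, feats), crf_decode(model, feats))
})

test_that("tidy and glance summarize a fitted model", {
  train <- list(list(features = list("a", "b"), labels = c("O", "O")))
  model <- crf_train(train, crf_config())
  td <- tidy(model)
  expect_setequal(unique(td$type), c("emission", "transition", "initial"))
  expect_equal(nrow(td), length(model$weights))
  gl <- glance(model)
  expect_equal(gl$n_features, 2)
  expect_true(gl$converged)
})
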