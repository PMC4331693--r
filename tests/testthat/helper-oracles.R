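# Independent oracles and shared fixtures for the test suite.

# Exhaustive enumeration oracle for a linear-chain CRF: scores every
# possible labeling directly from the weight vector (layout as in the
# engine: emission block, transition block, initial block).
enumerate_labelings <- function(w, featids, nF, nS,
                                trans_mask = matrix(TRUE, nS, nS),
                                init_mask = rep(TRUE, nS)) {
  T <- length(featids)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(nS)), T),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(seqs) <- NULL
  node <- matrix(0, T, nS)
  for (t in seq_len(T)) {
    for (f in featids[[t]]) node[t, ] <- node[t, ] + w[(f - 1) * nS + seq_len(nS)]
  }
  offT <- nF * nS
  offI <- offT + nS * nS
  score <- vapply(seq_len(nrow(seqs)), function(i) {
    y <- seqs[i, ]
    if (!init_mask[y[1]]) return(-Inf)
    s <- w[offI + y[1]] + sum(node[cbind(seq_len(T), y)])
    if (T > 1) {
      for (t in 2:T) {
        if (!trans_mask[y[t - 1], y[t]]) return(-Inf)
        s <- s + w[offT + (y[t - 1] - 1) * nS + y[t]]
      }
    }
    s
  }, numeric(1))
  finite <- is.finite(score)
  m <- max(score[finite])
  logZ <- m + log(sum(exp(score[finite] - m)))
  list(paths = seqs, logp = score - logZ, logZ = logZ)
}

# wrap raw weights as a decodable model object (order-1, IOB labels)
toy_crf_model <- function(w, features, config = crf_config(order = 1L)) {
  structure(list(weights = w, features = features, config = config,
                 states = config$labels, nll = NA_real_, counts = NULL,
                 convergence = 0L, seed = 1L),
            class = "chem_crf")
}

# random strings over a mixed alphabet (letters, digits, punctuation,
# whitespace, some non-ASCII)
random_strings <- function(n, max_len = 12, ascii_only = FALSE) {
  pool <- c(letters, LETTERS, 0:9, "(", ")", "-", "+", ".", ",", " ", " ",
            "[", "]", "/", "_")
  if (!ascii_only) pool <- c(pool, "α", "β", "—", "µ")
  vapply(seq_len(n), function(i) {
    k <- sample.int(max_len, 1)
    paste(sample(pool, k, replace = TRUE), collapse = "")
  }, character(1))
}

# gap-aware reconstruction check: tokens must slice exactly, not overlap,
# and leave only whitespace uncovered
tokens_reconstruct <- function(text, tokens) {
  if (nrow(tokens) == 0) return(!grepl("\\S", text))
  if (is.unsorted(tokens$start)) return(FALSE)
  if (any(tokens$end <= tokens$start)) return(FALSE)
  if (nrow(tokens) > 1 &&
      any(tokens$start[-1] < tokens$end[-nrow(tokens)])) return(FALSE)
  sliced <- stringr::str_sub(text, tokens$start + 1, tokens$end)
  if (!all(sliced == tokens$text)) return(FALSE)
  covered <- rep(FALSE, stringr::str_length(text))
  for (i in seq_len(nrow(tokens))) {
    covered[(tokens$start[i] + 1):tokens$end[i]] <- TRUE
  }
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  all(grepl("[[:space:]]", chars[!covered]))
}

# per-type counter oracle for bracket balance (independent of the stack
# implementation under test)
counter_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (pair in list(c("(", ")"), c("[", "]"), c("{", "}"))) {
    depth <- cumsum((chars == pair[1]) - (chars == pair[2]))
    if (length(depth) > 0 && (any(depth < 0) || depth[length(depth)] != 0)) {
      return(FALSE)
    }
  }
  TRUE
}

# small taggers shared across tests (trained once per session)
the_shared <- new.env(parent = emptyenv())

shared_taggers <- function() {
  if (is.null(the_shared$fit)) {
    lex <- chem_lexicons()
    train <- generate_corpus(corpus_config(n_documents = 40, seed = 11))
    test <- generate_corpus(corpus_config(n_documents = 15, seed = 12))
    m1 <- train_tagger(train, "m1", lexicons = lex)
    m2 <- train_tagger(train, "m2", lexicons = lex)
    the_shared$fit <- list(lex = lex, train = train, test = test,
                           m1 = m1, m2 = m2)
  }
  the_shared$fit
}
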