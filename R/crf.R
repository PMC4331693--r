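chem_label_set <- c("B-CHEMICAL", "I-CHEMICAL", "O")

#' CRF configuration
#'
#' @param order Markov order of the label chain, 1 or 2. Order 2 is realized
#'   by composing adjacent label pairs into product states over an order-1
#'   engine with masked transitions, then projecting decoded sequences back.
#' @param sigma Gaussian prior variance (sigma > 0). The L2 penalty added to
#'   the negative log-likelihood is `||w||^2 / (2 sigma)`, so smaller sigma
#'   shrinks weights harder. Model 1 uses 1.0, Model 2 uses 4.0.
#' @param cutoff feature frequency threshold c: features with fewer than c
#'   total occurrences in the training data are excluded before
#'   optimization (0 disables; Model 2 uses 3).
#' @param max_iter,reltol L-BFGS stopping controls.
#' @param labels label inventory (IOB with a single CHEMICAL entity label).
#' @return A list of class `chem_crf_config`.
#' @export
crf_config <- function(order = 1L, sigma = 1.0, cutoff = 0L,
                       max_iter = 500L, reltol = 1e-6,
                       labels = chem_label_set) {
  chem_stopifnot(order %in% c(1L, 2L), "order must be 1 or 2")
  chem_stopifnot(sigma > 0, "sigma must be positive")
  chem_stopifnot(cutoff >= 0, "cutoff must be non-negative")
  structure(list(order = as.integer(order), sigma = sigma,
                 cutoff = as.integer(cutoff), max_iter = as.integer(max_iter),
                 reltol = reltol, labels = labels),
            class = "chem_crf_config")
}

# product-state bookkeeping for the order-2 composition
crf_states <- function(config) {
  labels <- config$labels
  if (config$order == 1L) {
    list(states = labels,
         trans_mask = matrix(TRUE, length(labels), length(labels)),
         init_mask = rep(TRUE, length(labels)),
         project = seq_along(labels))
  } else {
    grid <- expand.grid(b = labels, a = labels, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, c("a", "b")]
    states <- paste0(grid$a, ">", grid$b)
    nS <- length(states)
    trans_mask <- matrix(FALSE, nS, nS)
    for (i in seq_len(nS)) trans_mask[i, ] <- grid$a == grid$b[i]
    list(states = states, trans_mask = trans_mask,
         init_mask = grid$a == "O", # boundary context before the sequence
         project = match(grid$b, labels), grid = grid)
  }
}

labels_to_states <- function(y, config) {
  if (config$order == 1L) return(match(y, config$labels))
  prev <- c("O", y[-length(y)])
  match(paste0(prev, ">", y), crf_states(config)$states)
}

#' Encode mentions as IOB labels over a token sequence
#'
#' The token whose span starts a mention gets `B-CHEMICAL`, subsequent
#' tokens inside get `I-CHEMICAL`, all others `O`. A mention boundary that
#' falls strictly inside a token labels the whole token.
#'
#' @param tokens token tibble (columns `text`, `start`, `end`).
#' @param mentions mention rows for this sequence, offsets in the same
#'   coordinates as `tokens`. Overlapping mentions are an error.
#' @return Character vector of labels, one per token.
#' @export
iob_encode <- function(tokens, mentions) {
  labels <- rep("O", nrow(tokens))
  if (is.null(mentions) || nrow(mentions) == 0) return(labels)
  m <- mentions[order(mentions$start, mentions$end), ]
  if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)])) {
    abort("overlapping gold mentions in one sequence",
          class = "chemtagger_contract_error")
  }
  for (r in seq_len(nrow(m))) {
    hit <- which(tokens$start < m$end[r] & tokens$end > m$start[r])
    if (length(hit) == 0) next
    labels[hit[1]] <- "B-CHEMICAL"
    if (length(hit) > 1) labels[hit[-1]] <- "I-CHEMICAL"
  }
  labels
}

#' Decode IOB labels into mention spans
#'
#' Maximal `B (I)*` runs become mentions spanning from the first token's
#' start to the last token's end, with text sliced from `source_text`.
#' An `I` following `O` or at the sequence start is repaired by treating it
#' as `B` (with a warning unless `quiet`).
#'
#' @param tokens token tibble the labels refer to.
#' @param labels character vector of IOB labels.
#' @param source_text text the token offsets index into.
#' @param doc_id,section identifiers stamped onto the output rows.
#' @param quiet suppress the orphan-`I` repair warning.
#' @return A mention tibble.
#' @export
iob_decode <- function(tokens, labels, source_text, doc_id = "D1",
                       section = "A", quiet = FALSE) {
  n <- nrow(tokens)
  chem_stopifnot(length(labels) == n, "one label per token required")
  if (n == 0) return(empty_mentions())
  inside <- labels == "I-CHEMICAL"
  orphan <- inside & !c(FALSE, labels[-n] %in% c("B-CHEMICAL", "I-CHEMICAL"))
  if (any(orphan)) {
    if (!quiet) {
      warn(sprintf("repaired %d orphan I label(s) by treating them as B",
                   sum(orphan)))
    }
    labels[orphan] <- "B-CHEMICAL"
  }
  begins <- which(labels == "B-CHEMICAL")
  if (length(begins) == 0) return(empty_mentions())
  spans <- map(begins, function(b) {
    e <- b
    while (e + 1L <= n && labels[e + 1L] == "I-CHEMICAL") e <- e + 1L
    c(tokens$start[b], tokens$end[e])
  })
  tibble(
    doc_id = doc_id, section = section,
    start = map_int(spans, 1), end = map_int(spans, 2),
    text = str_slice(source_text, map_int(spans, 1), map_int(spans, 2)),
    subtype = NA_character_, probability = NA_real_
  )
}

#' Train a linear-chain CRF
#'
#' L2-regularized maximum likelihood via L-BFGS with analytic
#' forward-backward gradients. Features occurring fewer than
#' `config$cutoff` times across the training data are excluded before
#' optimization. Training is deterministic given the data order (weights
#' start at zero and the objective is convex), so repeated runs produce
#' bit-identical models.
#'
#' @param sequences list of training sequences; each element is a list with
#'   `features` (list of character vectors, one per token, from one of the
#'   extractors) and `labels` (character IOB labels, one per token).
#' @param config a [crf_config()].
#' @param seed integer recorded with the model (the optimization itself is
#'   deterministic).
#' @return An object of class `chem_crf`.
#' @export
crf_train <- function(sequences, config = crf_config(), seed = 1L) {
  chem_stopifnot(length(sequences) >= 1, "need at least one training sequence")
  feats_all <- unlist(lapply(sequences, function(s) unlist(s$features,
                                                           use.names = FALSE)),
                      use.names = FALSE)
  chem_stopifnot(length(feats_all) > 0, "training data has no features")
  counts <- table(feats_all)
  keep <- names(counts)[as.vector(counts) >= config$cutoff]
  features <- sort(keep, method = "radix")
  st <- crf_states(config)
  nS <- length(st$states)
  nF <- length(features)

  seq_feats <- lapply(sequences, function(s) {
    lapply(s$features, function(fv) {
      ids <- match(fv, features)
      ids[!is.na(ids)]
    })
  })
  seq_labels <- lapply(sequences, function(s) {
    ids <- labels_to_states(s$labels, config)
    chem_stopifnot(!anyNA(ids), "label outside the configured label set")
    ids
  })
  nonempty <- lengths(seq_feats) > 0
  seq_feats <- seq_feats[nonempty]
  seq_labels <- seq_labels[nonempty]
  chem_stopifnot(length(seq_feats) >= 1, "all training sequences are empty")

  nW <- nF * nS + nS * nS + nS
  cache <- new.env(parent = emptyenv())
  objective <- function(w) {
    if (!is.null(cache$w) && identical(w, cache$w)) return(cache$res)
    res <- crf_nll_grad_cpp(w, seq_feats, seq_labels, nF, nS,
                            st$trans_mask, st$init_mask, config$sigma)
    cache$w <- w
    cache$res <- res
    res
  }
  fit <- stats::optim(
    par = rep(0, nW),
    fn = function(w) objective(w)$nll,
    gr = function(w) objective(w)$grad,
    method = "L-BFGS-B",
    control = list(maxit = config$max_iter,
                   factr = config$reltol / .Machine$double.eps)
  )
  structure(list(
    weights = fit$par, features = features, config = config,
    states = st$states, nll = fit$value, counts = fit$counts,
    convergence = fit$convergence, seed = as.integer(seed)
  ), class = "chem_crf")
}

#' @export
print.chem_crf <- function(x, ...) {
  cat(sprintf("<chem_crf: order %d, sigma %g, cutoff %d; %d features, %d weights; nll %.4f>\n",
              x$config$order, x$config$sigma, x$config$cutoff,
              length(x$features), length(x$weights), x$nll))
  invisible(x)
}

model_feature_ids <- function(model, features) {
  lapply(features, function(fv) {
    ids <- match(fv, model$features)
    ids[!is.na(ids)]
  })
}

#' Viterbi decoding
#'
#' Returns the label sequence with the highest joint probability, along
#' with that (normalized) probability.
#'
#' @param model a trained [crf_train()] model.
#' @param features list of character vectors, one per token (same extractor
#'   as used in training; unseen features are ignored).
#' @return List with elements `labels` (character vector) and `probability`.
#' @export
crf_decode <- function(model, features) {
  if (length(features) == 0) return(list(labels = character(), probability = 1))
  st <- crf_states(model$config)
  ids <- model_feature_ids(model, features)
  out <- crf_viterbi_cpp(model$weights, ids, length(model$features),
                         length(st$states), st$trans_mask, st$init_mask)
  list(labels = model$config$labels[st$project[out$path]],
       probability = exp(out$logscore - out$logZ))
}

#' n-best decoding
#'
#' The `n` distinct label sequences of highest joint probability, in
#' descending order; exact score ties are broken lexicographically by label
#' sequence. The probabilities are normalized by the full partition
#' function, so they sum to at most 1.
#'
#' @inheritParams crf_decode
#' @param n number of sequences requested (fewer are returned when the
#'   state space is exhausted).
#' @return Tibble with a list-column `labels` and column `probability`.
#' @export
crf_nbest <- function(model, features, n = 20L) {
  chem_stopifnot(n >= 1, "n must be at least 1")
  if (length(features) == 0) {
    return(tibble(labels = list(character()), probability = 1))
  }
  st <- crf_states(model$config)
  ids <- model_feature_ids(model, features)
  out <- crf_nbest_cpp(model$weights, ids, as.integer(n),
                       length(model$features), length(st$states),
                       st$trans_mask, st$init_mask)
  tibble(
    labels = map(out$paths, function(p) model$config$labels[st$project[p]]),
    probability = exp(out$logscores - out$logZ)
  )
}

#' Save / load a trained CRF
#'
#' Models are stored as a self-describing JSON archive (configuration,
#' feature names, weights serialized at full precision) and reload
#' bit-identically.
#'
#' @param model a `chem_crf` object.
#' @param path file path.
#' @return `read_crf_model` returns the `chem_crf`; `write_crf_model`
#'   returns `model` invisibly.
#' @export
write_crf_model <- function(model, path) {
  payload <- list(
    format = "chemtagger-crf", version = 1L,
    config = unclass(model$config),
    features = model$features,
    weights = sprintf("%.17g", model$weights),
    states = model$states, nll = sprintf("%.17g", model$nll),
    convergence = model$convergence, seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = FALSE)
  invisible(model)
}

#' @rdname write_crf_model
#' @export
read_crf_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  chem_stopifnot(identical(payload$format, "chemtagger-crf"),
                 "not a chemtagger CRF model file")
  cfg <- payload$config
  config <- crf_config(order = cfg$order, sigma = cfg$sigma,
                       cutoff = cfg$cutoff, max_iter = cfg$max_iter,
                       reltol = cfg$reltol, labels = cfg$labels)
  structure(list(
    weights = as.numeric(payload$weights),
    features = as.character(payload$features),
    config = config, states = payload$states,
    nll = as.numeric(payload$nll),
    counts = NULL, convergence = payload$convergence,
    seed = payload$seed
  ), class = "chem_crf")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained CRF into a weight table
#'
#' @param x a `chem_crf`.
#' @param ... unused.
#' @return Tibble with columns `type` (`emission`, `transition`,
#'   `initial`), `term`, `state`, `weight`.
#' @method tidy chem_crf
#' @export
tidy.chem_crf <- function(x, ...) {
  nS <- length(x$states)
  nF <- length(x$features)
  w <- x$weights
  emission <- tibble(
    type = "emission",
    term = rep(x$features, each = nS),
    state = rep(x$states, times = nF),
    weight = w[seq_len(nF * nS)]
  )
  trans <- tibble(
    type = "transition",
    term = rep(x$states, each = nS),
    state = rep(x$states, times = nS),
    weight = w[nF * nS + seq_len(nS * nS)]
  )
  init <- tibble(type = "initial", term = "(start)", state = x$states,
                 weight = w[nF * nS + nS * nS + seq_len(nS)])
  bind_rows(emission, trans, init)
}

#' Model-level summary of a trained CRF
#'
#' @param x a `chem_crf`.
#' @param ... unused.
#' @return One-row tibble: order, sigma, cutoff, feature and weight counts,
#'   final penalized negative log-likelihood, convergence flag.
#' @method glance chem_crf
#' @export
glance.chem_crf <- function(x, ...) {
  tibble(order = x$config$order, sigma = x$config$sigma,
         cutoff = x$config$cutoff, n_features = length(x$features),
         n_weights = length(x$weights), nll = x$nll,
         converged = identical(x$convergence, 0L) || identical(x$convergence, 0))
}
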