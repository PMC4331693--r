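# End-to-end tagger objects: corpus -> sequences -> features -> CRF, and
# back from label sequences to standoff mentions, with the per-model
# preprocessing conventions (Model 1: sentence segmentation, no
# transliteration; Model 2: transliteration, whole-section sequences) and
# the per-model post-processing cascade.

model_default_config <- function(model) {
  switch(model,
         m1 = crf_config(order = 1L, sigma = 1.0, cutoff = 0L),
         m2 = crf_config(order = 2L, sigma = 4.0, cutoff = 3L))
}

# cut one section into decoding units: sentences for m1, whole section for m2
section_units <- function(text, model) {
  if (model == "m1") {
    spans <- segment_sentences(text)
    if (nrow(spans) == 0) return(tibble(start = integer(), end = integer()))
    spans
  } else {
    if (!nzchar(text)) return(tibble(start = integer(), end = integer()))
    tibble(start = 0L, end = str_length(text))
  }
}

unit_features <- function(unit_text, tokens, model, lexicons,
                          pos_tagger = NULL, external_tagger = NULL) {
  if (model == "m1") {
    extract_features_m1(tokens, unit_text, lexicons,
                        pos_tagger = pos_tagger,
                        external_tagger = external_tagger)
  } else {
    extract_features_m2(tokens, lexicons)
  }
}

# sequences: one row per decoding unit, with local-coordinate tokens and
# features; `unit_start` shifts local offsets back into section coordinates
prepare_sequences <- function(corpus, model, lexicons,
                              pos_tagger = NULL, external_tagger = NULL,
                              with_labels = TRUE) {
  docs <- corpus$documents
  mentions <- corpus$mentions
  out <- list()
  for (d in seq_len(nrow(docs))) {
    doc <- docs[d, ]
    for (sec in c("T", "A")) {
      src <- section_text(doc, sec)
      work <- if (model == "m2") translit_ascii(src) else src
      units <- section_units(work, model)
      for (u in seq_len(nrow(units))) {
        us <- units$start[u]; ue <- units$end[u]
        unit_text <- str_slice(work, us, ue)
        tokens <- if (model == "m1") tokenize_m1(unit_text)
                  else tokenize_m2(unit_text)
        if (nrow(tokens) == 0) next
        feats <- unit_features(unit_text, tokens, model, lexicons,
                               pos_tagger, external_tagger)
        labels <- NULL
        if (with_labels) {
          local_mentions <- mentions |>
            filter(.data$doc_id == doc$doc_id, .data$section == sec,
                   .data$start < ue, .data$end > us) |>
            mutate(start = .data$start - us, end = .data$end - us)
          labels <- iob_encode(tokens, local_mentions)
        }
        out[[length(out) + 1L]] <- list(
          doc_id = doc$doc_id, section = sec, unit_start = us,
          source_text = src, tokens = tokens, features = feats,
          labels = labels)
      }
    }
  }
  out
}

#' Train a chemical tagger
#'
#' Runs the model's preprocessing (Model 1: rule-based sentence
#' segmentation, no transliteration; Model 2: ASCII transliteration, one
#' sequence per section), extracts the model's feature set, and fits the
#' CRF with the model's default configuration (Model 1: order 1, sigma 1.0,
#' cutoff 0; Model 2: order 2, sigma 4.0, cutoff 3) unless overridden.
#'
#' @param corpus an annotated [chem_corpus()].
#' @param model `"m1"` or `"m2"`.
#' @param config optional [crf_config()] override.
#' @param lexicons a [chem_lexicons()].
#' @param pos_tagger,external_tagger optional pluggable adapters passed to
#'   [extract_features_m1()] (Model 1 only).
#' @param seed passed to [crf_train()].
#' @return An object of class `chem_tagger`.
#' @export
train_tagger <- function(corpus, model = c("m1", "m2"), config = NULL,
                         lexicons = chem_lexicons(),
                         pos_tagger = NULL, external_tagger = NULL,
                         seed = 1L) {
  model <- match.arg(model)
  config <- config %||% model_default_config(model)
  seqs <- prepare_sequences(corpus, model, lexicons, pos_tagger,
                            external_tagger, with_labels = TRUE)
  chem_stopifnot(length(seqs) > 0, "corpus yields no token sequences")
  crf <- crf_train(lapply(seqs, function(s) {
    list(features = s$features, labels = s$labels)
  }), config, seed = seed)
  structure(list(model = model, crf = crf, config = config,
                 pos_tagger = pos_tagger, external_tagger = external_tagger),
            class = "chem_tagger")
}

#' @export
print.chem_tagger <- function(x, ...) {
  cat(sprintf("<chem_tagger %s>\n", x$model))
  print(x$crf)
  invisible(x)
}

#' Tag a corpus with a trained tagger
#'
#' Decodes every sentence/section, converts label sequences to standoff
#' mentions in source coordinates, and (optionally) applies the model's
#' post-processing cascade. With `marginals = TRUE` (the Model 1 default)
#' each unit is decoded to its `n` best label sequences and every mention
#' carries the approximated marginal probability (sum of joint
#' probabilities of the sequences containing its exact span); otherwise
#' mentions carry the Viterbi sequence's joint probability and no
#' `marginal` column.
#'
#' @param tagger a [train_tagger()] result.
#' @param corpus corpus to tag (annotations, if present, are ignored).
#' @param lexicons a [chem_lexicons()].
#' @param marginals whether to decode n-best and attach marginals.
#' @param n n-best list size (default 20).
#' @param marginal_threshold mentions with marginal below this are dropped
#'   from the primary output (0.5 keeps roughly the Viterbi set; the
#'   high-recall combination uses 0.1). Ignored when `marginals = FALSE`.
#' @param postprocess apply the rule-based cascade.
#' @param identifier_patterns optional [compile_identifier_lexicon()] table.
#' @param identifier_probability probability for identifier matches.
#' @return Mention tibble (with a `marginal` column when
#'   `marginals = TRUE`).
#' @export
tag_corpus <- function(tagger, corpus, lexicons = chem_lexicons(),
                       marginals = tagger$model == "m1", n = 20L,
                       marginal_threshold = 0.5,
                       postprocess = TRUE, identifier_patterns = NULL,
                       identifier_probability = 0.9) {
  seqs <- prepare_sequences(corpus, tagger$model, lexicons,
                            tagger$pos_tagger, tagger$external_tagger,
                            with_labels = FALSE)
  mention_sets <- map(seqs, function(s) {
    if (marginals) {
      nb <- crf_nbest(tagger$crf, s$features, n = n)
      m <- mention_marginals(nb, s$tokens,
                             str_slice(s$source_text, s$unit_start,
                                       str_length(s$source_text)),
                             s$doc_id, s$section)
      m <- m[m$marginal >= marginal_threshold, ]
    } else {
      dec <- crf_decode(tagger$crf, s$features)
      m <- iob_decode(s$tokens, dec$labels,
                      str_slice(s$source_text, s$unit_start,
                                str_length(s$source_text)),
                      s$doc_id, s$section, quiet = TRUE)
      if (nrow(m) > 0) m$probability <- dec$probability
    }
    if (nrow(m) > 0) {
      m$start <- m$start + s$unit_start
      m$end <- m$end + s$unit_start
      # re-slice from the untransliterated source (same offsets)
      m$text <- str_slice(s$source_text, m$start, m$end)
    }
    m
  })
  mention_sets <- mention_sets[vapply(mention_sets, nrow, integer(1)) > 0]
  out <- if (length(mention_sets) == 0) empty_mentions()
         else bind_rows(mention_sets)
  if (marginals && !"marginal" %in% names(out)) out$marginal <- double()
  if (postprocess && nrow(out) >= 0) {
    docs <- corpus$documents
    per_doc <- map(seq_len(nrow(docs)), function(d) {
      doc <- docs[d, ]
      m <- out[out$doc_id == doc$doc_id, ]
      marg <- if (marginals && nrow(m) > 0) {
        m[, c("doc_id", "section", "start", "end", "marginal")]
      } else NULL
      res <- postprocess_mentions(
        m[, setdiff(names(m), "marginal")], doc,
        mode = toupper(tagger$model),
        identifier_patterns = identifier_patterns,
        lexicons = lexicons,
        identifier_probability = identifier_probability)
      if (!is.null(marg)) {
        res <- left_join(res, marg,
                         by = c("doc_id", "section", "start", "end"))
      }
      res
    })
    out <- bind_rows(per_doc)
  }
  arrange(out, .data$doc_id, .data$section, .data$start, .data$end)
}

#' n-best mention marginals for a whole corpus
#'
#' Convenience wrapper used by the high-recall combination: tags every
#' sequence with [crf_nbest()] and returns the union of decoded mentions
#' with their marginals, in source coordinates, without any filtering or
#' post-processing.
#'
#' @inheritParams tag_corpus
#' @return Mention tibble with a `marginal` column.
#' @export
corpus_mention_marginals <- function(tagger, corpus,
                                     lexicons = chem_lexicons(), n = 20L) {
  tag_corpus(tagger, corpus, lexicons, marginals = TRUE, n = n,
             marginal_threshold = 0, postprocess = FALSE)
}

#' Joint sweep of regularization and feature cutoff
#'
#' Trains one tagger per (sigma, cutoff) grid cell and evaluates
#' mention-level exact F on the evaluation corpus: the default grids
#' produce the 16-cell experiment over sigma in \{0.5, 1, 2, 4\} and c in
#' \{0, 1, 3, 5\}.
#'
#' @param train_corpus,eval_corpus annotated corpora.
#' @param model `"m1"` or `"m2"`.
#' @param sigma_grid,cutoff_grid numeric grids.
#' @param lexicons a [chem_lexicons()].
#' @param max_iter optimizer iteration cap for the sweep.
#' @param seed training seed.
#' @return Tibble with one row per cell: `sigma`, `cutoff`, `tp`, `fp`,
#'   `fn`, `p`, `r`, `f`.
#' @export
crf_sweep <- function(train_corpus, eval_corpus, model = "m1",
                      sigma_grid = c(0.5, 1, 2, 4),
                      cutoff_grid = c(0L, 1L, 3L, 5L),
                      lexicons = chem_lexicons(), max_iter = 100L,
                      seed = 1L) {
  base <- model_default_config(model)
  grid <- tidyr::expand_grid(sigma = sigma_grid, cutoff = cutoff_grid)
  rows <- pmap(grid, function(sigma, cutoff) {
    cfg <- crf_config(order = base$order, sigma = sigma,
                      cutoff = as.integer(cutoff), max_iter = max_iter,
                      reltol = base$reltol)
    tagger <- train_tagger(train_corpus, model, config = cfg,
                           lexicons = lexicons, seed = seed)
    pred <- tag_corpus(tagger, eval_corpus, lexicons,
                       marginals = FALSE, postprocess = FALSE)
    scores <- evaluate_cem(eval_corpus$mentions, pred, mode = "exact")
    bind_cols(tibble(sigma = sigma, cutoff = as.integer(cutoff)),
              as_tibble(scores))
  })
  bind_rows(rows)
}
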