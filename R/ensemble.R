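# Mention-marginal approximation from n-best lists, the three model
# combination strategies, and document-level (CDI) probabilities via a
# noisy-or over per-occurrence marginals.

#' Approximate mention marginals from an n-best list
#'
#' The mention set is the union of [iob_decode()] over the n decoded label
#' sequences; each mention's marginal is the sum of the joint probabilities
#' of the sequences in which exactly that span appears. With n at least as
#' large as the number of possible labelings this equals the exact marginal.
#'
#' @param nbest tibble from [crf_nbest()] (`labels` list-column,
#'   `probability`).
#' @param tokens token tibble the labels refer to.
#' @param source_text section (or sentence) text for slicing mention text.
#' @param doc_id,section identifiers stamped onto the mentions.
#' @return Mention tibble with a `marginal` column.
#' @export
mention_marginals <- function(nbest, tokens, source_text, doc_id = "D1",
                              section = "A") {
  per_seq <- map2(nbest$labels, nbest$probability, function(lab, p) {
    m <- iob_decode(tokens, lab, source_text, doc_id, section, quiet = TRUE)
    if (nrow(m) == 0) return(NULL)
    m$seq_probability <- p
    m
  })
  per_seq <- per_seq[!vapply(per_seq, is.null, logical(1))]
  if (length(per_seq) == 0) {
    out <- empty_mentions()
    out$marginal <- double()
    return(out)
  }
  bind_rows(per_seq) |>
    group_by(.data$doc_id, .data$section, .data$start, .data$end,
             .data$text) |>
    summarise(marginal = sum(.data$seq_probability), .groups = "drop") |>
    mutate(subtype = NA_character_, probability = .data$marginal) |>
    select("doc_id", "section", "start", "end", "text", "subtype",
           "probability", "marginal") |>
    arrange(.data$section, .data$start, .data$end)
}

#' Noisy-or combination of probabilities
#'
#' `1 - prod(1 - p)`: the probability that at least one of several
#' independent events occurs. The empty vector gives 0; any entry equal to
#' 1 gives 1. Monotone non-decreasing in every argument and under list
#' extension.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return A single probability.
#' @export
noisy_or <- function(p) {
  chem_stopifnot(all(p >= 0 & p <= 1), "noisy_or inputs must lie in [0, 1]")
  1 - prod(1 - p)
}

#' Naive combination: pool the two models' mentions
#'
#' Set union by span; duplicate spans keep the maximum probability;
#' overlapping non-identical spans are both kept (mention-level scoring is
#' exact-span).
#'
#' @param m1,m2 mention tibbles.
#' @return Combined mention tibble.
#' @export
combine_naive <- function(m1, m2) {
  dedup_spans(bind_rows(as_mentions(m1), as_mentions(m2)))
}

# duplicate spans keep max probability (NA treated as lowest)
dedup_spans <- function(m) {
  if (nrow(m) == 0) return(m)
  m |>
    group_by(.data$doc_id, .data$section, .data$start, .data$end) |>
    arrange(desc(ifelse(is.na(.data$probability), -Inf, .data$probability)),
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$doc_id, .data$section, .data$start, .data$end)
}

#' Heuristic combination: swap the mid-length band to Model 2
#'
#' Model 1 mentions whose text length is 5 to 15 characters (inclusive)
#' are dropped and replaced by the Model 2 mentions in that length band;
#' Model 1 mentions outside the band are kept.
#'
#' @param m1,m2 mention tibbles.
#' @return Combined mention tibble.
#' @export
combine_heuristic <- function(m1, m2) {
  m1 <- as_mentions(m1); m2 <- as_mentions(m2)
  len1 <- str_length(m1$text); len2 <- str_length(m2$text)
  dedup_spans(bind_rows(m1[len1 < 5 | len1 > 15, ],
                        m2[len2 >= 5 & len2 <= 15, ]))
}

#' High-recall combination
#'
#' The union of Model 2's mentions with every Model 1 n-best mention whose
#' approximated marginal is at least `threshold` (inclusive). The result is
#' a superset of Model 2's output, so its recall can only be higher.
#'
#' @param m1_marginals tibble from [mention_marginals()].
#' @param m2 Model 2 mention tibble.
#' @param threshold minimum marginal probability, 0.1 by default.
#' @return Combined mention tibble.
#' @export
combine_high_recall <- function(m1_marginals, m2, threshold = 0.1) {
  keep <- as_mentions(m1_marginals[m1_marginals$marginal >= threshold,
                                   setdiff(names(m1_marginals), "marginal")])
  dedup_spans(bind_rows(as_mentions(m2), keep))
}

#' Convert mention-level output to document-level (CDI) terms
#'
#' Groups mentions by (document, text); the abstract-level probability of a
#' text is the noisy-or of its occurrences' marginals. Occurrences without
#' a marginal (Model 2 or rule-added mentions) contribute a small fixed
#' probability instead. Output is sorted by descending probability within
#' each document.
#'
#' @param mentions mention tibble; a `marginal` column is used when
#'   present, otherwise `probability`.
#' @param fixed_probability per-occurrence probability used where no
#'   marginal is available (default 0.1).
#' @return Tibble with columns `doc_id`, `text`, `probability`.
#' @export
cem_to_cdi <- function(mentions, fixed_probability = 0.1) {
  m <- as_tibble(mentions)
  if (nrow(m) == 0) {
    return(tibble(doc_id = character(), text = character(),
                  probability = double()))
  }
  pm <- if ("marginal" %in% names(m)) m$marginal else m$probability
  pm <- ifelse(is.na(pm), fixed_probability, pm)
  m |>
    mutate(.pm = pm) |>
    group_by(.data$doc_id, .data$text) |>
    summarise(probability = noisy_or(.data$.pm), .groups = "drop") |>
    group_by(.data$doc_id) |>
    arrange(desc(.data$probability), .data$text, .by_group = TRUE) |>
    ungroup()
}
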