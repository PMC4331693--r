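# Mention-level (CEM) and document-level (CDI) precision / recall / F,
# micro-averaged over documents, with exact or overlap span matching and
# per-subtype recall.

score_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble(tp = tp, fp = fp, fn = fn, p = p, r = r, f = f)
}

#' Evaluate mention-level (CEM) predictions
#'
#' Exact mode matches on (document, section, start, end). Overlap mode
#' performs greedy one-to-one matching of overlapping same-document-section
#' spans: gold mentions are processed in document order and each takes its
#' leftmost overlapping unmatched prediction. Counts are micro-averaged
#' over all documents. `p = tp/(tp+fp)`, `r = tp/(tp+fn)`,
#' `f = 2pr/(p+r)` (0 where undefined).
#'
#' @param gold,pred mention tibbles.
#' @param mode `"exact"` or `"overlap"`.
#' @return One-row tibble of class `chem_eval`: `tp`, `fp`, `fn`, `p`,
#'   `r`, `f`.
#' @export
evaluate_cem <- function(gold, pred, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  gold <- as_mentions(gold)
  pred <- as_mentions(pred)
  if (mode == "exact") {
    key <- function(m) paste(m$doc_id, m$section, m$start, m$end, sep = "\r")
    gk <- key(gold); pk <- key(pred)
    tp <- sum(pk %in% gk)
    counts <- score_from_counts(tp, nrow(pred) - tp, nrow(gold) - sum(gk %in% pk))
  } else {
    gold <- arrange(gold, .data$doc_id, .data$section, .data$start, .data$end)
    matched_pred <- rep(FALSE, nrow(pred))
    tp <- 0L
    for (i in seq_len(nrow(gold))) {
      cand <- which(!matched_pred &
                      pred$doc_id == gold$doc_id[i] &
                      pred$section == gold$section[i] &
                      pred$start < gold$end[i] & pred$end > gold$start[i])
      if (length(cand) == 0) next
      pick <- cand[order(pred$start[cand], pred$end[cand])][1]
      matched_pred[pick] <- TRUE
      tp <- tp + 1L
    }
    counts <- score_from_counts(tp, nrow(pred) - tp, nrow(gold) - tp)
  }
  structure(counts, class = c("chem_eval", class(counts)))
}

#' Evaluate document-level (CDI) predictions
#'
#' A true positive is a case-sensitive exact text match within a document.
#' Gold text sets are the distinct mention texts per document. Duplicate
#' predicted texts within a document are a contract error.
#'
#' @param gold mention tibble (gold standard).
#' @param pred tibble with `doc_id`, `text` (e.g. from [cem_to_cdi()]).
#' @return One-row `chem_eval` tibble.
#' @export
evaluate_cdi <- function(gold, pred) {
  gold_terms <- as_mentions(gold) |> distinct(.data$doc_id, .data$text)
  pred <- as_tibble(pred)
  dup <- pred |> count(.data$doc_id, .data$text) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate predicted CDI text %s in document %s",
                  dQuote(dup$text[1], q = FALSE), dup$doc_id[1]),
          class = "chemtagger_contract_error")
  }
  gk <- paste(gold_terms$doc_id, gold_terms$text, sep = "\r")
  pk <- paste(pred$doc_id, pred$text, sep = "\r")
  tp <- sum(pk %in% gk)
  counts <- score_from_counts(tp, nrow(pred) - tp, nrow(gold_terms) - tp)
  structure(counts, class = c("chem_eval", class(counts)))
}

#' Recall per gold annotation subtype
#'
#' For each subtype present in the gold standard, the fraction of its gold
#' mentions exactly matched by a prediction. Subtypes with zero gold
#' mentions are omitted.
#'
#' @param gold mention tibble with a `subtype` column.
#' @param pred mention tibble.
#' @return Tibble with columns `subtype`, `n_gold`, `n_matched`, `recall`.
#' @export
recall_by_subtype <- function(gold, pred) {
  gold <- as_mentions(gold)
  pred <- as_mentions(pred)
  pk <- paste(pred$doc_id, pred$section, pred$start, pred$end, sep = "\r")
  gold |>
    mutate(matched = paste(.data$doc_id, .data$section, .data$start,
                           .data$end, sep = "\r") %in% pk,
           subtype = ifelse(is.na(.data$subtype), "NONE", .data$subtype)) |>
    group_by(.data$subtype) |>
    summarise(n_gold = n(), n_matched = sum(.data$matched),
              recall = .data$n_matched / .data$n_gold, .groups = "drop") |>
    arrange(.data$subtype)
}

#' @export
print.chem_eval <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d  p=%.4f r=%.4f f=%.4f\n",
              x$tp, x$fp, x$fn, x$p, x$r, x$f))
  invisible(x)
}

#' Plot precision / recall / F of one or more evaluations
#'
#' @param object a `chem_eval` row or a tibble of several (e.g. bound
#'   together with a `setup` column naming each run).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot chem_eval
#' @export
autoplot.chem_eval <- function(object, ...) {
  df <- as_tibble(object)
  if (!"setup" %in% names(df)) df$setup <- "run"
  long <- tidyr::pivot_longer(df, c("p", "r", "f"), names_to = "metric",
                              values_to = "value")
  long$metric <- factor(long$metric, levels = c("p", "r", "f"),
                        labels = c("precision", "recall", "f-measure"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$setup, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write an evaluation report as TSV
#'
#' Overall counts/scores and, when gold subtypes are available, per-subtype
#' recall appended as additional rows.
#'
#' @param eval a `chem_eval` row.
#' @param path output path.
#' @param by_subtype optional tibble from [recall_by_subtype()].
#' @return `eval`, invisibly.
#' @export
write_eval_report <- function(eval, path, by_subtype = NULL) {
  lines <- c(
    paste(c("metric", "value"), collapse = "\t"),
    paste("tp", eval$tp, sep = "\t"), paste("fp", eval$fp, sep = "\t"),
    paste("fn", eval$fn, sep = "\t"),
    paste("precision", format_prob(eval$p), sep = "\t"),
    paste("recall", format_prob(eval$r), sep = "\t"),
    paste("f", format_prob(eval$f), sep = "\t")
  )
  if (!is.null(by_subtype)) {
    lines <- c(lines, paste0("recall_", by_subtype$subtype, "\t",
                             format_prob(by_subtype$recall)))
  }
  writeLines(lines, path)
  invisible(eval)
}
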