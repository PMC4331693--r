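# Deterministic synthetic-corpus generator. Documents are filler-word
# sentences with injected chemical-like phrases built from per-subtype
# grammars over the bundled lexicons; every injected span is recorded as a
# gold mention with exact offsets. The generator runs on an isolated RNG
# stream seeded from its config, so a fixed seed yields a byte-identical
# corpus.

#' Generator configuration
#'
#' @param n_documents number of abstracts to generate.
#' @param mean_sentences mean number of abstract sentences per document
#'   (Poisson, floored at 1).
#' @param chemical_density per-sentence probability weight of chemical
#'   injection (each sentence draws Binomial(2, density) chemical phrases;
#'   0 yields an unannotated corpus).
#' @param subtype_mix named probability vector over the seven subtypes;
#'   must sum to 1.
#' @param repeat_prob probability that an injected chemical repeats an
#'   earlier mention text of the same document (makes consistency and
#'   document-indexing behavior exercisable).
#' @param seed integer seed of the generator's private RNG stream.
#' @return A list of class `chem_gen_config`.
#' @export
corpus_config <- function(n_documents = 50L,
                          mean_sentences = 3,
                          chemical_density = 0.5,
                          subtype_mix = c(SYSTEMATIC = 0.25, FORMULA = 0.15,
                                          TRIVIAL = 0.25, ABBREVIATION = 0.10,
                                          IDENTIFIER = 0.10, FAMILY = 0.10,
                                          MULTIPLE = 0.05),
                          repeat_prob = 0.3,
                          seed = 1L) {
  chem_stopifnot(abs(sum(subtype_mix) - 1) < 1e-8,
                 "subtype_mix probabilities must sum to 1")
  chem_stopifnot(chemical_density >= 0 && chemical_density <= 1,
                 "chemical_density must lie in [0, 1]")
  structure(list(n_documents = as.integer(n_documents),
                 mean_sentences = mean_sentences,
                 chemical_density = chemical_density,
                 subtype_mix = subtype_mix,
                 repeat_prob = repeat_prob,
                 seed = as.integer(seed)),
            class = "chem_gen_config")
}

# run code under a private RNG stream, restoring the caller's stream
with_gen_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

the_fillers <- new.env(parent = emptyenv())

filler_words <- function() {
  if (is.null(the_fillers$words)) {
    the_fillers$words <- read_utf8_lines(extdata_path("filler_words.txt"))
  }
  the_fillers$words
}

gen_fillers <- function(n) sample(filler_words(), n, replace = TRUE)

# ---- subtype grammars -------------------------------------------------
# each returns list(text, anns = tibble(rel_start, rel_end, subtype))
# with offsets relative to the produced segment text

ann1 <- function(text, subtype) {
  list(text = text,
       anns = tibble(rel_start = 0L, rel_end = str_length(text),
                     subtype = subtype))
}

gen_systematic <- function(lex) {
  locant <- if (stats::runif(1) < 0.5) paste0(sample(2:9, 1), "-") else ""
  n_units <- sample(1:2, 1)
  units <- vapply(seq_len(n_units), function(i) {
    paste0(sample(lex$simple_multipliers[1:6], 1), "-",
           sample(lex$alkane_stems[1:8], 1), "-yl")
  }, character(1))
  core <- paste0(sample(lex$alkane_stems[1:8], 1),
                 sample(c("-one", "-ol", "-ate", "-ene"), 1))
  body <- if (stats::runif(1) < 0.4) {
    paste0("(", paste(units, collapse = "-"), ")-", core)
  } else {
    paste0(paste(units, collapse = "-"), "-", core)
  }
  ann1(paste0(locant, body), "SYSTEMATIC")
}

gen_formula <- function(lex) {
  n_pairs <- sample(2:4, 1)
  sym <- sample(c("C", "H", "O", "N", "Na", "Cl", "Cu", "Fe", "S", "P"),
                n_pairs, replace = TRUE)
  cnt <- sample(c("", as.character(2:12)), n_pairs, replace = TRUE)
  ann1(paste0(paste0(sym, cnt), collapse = ""), "FORMULA")
}

gen_trivial <- function(lex) {
  ann1(sample(lex$trivial_rings, 1), "TRIVIAL")
}

gen_family <- function(lex) {
  ann1(paste0(sample(lex$trivial_rings, 1), "s"), "FAMILY")
}

gen_identifier <- function(lex) {
  letters_part <- paste0(sample(LETTERS, sample(2:5, 1), replace = TRUE),
                         collapse = "")
  digits_part <- paste0(sample(0:9, sample(2:6, 1), replace = TRUE),
                        collapse = "")
  sep <- sample(c("-", "", " ", "_"), 1, prob = c(0.5, 0.3, 0.1, 0.1))
  ann1(paste0(letters_part, sep, digits_part), "IDENTIFIER")
}

gen_multiple <- function(lex) {
  k <- sample(2:3, 1)
  stems <- sample(lex$alkane_stems[1:8], k)
  text <- paste0(paste(paste0(stems, "-yl"), collapse = ", "), " ",
                 sample(c("acids", "esters"), 1))
  # coordination annotated as one mention over the whole span
  ann1(text, "MULTIPLE")
}

# abbreviation definition "long form (SF)": two mentions in one segment
gen_abbreviation <- function(lex) {
  lf <- sample(lex$trivial_rings, 1)
  sf <- toupper(paste0(substr(lf, 1, 1),
                       substr(lf, sample(2:4, 1), sample(2:4, 1) + 1)))
  sf <- substr(sf, 1, 3)
  text <- paste0(lf, " (", sf, ")")
  list(text = text,
       anns = tibble(
         rel_start = c(0L, str_length(lf) + 2L),
         rel_end = c(str_length(lf), str_length(lf) + 2L + str_length(sf)),
         subtype = c("TRIVIAL", "ABBREVIATION")),
       short_form = sf)
}

gen_chemical <- function(subtype, lex) {
  switch(subtype,
         SYSTEMATIC = gen_systematic(lex),
         FORMULA = gen_formula(lex),
         TRIVIAL = gen_trivial(lex),
         ABBREVIATION = gen_abbreviation(lex),
         IDENTIFIER = gen_identifier(lex),
         FAMILY = gen_family(lex),
         MULTIPLE = gen_multiple(lex))
}

# assemble segments (each with relative annotations) into one text,
# converting annotation offsets to absolute
assemble_segments <- function(segments, sep = " ") {
  text <- ""
  anns <- list()
  offset <- 0L
  for (seg in segments) {
    if (offset > 0L) {
      text <- paste0(text, sep)
      offset <- offset + str_length(sep)
    }
    text <- paste0(text, seg$text)
    if (!is.null(seg$anns) && nrow(seg$anns) > 0) {
      a <- seg$anns
      anns[[length(anns) + 1L]] <- tibble(
        start = offset + a$rel_start, end = offset + a$rel_end,
        subtype = a$subtype)
    }
    offset <- offset + str_length(seg$text)
  }
  list(text = text, anns = if (length(anns) > 0) bind_rows(anns)
       else tibble(start = integer(), end = integer(), subtype = character()))
}

gen_sentence <- function(config, lex, doc_state) {
  n_fill <- sample(5:9, 1)
  fillers <- gen_fillers(n_fill)
  n_chem <- stats::rbinom(1, 2, config$chemical_density)
  segments <- lapply(fillers, function(w) list(text = w, anns = NULL))
  if (n_chem > 0) {
    for (k in seq_len(n_chem)) {
      reuse <- length(doc_state$texts) > 0 &&
        stats::runif(1) < config$repeat_prob
      if (reuse) {
        i <- sample(length(doc_state$texts), 1)
        seg <- ann1(doc_state$texts[[i]], doc_state$subtypes[[i]])
      } else {
        subtype <- sample(names(config$subtype_mix), 1,
                          prob = config$subtype_mix)
        seg <- gen_chemical(subtype, lex)
        reusable <- if (!is.null(seg$short_form)) seg$short_form else {
          if (nrow(seg$anns) == 1) seg$text else NA_character_
        }
        reuse_subtype <- if (!is.null(seg$short_form)) "ABBREVIATION" else
          seg$anns$subtype[1]
        if (!is.na(reusable)) {
          doc_state$texts[[length(doc_state$texts) + 1L]] <- reusable
          doc_state$subtypes[[length(doc_state$subtypes) + 1L]] <- reuse_subtype
        }
      }
      pos <- sample(seq_len(length(segments) + 1L), 1)
      segments <- append(segments, list(seg), after = pos - 1L)
    }
  }
  seg <- assemble_segments(segments)
  seg$text <- paste0(seg$text, ".")
  seg
}

#' Generate a synthetic annotated corpus
#'
#' Produces `n_documents` abstracts of filler-word sentences with injected
#' chemical-like mentions drawn from per-subtype grammars (systematic
#' multiplier-stem-suffix chains with locants, element-symbol formulas,
#' trivial ring names, abbreviation definitions of the form
#' `long form (SF)`, letters+digits identifiers, pluralized families, and
#' coordinated lists). Every injected span is recorded as a gold mention
#' with exact offsets and subtype; the output satisfies all corpus
#' invariants by construction.
#'
#' @param config a [corpus_config()].
#' @return A [chem_corpus()].
#' @export
generate_corpus <- function(config = corpus_config()) {
  lex <- chem_lexicons()
  with_gen_rng(config$seed, {
    docs <- list()
    anns <- list()
    for (d in seq_len(config$n_documents)) {
      doc_id <- sprintf("D%05d", d)
      doc_state <- new.env(parent = emptyenv())
      doc_state$texts <- list()
      doc_state$subtypes <- list()
      title_seg <- gen_sentence(config, lex, doc_state)
      n_sent <- max(1L, stats::rpois(1, config$mean_sentences))
      sent <- lapply(seq_len(n_sent), function(i) {
        gen_sentence(config, lex, doc_state)
      })
      abstract <- ""
      abs_anns <- list()
      off <- 0L
      for (s in sent) {
        if (off > 0L) { abstract <- paste0(abstract, " "); off <- off + 1L }
        abstract <- paste0(abstract, s$text)
        if (nrow(s$anns) > 0) {
          a <- s$anns
          a$start <- a$start + off
          a$end <- a$end + off
          abs_anns[[length(abs_anns) + 1L]] <- a
        }
        off <- off + str_length(s$text)
      }
      docs[[d]] <- tibble(doc_id = doc_id, title = title_seg$text,
                          abstract = abstract)
      doc_ann <- list()
      if (nrow(title_seg$anns) > 0) {
        a <- title_seg$anns
        doc_ann[[length(doc_ann) + 1L]] <-
          tibble(doc_id = doc_id, section = "T", start = a$start,
                 end = a$end, subtype = a$subtype)
      }
      if (length(abs_anns) > 0) {
        a <- bind_rows(abs_anns)
        doc_ann[[length(doc_ann) + 1L]] <-
          tibble(doc_id = doc_id, section = "A", start = a$start,
                 end = a$end, subtype = a$subtype)
      }
      if (length(doc_ann) > 0) anns[[length(anns) + 1L]] <- bind_rows(doc_ann)
    }
    documents <- bind_rows(docs)
    mentions <- if (length(anns) > 0) bind_rows(anns) else NULL
    if (!is.null(mentions) && nrow(mentions) > 0) {
      idx <- match(mentions$doc_id, documents$doc_id)
      src <- ifelse(mentions$section == "T", documents$title[idx],
                    documents$abstract[idx])
      mentions$text <- str_slice(src, mentions$start, mentions$end)
      mentions$probability <- NA_real_
      # identical repeated spans can arise from reuse; keep one
      mentions <- distinct(mentions, .data$doc_id, .data$section,
                           .data$start, .data$end, .keep_all = TRUE)
      chem_corpus(documents, mentions)
    } else {
      chem_corpus(documents)
    }
  })
}

#' Write the toy lexicon files
#'
#' Emits, under `dir`: the element table (118 real symbols/names), the 20
#' amino acids, the semantic affix lists, a 50-entry normalization lexicon
#' pair (`primary_vocab.tsv` with MeSH-style identifiers covering the
#' trivial ring names and common generated chemicals, and
#' `secondary_vocab.tsv` with ChEBI-style identifiers, partially
#' overlapping), and an identifier name list (including `NSC-114792`)
#' whose entries all match the letters\{2,5\}+digits\{2,\} shape.
#'
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
generate_toy_lexicons <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lex <- chem_lexicons()
  paths <- c(
    elements = file.path(dir, "elements.tsv"),
    amino_acids = file.path(dir, "amino_acids.tsv"),
    affixes = file.path(dir, "semantic_affixes.tsv"),
    primary = file.path(dir, "primary_vocab.tsv"),
    secondary = file.path(dir, "secondary_vocab.tsv"),
    identifiers = file.path(dir, "identifier_names.txt")
  )
  file.copy(extdata_path("elements.tsv"), paths[["elements"]],
            overwrite = TRUE)
  file.copy(extdata_path("amino_acids.tsv"), paths[["amino_acids"]],
            overwrite = TRUE)
  file.copy(extdata_path("semantic_affixes.tsv"), paths[["affixes"]],
            overwrite = TRUE)
  rings <- lex$trivial_rings
  families <- paste0(rings, "s")
  extras <- c("aspirin", "caffeine", "glucose", "ethanol", "acetone",
              "ibuprofen", "paracetamol", "flavone-C-glycoside", "water")
  primary_names <- c(rings, families, extras)[1:50]
  primary <- paste0(primary_names, "\t",
                    sprintf("MESH:D%06d", seq_along(primary_names)))
  writeLines(primary, paths[["primary"]])
  secondary_names <- c(rings[1:10], extras)
  secondary <- paste0(secondary_names, "\t",
                      sprintf("CHEBI:%05d", seq_along(secondary_names)))
  writeLines(secondary, paths[["secondary"]])
  id_names <- c("NSC-114792",
                paste0("NSC-", 100000 + 7 * seq_len(20)),
                paste0("CHEM", 10 + 3 * seq_len(20)),
                paste0("AB-", 1000 + 11 * seq_len(9)))
  writeLines(id_names, paths[["identifiers"]])
  invisible(paths)
}
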