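---
title: "Methods: a CRF ensemble for chemical named-entity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a CRF ensemble for chemical named-entity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtagger)
```

## The task

Chemical mentions in titles and abstracts of scientific articles are
annotated as character spans, optionally carrying one of seven subtypes
(SYSTEMATIC, FORMULA, TRIVIAL, ABBREVIATION, IDENTIFIER, FAMILY, MULTIPLE).
Two evaluation views are supported: the mention level (CEM — predict exact
spans) and the document level (CDI — predict the set of distinct chemical
texts per abstract, ranked by confidence). All offsets in the package are
0-based, half-open, counted in Unicode code points within the title or
abstract separately; every mention object must satisfy the *slice
invariant* — its text equals the substring of the section at its offsets —
and this is checked at every I/O boundary.

## Two deliberately different taggers

The package trains two linear-chain conditional random field (CRF) taggers
whose preprocessing and feature sets were designed independently, because
an ensemble only helps when its members err differently.

**Model 1** segments each section into sentences with a deterministic
rule-based splitter (a sentence ends after `.`, `!` or `?` followed by
whitespace and an uppercase letter or digit, except for periods between
digits or after a single uppercase initial), does *not* transliterate, and
tokenizes by splitting at whitespace, isolating punctuation characters,
breaking between letters and digits in both directions and between a
lowercase letter and a following uppercase letter (`FCH2CH2N3` becomes
`FCH / 2 / CH / 2 / N / 3`). Its features are token identity, lemma,
word shape (`Cu(2+` has shape `Aax0x`), capitalization class, Roman-numeral
and Greek-letter flags, character 2–4-grams, element symbol and name
flags, three amino-acid flags, a whole-token chemical-formula flag (can the
token be segmented entirely into case-sensitive element symbols?), a
cross-token amino-acid-sequence flag (`Phe-Cys-Tyr`), and optional
part-of-speech and external-recognizer flags behind pluggable adapters
that default to absent. Context copies span ±2 tokens. The CRF is order 1
with Gaussian prior variance σ = 1.0 and no feature cutoff.

**Model 2** transliterates non-ASCII characters to ASCII through a bundled
single-character table (so transliterated offsets are identical to source
offsets), treats each whole section as one sequence, and tokenizes into
maximal single-class runs — uppercase, lowercase, digits — plus isolated
punctuation (`NaCl` becomes `N / a / C / l`). Its features are token
identity, Porter stem, prefixes and suffixes of length 1–5, binned
character counts (total/digits/uppercase/lowercase, binned 0–3 and 4+),
Roman/Greek flags, semantic affix flags (chemical suffixes anchored at the
token end, alkane stems and simple multipliers at the token start, trivial
ring names as whole tokens), an element-name flag, and full plus run-length
merged case patterns (`CD40` gives `AA00` and `A0`). Context copies span
±3 tokens. The CRF is order 2 with σ = 4.0 and feature cutoff c = 3.

Where the feature-length range for affixes is quoted differently in
different accounts (1–5 versus 2–5), the package exposes `lmin`/`lmax`
arguments and defaults to 1–5.

## The CRF engine

The engine is a generic order-1 linear-chain CRF over masked state
spaces, written in C++ (forward–backward with log-sum-exp, analytic
gradients) and trained with L-BFGS from a zero initialization. Because the
penalized likelihood is convex and the feature dictionary is sorted
deterministically, training is reproducible bit-for-bit.

* **Regularization.** The penalty is `‖w‖² / (2σ)` with σ the Gaussian
  prior variance, so σ = 1.0 and σ = 4.0 are directly comparable knobs;
  translate to a plain L2 coefficient as `λ = 1/σ`.
* **Feature cutoff.** `c` counts *total occurrences* of a feature string in
  the training data; features with fewer than `c` occurrences are removed
  before optimization. A cutoff above every count leaves a model with only
  transition and initial weights, which decodes everything as outside.
* **Order 2.** Realized by composing adjacent label pairs into product
  states ((prev, cur) over the three IOB labels, nine states), masking
  transitions to those with matching middle label and initial states to
  those with an outside left context, then projecting decoded product
  sequences back to plain labels. This keeps one engine for both orders.
* **Optimizer.** L-BFGS to convergence (relative tolerance 1e-6, at most
  500 iterations). These are exposed through `crf_config()`.
* **Decoding.** Viterbi returns the argmax sequence with its normalized
  joint probability. `crf_nbest()` is a k-best suffix-decoding variant
  returning the n distinct highest-probability sequences; exact score ties
  are ordered lexicographically by label sequence. Both are validated in
  the test suite against exhaustive enumeration of all `3^L` labelings on
  random toy models (L ≤ 8, tolerance 1e-9).

IOB encoding labels the token that starts a mention `B-CHEMICAL` and
subsequent covered tokens `I-CHEMICAL`; a mention boundary falling strictly
inside a token labels the whole token. Decoding repairs an orphan `I` by
treating it as `B` and warns (once per call).

## From n-best lists to probabilities

The mention-level confidence of Model 1 is an approximated marginal: the
mentions of the n = 20 best label sequences are pooled, and each mention's
marginal is the sum of the joint probabilities of the sequences containing
exactly that span. When n covers all labelings this equals the exact
marginal (tested by enumeration). Model 2's engine history did not provide
n-best inference, so its occurrences enter document-level scoring with a
small fixed probability, 0.1 by default — chosen to rank below any
confident Model 1 marginal; the value is configurable and not a measured
quantity.

For Model 1's primary mention output, `tag_corpus()` keeps n-best mentions
with marginal ≥ 0.5 — the operating point closest to plain Viterbi
decoding; the high-recall combination instead consumes the unfiltered
marginal table and applies its own 0.1 threshold.

Document-level (CDI) confidence for a text `t` appearing with
per-occurrence probabilities `p1 … pn` in one abstract is the noisy-or
`1 − ∏(1 − pi)`, i.e. the probability that at least one occurrence is a
true mention under an independence assumption.

## Combination strategies

* **Naïve**: pool both models' mentions; duplicate spans keep the maximum
  probability. Raises recall at the cost of precision.
* **Heuristic**: keep Model 1 mentions except those whose text length is
  5–15 characters (inclusive — the boundary lengths are in range), which
  are replaced by Model 2's mentions in the same band. The band is applied
  to mention text length; an alternative reading (span-overlap replacement)
  is possible but the length-band reading is implemented.
* **High recall**: union of Model 2's output with every Model 1 n-best
  mention whose marginal is at least 0.1 (inclusive). The result is a
  superset of Model 2's output, so its recall can only be higher — this is
  asserted as a property test.

## Post-processing

Four rule passes run per document, in this order: consistency (Model 1
only), abbreviations, bracket balancing, identifier matching, then overlap
resolution (longer span wins, then higher probability). The order is a
package choice; the passes are order-sensitive only through overlap
checks.

* **Consistency**: any character sequence tagged at least twice in a
  document gets its remaining word-boundary-delimited occurrences added,
  unless a new span would overlap an existing mention (so a tagged
  `GO-PDEA` blocks adding an inner `GO`). Matching is case-sensitive (a
  choice — the alternative is not documented anywhere authoritative).
  Added mentions inherit the maximum probability of their sources. The
  pass is monotone and idempotent.
* **Abbreviations**: parenthesized definitions `long form (SF)` are found
  by a Schwartz–Hearst-style right-to-left alignment that tolerates digits
  and punctuation in the short form and leading non-alphabetic material in
  the long form; when alignment fails but the short form parses as element
  symbols plus digits, the immediately preceding word is accepted
  (`water (H2O)`). The detector is pluggable so an external tool can
  replace it. If the long form is tagged, all short-form occurrences are
  tagged (both models); Model 2 additionally tags all long-form occurrences
  when both forms were tagged, and *removes* short-form mentions when the
  long form was not tagged.
* **Bracket balancing**: mentions with unbalanced `()[]{}` are repaired by
  one single-character edit, tried as extend-right, extend-left,
  trim-right, trim-left (extensions must take in a bracket character);
  if nothing balances, the mention is dropped. `Cu(2+` followed by `)`
  extends to `Cu(2+)`.
* **Identifiers**: names shaped as 2–5 letters, up to two `-`/`_`/space
  separators and 2+ digits compile to patterns whose separator may vary
  (`NSC-114792` → `NSC[\-\_ ]{0,2}114792`); word-boundary matches in title
  and abstract (both — the restriction to abstracts only is not
  documented anywhere authoritative) become IDENTIFIER mentions with a
  fixed probability of 0.9, reflecting that lexicon matches are trusted.

## Normalization

Mentions map to vocabulary identifiers by exact key lookup, where the key
lowercases and strips all whitespace and punctuation
(`flavone-C-glycoside` → `flavonecglycoside`). Two vocabularies load from
`name<TAB>identifier` files: the primary vocabulary (MeSH-style) shadows
the secondary one (ChEBI-style), and within one source the first entry
wins on key collisions. A mention that fails direct lookup but matches a
detected abbreviation's short form inherits the long form's identifier.
Lookup is total: every mention is returned, mapped or not.

## The synthetic corpus generator

`generate_corpus()` emulates the corpus format and the surface statistics
that matter to the pipeline: filler-word sentences with injected chemical
phrases drawn from per-subtype grammars (multiplier–stem–suffix chains with
locants and brackets; element-symbol/digit formulas; trivial ring names;
`long form (SF)` abbreviation definitions; letter+digit identifiers;
pluralized families; coordinated lists), with exact gold offsets recorded
at injection. Within a document an injected chemical repeats an earlier one
with probability 0.3, which exercises consistency and document indexing.
It runs on a private RNG stream seeded from its config, so a fixed seed
yields a byte-identical corpus and the caller's RNG state is untouched.

Defaults — 50 documents, mean 3 abstract sentences, per-sentence chemical
injection Binomial(2, 0.5), subtype mix 25/15/25/10/10/10/5% over
SYSTEMATIC/FORMULA/TRIVIAL/ABBREVIATION/IDENTIFIER/FAMILY/MULTIPLE — were
chosen once to resemble the annotation density and subtype balance of real
chemistry-abstract corpora at a size the whole pipeline can train on in
seconds to minutes.

What the generator does *not* emulate: linguistic fluency, annotation
guideline edge cases (nested or discontinuous mentions, boundary
ambiguities of real IUPAC names), genuine ambiguity between chemical and
non-chemical tokens, and realistic abbreviation polysemy. Consequently,
passing tests show that the machinery — features, training, decoding,
rules, scoring — is correct and separable grammar is learned essentially
perfectly; they do not certify performance on real corpora, which is why
no real-corpus scores are claimed anywhere in the package.

## Numerical and scale choices

The test suite trains Model 2 on 200 generated documents and evaluates 50
held-out ones (seed 1), asserting held-out exact-span F ≥ 0.95 and
bit-identical repeatability; the grammar is separable by design, so this
is a correctness bar, not a performance claim. The σ×c sweep runs its full
16-cell grid (σ ∈ {0.5, 1, 2, 4} × c ∈ {0, 1, 3, 5}) on a 50-document
fixture with the iteration cap lowered to 60, a size chosen so the whole
suite completes comfortably on one CPU. Decoding oracles use exhaustive
enumeration at L ≤ 8; probability comparisons use tolerance 1e-9. Model
serialization writes weights with 17 significant digits, which round-trips
IEEE doubles exactly.

## Known limitations

* The built-in sentence splitter and abbreviation detector are
  deterministic stand-ins for more sophisticated components; both are
  pluggable.
* Order-2 composition scales the per-feature weight count by the product
  state count (9 instead of 3), which is wasteful for very large feature
  spaces.
* Overlap-mode evaluation uses greedy one-to-one matching (gold in
  document order, leftmost overlapping prediction first); other matching
  disciplines would give slightly different overlap scores.
* Normalization is exact key lookup only: no synonym expansion, no
  disambiguation, no structure-aware matching.
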