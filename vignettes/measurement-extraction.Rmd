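---
title: "Extracting lesion measurements and their descriptors from radiology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting lesion measurements and their descriptors from radiology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionext)
```

## The task

A narrative radiology report records lesion sizes as free text, usually in
the Findings section, and the size alone does not identify a lesion: the
same "4 mm" can occur several times in one sentence. What makes a
measurement re-identifiable across studies is its context — whether it is
a current or a prior value, the anatomy and finding it describes, and the
image/series/segment where it was taken. `lesionext` turns each
measurement mention into a *frame*: the numeric size plus seven descriptor
slots (temporality, anatomical entity, imaging observation, RadLex-style
descriptor, image number, series number, organ segment).

The design is deliberately hybrid. Everything whose surface form is
closed and conventional — sizes, units, "image 127", "previously 7 mm",
section headers — is handled by explicit grammars, which are auditable
and never need training data. Only the genuinely open-vocabulary part,
entity mention detection, uses a statistical sequence model, with a
dictionary look-up as the baseline it must beat.

## Pre-processing

Section headers (Comparison, Technique, Clinical History, Findings,
Conclusions) are matched case-insensitively at line starts (colon
optional at end of line) and anywhere in running text when written in ALL
CAPS with a colon, the dominant dictation style. "Impression" and
"Conclusion(s)" map to Conclusions; "History"/"Indication" to Clinical
History. Text before the first recognized header — or a report with no
recognized header at all, as in many mammography reports — becomes an
`OTHER` section, and `select_findings()` falls back to it so unheaded
reports still flow through the pipeline. This fallback is the package's
own choice for an input class whose handling is genuinely underdetermined.

Sentence splitting is a small rule set rather than a trained model: a
sentence ends at `.`/`!`/`?` followed by whitespace, unless the period
belongs to a decimal number, a known abbreviation or a single initial.
Semicolons and parentheses never split, which keeps long enumerating
sentences ("..., for example 4 mm ... (image 127, previously 7 mm), 4 mm
...") intact — exactly the sentences this package exists for.

Lowercasing and punctuation removal happen only *after* measurement and
reference tagging (`normalize_after_tagging()`), with tagged spans
protected and a reversible offset map, so surfaces like `1.2 x 3.4 cm`
and `(image 127)` are never mangled. In `build_frames()` this
normalization is realized at the feature level (features use lowercased
forms; punctuation tokens carry a `PUNCT` tag), which is equivalent for
the models used here and keeps all spans in raw-text coordinates.

All spans in the package are 1-based and inclusive, so
`substring(text, start, end)` always recovers the surface exactly.

## The measurement grammar

A mention is one to three *dimensions* joined by `x`/`×`. A dimension is
an integer or decimal, optionally a range (`4-5`); each dimension may
carry its own unit and the final one must (`4 mm x 6 mm`,
`1.2 x 3.4 cm`). Units `mm`/`cm` and their long forms are normalized; no
unit conversion is performed — frames carry the size as written. A range
is kept as one mention whose value is the larger endpoint, with the range
retained in the surface. A look-behind forbids a match directly after a
word character or dot, so `127` inside `image 127` or the `2` of `1.2`
can never seed a match. Bare numbers without units never match — which is
why "increased in size (by 1 mm)" yields exactly one mention, `1 mm`.

The test suite checks this grammar against an independently written
brute-force oracle that enumerates every substring of a sentence and
keeps the maximal ones matching an anchored restatement of the grammar.

## Temporality

Each mention is `CURRENT` or `PRIOR`. The sentence is swept left to
right with a running state: prior cues (`previously`, `previous`,
`prior`, `was`, `were`, `compared to/with`, `from <date-like token>`)
switch it to `PRIOR`; current cues (`now`, `currently`, `today`) switch
it back; a closing parenthesis or semicolon resets it to the `CURRENT`
default. A mention takes the state in force at its start. This
deliberately in-sentence design (no use of the Comparison section)
reproduces the conventional dictation patterns — "4 mm nodule
(previously 7 mm)", "previously 9 mm, now 4 mm" — while staying fully
deterministic. Cue lists are configurable (`lex_config()`).

## Sub-sentence division

Descriptor linking needs a scope: a sentence with several measurements is
partitioned into contiguous *sub-sentences*, one measurement each.
Between two adjacent mentions the boundary is chosen by the first
applicable rule:

1. if the right-hand mention is `PRIOR` and a prior cue lies in the gap,
   split immediately before the cue;
2. else after the last closing parenthesis in the gap, or before the
   first opening one;
3. else after the last comma or semicolon;
4. else at the whitespace nearest the gap midpoint.

Rule 1 outranks the parenthesis rule on purpose: in "4 mm left frontal
nodule (image 127, previously 7 mm)" the image reference belongs to the
*current* measurement, so the split must fall before "previously", not at
the parenthesis. Ordering the parenthesis rule first would hand every
parenthesized image number to the prior frame, which contradicts how
radiologists use these parentheticals. Every character belongs to
exactly one sub-sentence, so an entity can never be equidistantly torn
between two frames; an entity straddling a boundary goes to the
sub-sentence holding the majority of its span, left-biased on exact ties.

## Entity tagging

Three open-vocabulary entity types are tagged: anatomical entities,
imaging observations and RadLex-style descriptors. The package ships
small curated lexicons (~80 anatomy phrases including laterality
combinations, ~50 observations, ~45 descriptors); they are deliberately
compact, user-replaceable, and double as the closed vocabulary of the
synthetic generator.

The baseline tagger is greedy leftmost-longest case-insensitive lexicon
lookup (`dictionary_tag()`), which is also the pre-annotator for
bootstrapping training corpora ("light annotation":
`corrupt_for_light_annotation()` simulates the uncorrected state of such
a corpus).

The trainable tagger is a linear-chain CRF (`crf()`) over BIO labels.
Per-token features are the lowercased word, a coarse rule-based POS tag,
3-character prefix/suffix, a digit flag, dictionary-membership flags, and
windowed context copies of word/POS/dictionary features for ±2 neighbors
(boundary sentinels at sentence edges). No chunk or parse features are
used. Training maximizes the L2-penalized conditional log-likelihood
with L-BFGS; decoding is Viterbi followed by BIO repair (a headless `I-X`
becomes `B-X`), so output is always a valid BIO sequence. Defaults
follow common CRF-toolkit practice: L2 strength 1.0, 100 L-BFGS
iterations, window 2 — all recorded in `lex_config()$crf`. No POS tagger
or CRF toolkit for R ships in the package's dependency set, so both are
implemented here; the POS tagger is a deterministic closed-class/suffix
rule tagger, which is sufficient for its only role as a feature source.

Measurements and image/series/segment references are rule-tagged, never
CRF-tagged; their categories enter the label set only when a model is
trained for *label-transition analysis*
(`bio_label_set(extended = TRUE)`, `extract_transition_scores()`).
Linear-chain CRF transition parameters are unnormalized scores, not
conditional probabilities; the extractor returns raw scores by default
and offers a softmax-normalized view, labeled as such, for readers who
prefer a probability scale.

## Frame assembly

Entities link only within their sub-sentence; image/series/segment slots
take the nearest in-sub-sentence reference of each kind, else inherit
from *sentence-scope* references — those preceding the sentence's first
measurement, such as a leading "series 11", which are shared by every
frame of the sentence. Sentence scope (rather than paragraph scope) is
the package's choice; it suffices for the dictation patterns the linker
targets.

A `PRIOR` frame whose own sub-sentence contains no anatomy or observation
inherits those two slots from its paired current sub-sentence — but only
entities *after* the current measurement mention. The asymmetry is
deliberate: in "4 mm left frontal nodule (..., previously 7 mm)" the
prior 7 mm is the same left frontal nodule, while sentence-initial
modifiers ("scattered enhancing nodules ...") were dictated about the
enumeration as a whole and are left to the first frame, which is where a
sub-sentence-scoped linker genuinely sees them. RadLex descriptors,
image numbers and segments are not inherited (the prior measurement was
not made on this study's images).

## Evaluation

System frames align to gold frames when document, span overlap and
dimension values+units agree; the best-scoring pairing wins (greedy by
descriptor-match count, leftmost on ties). Text slots match exactly
after lowercasing and whitespace collapse — fuzzy matching would make
scores irreproducible; numeric slots by equality; temporality by label.
Precision/recall/F are percentages; an undefined metric (zero
denominator) is an explicit `NA`, never a silent 0.

Frame-level categories: `FULL` when the measurement and every gold
descriptor value matched (descriptors absent from both sides count
vacuously toward `FULL` — otherwise a frame with few gold descriptors
could never be full), `PARTIAL` when at least one matched and one
missed, `NO_MATCH` when nothing matched (including a missed
measurement). `combination_match_table()` reports, for any set of
descriptor combinations, how many extracted measurements matched at
least that combination; counts are antitone under combination inclusion
by construction. Scoring is entity-level throughout (one unit per
descriptor value, not per token).

The inferred gold for the shipped multi-nodule example assigns the
sentence-initial modifiers to all ten frames and image numbers to the
five current frames only; `multi_nodule_gold()` documents this as an
annotation choice made here, constructed in code.

## The synthetic generator

`generate_corpus()` emulates the corpus structure the pipeline assumes:
section-headed reports whose Findings sentences come from a template
grammar (measurement-first, observation-first, prior parentheticals,
shared series prefixes) over the package lexicons, with every gold view
(frames, standoff spans, BIO tokens) emitted consistently by
construction. Defaults were fixed once as the study conditions:

* mostly single-measurement sentences (75/20/5% for 1/2/3 lesions) —
  multi-measurement sentences are the known hard case, mammography
  sentences essentially never have more than one;
* prior-pair probability 0.45, making ~31% of all mentions historical,
  the proportion typical of oncology follow-up reporting;
* mostly one-dimensional sizes (70/25/5%), mm/cm mix 55/45;
* a 10% surface-variant rate (pluralization, benign typos) as the only
  source of out-of-lexicon forms, so the dictionary baseline is exactly
  lexicon-closed at variant rate 0.

The generator does *not* mimic real dictation diversity: institutional
templates, negation, hedging, mixed-language text, transcription noise,
or realistic report-length and vocabulary distributions. Passing tests
on this corpus therefore demonstrate internal correctness of the
grammars, the learner and the scorer under the stated conditions — not
clinical-grade accuracy on real reports, which would require real
annotated data.

Everything stochastic flows from explicit integer seeds; a corpus is a
deterministic function of its config.

## Problem sizes and numerical choices

The test suite exercises the invariants at sizes chosen to make the
properties meaningful while keeping the suite quick: 10,000 generated
sentences for the count-conservation and partition properties; a
brute-force oracle comparison on 40 sentences (the oracle is quadratic
in sentence length); and a parameter-recovery experiment training the
CRF on 800 synthetic sentences and scoring entity-level F on 200
held-out ones, asserted at F ≥ 0.9 within a ±0.05 stochastic tolerance.
L-BFGS starts from zero weights (the objective is convex, so
initialization affects only runtime); ties in Viterbi resolve to the
lowest label index, making predictions deterministic; saved models
reload with bit-identical predictions.

## Limitations

* Descriptor linking is rule-based within sub-sentences; relations are
  not modeled statistically, so shared modifiers reach only the nearest
  frame (the worked example's nine partial matches show exactly this).
* Temporality uses in-sentence cues only; a measurement whose
  prior-ness is implied solely by the Comparison section is labeled
  `CURRENT`.
* Lexicons are compact starter lists, not a RadLex export; real
  deployments should substitute site-specific dictionaries via the
  config.
* No cross-report lesion tracking, volumetrics, date normalization,
  HL7/DICOM-SR parsing or de-identification; inputs are plain text.
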