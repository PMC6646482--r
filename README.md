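# lesionext

Lesion size measurements ("4 mm left frontal nodule", "1.2 x 3.4 cm mass")
are the predominant quantitative content of narrative radiology reports,
and tracking a lesion across studies requires more than the number itself:
the same size must be tied to *where* it was measured and *when*.
`lesionext` extracts every measurement mention from a report's Findings
section and emits one structured **frame** per measurement, linking it to
seven descriptors:

1. temporality — current scan vs. reference to a prior study,
2. anatomical entity,
3. imaging observation (the finding being measured),
4. RadLex-style descriptor (a qualifier such as "scattered"),
5. image (slice) number,
6. series number,
7. organ segment number.

It is aimed at researchers building lesion-tracking, tumor-burden or
report-summarization tools who need structured measurements from CT, MR or
mammography reports.

## Method

The pipeline is hybrid. Deterministic regular-expression grammars handle
report sectioning, sentence splitting, measurement + temporality tagging,
division of multi-measurement sentences into *sub-sentences* (one
measurement each — the scope for descriptor linking), and image/series/
segment references. Entity tagging is either a dictionary baseline
(greedy leftmost-longest lexicon lookup) or a linear-chain conditional
random field over token features. The CRF scores a BIO label sequence
*y* for a token sequence *x* as

    score(y | x) = Σ_t  w · f(x, t, y_t)  +  Σ_t  T[y_{t−1}, y_t]

with sparse emission features *f* (word form, POS, affixes, dictionary
flags, ±2 context window) and a dense label-transition matrix *T*;
training maximizes the L2-penalized conditional log-likelihood by L-BFGS
and decoding is Viterbi (`crf()`, `predict()`, `coef()`). Rule-based
linking then fills each frame from the entities and scan references in
its measurement's sub-sentence, inheriting sentence-scope references
(e.g. a leading "series 11") when a sub-sentence has none.

The package also ships the evaluation scheme (per-descriptor
precision/recall/F and frame-level full/partial/no-match classification)
and a seeded synthetic report generator with paired gold frames, standoff
entity spans and BIO tokens, so the entire system trains and evaluates
without any clinical data.

## Worked example

```r
library(lesionext)

txt <- paste(readLines(multi_nodule_example()), collapse = "\n")
frames <- build_frames(rad_report(txt, doc_id = "example"))
for (f in frames[1:4]) print(f)
```

```
[example.1] 4 mm (CURRENT) AE=left frontal IO=enhancing|nodule RD=scattered image=127 series=11 segment=-
[example.2] 7 mm (PRIOR) AE=left frontal IO=nodule RD=- image=- series=11 segment=-
[example.3] 4 mm (CURRENT) AE=right frontal IO=nodule RD=- image=124 series=11 segment=-
[example.4] 9 mm (PRIOR) AE=right frontal IO=nodule RD=- image=- series=11 segment=-
```

The fixture is a single Findings sentence enumerating five shrinking
nodules, each with its prior size in parentheses. The pipeline finds all
ten measurements (five current, five prior), shares the leading
"series 11" across every frame, attaches each "image N" to its own
nodule, and lets each prior measurement inherit the anatomy and
observation of its current partner. Scoring against a gold standard in
which the sentence-initial modifiers "scattered" and "enhancing" describe
*all* ten nodules:

```r
gold <- multi_nodule_gold()
for (i in seq_along(gold)) gold[[i]]$doc_id <- "example"
evaluate_frames(frames, gold)
```

```
    information_type tp fp fn precision recall f_score
         measurement 10  0  0       100    100  100.00
         temporality 10  0  0       100    100  100.00
   anatomical_entity 10  0  0       100    100  100.00
 imaging_observation 11  0  9       100     55   70.97
   radlex_descriptor  1  0  9       100     10   18.18
        image_number  5  0  0       100    100  100.00
       series_number 10  0  0       100    100  100.00
             segment  0  0  0        NA     NA      NA

match categories:  FULL 1, PARTIAL 9, NO_MATCH 0 (of 10 gold frames)
```

Every measurement, temporality, location and series/image number is
correct, but because descriptor linking is scoped to sub-sentences, the
shared modifiers reach only the first frame — so nine of the ten frames
are partial matches. `NA` marks a metric whose denominator is zero (no
segment is annotated on either side), never a silent zero.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli","lesionext",package="lesionext"))')
Rscript $CLI synth   --out corpus --n-reports 100 --seed 7
Rscript $CLI train   --corpus corpus/standoff.jsonl --out model.rds
Rscript $CLI extract --input corpus --out frames.jsonl --tagger crf --model model.rds
Rscript $CLI eval    --system frames.jsonl --gold corpus/gold_frames.jsonl --out results
```

## Documentation

The methods vignette (`vignettes/measurement-extraction.Rmd`) describes
the grammars, the CRF, the evaluation definitions, the synthetic
generator's study conditions, and the package's design decisions and
limitations.
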