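# Shared test helpers: an independent brute-force oracle for the
# measurement grammar, entity-level F computation, and a small cached CRF
# so several test files can share one training run.

# Brute-force measurement matcher: enumerate every substring, test it
# against an anchored re-statement of the dimension grammar, keep maximal
# boundary-clean matches.  Written independently of the tagger's scanning
# logic (which relies on a single leftmost-greedy regex pass).
oracle_measurements <- function(text) {
  num <- "\\d+(?:\\.\\d+)?"
  rng <- paste0(num, "(?:\\s*-\\s*", num, ")?")
  unit <- "(?:millimeters?|centimeters?|mm|cm)"
  full <- paste0("^(?:", rng, "(?:\\s*", unit, ")?\\s*[x×]\\s*){0,2}",
                 rng, "\\s*", unit, "$")
  n <- nchar(text)
  cand <- list()
  for (i in seq_len(n)) {
    if (i > 1 && grepl("^[\\w.]$", substring(text, i - 1, i - 1),
                       perl = TRUE)) {
      next
    }
    for (j in i:n) {
      s <- substring(text, i, j)
      if (grepl(full, s, perl = TRUE, ignore.case = TRUE)) {
        cand[[length(cand) + 1L]] <- c(start = i, end = j)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, "start"] <= m[r, "start"] & m[, "end"] >= m[r, "end"] &
           (m[, "start"] < m[r, "start"] | m[, "end"] > m[r, "end"]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  data.frame(start = unname(m[, "start"]), end = unname(m[, "end"]))
}

# Entity-level F score between predicted and gold entity tables
# (type + exact span).
entity_prf <- function(pred, gold) {
  key <- function(d) {
    if (nrow(d) == 0) return(character(0))
    paste(d$type, d$start, d$end)
  }
  tp <- length(intersect(key(pred), key(gold)))
  fp <- length(setdiff(key(pred), key(gold)))
  fn <- length(setdiff(key(gold), key(pred)))
  f <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  c(tp = tp, fp = fp, fn = fn, f = f)
}

# Featurized sentences + BIO labels for a batch of generated sentences.
featurized_gold <- function(sents, lexicons = default_lexicons()) {
  keep <- c("ANATOMICAL_ENTITY", "IMAGING_OBSERVATION", "RADLEX_DESCRIPTOR")
  toks <- lapply(sents, function(s) tokenize_and_pos(s$text))
  labs <- lapply(seq_along(sents), function(i) {
    e <- sents[[i]]$entities
    e <- e[e$label %in% keep, , drop = FALSE]
    entities_to_labels(toks[[i]], data.frame(
      type = e$label, start = e$start, end = e$end,
      stringsAsFactors = FALSE))
  })
  list(tokens = toks,
       x = lapply(toks, featurize, lexicons = lexicons),
       y = labs)
}

# One small trained CRF shared across test files (trained on first use).
.helper_cache <- new.env(parent = emptyenv())
small_crf <- function() {
  if (is.null(.helper_cache$model)) {
    set.seed(2024)
    sents <- replicate(150, generate_sentence(synth_config()),
                       simplify = FALSE)
    fg <- featurized_gold(sents)
    .helper_cache$model <- crf(fg$x, fg$y, labels = bio_label_set(),
                               maxit = 60)
    .helper_cache$train <- fg
  }
  .helper_cache$model
}

# Minimal frame for evaluation plumbing tests
make_eval_frame <- function(doc = "d1") {
  lesionext:::new_frame(
    "f1", doc, 1L, "4 mm", 1L, 4L,
    data.frame(value = 4, unit = "mm", start = 1L, end = 4L), "CURRENT")
}

# The featurized training batch behind small_crf()
small_crf_train <- function() {
  small_crf()
  .helper_cache$train
}

example_text <- function() {
  paste(readLines(multi_nodule_example(), encoding = "UTF-8",
                  warn = FALSE), collapse = "\n")
}
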