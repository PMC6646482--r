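test_that("tokenizer produces span-recoverable tokens with POS tags", {
  t1 <- tokenize_and_pos("4 mm left frontal nodule")
  expect_equal(nrow(t1), 5L)
  expect_equal(substring("4 mm left frontal nodule", t1$start, t1$end),
               t1$surface)
  expect_equal(t1$pos[1], "CD")

  expect_equal(nrow(tokenize_and_pos("")), 0L)

  # decimals stay whole; punctuation is split out
  t2 <- tokenize_and_pos("measures 1.2 cm (image 7).")
  expect_true("1.2" %in% t2$surface)
  expect_true("(" %in% t2$surface)
  expect_equal(t2$pos[t2$surface == "("], "PUNCT")

  t3 <- tokenize_and_pos("enhancing nodules")
  expect_equal(t3$pos, c("VBG", "NN"))
})

test_that("feature extraction encodes lexicon, context and shape", {
  toks <- tokenize_and_pos("scattered nodule near image 127")
  f <- featurize(toks)
  expect_length(f, 5L)
  expect_true("dict=desc" %in% f[[1]])
  expect_true("dict=obs" %in% f[[2]])
  expect_true("w[-1]=__BOS1__" %in% f[[1]])
  expect_true("isdigit" %in% f[[5]])
  expect_true("w[-1]=nodule" %in% f[[3]])
  expect_true("dict=none" %in% f[[5]])
})

test_that("dictionary tagging is greedy leftmost-longest", {
  lex <- list(anatomical_entity = c("frontal", "left frontal"),
              imaging_observation = "nodule",
              radlex_descriptor = character(0))
  toks <- tokenize_and_pos("left frontal nodule")
  hits <- dictionary_tag(toks, lex)
  expect_equal(hits$surface, c("left frontal", "nodule"))
  expect_equal(hits$type, c("ANATOMICAL_ENTITY", "IMAGING_OBSERVATION"))

  # case-insensitive; no hit for out-of-lexicon tokens
  toks2 <- tokenize_and_pos("LEFT FRONTAL mass")
  hits2 <- dictionary_tag(toks2, lex)
  expect_equal(hits2$surface, "LEFT FRONTAL")

  # overlapping candidate phrases cannot produce overlapping output
  lex3 <- list(anatomical_entity = c("liver", "liver segment"),
               imaging_observation = c("segment five lesion"),
               radlex_descriptor = character(0))
  hits3 <- dictionary_tag(tokenize_and_pos("liver segment five lesion"),
                          lex3)
  expect_equal(hits3$surface, "liver segment")
  if (nrow(hits3) > 1) {
    expect_true(all(hits3$start[-1] > hits3$end[-nrow(hits3)]))
  }
})

test_that("BIO repair and entity conversion are total and inverse", {
  expect_equal(bio_repair(c("I-ANATOMICAL_ENTITY", "O")),
               c("B-ANATOMICAL_ENTITY", "O"))
  expect_true(bio_valid(c("B-ANATOMICAL_ENTITY", "I-ANATOMICAL_ENTITY")))
  expect_false(bio_valid(c("O", "I-ANATOMICAL_ENTITY")))

  toks <- tokenize_and_pos("left frontal nodule")
  ents <- labels_to_entities(
    toks, c("B-ANATOMICAL_ENTITY", "I-ANATOMICAL_ENTITY", "O"))
  expect_equal(ents$surface, "left frontal")
  expect_equal(ents$type, "ANATOMICAL_ENTITY")

  expect_equal(nrow(labels_to_entities(toks, rep("O", 3))), 0L)

  two <- labels_to_entities(
    toks[1:2, ], c("B-ANATOMICAL_ENTITY", "B-IMAGING_OBSERVATION"))
  expect_equal(nrow(two), 2L)

  # round trip: entities -> labels -> entities
  labs <- entities_to_labels(toks, ents[, c("type", "start", "end")])
  expect_equal(labs, c("B-ANATOMICAL_ENTITY", "I-ANATOMICAL_ENTITY", "O"))
})

test_that("CRF training honours its contracts", {
  expect_error(crf(list(), list()), "empty")
  toks <- tokenize_and_pos("liver cyst")
  x <- list(featurize(toks))
  expect_error(
    crf(x, list(c("B-NOT_A_TYPE", "O")), labels = bio_label_set()),
    "outside")

  # one-sentence corpus is memorized
  y <- list(c("B-ANATOMICAL_ENTITY", "B-IMAGING_OBSERVATION"))
  m1 <- crf(x, y, maxit = 40)
  expect_equal(predict(m1, x), y)

  # all-O gold yields all-O predictions
  m0 <- crf(x, list(c("O", "O")), labels = bio_label_set(), maxit = 20)
  expect_equal(predict(m0, x), list(c("O", "O")))
  expect_equal(predict(m0, list()), list())
})

test_that("trained CRF beats the dictionary baseline on its train set", {
  model <- small_crf()
  fg <- small_crf_train()
  pred <- predict(model, fg$x)
  crf_acc <- mean(unlist(pred) == unlist(fg$y))
  dict_labels <- lapply(fg$tokens, function(toks) {
    hits <- dictionary_tag(toks)
    entities_to_labels(toks, data.frame(type = hits$type,
                                        start = hits$start,
                                        end = hits$end,
                                        stringsAsFactors = FALSE))
  })
  dict_acc <- mean(unlist(dict_labels) == unlist(fg$y))
  expect_gte(crf_acc, dict_acc)
  # every emitted sequence is BIO-valid
  expect_true(all(vapply(pred, bio_valid, logical(1))))
})

test_that("model persistence gives bit-identical predictions", {
  model <- small_crf()
  fg <- small_crf_train()
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  crf_save(model, path)
  reloaded <- crf_load(path)
  expect_identical(predict(reloaded, fg$x[1:20]),
                   predict(model, fg$x[1:20]))
  expect_identical(extract_transition_scores(reloaded),
                   extract_transition_scores(model))
})

test_that("feature-template mismatch is detected at predict time", {
  model <- small_crf()
  bogus <- list(list(c("chunk=NP", "w=nodule")))
  expect_error(predict(model, bogus), "template")
})

test_that("transition scores expose descriptor sequencing", {
  # grammar that always places an imaging observation right after the
  # measurement; the learned transition must prefer it over SEGMENT
  set.seed(77)
  lex <- default_lexicons()
  sents <- lapply(1:80, function(i) {
    io <- sample(lex$imaging_observation, 1)
    ae <- sample(lex$anatomical_entity, 1)
    sz <- paste0(sample(2:30, 1), " mm")
    seg <- sample(1:8, 1)
    text <- paste0(sz, " ", io, " in the ", ae, " segment ", seg, ".")
    toks <- tokenize_and_pos(text)
    loc <- function(s) {
      p <- regexpr(s, text, fixed = TRUE)
      c(p, p + attr(p, "match.length") - 1L)
    }
    spans <- rbind(loc(sz), loc(io), loc(ae), loc(paste0("segment ", seg)))
    ents <- data.frame(
      type = c("MEASUREMENT", "IMAGING_OBSERVATION", "ANATOMICAL_ENTITY",
               "SEGMENT"),
      start = spans[, 1], end = spans[, 2], stringsAsFactors = FALSE)
    list(x = featurize(toks), y = entities_to_labels(toks, ents))
  })
  m <- crf(lapply(sents, `[[`, "x"), lapply(sents, `[[`, "y"),
           labels = bio_label_set(extended = TRUE), maxit = 60)
  tm <- extract_transition_scores(m)
  expect_equal(dim(tm), c(17L, 17L))
  expect_equal(rownames(tm), bio_label_set(extended = TRUE))
  expect_gt(tm["I-MEASUREMENT", "B-IMAGING_OBSERVATION"],
            tm["I-MEASUREMENT", "B-SEGMENT"])
  # softmax view is a row-stochastic relabeling of the same matrix
  sm <- extract_transition_scores(m, normalize = "softmax")
  expect_equal(unname(rowSums(sm)), rep(1, nrow(sm)))
  expect_error(extract_transition_scores(list()), "crf")
})
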