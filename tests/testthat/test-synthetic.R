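test_that("generation is a deterministic function of the config", {
  c1 <- generate_corpus(synth_config(seed = 7, n_reports = 6))
  c2 <- generate_corpus(synth_config(seed = 7, n_reports = 6))
  expect_identical(vapply(c1$reports, `[[`, character(1), "text"),
                   vapply(c2$reports, `[[`, character(1), "text"))
  expect_identical(serialize_frames(c1$frames),
                   serialize_frames(c2$frames))
  c3 <- generate_corpus(synth_config(seed = 8, n_reports = 6))
  expect_false(identical(c1$reports[[1]]$text, c3$reports[[1]]$text))
})

test_that("constrained configs constrain the output", {
  cfg <- synth_config(seed = 3, n_reports = 8,
                      measurements_per_sentence = c("1" = 1),
                      prior_pair_probability = 0)
  corpus <- generate_corpus(cfg)
  per_sent <- table(vapply(corpus$frames, function(f) {
    paste(f$doc_id, f$sentence_id)
  }, character(1)))
  expect_true(all(per_sent == 1L))
  expect_true(all(vapply(corpus$frames, `[[`, character(1),
                         "temporality") == "CURRENT"))

  expect_length(generate_corpus(synth_config(n_reports = 0))$reports, 0L)

  bad <- synth_config()
  bad$unit_mix <- c(mm = 0.7, cm = 0.7)
  expect_error(generate_corpus(bad), "distribution")
  expect_error(synth_config(prior_pair_probability = 1.2), "\\[0, 1\\]")
})

test_that("re-tagging generated text reproduces the gold measurements", {
  corpus <- generate_corpus(synth_config(seed = 19, n_reports = 20))
  for (s in corpus$standoff) {
    gold_m <- s$entities[s$entities$label == "MEASUREMENT", , drop = FALSE]
    got <- tag_measurements(s$text)
    expect_equal(got$start, gold_m$start, info = s$text)
    expect_equal(got$end, gold_m$end, info = s$text)
    expect_equal(got$surface, gold_m$surface, info = s$text)
  }
})

test_that("default generator exercises every template and slot", {
  corpus <- generate_corpus(synth_config(seed = 29, n_reports = 60))
  fr <- corpus$frames
  grab <- function(field) vapply(fr, `[[`, integer(1), field)
  expect_gt(sum(!is.na(grab("image_number"))), 0L)
  expect_gt(sum(!is.na(grab("series_number"))), 0L)
  expect_gt(sum(!is.na(grab("segment"))), 0L)
  tmp <- vapply(fr, `[[`, character(1), "temporality")
  expect_gt(sum(tmp == "PRIOR"), 0L)
  expect_gt(sum(lengths(lapply(fr, `[[`, "radlex_descriptor")) > 0), 0L)
  expect_gt(sum(lengths(lapply(fr, `[[`, "anatomical_entity")) > 0), 0L)
  expect_gt(sum(lengths(lapply(fr, `[[`, "imaging_observation")) > 0), 0L)
  ndims <- vapply(fr, function(f) nrow(f$measurement$dims), integer(1))
  expect_setequal(unique(ndims), c(1L, 2L, 3L))
  # both sentence styles and the series-prefix template occur
  expect_true(any(grepl("measures", vapply(corpus$standoff, `[[`,
                                           character(1), "text"))))
  expect_true(any(grepl("^On series", vapply(corpus$standoff, `[[`,
                                             character(1), "text"))))
  # historical fraction sits near the configured study condition (~31%)
  expect_gt(mean(tmp == "PRIOR"), 0.2)
  expect_lt(mean(tmp == "PRIOR"), 0.45)
})

test_that("gold views are mutually consistent", {
  corpus <- generate_corpus(synth_config(seed = 43, n_reports = 10))
  # every standoff entity surface is the exact slice of its sentence
  for (s in corpus$standoff) {
    expect_equal(substring(s$text, s$entities$start, s$entities$end),
                 s$entities$surface)
  }
  # frames' spans resolve inside their report text
  texts <- stats::setNames(
    vapply(corpus$reports, `[[`, character(1), "text"),
    vapply(corpus$reports, `[[`, character(1), "doc_id"))
  for (f in corpus$frames) {
    expect_equal(substring(texts[[f$doc_id]], f$measurement$start,
                           f$measurement$end), f$measurement$surface)
  }
  # BIO projection has one label per token
  bio <- standoff_to_bio(corpus$standoff)
  expect_equal(vapply(bio$tokens, nrow, integer(1)),
               lengths(bio$labels))
})

test_that("zero variant rate keeps the corpus inside the lexicon", {
  corpus <- generate_corpus(synth_config(seed = 67, n_reports = 15,
                                         variant_rate = 0))
  keep <- c("ANATOMICAL_ENTITY", "IMAGING_OBSERVATION",
            "RADLEX_DESCRIPTOR")
  tp <- 0L; fn <- 0L
  for (s in corpus$standoff) {
    gold <- s$entities[s$entities$label %in% keep, , drop = FALSE]
    gold <- data.frame(type = gold$label, start = gold$start,
                       end = gold$end, stringsAsFactors = FALSE)
    pred <- dictionary_tag(tokenize_and_pos(s$text))
    r <- entity_prf(pred, gold)
    tp <- tp + r[["tp"]]; fn <- fn + r[["fn"]]
  }
  expect_gt(tp, 0L)
  expect_equal(fn, 0L)  # dictionary recall 1.0 on lexicon-closed text
})

test_that("light-annotation corruption degrades gold controllably", {
  corpus <- generate_corpus(synth_config(seed = 3, n_reports = 8))
  so <- corpus$standoff
  n_ents <- sum(vapply(so, function(s) nrow(s$entities), integer(1)))

  same <- corrupt_for_light_annotation(so, drop_rate = 0, seed = 1)
  expect_identical(same, so)

  gone <- corrupt_for_light_annotation(so, drop_rate = 1, seed = 1)
  expect_equal(sum(vapply(gone, function(s) nrow(s$entities),
                          integer(1))), 0L)

  d1 <- corrupt_for_light_annotation(so, drop_rate = 0.2, seed = 99)
  d2 <- corrupt_for_light_annotation(so, drop_rate = 0.2, seed = 99)
  expect_identical(d1, d2)
  kept <- sum(vapply(d1, function(s) nrow(s$entities), integer(1)))
  expect_lt(kept, n_ents)
  expect_gt(kept, 0.5 * n_ents)

  sh <- corrupt_for_light_annotation(so, drop_rate = 0, shift_rate = 1,
                                     seed = 5)
  shifted <- sum(vapply(seq_along(so), function(i) {
    sum(sh[[i]]$entities$end != so[[i]]$entities$end)
  }, integer(1)))
  expect_gt(shifted, 0L)
})

test_that("corpus files are written and read back consistently", {
  dir <- tempfile("corpus")
  on.exit(unlink(dir, recursive = TRUE))
  corpus <- generate_corpus(synth_config(seed = 21, n_reports = 5),
                            dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(file.path(dir, "reports")), 5L)

  so <- read_standoff(file.path(dir, "standoff.jsonl"))
  expect_equal(length(so), length(corpus$standoff))
  expect_equal(so[[1]]$text, corpus$standoff[[1]]$text)
  expect_equal(so[[1]]$entities, corpus$standoff[[1]]$entities)

  fr <- read_frames(file.path(dir, "gold_frames.jsonl"))
  expect_equal(fr, corpus$frames)

  bio <- read_bio(file.path(dir, "corpus_bio.tsv"))
  expect_equal(length(bio$tokens), length(corpus$standoff))
  expect_true(all(vapply(bio$labels, function(l) {
    all(grepl("^(O|[BI]-[A-Z_]+)$", l))
  }, logical(1))))
})
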