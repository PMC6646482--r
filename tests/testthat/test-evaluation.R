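test_that("metrics from counts reproduce the analytic values", {
  m <- metrics_from_counts(784, 29, 0)
  expect_equal(round(m$precision, 2), 96.43)
  expect_equal(m$recall, 100)
  expect_equal(round(m$f_score, 2), 98.18)

  perfect <- metrics_from_counts(10, 0, 0)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_score),
               c(100, 100, 100))

  half <- metrics_from_counts(1, 1, 1)
  expect_equal(c(half$precision, half$recall, half$f_score),
               c(50, 50, 50))

  # undefined denominators give explicit NA markers, never silent zeros
  undef <- metrics_from_counts(0, 0, 0)
  expect_true(is.na(undef$precision))
  expect_true(is.na(undef$recall))
  expect_true(is.na(undef$f_score))

  # vector form accepted
  expect_equal(metrics_from_counts(c(tp = 784, fp = 29, fn = 0))$recall,
               100)
})

make_frame <- function(id = "f1", doc = "d1", surface = "4 mm",
                       start = 1L, end = 4L, value = 4, unit = "mm",
                       temporality = "CURRENT", ae = character(0),
                       io = character(0), rd = character(0),
                       image = NA_integer_, series = NA_integer_,
                       segment = NA_integer_) {
  lesionext:::new_frame(
    id, doc, 1L, surface, start, end,
    data.frame(value = value, unit = unit, start = start, end = end),
    temporality, ae, io, rd, image, series, segment)
}

test_that("descriptor scoring follows the matching definition", {
  gold <- list(make_frame(temporality = "PRIOR", ae = "left frontal",
                          image = 127L))
  same <- list(make_frame(temporality = "PRIOR", ae = "Left  Frontal",
                          image = 127L))
  # temporality and normalized text match; numeric equality for image
  expect_equal(score_descriptor(same, gold, "temporality"),
               c(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(score_descriptor(same, gold, "anatomical_entity"),
               c(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(score_descriptor(same, gold, "image_number"),
               c(tp = 1L, fp = 0L, fn = 0L))

  wrong_img <- list(make_frame(temporality = "PRIOR", image = 124L))
  expect_equal(score_descriptor(wrong_img, gold, "image_number"),
               c(tp = 0L, fp = 1L, fn = 1L))
  # gold has an anatomical entity, system has none
  expect_equal(score_descriptor(wrong_img, gold, "anatomical_entity"),
               c(tp = 0L, fp = 0L, fn = 1L))

  # unaligned frames count wholly as FP / FN on the measurement row
  far <- list(make_frame(surface = "9 mm", start = 50L, end = 53L,
                         value = 9))
  expect_equal(score_descriptor(far, gold, "measurement"),
               c(tp = 0L, fp = 1L, fn = 1L))
})

test_that("alignment requires overlap and equal dimensions", {
  gold <- list(make_frame())
  # same span, different value: no alignment
  a1 <- align_frames(list(make_frame(value = 5)), gold)
  expect_equal(nrow(a1$pairs), 0L)
  # overlapping span, same dimensions: aligned
  a2 <- align_frames(list(make_frame(start = 2L, end = 5L)), gold)
  expect_equal(nrow(a2$pairs), 1L)
  # two candidates: the better-matching one wins, the other becomes FP
  sys <- list(make_frame(ae = "liver"),
              make_frame(id = "f2", start = 3L, end = 6L))
  gold2 <- list(make_frame(ae = "liver"))
  a3 <- align_frames(sys, gold2)
  expect_equal(a3$pairs[1, ], c(sys = 1L, gold = 1L))
  expect_equal(a3$sys_unmatched, 2L)
})

test_that("full/partial/no-match classification partitions outcomes", {
  gold <- make_frame(ae = "liver", io = "nodule", image = 12L)

  full <- classify_match(gold, gold)
  expect_equal(full$category, "FULL")
  expect_length(full$missed_descriptors, 0L)

  partial <- classify_match(make_frame(ae = "liver"), gold)
  expect_equal(partial$category, "PARTIAL")
  expect_true("imaging_observation" %in% partial$missed_descriptors)

  # nothing but the measurement matched, and even temporality wrong
  none <- classify_match(make_frame(temporality = "PRIOR"), gold)
  expect_equal(none$category, "NO_MATCH")

  # missed measurement is a NO_MATCH
  missed <- classify_match(NULL, gold)
  expect_equal(missed$category, "NO_MATCH")
  expect_false(missed$measurement_matched)

  # descriptors absent from both sides count vacuously toward FULL
  bare <- make_frame()
  expect_equal(classify_match(make_frame(), bare)$category, "FULL")
})

test_that("worked-example evaluation yields nine partial matches", {
  sys <- build_frames(rad_report(example_text(),
                                 doc_id = "multi_nodule_example"))
  gold <- multi_nodule_gold()
  ev <- evaluate_frames(sys, gold)
  cats <- vapply(ev$matches, `[[`, character(1), "category")
  expect_equal(sum(cats == "PARTIAL"), 9L)
  expect_equal(sum(cats == "FULL"), 1L)
  # partition invariant
  expect_equal(sum(cats %in% c("FULL", "PARTIAL", "NO_MATCH")),
               length(gold))
  # measurement row is perfect on this sentence
  meas <- ev$metrics[ev$metrics$information_type == "measurement", ]
  expect_equal(meas$recall, 100)
  expect_equal(meas$precision, 100)
  # F lies between precision and recall on every defined row
  def <- ev$metrics[!is.na(ev$metrics$f_score), ]
  expect_true(all(def$f_score >= pmin(def$precision, def$recall) - 1e-9))
  expect_true(all(def$f_score <= pmax(def$precision, def$recall) + 1e-9))
})

test_that("combination match table is antitone in inclusion", {
  sys <- build_frames(rad_report(example_text(),
                                 doc_id = "multi_nodule_example"))
  ev <- evaluate_frames(sys, multi_nodule_gold())
  combos <- list(character(0),
                 "anatomical_entity",
                 c("anatomical_entity", "imaging_observation"),
                 c("anatomical_entity", "imaging_observation",
                   "radlex_descriptor"))
  tab <- combination_match_table(ev$matches, combos)
  expect_equal(tab$percent[1], 100)
  expect_true(all(diff(tab$count) <= 0))
  # every frame matched its anatomical entity on this sentence
  expect_equal(tab$count[2], 10L)
})

test_that("pipeline comparison reports rows side by side", {
  sys <- build_frames(rad_report(example_text(), doc_id = "ex"))
  gold <- lapply(multi_nodule_gold(), function(f) {
    f$doc_id <- "ex"
    f
  })
  same <- compare_pipelines(sys, sys, gold)
  expect_equal(same$precision_baseline, same$precision_proposed)
  expect_equal(same$recall_baseline, same$recall_proposed)

  # a pipeline that never emits RadLex descriptors has RD recall 0
  stripped <- lapply(sys, function(f) {
    f$radlex_descriptor <- character(0)
    f
  })
  cmp <- compare_pipelines(stripped, sys, gold)
  rd <- cmp[cmp$information_type == "radlex_descriptor", ]
  expect_equal(rd$recall_baseline, 0)
  expect_gt(rd$recall_proposed, 0)
})

test_that("CRF pipeline recall dominates the baseline on variant text", {
  model <- small_crf()
  set.seed(404)
  cfg <- synth_config(seed = 404, variant_rate = 0.35)
  sents <- replicate(60, generate_sentence(cfg), simplify = FALSE)
  keep <- c("ANATOMICAL_ENTITY", "IMAGING_OBSERVATION",
            "RADLEX_DESCRIPTOR")
  recall <- c(crf = 0, dict = 0)
  tp <- c(crf = 0L, dict = 0L)
  fn <- c(crf = 0L, dict = 0L)
  for (s in sents) {
    toks <- tokenize_and_pos(s$text)
    gold <- s$entities[s$entities$label %in% keep, , drop = FALSE]
    gold <- data.frame(type = gold$label, start = gold$start,
                       end = gold$end, stringsAsFactors = FALSE)
    pred_crf <- labels_to_entities(toks, predict(model, featurize(toks)))
    pred_dict <- dictionary_tag(toks)
    for (nm in c("crf", "dict")) {
      p <- if (nm == "crf") pred_crf else pred_dict
      r <- entity_prf(p, gold)
      tp[nm] <- tp[nm] + r["tp"]
      fn[nm] <- fn[nm] + r["fn"]
    }
  }
  rec <- tp / (tp + fn)
  expect_gte(rec[["crf"]], rec[["dict"]])
  expect_lt(rec[["dict"]], 1)  # variants do hurt the baseline
})
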