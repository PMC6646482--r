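test_that("measurement tagging finds maximal size expressions", {
  m <- tag_measurements(
    "4 mm left frontal nodule (image 127, previously 7 mm)")
  expect_equal(m$surface, c("4 mm", "7 mm"))

  m2 <- tag_measurements("increased in size (by 1 mm)")
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$dims[[1]]$value, 1)
  expect_equal(m2$dims[[1]]$unit, "mm")

  m3 <- tag_measurements("1.2 x 3.4 x 2.0 cm mass")
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$dims[[1]]$value, c(1.2, 3.4, 2.0))
  expect_equal(m3$dims[[1]]$unit, rep("cm", 3))

  # per-dimension units collapse into one mention too
  m4 <- tag_measurements("4 mm x 6 mm node")
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$dims[[1]]$value, c(4, 6))

  # a range is one mention carrying the larger value
  m5 <- tag_measurements("4-5 mm nodule")
  expect_equal(nrow(m5), 1L)
  expect_equal(m5$surface, "4-5 mm")
  expect_equal(m5$dims[[1]]$value, 5)

  # long unit names normalize
  m6 <- tag_measurements("about 3 centimeters in size")
  expect_equal(m6$dims[[1]]$unit, "cm")

  expect_equal(nrow(tag_measurements("no focal lesion")), 0L)
  # bare numbers without units never match
  expect_equal(nrow(tag_measurements("image 127 and series 11")), 0L)
})

test_that("tagger agrees with the brute-force grammar oracle", {
  set.seed(31)
  cfg <- synth_config(seed = 31)
  for (i in 1:40) {
    s <- generate_sentence(cfg)
    got <- tag_measurements(s$text)
    want <- oracle_measurements(s$text)
    expect_equal(got$start, want$start, info = s$text)
    expect_equal(got$end, want$end, info = s$text)
  }
})

test_that("temporality cues label mentions current or prior", {
  lab <- function(text) {
    m <- tag_measurements(text)
    tag_temporality(text, m)$temporality
  }
  expect_equal(lab("4 mm nodule (previously 7 mm)"),
               c("CURRENT", "PRIOR"))
  expect_equal(lab("measures 5 mm"), "CURRENT")
  # "now" terminates the prior scope
  expect_equal(lab("previously 9 mm, now 4 mm"), c("PRIOR", "CURRENT"))
  # closing parenthesis resets to current
  expect_equal(lab("nodule (was 6 mm) and a new 2 mm focus"),
               c("PRIOR", "CURRENT"))
  expect_equal(lab("measures 8 mm, compared to 10 mm on the prior exam"),
               c("CURRENT", "PRIOR"))
  # a date-like token after "from" opens a prior scope
  expect_equal(lab("from 3/21 measurement of 9 mm, now 4 mm"),
               c("PRIOR", "CURRENT"))
})

test_that("every mention carries exactly one temporality label", {
  set.seed(13)
  cfg <- synth_config(seed = 13)
  for (i in 1:60) {
    s <- generate_sentence(cfg)
    m <- tag_temporality(s$text, tag_measurements(s$text))
    expect_true(all(m$temporality %in% c("CURRENT", "PRIOR")))
  }
})

test_that("sub-sentence division yields one part per measurement", {
  one <- tag_measurements("Stable 4 mm nodule in the liver.")
  d1 <- divide_subsentences("Stable 4 mm nodule in the liver.", one)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$start, 1L)
  expect_equal(d1$end, nchar("Stable 4 mm nodule in the liver."))

  # current/prior pair: a current part and a historical part, with the
  # prior cue staying in the historical part
  s <- "Stable 4 mm liver nodule (image 22, previously 7 mm)."
  m <- tag_temporality(s, tag_measurements(s))
  d2 <- divide_subsentences(s, m)
  expect_equal(nrow(d2), 2L)
  expect_equal(substring(s, d2$start[2], d2$end[2]), "previously 7 mm).")
  expect_match(substring(s, d2$start[1], d2$end[1]), "image 22")

  # the worked example divides into ten parts
  txt <- example_text()
  body <- segment_sections(txt)
  sent <- split_sentences(txt, body$start[1], body$end[1])
  mm <- tag_temporality(sent$text, tag_measurements(sent$text))
  d3 <- divide_subsentences(sent$text, mm)
  expect_equal(nrow(d3), 10L)
})

test_that("division is a partition: count conservation on generated text", {
  set.seed(59)
  cfg <- synth_config(seed = 59)
  for (i in 1:60) {
    s <- generate_sentence(cfg)
    m <- tag_temporality(s$text, tag_measurements(s$text))
    d <- divide_subsentences(s$text, m)
    expect_equal(nrow(d), nrow(m))
    expect_equal(d$start[1], 1L)
    expect_equal(d$end[nrow(d)], nchar(s$text))
    if (nrow(d) > 1) {
      expect_equal(d$start[-1], d$end[-nrow(d)] + 1L)
    }
    # each sub-sentence owns exactly its measurement
    for (k in seq_len(nrow(d))) {
      inside <- m$start >= d$start[k] & m$end <= d$end[k]
      expect_equal(sum(inside), 1L)
      expect_equal(which(inside), d$mention_index[k])
    }
  }
})

test_that("scan references are tagged with kind and number", {
  r <- tag_scan_references(
    "reduced nodules on series 11, for example (image 127, ...)")
  expect_equal(r$kind, c("SERIES", "IMAGE"))
  expect_equal(r$number, c(11L, 127L))

  expect_equal(tag_scan_references("segment 5 lesion")$kind, "SEGMENT")
  expect_equal(tag_scan_references("segment 5 lesion")$number, 5L)

  # dictation shorthands and separators
  expect_equal(tag_scan_references("img 45 and se: 3 and seg #6")$kind,
               c("IMAGE", "SERIES", "SEGMENT"))
  r2 <- tag_scan_references("images 12-14")
  expect_equal(r2$number, 12L)
  expect_equal(r2$number_hi, 14L)

  # no false trigger without a numeric tail
  expect_equal(nrow(tag_scan_references("imaging was performed")), 0L)
  expect_equal(nrow(tag_scan_references("a series of segments")), 0L)
})

test_that("mentions never overlap each other or scan references", {
  set.seed(23)
  cfg <- synth_config(seed = 23)
  for (i in 1:50) {
    s <- generate_sentence(cfg)
    m <- tag_measurements(s$text)
    r <- tag_scan_references(s$text)
    spans <- rbind(m[, c("start", "end")], r[, c("start", "end")])
    spans <- spans[order(spans$start), , drop = FALSE]
    if (nrow(spans) > 1) {
      expect_true(all(spans$start[-1] > spans$end[-nrow(spans)]))
    }
  }
})
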