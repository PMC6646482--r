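# Scoring of system frames against gold frames: per-descriptor
# precision/recall/F at sentence level and full/partial/no-match
# classification at frame level.

.descriptor_names <- c("temporality", "anatomical_entity",
                       "imaging_observation", "radlex_descriptor",
                       "image_number", "series_number", "segment")

.norm_text <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Descriptor values of a frame as a normalized character multiset
# (numeric slots contribute zero or one value; temporality exactly one).
.descriptor_values <- function(frame, descriptor) {
  v <- frame[[descriptor]]
  if (descriptor %in% c("image_number", "series_number", "segment")) {
    if (is.na(v)) character(0) else as.character(v)
  } else if (descriptor == "temporality") {
    as.character(v)
  } else {
    .norm_text(v)
  }
}

# multiset intersection size of two character vectors
.multiset_overlap <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  ta <- table(a)
  tb <- table(b)
  common <- intersect(names(ta), names(tb))
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

.dims_equal <- function(f1, f2) {
  d1 <- f1$measurement$dims
  d2 <- f2$measurement$dims
  nrow(d1) == nrow(d2) &&
    isTRUE(all.equal(d1$value, d2$value)) &&
    identical(d1$unit, d2$unit)
}

.spans_overlap <- function(f1, f2) {
  f1$measurement$start <= f2$measurement$end &&
    f1$measurement$end >= f2$measurement$start
}

# number of gold descriptor values the system frame reproduces
.pair_match_count <- function(sys, gold) {
  sum(vapply(.descriptor_names, function(d) {
    .multiset_overlap(.descriptor_values(sys, d),
                      .descriptor_values(gold, d))
  }, integer(1)))
}

#' Align system frames with gold frames
#'
#' A system frame can match a gold frame when both are from the same
#' document, their measurement spans overlap, and their dimensions (value
#' and unit lists) are equal.  When several pairings are possible the
#' best-scoring one wins, greedily by descriptor-match count with the
#' leftmost system frame on ties; every frame is used at most once.
#'
#' @param system,gold Lists of `measurement_frame` objects.
#' @return A list with `pairs` (two-column matrix of indices into `system`
#'   and `gold`), `sys_unmatched`, `gold_unmatched` (integer vectors).
#' @export
align_frames <- function(system, gold) {
  cand <- list()
  for (i in seq_along(system)) {
    for (j in seq_along(gold)) {
      if (!identical(system[[i]]$doc_id, gold[[j]]$doc_id)) next
      if (!.spans_overlap(system[[i]], gold[[j]])) next
      if (!.dims_equal(system[[i]], gold[[j]])) next
      cand[[length(cand) + 1L]] <- c(
        i = i, j = j, score = .pair_match_count(system[[i]], gold[[j]]),
        start = system[[i]]$measurement$start
      )
    }
  }
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("sys", "gold")))
  if (length(cand) > 0) {
    cdf <- do.call(rbind, cand)
    cdf <- cdf[order(-cdf[, "score"], cdf[, "start"], cdf[, "i"],
                     cdf[, "j"]), , drop = FALSE]
    used_i <- logical(length(system))
    used_j <- logical(length(gold))
    for (r in seq_len(nrow(cdf))) {
      i <- cdf[r, "i"]; j <- cdf[r, "j"]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  list(
    pairs = pairs,
    sys_unmatched = setdiff(seq_along(system), pairs[, 1]),
    gold_unmatched = setdiff(seq_along(gold), pairs[, 2])
  )
}

#' Precision, recall and F score from confusion counts
#'
#' Precision = 100 tp/(tp+fp), recall = 100 tp/(tp+fn), F their harmonic
#' mean, all as percentages.  An undefined metric (zero denominator) is
#' reported as `NA`, never as a silent zero.  Full precision is retained;
#' rounding to two decimals happens only at display time.
#'
#' @param tp,fp,fn Non-negative counts.  `tp` may also be a length-3
#'   (optionally named) vector `c(tp, fp, fn)`.
#' @param information_type Row label.
#' @return A one-row data.frame (`information_type`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_score`).
#' @examples
#' metrics_from_counts(784, 29, 0)
#' @export
metrics_from_counts <- function(tp, fp = NULL, fn = NULL,
                                information_type = "measurement") {
  if (length(tp) == 3 && is.null(fp)) {
    fp <- tp[[2]]; fn <- tp[[3]]; tp <- tp[[1]]
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  data.frame(information_type = information_type, tp = tp, fp = fp,
             fn = fn, precision = precision, recall = recall, f_score = f,
             stringsAsFactors = FALSE)
}

#' Confusion counts for one descriptor
#'
#' Over aligned frame pairs, a system descriptor value is a true positive
#' iff it equals the gold value (case/whitespace-normalized surface match
#' for text slots, numeric equality for image/series/segment, label
#' equality for temporality); surplus system values are false positives and
#' surplus gold values false negatives.  Values carried by unaligned frames
#' count wholly as FP (system side) or FN (gold side).  The pseudo
#' descriptor `"measurement"` scores the alignment itself.
#'
#' @param system,gold Lists of `measurement_frame` objects.
#' @param descriptor One of the seven descriptor names or `"measurement"`.
#' @param alignment Optional precomputed [align_frames()] result.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
score_descriptor <- function(system, gold, descriptor,
                             alignment = align_frames(system, gold)) {
  if (descriptor == "measurement") {
    return(c(tp = nrow(alignment$pairs),
             fp = length(alignment$sys_unmatched),
             fn = length(alignment$gold_unmatched)))
  }
  stopifnot(descriptor %in% .descriptor_names)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (r in seq_len(nrow(alignment$pairs))) {
    sv <- .descriptor_values(system[[alignment$pairs[r, 1]]], descriptor)
    gv <- .descriptor_values(gold[[alignment$pairs[r, 2]]], descriptor)
    ov <- .multiset_overlap(sv, gv)
    tp <- tp + ov
    fp <- fp + length(sv) - ov
    fn <- fn + length(gv) - ov
  }
  for (i in alignment$sys_unmatched) {
    fp <- fp + length(.descriptor_values(system[[i]], descriptor))
  }
  for (j in alignment$gold_unmatched) {
    fn <- fn + length(.descriptor_values(gold[[j]], descriptor))
  }
  c(tp = tp, fp = fp, fn = fn)
}

#' Classify one frame pair as full, partial or no match
#'
#' A gold frame is a `FULL` match when its measurement was extracted and
#' every gold descriptor value was reproduced (descriptors absent from both
#' sides count vacuously toward `FULL`); `PARTIAL` when at least one gold
#' descriptor matched and at least one was missed; `NO_MATCH` when none
#' matched (including the case where the measurement itself was missed,
#' `system = NULL`).
#'
#' @param system A `measurement_frame`, or `NULL` when the gold
#'   measurement has no aligned system frame.
#' @param gold The gold `measurement_frame`.
#' @return A list with `frame_id` (gold id), `category`,
#'   `measurement_matched`, `matched_descriptors` (descriptors whose gold
#'   values, if any, were all reproduced — vacuous ones excluded),
#'   `missed_descriptors` (descriptors with at least one missed gold
#'   value).
#' @export
classify_match <- function(system, gold) {
  matched <- character(0)
  missed <- character(0)
  meas <- !is.null(system)
  for (d in .descriptor_names) {
    gv <- .descriptor_values(gold, d)
    if (length(gv) == 0) next
    sv <- if (meas) .descriptor_values(system, d) else character(0)
    if (.multiset_overlap(sv, gv) == length(gv)) {
      matched <- c(matched, d)
    } else {
      missed <- c(missed, d)
    }
  }
  category <- if (meas && length(missed) == 0) {
    "FULL"
  } else if (length(matched) == 0) {
    "NO_MATCH"
  } else {
    "PARTIAL"
  }
  list(frame_id = gold$frame_id, category = category,
       measurement_matched = meas, matched_descriptors = matched,
       missed_descriptors = missed)
}

#' Evaluate system frames against gold frames
#'
#' Computes the full scoreboard: the measurement row plus one
#' precision/recall/F row per descriptor, and the per-frame
#' full/partial/no-match classification.
#'
#' @param system,gold Lists of `measurement_frame` objects.
#' @return A list of class `"frame_evaluation"`: `metrics` (data.frame,
#'   eight rows), `matches` (list of [classify_match()] results, one per
#'   gold frame), `alignment`.
#' @export
evaluate_frames <- function(system, gold) {
  alignment <- align_frames(system, gold)
  metrics <- do.call(rbind, lapply(
    c("measurement", .descriptor_names),
    function(d) {
      metrics_from_counts(score_descriptor(system, gold, d, alignment),
                          information_type = d)
    }
  ))
  sys_of_gold <- rep(NA_integer_, length(gold))
  if (nrow(alignment$pairs) > 0) {
    sys_of_gold[alignment$pairs[, 2]] <- alignment$pairs[, 1]
  }
  matches <- lapply(seq_along(gold), function(j) {
    s <- if (is.na(sys_of_gold[j])) NULL else system[[sys_of_gold[j]]]
    classify_match(s, gold[[j]])
  })
  structure(list(metrics = metrics, matches = matches,
                 alignment = alignment),
            class = "frame_evaluation")
}

#' @export
print.frame_evaluation <- function(x, ...) {
  m <- x$metrics
  m$precision <- round(m$precision, 2)
  m$recall <- round(m$recall, 2)
  m$f_score <- round(m$f_score, 2)
  print(m, row.names = FALSE)
  cats <- vapply(x$matches, `[[`, character(1), "category")
  cat("\nmatch categories: ",
      sprintf("FULL %d, PARTIAL %d, NO_MATCH %d (of %d gold frames)\n",
              sum(cats == "FULL"), sum(cats == "PARTIAL"),
              sum(cats == "NO_MATCH"), length(cats)))
  invisible(x)
}

#' Match counts for descriptor combinations
#'
#' For each requested descriptor combination, the number and percentage of
#' extracted measurements whose matched-descriptor set contains the whole
#' combination.  The empty combination counts every matched measurement;
#' counts are antitone in combination inclusion (a superset can never
#' count more frames than its subset).
#'
#' @param matches List of [classify_match()] results (e.g.
#'   `evaluate_frames(...)$matches`).
#' @param combinations A list of character vectors of descriptor names; a
#'   `NULL`/empty element denotes the empty combination.
#' @return A data.frame with columns `combination`, `count`, `percent`.
#' @export
combination_match_table <- function(matches, combinations) {
  extracted <- Filter(function(m) m$measurement_matched, matches)
  denom <- length(extracted)
  rows <- lapply(combinations, function(combo) {
    combo <- as.character(combo)
    stopifnot(all(combo %in% .descriptor_names))
    cnt <- sum(vapply(extracted, function(m) {
      all(combo %in% m$matched_descriptors)
    }, logical(1)))
    data.frame(
      combination = if (length(combo) == 0) "(measurement only)" else
        paste(combo, collapse = "+"),
      count = cnt,
      percent = if (denom > 0) 100 * cnt / denom else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Side-by-side evaluation of two pipelines
#'
#' Scores the dictionary baseline and the proposed (CRF) pipeline against
#' the same gold frames and returns their per-descriptor metric rows side
#' by side.
#'
#' @param baseline,proposed Lists of system `measurement_frame` objects.
#' @param gold List of gold `measurement_frame` objects.
#' @return A data.frame with one row per information type and separate
#'   precision/recall/F columns per pipeline.
#' @export
compare_pipelines <- function(baseline, proposed, gold) {
  mb <- evaluate_frames(baseline, gold)$metrics
  mp <- evaluate_frames(proposed, gold)$metrics
  data.frame(
    information_type = mb$information_type,
    precision_baseline = mb$precision, recall_baseline = mb$recall,
    f_baseline = mb$f_score,
    precision_proposed = mp$precision, recall_proposed = mp$recall,
    f_proposed = mp$f_score,
    stringsAsFactors = FALSE
  )
}
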