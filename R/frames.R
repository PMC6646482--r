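# A measurement frame is the pipeline's unit of output: one measurement
# plus its seven descriptor slots (temporality, anatomical entity, imaging
# observation, RadLex descriptor, image number, series number, segment).

.frame_schema_version <- "1"

new_frame <- function(frame_id, doc_id, sentence_id, surface, start, end,
                      dims, temporality,
                      anatomical_entity = character(0),
                      imaging_observation = character(0),
                      radlex_descriptor = character(0),
                      image_number = NA_integer_,
                      series_number = NA_integer_,
                      segment = NA_integer_) {
  structure(
    list(
      frame_id = as.character(frame_id),
      doc_id = as.character(doc_id),
      sentence_id = as.integer(sentence_id),
      measurement = list(
        surface = as.character(surface),
        start = as.integer(start),
        end = as.integer(end),
        dims = data.frame(
          value = as.numeric(dims$value),
          unit = as.character(dims$unit),
          start = as.integer(dims$start),
          end = as.integer(dims$end),
          stringsAsFactors = FALSE
        )
      ),
      temporality = as.character(temporality),
      anatomical_entity = as.character(anatomical_entity),
      imaging_observation = as.character(imaging_observation),
      radlex_descriptor = as.character(radlex_descriptor),
      image_number = as.integer(image_number),
      series_number = as.integer(series_number),
      segment = as.integer(segment)
    ),
    class = "measurement_frame"
  )
}

#' @export
print.measurement_frame <- function(x, ...) {
  dims <- paste(paste0(x$measurement$dims$value, " ",
                       x$measurement$dims$unit), collapse = " x ")
  slot <- function(v) if (length(v) == 0) "-" else paste(v, collapse = "|")
  num <- function(v) if (is.na(v)) "-" else v
  cat(sprintf(
    "[%s] %s (%s) AE=%s IO=%s RD=%s image=%s series=%s segment=%s\n",
    x$frame_id, dims, x$temporality, slot(x$anatomical_entity),
    slot(x$imaging_observation), slot(x$radlex_descriptor),
    num(x$image_number), num(x$series_number), num(x$segment)))
  invisible(x)
}

# Does entity row r of `entities` belong to the sub-sentence [s, e]?
# Majority of its span must fall inside; an exact half-half split goes to
# the sub-sentence containing the entity's first character (left bias).
.entity_in_span <- function(entities, r, s, e) {
  ov <- min(entities$end[r], e) - max(entities$start[r], s) + 1L
  if (ov <= 0L) return(FALSE)
  len <- entities$end[r] - entities$start[r] + 1L
  if (2L * ov > len) return(TRUE)
  if (2L * ov == len) return(entities$start[r] >= s)
  FALSE
}

.nearest_ref <- function(refs, kind, m_start, m_end) {
  cand <- refs[refs$kind == kind, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_integer_)
  dist <- mapply(function(s, e) {
    if (e < m_start) m_start - e else if (s > m_end) s - m_end else 0L
  }, cand$start, cand$end)
  as.integer(cand$number[which.min(dist)])
}

#' Link a measurement to its descriptors
#'
#' Builds one frame for the single measurement owned by a sub-sentence.
#' Entity mentions whose span falls (by majority, left-biased on exact
#' ties) inside the sub-sentence populate the anatomical-entity,
#' imaging-observation and RadLex-descriptor slots; the image, series and
#' segment slots take the nearest in-sub-sentence scan reference of each
#' kind, else are inherited from the sentence-scope references (those
#' preceding the sentence's first measurement, e.g. a leading "series 11"
#' shared by every measurement of the sentence).  Temporality is copied
#' from the measurement.
#'
#' @param sub One row of [divide_subsentences()] output (`start`, `end`).
#' @param mentions Sentence mention table from [tag_temporality()].
#' @param entities Sentence entity table (`type`, `start`, `end`,
#'   `surface`).
#' @param scan_refs Sentence scan-reference table from
#'   [tag_scan_references()].
#' @param sentence_scope_refs Subset of `scan_refs` shared by all
#'   sub-sentences.
#' @param doc_id,sentence_id,frame_id Identifiers stamped on the frame.
#' @return A `measurement_frame` object.
#' @export
link_descriptors <- function(sub, mentions, entities, scan_refs,
                             sentence_scope_refs = scan_refs[0, ],
                             doc_id = "doc1", sentence_id = 1L,
                             frame_id = "f1") {
  own <- which(mentions$start >= sub$start & mentions$end <= sub$end)
  if (length(own) != 1L) {
    stop("sub-sentence must own exactly one measurement (found ",
         length(own), "): tagger contract violated", call. = FALSE)
  }
  m <- mentions[own, , drop = FALSE]
  keep <- vapply(seq_len(nrow(entities)), function(r) {
    .entity_in_span(entities, r, sub$start, sub$end)
  }, logical(1))
  ent <- entities[keep, , drop = FALSE]
  in_refs <- scan_refs[
    vapply(seq_len(nrow(scan_refs)), function(r) {
      .entity_in_span(scan_refs, r, sub$start, sub$end)
    }, logical(1)), , drop = FALSE]
  pick <- function(kind) {
    v <- .nearest_ref(in_refs, kind, m$start, m$end)
    if (is.na(v)) v <- .nearest_ref(sentence_scope_refs, kind,
                                    m$start, m$end)
    v
  }
  new_frame(
    frame_id = frame_id, doc_id = doc_id, sentence_id = sentence_id,
    surface = m$surface, start = m$start, end = m$end,
    dims = m$dims[[1]],
    temporality = m$temporality,
    anatomical_entity = ent$surface[ent$type == "ANATOMICAL_ENTITY"],
    imaging_observation = ent$surface[ent$type == "IMAGING_OBSERVATION"],
    radlex_descriptor = ent$surface[ent$type == "RADLEX_DESCRIPTOR"],
    image_number = pick("IMAGE"),
    series_number = pick("SERIES"),
    segment = pick("SEGMENT")
  )
}

# Tag entities in a sentence with either the dictionary baseline or a CRF.
.tag_entities <- function(tokens, tagger, model, config) {
  if (tagger == "dictionary" || is.null(model)) {
    return(dictionary_tag(tokens, config$lexicons))
  }
  feats <- featurize(tokens, config$lexicons, window = config$crf$window)
  labels <- predict(model, feats)
  ents <- labels_to_entities(tokens, labels)
  ents[ents$type %in% c("ANATOMICAL_ENTITY", "IMAGING_OBSERVATION",
                        "RADLEX_DESCRIPTOR"), , drop = FALSE]
}

#' Run the full extraction pipeline on one report
#'
#' End-to-end composition: section segmentation, Findings selection,
#' sentence splitting, measurement and temporality tagging, sub-sentence
#' division, scan-reference tagging, entity tagging (dictionary baseline or
#' CRF), and descriptor linking.  Emits exactly one frame per detected
#' measurement, in document order.  A `PRIOR` frame with no anatomical
#' entity or imaging observation of its own inherits those slots from its
#' paired current sub-sentence (only entities following the current
#' measurement are inherited — a prior "7 mm" inherits "nodule", never a
#' sentence-initial modifier).
#'
#' @param report A [rad_report()] object, or a character string of report
#'   text.
#' @param tagger `"dictionary"` (default) or `"crf"`.
#' @param model A fitted [crf()] model (required when `tagger = "crf"`).
#' @param config A [lex_config()] object.
#' @return A list of `measurement_frame` objects.
#' @examples
#' build_frames("FINDINGS: Stable 4 mm nodule in the liver (image 12).")
#' @export
build_frames <- function(report, tagger = c("dictionary", "crf"),
                         model = NULL, config = lex_config()) {
  tagger <- match.arg(tagger)
  if (tagger == "crf" && is.null(model)) {
    stop("tagger = \"crf\" requires a fitted model", call. = FALSE)
  }
  if (is.character(report)) report <- rad_report(report, config = config)
  stopifnot(inherits(report, "rad_report"))
  frames <- list()
  n_frames <- 0L
  sent_counter <- 0L
  findings <- select_findings(report)
  for (si in seq_len(nrow(findings))) {
    sentences <- split_sentences(report$raw_text,
                                 findings$start[si], findings$end[si])
    for (sj in seq_len(nrow(sentences))) {
      sent_counter <- sent_counter + 1L
      stext <- sentences$text[sj]
      soff <- sentences$start[sj]
      mentions <- tag_measurements(stext, soff, config)
      if (nrow(mentions) == 0) next
      mentions <- tag_temporality(stext, mentions, soff, config)
      subs <- divide_subsentences(stext, mentions, soff, config)
      refs <- tag_scan_references(stext, soff)
      scope_refs <- refs[refs$end < min(mentions$start), , drop = FALSE]
      tokens <- tokenize_and_pos(stext, soff)
      entities <- .tag_entities(tokens, tagger, model, config)
      # surfaces verbatim from the report, not token-joined
      if (nrow(entities) > 0) {
        entities$surface <- substring(report$raw_text, entities$start,
                                      entities$end)
      }
      sent_frames <- list()
      sub_entities <- list()
      for (k in seq_len(nrow(subs))) {
        n_frames <- n_frames + 1L
        fr <- link_descriptors(
          subs[k, ], mentions, entities, refs, scope_refs,
          doc_id = report$doc_id, sentence_id = sent_counter,
          frame_id = paste0(report$doc_id, ".", n_frames)
        )
        sent_frames[[k]] <- fr
        keep <- vapply(seq_len(nrow(entities)), function(r) {
          .entity_in_span(entities, r, subs$start[k], subs$end[k])
        }, logical(1))
        sub_entities[[k]] <- entities[keep, , drop = FALSE]
      }
      # prior frames inherit AE/IO from their paired current sub-sentence
      for (k in seq_len(nrow(subs))) {
        fr <- sent_frames[[k]]
        if (fr$temporality != "PRIOR") next
        if (length(fr$anatomical_entity) > 0 &&
            length(fr$imaging_observation) > 0) next
        cur <- rev(which(mentions$temporality[subs$mention_index] ==
                           "CURRENT" & seq_len(nrow(subs)) < k))
        if (length(cur) == 0) next
        j <- cur[1]
        m_end <- mentions$end[subs$mention_index[j]]
        donor <- sub_entities[[j]]
        donor <- donor[donor$start > m_end, , drop = FALSE]
        if (length(fr$anatomical_entity) == 0) {
          fr$anatomical_entity <-
            donor$surface[donor$type == "ANATOMICAL_ENTITY"]
        }
        if (length(fr$imaging_observation) == 0) {
          fr$imaging_observation <-
            donor$surface[donor$type == "IMAGING_OBSERVATION"]
        }
        sent_frames[[k]] <- fr
      }
      frames <- c(frames, sent_frames)
    }
  }
  frames
}

# --- serialization -----------------------------------------------------------

.frame_to_list <- function(fr) {
  list(
    schema = .frame_schema_version,
    frame_id = fr$frame_id,
    doc_id = fr$doc_id,
    sentence_id = fr$sentence_id,
    measurement = list(
      surface = fr$measurement$surface,
      start = fr$measurement$start,
      end = fr$measurement$end,
      dims = lapply(seq_len(nrow(fr$measurement$dims)), function(i) {
        as.list(fr$measurement$dims[i, ])
      })
    ),
    temporality = fr$temporality,
    anatomical_entity = as.list(fr$anatomical_entity),
    imaging_observation = as.list(fr$imaging_observation),
    radlex_descriptor = as.list(fr$radlex_descriptor),
    image_number = fr$image_number,
    series_number = fr$series_number,
    segment = fr$segment
  )
}

.frame_from_list <- function(x) {
  dims <- do.call(rbind, lapply(x$measurement$dims, function(d) {
    data.frame(value = as.numeric(d$value), unit = as.character(d$unit),
               start = as.integer(d$start), end = as.integer(d$end),
               stringsAsFactors = FALSE)
  }))
  num <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  chr <- function(v) as.character(unlist(v))
  new_frame(
    frame_id = x$frame_id, doc_id = x$doc_id, sentence_id = x$sentence_id,
    surface = x$measurement$surface, start = x$measurement$start,
    end = x$measurement$end, dims = dims, temporality = x$temporality,
    anatomical_entity = chr(x$anatomical_entity),
    imaging_observation = chr(x$imaging_observation),
    radlex_descriptor = chr(x$radlex_descriptor),
    image_number = num(x$image_number),
    series_number = num(x$series_number),
    segment = num(x$segment)
  )
}

#' Write frames as JSON lines
#'
#' One frame per line, schema-versioned, UTF-8; the round trip through
#' [read_frames()] is lossless.
#'
#' @param frames A list of `measurement_frame` objects.
#' @param path Output file; if `NULL`, the JSON lines are returned as a
#'   character vector.
#' @return `path` (or the lines), invisibly when writing.
#' @export
serialize_frames <- function(frames, path = NULL) {
  lines <- vapply(frames, function(fr) {
    as.character(jsonlite::toJSON(.frame_to_list(fr), auto_unbox = TRUE,
                                  null = "null", na = "null", digits = NA))
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read frames from JSON lines
#' @param path File written by [serialize_frames()] (or a character vector
#'   of JSON lines).
#' @return A list of `measurement_frame` objects.
#' @export
read_frames <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readLines(path, encoding = "UTF-8")
  } else {
    path
  }
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    .frame_from_list(jsonlite::fromJSON(ln, simplifyVector = FALSE))
  })
}

#' Flatten frames to a data.frame
#'
#' One row per frame; list-valued descriptor slots are joined with `"|"`.
#' Convenient for CSV export and inspection.
#'
#' @param frames A list of `measurement_frame` objects.
#' @return A data.frame.
#' @export
frames_to_table <- function(frames) {
  if (length(frames) == 0) {
    return(data.frame(frame_id = character(), doc_id = character(),
                      sentence_id = integer(), surface = character(),
                      values = character(), unit = character(),
                      temporality = character(),
                      anatomical_entity = character(),
                      imaging_observation = character(),
                      radlex_descriptor = character(),
                      image_number = integer(), series_number = integer(),
                      segment = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(frames, function(fr) {
    data.frame(
      frame_id = fr$frame_id, doc_id = fr$doc_id,
      sentence_id = fr$sentence_id,
      surface = fr$measurement$surface,
      values = paste(fr$measurement$dims$value, collapse = "x"),
      unit = fr$measurement$dims$unit[nrow(fr$measurement$dims)],
      temporality = fr$temporality,
      anatomical_entity = paste(fr$anatomical_entity, collapse = "|"),
      imaging_observation = paste(fr$imaging_observation, collapse = "|"),
      radlex_descriptor = paste(fr$radlex_descriptor, collapse = "|"),
      image_number = fr$image_number, series_number = fr$series_number,
      segment = fr$segment, stringsAsFactors = FALSE
    )
  }))
}
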