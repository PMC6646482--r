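# Seeded generator of Findings-style sentences and reports with paired
# gold annotations (frames, standoff entity spans, BIO tokens).  The
# generator's closed vocabulary is the package lexicon, so brute-force
# oracles over the grammar are feasible; surface variants (pluralization,
# benign typos) are the only source of out-of-lexicon forms.

#' Synthetic corpus configuration
#'
#' Defines the study conditions the generator emulates: how many reports,
#' how many measurements per sentence, how often a measurement carries a
#' prior reference, the dimension-count and unit mixes, and the rate of
#' out-of-lexicon surface variants.  Defaults are chosen once to mirror a
#' routine cross-sectional oncology follow-up corpus: mostly
#' single-measurement sentences, roughly a third of mentions historical,
#' mostly one-dimensional sizes.
#'
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the config.
#' @param n_reports Number of reports.
#' @param sentences_per_report Named probability vector over sentence
#'   counts per report.
#' @param measurements_per_sentence Named probability vector over the
#'   number of measured lesions per sentence (prior references add further
#'   mentions).
#' @param prior_pair_probability Probability that a lesion carries a
#'   "previously N mm" prior measurement (0.45 makes ~31% of all mentions
#'   historical).
#' @param dims_per_measurement Named probability vector over 1-3
#'   dimensions.
#' @param unit_mix Named probability vector over `mm`/`cm`.
#' @param variant_rate Probability that an entity surface is realized as an
#'   out-of-lexicon variant (plural or benign typo).
#' @param p_series_prefix Probability of a sentence-initial shared series
#'   reference ("On series 11, ...").
#' @param p_image,p_series,p_segment Per-lesion probabilities of image,
#'   series and segment references.
#' @param lexicons Entity lexicons (see [default_lexicons()]).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 42L,
                         n_reports = 100L,
                         sentences_per_report =
                           c("1" = 0.25, "2" = 0.35, "3" = 0.25, "4" = 0.15),
                         measurements_per_sentence =
                           c("1" = 0.75, "2" = 0.20, "3" = 0.05),
                         prior_pair_probability = 0.45,
                         dims_per_measurement =
                           c("1" = 0.70, "2" = 0.25, "3" = 0.05),
                         unit_mix = c(mm = 0.55, cm = 0.45),
                         variant_rate = 0.10,
                         p_series_prefix = 0.20,
                         p_image = 0.60,
                         p_series = 0.35,
                         p_segment = 0.15,
                         lexicons = default_lexicons()) {
  cfg <- structure(
    list(seed = as.integer(seed), n_reports = as.integer(n_reports),
         sentences_per_report = sentences_per_report,
         measurements_per_sentence = measurements_per_sentence,
         prior_pair_probability = prior_pair_probability,
         dims_per_measurement = dims_per_measurement,
         unit_mix = unit_mix, variant_rate = variant_rate,
         p_series_prefix = p_series_prefix, p_image = p_image,
         p_series = p_series, p_segment = p_segment, lexicons = lexicons),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' @rdname synth_config
#' @export
validate_synth_config <- function(config) {
  probs <- c(config$prior_pair_probability, config$variant_rate,
             config$p_series_prefix, config$p_image, config$p_series,
             config$p_segment)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (d in c("sentences_per_report", "measurements_per_sentence",
              "dims_per_measurement", "unit_mix")) {
    v <- config[[d]]
    if (any(v < 0) || abs(sum(v) - 1) > 1e-8) {
      stop(d, " must be a probability distribution summing to 1",
           call. = FALSE)
    }
  }
  if (config$n_reports < 0) stop("n_reports must be >= 0", call. = FALSE)
  invisible(config)
}

.rcat <- function(dist) {
  as.integer(sample(names(dist), 1L, prob = dist))
}

.pluralize <- function(w) {
  if (grepl("(s|x|ch|sh)$", w)) return(paste0(w, "es"))
  if (grepl("[^aeiou]y$", w)) return(sub("y$", "ies", w))
  paste0(w, "s")
}

# benign typo: double a middle letter
.typo <- function(w) {
  if (nchar(w) < 4) return(w)
  i <- sample(2:(nchar(w) - 1L), 1L)
  paste0(substring(w, 1, i), substring(w, i, nchar(w)))
}

.variant <- function(w, rate, plural_ok = TRUE) {
  if (stats::runif(1) >= rate) return(w)
  if (plural_ok && stats::runif(1) < 0.67) .pluralize(w) else .typo(w)
}

.make_size <- function(ndim, unit) {
  one <- function() {
    if (unit == "mm") as.character(sample(2:35, 1L))
    else sprintf("%.1f", stats::runif(1, 0.5, 9.9))
  }
  if (ndim == 1L && stats::runif(1) < 0.05) {
    a <- sample(2:30, 1L)
    return(paste0(a, "-", a + sample(1:3, 1L), " ", unit))
  }
  vals <- vapply(seq_len(ndim), function(i) one(), character(1))
  if (ndim == 2L && stats::runif(1) < 0.3) {
    paste0(vals[1], " ", unit, " x ", vals[2], " ", unit)
  } else {
    paste0(paste(vals, collapse = " x "), " ", unit)
  }
}

# sentence text builder with span tracking (1-based inclusive)
.new_buf <- function() {
  e <- new.env(parent = emptyenv())
  e$text <- ""
  e$pos <- 0L
  e
}
.emit <- function(buf, s) {
  start <- buf$pos + 1L
  buf$text <- paste0(buf$text, s)
  buf$pos <- buf$pos + nchar(s)
  c(start = start, end = buf$pos)
}

#' Generate one synthetic Findings sentence with gold annotations
#'
#' Draws a sentence from the template grammar (measurement-first,
#' observation-first, optional prior parenthetical, optional shared series
#' prefix), using the current RNG state.  Every measurement, entity and
#' scan reference is recorded with its exact span, and one gold frame per
#' measurement carries all seven descriptor slots as instantiated; a
#' sentence-initial modifier pair (as in "scattered enhancing nodules ...,
#' for example ...") is assigned to every gold frame of the sentence.
#'
#' @param config A [synth_config()] object.
#' @return A list with `text`, `mentions` (data.frame `start`, `end`,
#'   `surface`, `temporality`), `entities` (standoff data.frame `start`,
#'   `end`, `label`, `surface` — entity types plus rule-tagged
#'   `MEASUREMENT`/`IMAGE`/`SERIES`/`SEGMENT` spans), `frames` (gold
#'   frames with sentence-local coordinates).
#' @export
generate_sentence <- function(config = synth_config()) {
  lex <- config$lexicons
  buf <- .new_buf()
  mentions <- data.frame(start = integer(), end = integer(),
                         temporality = character(),
                         stringsAsFactors = FALSE)
  entities <- data.frame(start = integer(), end = integer(),
                         label = character(), stringsAsFactors = FALSE)
  add_ent <- function(span, label) {
    entities[nrow(entities) + 1L, ] <<-
      list(span[["start"]], span[["end"]], label)
  }
  add_mention <- function(span, temporality) {
    mentions[nrow(mentions) + 1L, ] <<-
      list(span[["start"]], span[["end"]], temporality)
    add_ent(span, "MEASUREMENT")
  }
  frames <- list()
  n_sites <- .rcat(config$measurements_per_sentence)
  shared_series <- NA_integer_
  shared_rd <- character(0)
  shared_io <- character(0)
  if (stats::runif(1) < config$p_series_prefix) {
    shared_series <- sample(1:20, 1L)
    .emit(buf, "On ")
    add_ent(.emit(buf, paste0("series ", shared_series)), "SERIES")
    .emit(buf, ", ")
    rd0 <- sample(lex$radlex_descriptor, 1L)
    io0 <- .variant(sample(lex$imaging_observation, 1L),
                    config$variant_rate)
    rd0_span <- .emit(buf, rd0); add_ent(rd0_span, "RADLEX_DESCRIPTOR")
    .emit(buf, " ")
    io0_span <- .emit(buf, io0); add_ent(io0_span, "IMAGING_OBSERVATION")
    .emit(buf, " noted, for example ")
    shared_rd <- rd0
    shared_io <- io0
  }
  for (i in seq_len(n_sites)) {
    if (i > 1L) .emit(buf, if (i == n_sites) ", and " else ", ")
    style <- if (stats::runif(1) < 0.6) "A" else "B"
    unit <- names(config$unit_mix)[
      sample(seq_along(config$unit_mix), 1L, prob = config$unit_mix)]
    ndim <- .rcat(config$dims_per_measurement)
    size_s <- .make_size(ndim, unit)
    has_prior <- stats::runif(1) < config$prior_pair_probability
    rd <- if (stats::runif(1) < 0.4) {
      .variant(sample(lex$radlex_descriptor, 1L), config$variant_rate,
               plural_ok = FALSE)
    } else {
      character(0)
    }
    ae <- sample(lex$anatomical_entity, 1L)
    io <- .variant(sample(lex$imaging_observation, 1L),
                   config$variant_rate)
    seg <- if (stats::runif(1) < config$p_segment) sample(1:8, 1L) else
      NA_integer_
    img <- if (stats::runif(1) < config$p_image) sample(20:400, 1L) else
      NA_integer_
    ser <- if (is.na(shared_series) &&
               stats::runif(1) < config$p_series) sample(1:20, 1L) else
      NA_integer_
    m_span <- NULL
    if (style == "A") {
      m_span <- .emit(buf, size_s)
      .emit(buf, " ")
      if (length(rd) > 0) {
        add_ent(.emit(buf, rd), "RADLEX_DESCRIPTOR")
        .emit(buf, " ")
      }
      add_ent(.emit(buf, ae), "ANATOMICAL_ENTITY")
      .emit(buf, " ")
      add_ent(.emit(buf, io), "IMAGING_OBSERVATION")
      if (!is.na(seg)) {
        .emit(buf, " in ")
        add_ent(.emit(buf, paste0("segment ", seg)), "SEGMENT")
      }
    } else {
      if (length(rd) > 0) {
        add_ent(.emit(buf, rd), "RADLEX_DESCRIPTOR")
        .emit(buf, " ")
      }
      add_ent(.emit(buf, io), "IMAGING_OBSERVATION")
      .emit(buf, " in the ")
      add_ent(.emit(buf, ae), "ANATOMICAL_ENTITY")
      if (!is.na(seg)) {
        .emit(buf, " ")
        add_ent(.emit(buf, paste0("segment ", seg)), "SEGMENT")
      }
      .emit(buf, " measures ")
      m_span <- .emit(buf, size_s)
    }
    add_mention(m_span, "CURRENT")
    p_span <- NULL
    if (!is.na(img) || !is.na(ser) || has_prior) {
      .emit(buf, " (")
      first <- TRUE
      if (!is.na(img)) {
        add_ent(.emit(buf, paste0("image ", img)), "IMAGE")
        first <- FALSE
      }
      if (!is.na(ser)) {
        if (!first) .emit(buf, ", ")
        add_ent(.emit(buf, paste0("series ", ser)), "SERIES")
        first <- FALSE
      }
      if (has_prior) {
        if (!first) .emit(buf, ", ")
        .emit(buf, "previously ")
        p_span <- .emit(buf, .make_size(1L, unit))
        add_mention(p_span, "PRIOR")
      }
      .emit(buf, ")")
    }
    series_i <- if (!is.na(shared_series)) shared_series else ser
    site_frame <- function(span, temporality) {
      surface <- substring(buf$text, span[["start"]], span[["end"]])
      tm <- tag_measurements(surface)
      stopifnot(nrow(tm) == 1L)
      dims <- tm$dims[[1]]
      dims$start <- dims$start + span[["start"]] - 1L
      dims$end <- dims$end + span[["start"]] - 1L
      is_prior <- temporality == "PRIOR"
      new_frame(
        frame_id = "tmp", doc_id = "tmp", sentence_id = 1L,
        surface = surface, start = span[["start"]], end = span[["end"]],
        dims = dims, temporality = temporality,
        anatomical_entity = ae,
        imaging_observation = c(io, shared_io),
        radlex_descriptor = c(if (!is_prior) rd else character(0),
                              shared_rd),
        image_number = if (is_prior) NA_integer_ else img,
        series_number = if (is_prior) {
          if (!is.na(shared_series)) shared_series else NA_integer_
        } else {
          series_i
        },
        segment = if (is_prior) NA_integer_ else seg
      )
    }
    frames[[length(frames) + 1L]] <- site_frame(m_span, "CURRENT")
    if (has_prior) {
      frames[[length(frames) + 1L]] <- site_frame(p_span, "PRIOR")
    }
  }
  .emit(buf, ".")
  text <- buf$text
  # sentence-initial capitalization (entity matching is case-insensitive)
  substring(text, 1, 1) <- toupper(substring(text, 1, 1))
  fill <- function(df) {
    df$surface <- substring(text, df$start, df$end)
    df
  }
  mentions <- fill(mentions)
  entities <- fill(entities)
  for (k in seq_along(frames)) {
    frames[[k]]$measurement$surface <- substring(
      text, frames[[k]]$measurement$start, frames[[k]]$measurement$end)
  }
  list(text = text, mentions = mentions, entities = entities,
       frames = frames)
}

.report_prefix <- paste0(
  "EXAM: CT chest, abdomen and pelvis with contrast.\n\n",
  "CLINICAL HISTORY: Follow-up of known malignancy.\n\n",
  "COMPARISON: Prior outside study.\n\n",
  "TECHNIQUE: Axial images were obtained after intravenous contrast.\n\n",
  "FINDINGS: ")
.report_suffix <- "\n\nIMPRESSION: Findings as described above."

#' Generate a synthetic gold corpus
#'
#' Produces `n_reports` section-headed reports whose Findings bodies come
#' from [generate_sentence()], together with three mutually consistent
#' gold views: frames (JSONL), standoff entity annotations per sentence
#' (JSONL) and token-level BIO (TSV).  The whole corpus is a deterministic
#' function of the config (including its seed).
#'
#' @param config A [synth_config()] object.
#' @param dir Optional output directory; when given, writes
#'   `reports/<doc_id>.txt`, `gold_frames.jsonl`, `standoff.jsonl`,
#'   `corpus_bio.tsv` and `manifest.json`.
#' @return A list of class `"gold_corpus"`: `reports` (list of
#'   `doc_id`/`text`), `frames` (gold frames, document coordinates),
#'   `standoff` (sentence records, sentence-local coordinates), `config`.
#' @export
generate_corpus <- function(config = synth_config(), dir = NULL) {
  validate_synth_config(config)
  set.seed(config$seed)
  reports <- list()
  frames <- list()
  standoff <- list()
  for (r in seq_len(config$n_reports)) {
    doc_id <- sprintf("synth%04d", r)
    n_sent <- .rcat(config$sentences_per_report)
    sents <- lapply(seq_len(n_sent), function(i) {
      generate_sentence(config)
    })
    body <- paste(vapply(sents, `[[`, character(1), "text"),
                  collapse = " ")
    text <- paste0(.report_prefix, body, .report_suffix)
    off <- nchar(.report_prefix) + 1L
    fcount <- 0L
    for (i in seq_along(sents)) {
      s <- sents[[i]]
      shift <- off - 1L
      for (fr in s$frames) {
        fcount <- fcount + 1L
        fr$frame_id <- sprintf("%s.%d", doc_id, fcount)
        fr$doc_id <- doc_id
        fr$sentence_id <- i
        fr$measurement$start <- fr$measurement$start + shift
        fr$measurement$end <- fr$measurement$end + shift
        fr$measurement$dims$start <- fr$measurement$dims$start + shift
        fr$measurement$dims$end <- fr$measurement$dims$end + shift
        frames[[length(frames) + 1L]] <- fr
      }
      ents <- s$entities
      standoff[[length(standoff) + 1L]] <- list(
        doc_id = doc_id, sentence_id = i, text = s$text,
        entities = ents[, c("start", "end", "label", "surface")]
      )
      off <- off + nchar(s$text) + 1L  # single space joiner
    }
    reports[[length(reports) + 1L]] <- list(doc_id = doc_id, text = text)
  }
  corpus <- structure(
    list(reports = reports, frames = frames, standoff = standoff,
         config = config),
    class = "gold_corpus")
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}

#' @export
print.gold_corpus <- function(x, ...) {
  cat("<gold_corpus> ", length(x$reports), " report(s), ",
      length(x$standoff), " sentence(s), ", length(x$frames),
      " gold frame(s), seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a gold corpus to disk
#'
#' @param corpus A `"gold_corpus"` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  for (rep in corpus$reports) {
    writeLines(rep$text, file.path(dir, "reports",
                                   paste0(rep$doc_id, ".txt")),
               useBytes = TRUE)
  }
  serialize_frames(corpus$frames, file.path(dir, "gold_frames.jsonl"))
  write_standoff(corpus$standoff, file.path(dir, "standoff.jsonl"))
  write_bio(standoff_to_bio(corpus$standoff),
            file.path(dir, "corpus_bio.tsv"))
  manifest <- lapply(corpus$reports, function(rep) {
    list(doc_id = rep$doc_id,
         path = file.path("reports", paste0(rep$doc_id, ".txt")))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Degrade gold annotations to simulate uncorrected pre-annotation
#'
#' Light annotation bootstraps a corpus by automatic dictionary
#' pre-annotation followed by manual correction; this helper simulates the
#' *uncorrected* state by randomly dropping entity annotations (and
#' optionally shifting span ends by one character), to study the sequence
#' model's robustness to noisy training gold.
#'
#' @param standoff A standoff list.
#' @param drop_rate Probability of dropping each entity.
#' @param shift_rate Probability of shifting a surviving entity's end
#'   inward by one character.
#' @param seed Optional seed (uses the current RNG state when `NULL`).
#' @return The degraded standoff list.
#' @export
corrupt_for_light_annotation <- function(standoff, drop_rate,
                                         shift_rate = 0, seed = NULL) {
  stopifnot(drop_rate >= 0, drop_rate <= 1,
            shift_rate >= 0, shift_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(standoff, function(s) {
    ents <- s$entities
    if (nrow(ents) > 0) {
      keep <- stats::runif(nrow(ents)) >= drop_rate
      ents <- ents[keep, , drop = FALSE]
      if (nrow(ents) > 0 && shift_rate > 0) {
        shift <- stats::runif(nrow(ents)) < shift_rate &
          ents$end > ents$start
        ents$end[shift] <- ents$end[shift] - 1L
        ents$surface[shift] <- substring(s$text, ents$start[shift],
                                         ents$end[shift])
      }
    }
    s$entities <- ents
    s
  })
}
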