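# Training-corpus formats.
#
# Standoff JSONL: one object per sentence,
#   {"doc_id": ..., "sentence_id": ..., "text": ...,
#    "entities": [{"start":, "end":, "label":, "surface":}, ...]}
# with 1-based inclusive character offsets into "text".
#
# BIO TSV: token TAB label per line, blank line between sentences.

.empty_entities <- function() {
  data.frame(start = integer(), end = integer(), label = character(),
             surface = character(), stringsAsFactors = FALSE)
}

#' Write / read standoff annotations
#'
#' @param standoff A list of sentence records; each has `doc_id`,
#'   `sentence_id`, `text` and an `entities` data.frame with columns
#'   `start`, `end`, `label`, `surface` (offsets into `text`).
#' @param path File path (JSON lines).
#' @return `write_standoff` returns `path` invisibly; `read_standoff`
#'   returns the standoff list.
#' @export
write_standoff <- function(standoff, path) {
  lines <- vapply(standoff, function(s) {
    ents <- lapply(seq_len(nrow(s$entities)), function(i) {
      as.list(s$entities[i, c("start", "end", "label", "surface")])
    })
    as.character(jsonlite::toJSON(
      list(doc_id = s$doc_id, sentence_id = s$sentence_id, text = s$text,
           entities = ents),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_standoff
#' @export
read_standoff <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    ents <- if (length(x$entities) == 0) .empty_entities() else {
      do.call(rbind, lapply(x$entities, function(e) {
        data.frame(start = as.integer(e$start), end = as.integer(e$end),
                   label = as.character(e$label),
                   surface = as.character(e$surface),
                   stringsAsFactors = FALSE)
      }))
    }
    list(doc_id = as.character(x$doc_id),
         sentence_id = as.integer(x$sentence_id),
         text = as.character(x$text), entities = ents)
  })
}

#' Convert standoff annotations to token-level BIO
#'
#' Tokenizes every sentence and projects its entity spans onto the tokens.
#'
#' @param standoff A standoff list (see [write_standoff()]).
#' @param keep_labels Optional character vector of entity labels to keep
#'   (others become `O`).
#' @return A list with `tokens` (list of token data.frames), `labels`
#'   (list of BIO label vectors) and `meta` (data.frame of doc/sentence
#'   ids).
#' @export
standoff_to_bio <- function(standoff, keep_labels = NULL) {
  tokens <- list()
  labels <- list()
  meta <- data.frame(doc_id = character(), sentence_id = integer(),
                     stringsAsFactors = FALSE)
  for (s in standoff) {
    toks <- tokenize_and_pos(s$text)
    ents <- s$entities
    if (!is.null(keep_labels)) {
      ents <- ents[ents$label %in% keep_labels, , drop = FALSE]
    }
    labs <- entities_to_labels(
      toks, data.frame(type = ents$label, start = ents$start,
                       end = ents$end, stringsAsFactors = FALSE))
    tokens[[length(tokens) + 1L]] <- toks
    labels[[length(labels) + 1L]] <- labs
    meta[nrow(meta) + 1L, ] <- list(s$doc_id, s$sentence_id)
  }
  list(tokens = tokens, labels = labels, meta = meta)
}

#' Write / read a BIO TSV corpus
#'
#' @param bio A list with `tokens` and `labels` as from
#'   [standoff_to_bio()].
#' @param path File path.
#' @return `write_bio` returns `path` invisibly; `read_bio` returns a list
#'   with `tokens` (surfaces retokenized with [tokenize_and_pos()] on the
#'   space-joined sentence) and `labels`.
#' @export
write_bio <- function(bio, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(bio$tokens)) {
    writeLines(paste(bio$tokens[[i]]$surface, bio$labels[[i]], sep = "\t"),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_bio
#' @export
read_bio <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  tokens <- list()
  labels <- list()
  cur_s <- character(0)
  cur_l <- character(0)
  flush <- function() {
    if (length(cur_s) > 0) {
      text <- paste(cur_s, collapse = " ")
      toks <- tokenize_and_pos(text)
      stopifnot(nrow(toks) == length(cur_l))
      tokens[[length(tokens) + 1L]] <<- toks
      labels[[length(labels) + 1L]] <<- cur_l
      cur_s <<- character(0)
      cur_l <<- character(0)
    }
  }
  for (ln in lines) {
    if (!nzchar(ln)) {
      flush()
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      cur_s <- c(cur_s, parts[1])
      cur_l <- c(cur_l, parts[2])
    }
  }
  flush()
  list(tokens = tokens, labels = labels)
}

#' Train the pipeline's entity CRF from standoff annotations
#'
#' Convenience wrapper around [featurize()] and [crf()]: tokenizes every
#' sentence, builds feature sequences and BIO label sequences, and fits
#' the sequence model with the config's CRF options.
#'
#' @param standoff A standoff list (see [write_standoff()]).
#' @param config A [lex_config()] object.
#' @param labels Declared BIO label set (default: the three entity types;
#'   use `bio_label_set(extended = TRUE)` for transition-score analysis
#'   over all rule-tagged categories).
#' @return A fitted `"crf"` model.
#' @export
train_crf <- function(standoff, config = lex_config(),
                      labels = bio_label_set()) {
  bio <- standoff_to_bio(
    standoff,
    keep_labels = unique(sub("^[BI]-", "",
                             setdiff(labels, "O"))))
  x <- lapply(bio$tokens, featurize, lexicons = config$lexicons,
              window = config$crf$window)
  crf(x, bio$labels, labels = labels, l2 = config$crf$l2,
      maxit = config$crf$maxit)
}
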