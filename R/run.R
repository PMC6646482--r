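# Workflow entry points wrapped by the command-line script
# (inst/cli/lesionext): extract, train, eval, synth.  Each function is a
# thin orchestration layer over the package's core operations and returns
# its main artifact invisibly, so the CLI only has to parse arguments and
# map errors to exit codes.

# Resolve an extract input argument to a data.frame doc_id/path.
.resolve_inputs <- function(input) {
  if (length(input) == 1 && dir.exists(input)) {
    manifest <- file.path(input, "manifest.json")
    if (file.exists(manifest)) {
      m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
      return(data.frame(
        doc_id = vapply(m, `[[`, character(1), "doc_id"),
        path = file.path(input, vapply(m, `[[`, character(1), "path")),
        stringsAsFactors = FALSE
      ))
    }
    files <- list.files(input, pattern = "\\.txt$", full.names = TRUE)
    return(data.frame(
      doc_id = tools::file_path_sans_ext(basename(files)),
      path = files, stringsAsFactors = FALSE
    ))
  }
  data.frame(doc_id = tools::file_path_sans_ext(basename(input)),
             path = input, stringsAsFactors = FALSE)
}

#' Extract measurement frames from report files
#'
#' Runs the full pipeline over one or more plain-text reports (one report
#' per file, UTF-8) and writes the resulting frames as JSON lines.  A
#' directory input is expanded through its `manifest.json` (doc_id to path
#' map) when present, else through every `.txt` file it contains.
#'
#' @param input File path(s), or a directory of reports.
#' @param output Output JSONL path.
#' @param tagger `"dictionary"` or `"crf"`.
#' @param model Path to a model file from [run_train()]/[crf_save()]
#'   (required for `tagger = "crf"`).
#' @param config A [lex_config()] object or path to a JSON config.
#' @return Invisibly, the list of extracted frames.
#' @export
run_extract <- function(input, output, tagger = c("dictionary", "crf"),
                        model = NULL, config = lex_config()) {
  tagger <- match.arg(tagger)
  if (is.character(config)) config <- load_config(config)
  crf_model <- NULL
  if (tagger == "crf") {
    if (is.null(model)) {
      stop("tagger = \"crf\" requires a --model file", call. = FALSE)
    }
    crf_model <- crf_load(model)
  }
  docs <- .resolve_inputs(input)
  frames <- list()
  for (i in seq_len(nrow(docs))) {
    if (!file.exists(docs$path[i])) {
      stop("input not readable for doc '", docs$doc_id[i], "': ",
           docs$path[i], call. = FALSE)
    }
    text <- paste(readLines(docs$path[i], encoding = "UTF-8",
                            warn = FALSE), collapse = "\n")
    rep <- rad_report(text, doc_id = docs$doc_id[i], config = config)
    fr <- build_frames(rep, tagger = tagger, model = crf_model,
                       config = config)
    message(sprintf("%s: %d frame(s)", docs$doc_id[i], length(fr)))
    frames <- c(frames, fr)
  }
  serialize_frames(frames, output)
  invisible(frames)
}

#' Train the entity CRF from an annotated corpus
#'
#' Reads a standoff JSONL corpus (or a BIO TSV one), fits the CRF with the
#' config's training options and saves the model.
#'
#' @param corpus Path to `standoff.jsonl` or a `*.tsv` BIO corpus.
#' @param model_out Output model path.
#' @param config A [lex_config()] object or path to a JSON config.
#' @param labels Declared BIO label set.
#' @return Invisibly, the fitted model.
#' @export
run_train <- function(corpus, model_out, config = lex_config(),
                      labels = bio_label_set()) {
  if (is.character(config)) config <- load_config(config)
  if (!file.exists(corpus)) {
    stop("corpus not found: ", corpus, call. = FALSE)
  }
  if (grepl("\\.tsv$", corpus)) {
    bio <- read_bio(corpus)
    if (length(bio$tokens) == 0) stop("empty corpus", call. = FALSE)
    x <- lapply(bio$tokens, featurize, lexicons = config$lexicons,
                window = config$crf$window)
    # categories outside the declared label set are not the model's task
    y <- lapply(bio$labels, function(l) ifelse(l %in% labels, l, "O"))
    model <- crf(x, y, labels = labels, l2 = config$crf$l2,
                 maxit = config$crf$maxit)
  } else {
    standoff <- read_standoff(corpus)
    if (length(standoff) == 0) stop("empty corpus", call. = FALSE)
    model <- train_crf(standoff, config, labels)
  }
  crf_save(model, model_out)
  message(sprintf("trained on %d sentence(s); %d feature(s); saved to %s",
                  model$n_sentences, length(model$features), model_out))
  invisible(model)
}

#' Evaluate system frames against gold frames
#'
#' Scores a frames JSONL file against a gold frames JSONL file and writes
#' the per-descriptor metric table (`<out_prefix>_metrics.csv`) and the
#' per-frame match classification (`<out_prefix>_matches.csv`).
#'
#' @param system_frames,gold_frames Paths to frames JSONL files.
#' @param out_prefix Output path prefix.
#' @return Invisibly, the [evaluate_frames()] result.
#' @export
run_eval <- function(system_frames, gold_frames, out_prefix = "eval") {
  sys <- read_frames(system_frames)
  gold <- read_frames(gold_frames)
  sys_docs <- unique(vapply(sys, `[[`, character(1), "doc_id"))
  gold_docs <- unique(vapply(gold, `[[`, character(1), "doc_id"))
  orphans <- setdiff(sys_docs, gold_docs)
  if (length(sys) > 0 && length(gold) > 0 && length(orphans) > 0) {
    stop("system doc_id(s) absent from gold: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  ev <- evaluate_frames(sys, gold)
  metrics <- ev$metrics
  metrics$precision <- round(metrics$precision, 2)
  metrics$recall <- round(metrics$recall, 2)
  metrics$f_score <- round(metrics$f_score, 2)
  utils::write.csv(metrics, paste0(out_prefix, "_metrics.csv"),
                   row.names = FALSE, na = "undefined")
  matches <- do.call(rbind, lapply(ev$matches, function(m) {
    data.frame(frame_id = m$frame_id, category = m$category,
               measurement_matched = m$measurement_matched,
               matched_descriptors = paste(m$matched_descriptors,
                                           collapse = "|"),
               missed_descriptors = paste(m$missed_descriptors,
                                          collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(matches)) {
    matches <- data.frame(frame_id = character(), category = character(),
                          measurement_matched = logical(),
                          matched_descriptors = character(),
                          missed_descriptors = character(),
                          stringsAsFactors = FALSE)
  }
  utils::write.csv(matches, paste0(out_prefix, "_matches.csv"),
                   row.names = FALSE)
  invisible(ev)
}

#' Generate a synthetic corpus on disk
#'
#' @param out_dir Output directory.
#' @param config A [synth_config()] object.
#' @param seed Optional seed override.
#' @return Invisibly, the generated corpus.
#' @export
run_synth <- function(out_dir, config = synth_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  corpus <- generate_corpus(config, dir = out_dir)
  message(sprintf("%d report(s), %d gold frame(s) written to %s",
                  length(corpus$reports), length(corpus$frames), out_dir))
  invisible(corpus)
}
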