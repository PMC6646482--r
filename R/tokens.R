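# --- tokenization and part of speech ----------------------------------------

.closed_class <- list(
  IN = c("in", "on", "of", "at", "with", "within", "to", "for", "by",
         "from", "near", "along", "through", "without"),
  DT = c("a", "an", "the", "this", "that", "these", "those", "no"),
  CC = c("and", "or", "but", "nor"),
  VB = c("is", "are", "was", "were", "be", "been", "measures", "measure",
         "measuring", "demonstrates", "demonstrate", "shows", "show",
         "seen", "noted", "identified", "appears", "appear", "remains",
         "remain", "has", "have", "represents"),
  RB = c("now", "currently", "previously", "today", "again", "not",
         "grossly", "most", "slightly", "mildly"),
  PRP = c("there", "it", "which")
)

# Deterministic rule-based coarse POS tagger (Penn-style tags).  Numbers ->
# CD; closed-class lookup; -ing/-ed -> VBG/VBN; -ly -> RB; common adjectival
# suffixes -> JJ; punctuation -> PUNCT; default NN.
.pos_tag <- function(surface) {
  w <- tolower(surface)
  if (grepl("^\\d+(\\.\\d+)?$", w)) return("CD")
  if (grepl("^[[:punct:]]+$", w)) return("PUNCT")
  for (tag in names(.closed_class)) {
    if (w %in% .closed_class[[tag]]) return(tag)
  }
  if (grepl("ing$", w)) return("VBG")
  if (grepl("ed$", w)) return("VBN")
  if (grepl("ly$", w)) return("RB")
  if (grepl("(ous|ive|al|ic|ar|ary|oid|ent|ense|dense|echoic|intense)$", w))
    return("JJ")
  "NN"
}

#' Tokenize text and assign part-of-speech tags
#'
#' Whitespace/punctuation-aware tokenizer: words (letters, with internal
#' hyphens/slashes kept, so `ground-glass` and `s/p` stay whole), numbers
#' (decimals kept whole, so `1.2` is one token), and individual punctuation
#' marks.  Spans index the input string so every token surface is
#' recoverable by `substring`.  POS tags come from a deterministic
#' rule-based tagger (coarse Penn-style tagset) — adequate as a CRF feature
#' source, which is its only role in this pipeline.
#'
#' @param text Text to tokenize (typically one sub-sentence).
#' @param offset Offset of `text` in the enclosing document.
#' @return A data.frame with columns `surface`, `start`, `end`, `pos`.
#' @examples
#' tokenize_and_pos("4 mm left frontal nodule")
#' @export
tokenize_and_pos <- function(text, offset = 1L) {
  out <- data.frame(surface = character(), start = integer(),
                    end = integer(), pos = character(),
                    stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text)) return(out)
  pat <- "\\d+(?:\\.\\d+)?|[A-Za-z]+(?:[-/][A-Za-z]+)*|[^\\sA-Za-z0-9]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    surface <- substring(text, starts[i], starts[i] + lens[i] - 1L)
    out[nrow(out) + 1L, ] <- list(surface, offset + starts[i] - 1L,
                                  offset + starts[i] + lens[i] - 2L,
                                  .pos_tag(surface))
  }
  out
}

# --- dictionary tagging ------------------------------------------------------

.lex_cache <- new.env(parent = emptyenv())

# Tokenized, lowercased lexicon phrases, longest first, with type priority
# anatomical_entity > imaging_observation > radlex_descriptor on duplicates.
# Compilation is cached on the lexicon object (tagging is called per
# sentence, often tens of thousands of times in one run).
.compile_lexicons <- function(lexicons) {
  if (!is.null(.lex_cache$lexicons) &&
      identical(.lex_cache$lexicons, lexicons)) {
    return(.lex_cache$entries)
  }
  entries <- .compile_lexicons_impl(lexicons)
  .lex_cache$lexicons <- lexicons
  .lex_cache$entries <- entries
  entries
}

.compile_lexicons_impl <- function(lexicons) {
  types <- c("anatomical_entity", "imaging_observation", "radlex_descriptor")
  entries <- list()
  seen <- character(0)
  for (ty in types) {
    for (phrase in lexicons[[ty]]) {
      key <- tolower(phrase)
      if (key %in% seen) next
      seen <- c(seen, key)
      toks <- tokenize_and_pos(key)$surface
      entries[[length(entries) + 1L]] <-
        list(type = toupper(ty), tokens = toks, n = length(toks))
    }
  }
  entries[order(-vapply(entries, `[[`, 1L, "n"))]
}

#' Dictionary-lookup entity tagging
#'
#' The baseline entity tagger (and the pre-annotator used to bootstrap
#' training corpora): greedy leftmost-longest, case-insensitive lookup of
#' lexicon phrases over the token sequence.  A longer phrase beats any
#' shorter phrase starting at the same token; output spans never overlap.
#'
#' @param tokens A token data.frame from [tokenize_and_pos()].
#' @param lexicons As returned by [default_lexicons()].
#' @return A data.frame with columns `type` (`ANATOMICAL_ENTITY`,
#'   `IMAGING_OBSERVATION`, `RADLEX_DESCRIPTOR`), `start`, `end`,
#'   `surface`, `first_token`, `last_token` (token indices).
#' @examples
#' toks <- tokenize_and_pos("left frontal nodule")
#' dictionary_tag(toks, default_lexicons())
#' @export
dictionary_tag <- function(tokens, lexicons = default_lexicons()) {
  out <- data.frame(type = character(), start = integer(), end = integer(),
                    surface = character(), first_token = integer(),
                    last_token = integer(), stringsAsFactors = FALSE)
  n <- nrow(tokens)
  if (n == 0) return(out)
  entries <- .compile_lexicons(lexicons)
  lower <- tolower(tokens$surface)
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (ent in entries) {
      j <- i + ent$n - 1L
      if (j > n) next
      if (identical(lower[i:j], ent$tokens)) {
        hit <- list(ent = ent, j = j)
        break  # entries sorted longest-first: first hit is the longest
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      j <- hit$j
      out[nrow(out) + 1L, ] <- list(
        hit$ent$type, tokens$start[i], tokens$end[j],
        NA_character_, i, j
      )
      i <- j + 1L
    }
  }
  out$surface <- vapply(seq_len(nrow(out)), function(r) {
    paste(tokens$surface[out$first_token[r]:out$last_token[r]],
          collapse = " ")
  }, character(1))
  out
}

# --- CRF features ------------------------------------------------------------

#' Token features for the sequence labeler
#'
#' Builds the per-token feature sets fed to the CRF: the lowercased word
#' form, POS tag, 3-character prefix/suffix, a digit flag, dictionary-map
#' flags (whether the token lies inside a leftmost-longest lexicon hit of
#' each type), and windowed context versions of the word/POS/dictionary
#' features for up to `window` neighbors on each side (missing context is
#' encoded with boundary sentinels).  No chunk or parse features are used.
#'
#' @param tokens Token data.frame from [tokenize_and_pos()].
#' @param lexicons As returned by [default_lexicons()].
#' @param window Context window size in tokens (default 2).
#' @return A list with one character vector of `name=value` features per
#'   token.
#' @export
featurize <- function(tokens, lexicons = default_lexicons(), window = 2L) {
  n <- nrow(tokens)
  if (n == 0) return(list())
  lower <- tolower(tokens$surface)
  pos <- tokens$pos
  dict <- rep("none", n)
  hits <- dictionary_tag(tokens, lexicons)
  for (r in seq_len(nrow(hits))) {
    rng <- hits$first_token[r]:hits$last_token[r]
    dict[rng] <- c(ANATOMICAL_ENTITY = "anat",
                   IMAGING_OBSERVATION = "obs",
                   RADLEX_DESCRIPTOR = "desc")[[hits$type[r]]]
  }
  at <- function(vec, idx) {
    if (idx < 1L) return(paste0("__BOS", 1L - idx, "__"))
    if (idx > n) return(paste0("__EOS", idx - n, "__"))
    vec[idx]
  }
  lapply(seq_len(n), function(t) {
    f <- c(
      "bias",
      paste0("w=", lower[t]),
      paste0("pos=", pos[t]),
      paste0("pre3=", substring(lower[t], 1L, 3L)),
      paste0("suf3=", substring(lower[t], max(1L, nchar(lower[t]) - 2L))),
      paste0("dict=", dict[t])
    )
    if (grepl("^\\d+(\\.\\d+)?$", lower[t])) f <- c(f, "isdigit")
    for (d in seq_len(window)) {
      f <- c(f,
             paste0("w[-", d, "]=", at(lower, t - d)),
             paste0("w[+", d, "]=", at(lower, t + d)),
             paste0("pos[-", d, "]=", at(pos, t - d)),
             paste0("pos[+", d, "]=", at(pos, t + d)),
             paste0("dict[-", d, "]=", at(dict, t - d)),
             paste0("dict[+", d, "]=", at(dict, t + d)))
    }
    unique(f)
  })
}

# --- BIO scheme --------------------------------------------------------------

#' Entity label set of the pipeline
#'
#' @param extended If `TRUE`, include the rule-tagged categories
#'   (`MEASUREMENT`, `IMAGE`, `SERIES`, `SEGMENT`, `TEMPORALITY`) used when
#'   training a model for label-transition analysis; otherwise only the
#'   three CRF entity categories.
#' @return Character vector of BIO labels, starting with `"O"`.
#' @export
bio_label_set <- function(extended = FALSE) {
  types <- c("ANATOMICAL_ENTITY", "IMAGING_OBSERVATION", "RADLEX_DESCRIPTOR")
  if (extended) {
    types <- c(types, "MEASUREMENT", "IMAGE", "SERIES", "SEGMENT",
               "TEMPORALITY")
  }
  c("O", paste0(rep(c("B-", "I-"), length(types)),
                rep(types, each = 2)))
}

#' Repair a label sequence to BIO validity
#'
#' An `I-X` token with no `B-X`/`I-X` immediately before it is rewritten to
#' `B-X`; this makes downstream entity extraction total.
#'
#' @param labels Character vector of BIO labels.
#' @return A valid BIO label vector.
#' @export
bio_repair <- function(labels) {
  if (length(labels) == 0) return(labels)
  for (t in seq_along(labels)) {
    if (!startsWith(labels[t], "I-")) next
    ty <- substring(labels[t], 3L)
    prev <- if (t == 1L) "O" else labels[t - 1L]
    if (!(prev %in% c(paste0("B-", ty), paste0("I-", ty)))) {
      labels[t] <- paste0("B-", ty)
    }
  }
  labels
}

#' Check BIO validity
#' @param labels Character vector of BIO labels.
#' @return `TRUE` if no `I-X` lacks a head.
#' @export
bio_valid <- function(labels) identical(labels, bio_repair(labels))

#' Convert a BIO label sequence to entity mentions
#'
#' Maximal `B-X (I-X)*` runs become one entity each.  The sequence is
#' repaired to BIO validity first.
#'
#' @param tokens Token data.frame aligned with `labels`.
#' @param labels Character vector of BIO labels, one per token.
#' @return A data.frame with columns `type`, `start`, `end`, `surface`,
#'   `first_token`, `last_token`.
#' @export
labels_to_entities <- function(tokens, labels) {
  stopifnot(nrow(tokens) == length(labels))
  labels <- bio_repair(labels)
  out <- data.frame(type = character(), start = integer(), end = integer(),
                    surface = character(), first_token = integer(),
                    last_token = integer(), stringsAsFactors = FALSE)
  t <- 1L
  while (t <= length(labels)) {
    if (startsWith(labels[t], "B-")) {
      ty <- substring(labels[t], 3L)
      j <- t
      while (j < length(labels) && labels[j + 1L] == paste0("I-", ty)) {
        j <- j + 1L
      }
      out[nrow(out) + 1L, ] <- list(
        ty, tokens$start[t], tokens$end[j],
        paste(tokens$surface[t:j], collapse = " "), t, j
      )
      t <- j + 1L
    } else {
      t <- t + 1L
    }
  }
  out
}

#' Convert entity mentions to a BIO label sequence
#'
#' Inverse of [labels_to_entities()]: tokens covered by an entity span get
#' `B-`/`I-` labels of its type; all others get `O`.  Entities whose span
#' does not align with token boundaries are snapped to the tokens they
#' overlap.
#'
#' @param tokens Token data.frame.
#' @param entities Data.frame with columns `type`, `start`, `end`.
#' @return Character vector of BIO labels, one per token.
#' @export
entities_to_labels <- function(tokens, entities) {
  labels <- rep("O", nrow(tokens))
  for (r in seq_len(nrow(entities))) {
    covered <- which(tokens$start <= entities$end[r] &
                     tokens$end >= entities$start[r])
    if (length(covered) == 0) next
    labels[covered[1]] <- paste0("B-", entities$type[r])
    if (length(covered) > 1) {
      labels[covered[-1]] <- paste0("I-", entities$type[r])
    }
  }
  labels
}
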