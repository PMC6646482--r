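# --- measurement grammar -----------------------------------------------------
#
# A measurement mention is 1-3 dimensions joined by "x"/"×".  Each dimension
# is a decimal or integer (optionally a range "4-5"), each may carry its own
# unit, and the final dimension must carry one; a trailing shared unit
# covers unitless earlier dimensions ("1.2 x 3.4 cm").

.num_re   <- "\\d+(?:\\.\\d+)?"
.range_re <- paste0(.num_re, "(?:\\s*-\\s*", .num_re, ")?")

.unit_re <- function(config) {
  paste0("(?:", paste(names(config$units), collapse = "|"), ")")
}

.mention_re <- function(config) {
  u <- .unit_re(config)
  dim_opt  <- paste0(.range_re, "(?:\\s*", u, "\\b)?")
  dim_unit <- paste0(.range_re, "\\s*", u, "\\b")
  paste0("(?<![\\w.])",
         "(?:", dim_opt, "\\s*[x×]\\s*){0,2}",
         dim_unit)
}

.canonical_unit <- function(surface, config) {
  s <- tolower(surface)
  for (pat in names(config$units)) {
    if (grepl(paste0("^(?:", pat, ")$"), s, perl = TRUE)) {
      return(unname(config$units[[pat]]))
    }
  }
  NA_character_
}

# Parse the dimensions inside one matched mention.  A range keeps the larger
# value; dimensions without their own unit take the mention's final unit.
.parse_dimensions <- function(surface, offset, config) {
  u <- .unit_re(config)
  dim_re <- paste0("(", .range_re, ")(\\s*(", u, ")\\b)?")
  m <- gregexpr(dim_re, surface, perl = TRUE, ignore.case = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  vals <- numeric(0); units <- character(0)
  dstart <- integer(0); dend <- integer(0)
  for (i in seq_along(starts)) {
    piece <- substring(surface, starts[i], starts[i] + lens[i] - 1L)
    numpart <- regmatches(piece, regexpr(.range_re, piece, perl = TRUE))
    nums <- as.numeric(strsplit(gsub("\\s", "", numpart), "-")[[1]])
    unit_m <- regexpr(paste0("(", u, ")\\s*$"), piece,
                      perl = TRUE, ignore.case = TRUE)
    unit <- if (unit_m > 0) {
      .canonical_unit(regmatches(piece, unit_m), config)
    } else {
      NA_character_
    }
    vals <- c(vals, max(nums))
    units <- c(units, unit)
    dstart <- c(dstart, offset + starts[i] - 1L)
    dend <- c(dend, offset + starts[i] + lens[i] - 2L)
  }
  units[is.na(units)] <- units[length(units)]
  data.frame(value = vals, unit = units, start = dstart, end = dend,
             stringsAsFactors = FALSE)
}

#' Tag measurement expressions in a sentence
#'
#' Finds every maximal lesion-size expression: one to three dimensions
#' (decimal, integer, or a range such as `4-5`), joined by `x`/`×`,
#' with per-dimension or trailing shared units in mm/cm (long unit names
#' accepted and normalized).  Matches are non-overlapping and returned in
#' document order; a multi-dimension form collapses into a single mention.
#' Temporality is unset (`NA`) at this stage; see [tag_temporality()].
#'
#' @param text Sentence text (raw, pre-normalization).
#' @param offset 1-based offset of `text` within the enclosing document
#'   (spans in the result are document coordinates when supplied).
#' @param config A [lex_config()] object.
#' @return A data.frame with one row per mention: `start`, `end`, `surface`,
#'   `temporality` (`NA`), and a list column `dims` of per-dimension
#'   data.frames (`value`, `unit`, `start`, `end`).
#' @examples
#' tag_measurements("1.2 x 3.4 x 2.0 cm mass")$dims[[1]]
#' @export
tag_measurements <- function(text, offset = 1L, config = lex_config()) {
  out <- data.frame(start = integer(), end = integer(),
                    surface = character(), temporality = character(),
                    stringsAsFactors = FALSE)
  out$dims <- list()
  m <- gregexpr(.mention_re(config), text, perl = TRUE,
                ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    surface <- substring(text, starts[i], starts[i] + lens[i] - 1L)
    # trim trailing whitespace the greedy joiner may have caught
    surface <- sub("\\s+$", "", surface)
    s <- offset + starts[i] - 1L
    e <- s + nchar(surface) - 1L
    dims <- .parse_dimensions(surface, s, config)
    row <- data.frame(start = s, end = e, surface = surface,
                      temporality = NA_character_,
                      stringsAsFactors = FALSE)
    row$dims <- list(dims)
    out <- rbind(out, row)
  }
  out
}

#' Label measurements as current or prior
#'
#' A measurement refers either to the current scan (`CURRENT`) or to an
#' earlier study (`PRIOR`).  The sentence is swept left to right: a prior
#' cue (`previously`, `prior`, `was`, `compared to`, `from <date>`, ...)
#' switches the running state to `PRIOR`, a current cue (`now`,
#' `currently`, `today`) switches it back, and a closing parenthesis or
#' semicolon resets it to the `CURRENT` default.  Each mention takes the
#' state in force at its start.  Cue lists are configurable.
#'
#' @param text Sentence text.
#' @param mentions Output of [tag_measurements()] on the same sentence.
#' @param offset Offset of `text` in the document (must match the one given
#'   to [tag_measurements()]).
#' @param config A [lex_config()] object.
#' @return `mentions` with the `temporality` column filled
#'   (`"CURRENT"`/`"PRIOR"`).
#' @examples
#' m <- tag_measurements("4 mm nodule (previously 7 mm)")
#' tag_temporality("4 mm nodule (previously 7 mm)", m)$temporality
#' @export
tag_temporality <- function(text, mentions, offset = 1L,
                            config = lex_config()) {
  if (nrow(mentions) == 0) return(mentions)
  events <- data.frame(pos = integer(), state = character(),
                       stringsAsFactors = FALSE)
  scan_cues <- function(patterns, state) {
    for (pat in patterns) {
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1) next
      events <<- rbind(events,
                       data.frame(pos = as.integer(m), state = state,
                                  stringsAsFactors = FALSE))
    }
  }
  scan_cues(config$prior_cues, "PRIOR")
  scan_cues(config$current_cues, "CURRENT")
  scan_cues(c("[);]"), "CURRENT")
  events <- events[order(events$pos), , drop = FALSE]
  for (i in seq_len(nrow(mentions))) {
    local_start <- mentions$start[i] - offset + 1L
    before <- events[events$pos < local_start, , drop = FALSE]
    mentions$temporality[i] <-
      if (nrow(before) == 0) "CURRENT" else before$state[nrow(before)]
  }
  mentions
}

#' Divide a sentence into sub-sentences, one per measurement
#'
#' Descriptor linking is scoped to sub-sentences: contiguous fragments that
#' partition the sentence, each owning exactly one measurement.  Between
#' two adjacent mentions the boundary is chosen, in order of preference:
#' (1) immediately before a prior cue when the right-hand mention is
#' `PRIOR`, so the cue stays with its prior measurement and a current
#' measurement keeps its parenthesized image reference; (2) after the last
#' closing parenthesis, else before the first opening parenthesis, in the
#' gap; (3) after the last comma or semicolon; (4) at the whitespace
#' nearest the gap midpoint.  A sentence with one current and one prior
#' mention thus yields a current part and a historical part.
#'
#' @param text Sentence text.
#' @param mentions Output of [tag_temporality()] (temporality must be set
#'   when prior-aware boundaries are wanted).
#' @param offset Offset of `text` in the document.
#' @param config A [lex_config()] object.
#' @return A data.frame with one row per mention: `start`, `end` (span of
#'   the sub-sentence, same coordinates as `mentions`), `mention_index`.
#' @export
divide_subsentences <- function(text, mentions, offset = 1L,
                                config = lex_config()) {
  stopifnot(nrow(mentions) > 0)
  n <- nchar(text)
  k <- nrow(mentions)
  if (k == 1L) {
    return(data.frame(start = offset, end = offset + n - 1L,
                      mention_index = 1L))
  }
  cut_after <- integer(0)  # local coords: sub i ends at cut_after[i]
  for (i in seq_len(k - 1L)) {
    gap_s <- mentions$end[i] - offset + 2L       # local, first char after m_i
    gap_e <- mentions$start[i + 1L] - offset     # local, char before m_{i+1}
    gap <- substring(text, gap_s, gap_e)
    boundary <- NA_integer_                      # last char of sub i, local
    if (identical(mentions$temporality[i + 1L], "PRIOR")) {
      best <- -1L
      for (pat in config$prior_cues) {
        mm <- gregexpr(pat, gap, perl = TRUE, ignore.case = TRUE)[[1]]
        if (mm[1] != -1) best <- max(best, max(as.integer(mm)))
      }
      if (best > 0L) boundary <- gap_s + best - 2L
    }
    if (is.na(boundary)) {
      close_par <- gregexpr(")", gap, fixed = TRUE)[[1]]
      open_par <- gregexpr("(", gap, fixed = TRUE)[[1]]
      if (close_par[1] != -1) {
        boundary <- gap_s + max(as.integer(close_par)) - 1L
      } else if (open_par[1] != -1) {
        boundary <- gap_s + min(as.integer(open_par)) - 2L
      }
    }
    if (is.na(boundary)) {
      delim <- gregexpr("[,;]", gap, perl = TRUE)[[1]]
      if (delim[1] != -1) boundary <- gap_s + max(as.integer(delim)) - 1L
    }
    if (is.na(boundary)) {
      mid <- (gap_s + gap_e) %/% 2L
      ws <- gregexpr("\\s", gap, perl = TRUE)[[1]]
      if (ws[1] != -1) {
        wpos <- gap_s + as.integer(ws) - 1L
        boundary <- wpos[which.min(abs(wpos - mid))]
      } else {
        boundary <- mid
      }
    }
    boundary <- min(max(boundary, gap_s - 1L), gap_e)
    cut_after <- c(cut_after, boundary)
  }
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  data.frame(start = offset + starts - 1L, end = offset + ends - 1L,
             mention_index = seq_len(k))
}

# --- scan references ---------------------------------------------------------

.scan_ref_res <- function() {
  num <- "(\\d+)(?:\\s*-\\s*(\\d+))?"
  tail <- paste0("\\.?\\s*[#:]?\\s*", num)
  c(
    IMAGE   = paste0("\\b(?:images?|img|im)", tail),
    SERIES  = paste0("\\b(?:series|ser|se)", tail),
    SEGMENT = paste0("\\b(?:segments?|seg)", tail)
  )
}

#' Tag image, series and segment references
#'
#' Finds scan-location references — the image (slice) number, acquisition
#' series number, and organ segment number — written as `image 127`,
#' `series 11`, `segment 5` or common dictation shorthands (`im`, `img`,
#' `ser`, `se`, `seg`, optional `#`/`:`; integer ranges allowed).  A
#' numeric tail is required, so words like "imaging" never trigger a match.
#'
#' @param text Sentence text.
#' @param offset Offset of `text` in the document.
#' @return A data.frame with columns `kind` (`IMAGE`/`SERIES`/`SEGMENT`),
#'   `number` (first integer), `number_hi` (`NA` or range upper bound),
#'   `start`, `end`, `surface`, ordered by `start`.
#' @examples
#' tag_scan_references("on series 11 (image 127)")
#' @export
tag_scan_references <- function(text, offset = 1L) {
  out <- data.frame(kind = character(), number = integer(),
                    number_hi = integer(), start = integer(),
                    end = integer(), surface = character(),
                    stringsAsFactors = FALSE)
  for (kind in names(.scan_ref_res())) {
    pat <- .scan_ref_res()[[kind]]
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      surface <- substring(text, starts[i], starts[i] + lens[i] - 1L)
      nums <- as.integer(
        regmatches(surface, gregexpr("\\d+", surface))[[1]]
      )
      out[nrow(out) + 1L, ] <- list(
        kind, nums[1],
        if (length(nums) > 1L) nums[2] else NA_integer_,
        offset + starts[i] - 1L,
        offset + starts[i] + lens[i] - 2L,
        surface
      )
    }
  }
  out[order(out$start), , drop = FALSE]
}
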