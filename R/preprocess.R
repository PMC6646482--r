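#' @section Coordinates:
#' All character spans in this package are 1-based and inclusive, so that
#' `substring(text, start, end)` recovers the surface string exactly.
#' @name lesionext-coordinates
#' @keywords internal
NULL

.section_names <- c("COMPARISON", "TECHNIQUE", "CLINICAL_HISTORY",
                    "FINDINGS", "CONCLUSIONS", "OTHER")

# Uppercase the literal letters of a regex while leaving escapes (\s, \d)
# untouched, so a lowercase pattern can be reused as its ALL-CAPS variant.
.upper_literals <- function(pat) {
  chars <- strsplit(pat, "", fixed = TRUE)[[1]]
  res <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "\\" && i < length(chars)) {
      res <- c(res, chars[i], chars[i + 1L])
      i <- i + 2L
    } else {
      res <- c(res, toupper(chars[i]))
      i <- i + 1L
    }
  }
  paste(res, collapse = "")
}

# Regex (perl) locating section headers: either at a line start (any case,
# colon optional when the header ends the line) or mid-text when written in
# ALL CAPS followed by a colon, the dominant dictation style.
.header_regex <- function(config) {
  alts <- paste(unname(config$header_patterns), collapse = "|")
  paste0(
    "(?im)",
    "(?:^[ \\t]*(?:", alts, ")[ \\t]*(?::|$))",
    "|",
    "(?-i:(?:(?<![A-Za-z])(?:", .upper_literals(alts), ")[ \\t]*:))"
  )
}

.header_name <- function(header_text, config) {
  h <- sub("[ \t]*:?[ \t]*$", "", sub("^[ \t]*", "", header_text))
  for (nm in names(config$header_patterns)) {
    pat <- paste0("^(?:", config$header_patterns[[nm]], ")$")
    if (grepl(pat, h, ignore.case = TRUE, perl = TRUE)) return(nm)
  }
  "OTHER"
}

#' Split a report into named sections
#'
#' Locates section headers (Comparison, Technique, Clinical History,
#' Findings, Conclusions/Impression) with a configurable pattern table and
#' returns the section bodies with their character spans.  Each section body
#' runs from the end of its header to the start of the next header (or end
#' of text).  Text before the first recognized header becomes an `OTHER`
#' section, as does the whole document when no header matches, so that
#' unheaded (e.g. mammography-style) reports still flow through the
#' pipeline.
#'
#' @param raw_text Report text (UTF-8).
#' @param config A [lex_config()] object (supplies `header_patterns`).
#' @return A data.frame with columns `name` (section name), `start`, `end`
#'   (1-based inclusive span of the section *body* in `raw_text`),
#'   `header_start`, `header_end` (span of the header itself, `NA` for
#'   fallback `OTHER` sections).  Zero rows for empty input.
#' @examples
#' segment_sections("FINDINGS: Liver is normal.")
#' @export
segment_sections <- function(raw_text, config = lex_config()) {
  empty <- data.frame(
    name = character(), start = integer(), end = integer(),
    header_start = integer(), header_end = integer(),
    stringsAsFactors = FALSE
  )
  if (is.null(raw_text) || !nzchar(raw_text)) return(empty)
  m <- gregexpr(.header_regex(config), raw_text, perl = TRUE)[[1]]
  out <- empty
  if (m[1] == -1) {
    hs <- integer(0); he <- integer(0)
  } else {
    hs <- as.integer(m)
    he <- hs + attr(m, "match.length") - 1L
  }
  n <- nchar(raw_text)
  add <- function(name, s, e, h1 = NA_integer_, h2 = NA_integer_) {
    # trim surrounding whitespace from the body span but keep it non-inverted
    while (s <= e && grepl("^\\s$", substring(raw_text, s, s))) s <- s + 1L
    while (e >= s && grepl("^\\s$", substring(raw_text, e, e))) e <- e - 1L
    if (s > e) return(invisible(NULL))
    out[nrow(out) + 1L, ] <<- list(name, s, e, h1, h2)
    invisible(NULL)
  }
  if (length(hs) == 0) {
    add("OTHER", 1L, n)
    return(out)
  }
  if (hs[1] > 1L) add("OTHER", 1L, hs[1] - 1L)
  for (i in seq_along(hs)) {
    body_start <- he[i] + 1L
    body_end <- if (i < length(hs)) hs[i + 1L] - 1L else n
    nm <- .header_name(substring(raw_text, hs[i], he[i]), config)
    add(nm, body_start, body_end, hs[i], he[i])
  }
  out
}

#' Construct a report object
#'
#' Bundles raw report text with its section table under a `doc_id`.
#'
#' @param raw_text Report text.
#' @param doc_id Document identifier (any string).
#' @param config A [lex_config()] object.
#' @return A list of class `"rad_report"` with elements `doc_id`,
#'   `raw_text`, `sections`.
#' @export
rad_report <- function(raw_text, doc_id = "doc1", config = lex_config()) {
  structure(
    list(
      doc_id = doc_id,
      raw_text = raw_text,
      sections = segment_sections(raw_text, config)
    ),
    class = "rad_report"
  )
}

#' @export
print.rad_report <- function(x, ...) {
  cat("<rad_report> ", x$doc_id, ": ", nchar(x$raw_text), " chars, ",
      nrow(x$sections), " section(s) [",
      paste(x$sections$name, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Select the Findings sections of a report
#'
#' Lesion measurements are dictated in the Findings section, which is the
#' pipeline's working input.  If the report has no recognized Findings
#' header, the fallback `OTHER` section(s) covering the body are returned
#' instead so unheaded reports are still processed in full.
#'
#' @param report A [rad_report()] object.
#' @return The subset of `report$sections` (same columns) to process, in
#'   document order.
#' @export
select_findings <- function(report) {
  stopifnot(inherits(report, "rad_report"))
  sec <- report$sections
  fin <- sec[sec$name == "FINDINGS", , drop = FALSE]
  if (nrow(fin) > 0) return(fin)
  sec[sec$name == "OTHER", , drop = FALSE]
}

# Abbreviations after which a period never ends a sentence.
.abbrev <- c("dr", "mr", "mrs", "ms", "st", "vs", "approx", "fig", "no",
             "cf", "e.g", "i.e", "pt", "s/p")

#' Split a section into sentences
#'
#' Regex sentence splitter tuned for radiology dictation: a sentence ends at
#' `.`, `!` or `?` followed by whitespace, unless the period sits inside a
#' decimal number (`1.2 cm`), follows a known abbreviation, or follows a
#' single initial.  Semicolons and parentheses never end a sentence, so long
#' enumerating sentences survive intact.  Returned spans index the original
#' report text.
#'
#' @param raw_text Full report text.
#' @param start,end Span of the section body to split (defaults: all of
#'   `raw_text`).
#' @return A data.frame with columns `sent_id`, `start`, `end`, `text`.
#' @examples
#' split_sentences("Liver normal. Spleen normal.")
#' @export
split_sentences <- function(raw_text, start = 1L, end = nchar(raw_text)) {
  out <- data.frame(sent_id = integer(), start = integer(), end = integer(),
                    text = character(), stringsAsFactors = FALSE)
  if (is.na(start) || is.na(end) || start > end) return(out)
  txt <- substring(raw_text, start, end)
  n <- nchar(txt)
  # candidate breaks: terminator run followed by whitespace or end of text
  m <- gregexpr("[.!?]+(?=\\s|$)", txt, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      pos <- as.integer(m[i])                 # first terminator char
      endpos <- pos + attr(m, "match.length")[i] - 1L
      ch <- substring(txt, pos, pos)
      if (ch == ".") {
        nxt <- if (endpos < n) substring(txt, endpos + 1L, endpos + 1L) else ""
        prev <- if (pos > 1L) substring(txt, pos - 1L, pos - 1L) else ""
        # decimal point: digit on both sides (no whitespace after -> not here)
        # abbreviation or single initial before the period
        wstart <- regmatches(substring(txt, 1L, pos - 1L),
                             regexpr("[A-Za-z./]+$",
                                     substring(txt, 1L, pos - 1L)))
        w <- if (length(wstart)) tolower(wstart) else ""
        if (w %in% .abbrev) next
        if (nchar(w) == 1L && grepl("^[A-Za-z]$", w)) next
        if (prev == "" ) next
      }
      breaks <- c(breaks, endpos)
    }
  }
  bounds <- unique(c(breaks, n))
  s <- 1L
  sid <- 0L
  for (b in bounds) {
    seg <- substring(txt, s, b)
    if (nzchar(trimws(seg))) {
      nl <- attr(regexpr("^\\s*", seg), "match.length")
      nt <- attr(regexpr("\\s*$", seg), "match.length")
      s2 <- s + nl            # first non-space, txt coords
      e2 <- b - nt            # last non-space, txt coords
      sid <- sid + 1L
      a <- start + (s2 - 1L)  # map to raw_text coords
      z <- start + (e2 - 1L)
      out[nrow(out) + 1L, ] <- list(sid, a, z, substring(raw_text, a, z))
    }
    s <- b + 1L
  }
  out
}

#' Lowercase and strip punctuation outside protected spans
#'
#' The pipeline normalizes text only *after* measurements and scan
#' references have been tagged, so that surfaces such as `1.2 x 3.4 cm` or
#' `(image 127)` are never mangled.  This function lowercases the whole
#' string, deletes punctuation characters that fall outside the protected
#' spans, collapses the resulting whitespace, and returns an offset map from
#' every character of the normalized string back to its source position.
#'
#' @param text The sentence text.
#' @param protected_spans A data.frame with columns `start`, `end` (1-based
#'   inclusive, into `text`) of spans that must survive verbatim (modulo
#'   lowercasing).  Overlapping spans signal a tagger inconsistency and
#'   raise an error.
#' @return A list with `text` (normalized string) and `offset_map` (integer
#'   vector, one entry per normalized character, giving the 1-based source
#'   offset in the input).
#' @examples
#' normalize_after_tagging("Stable 4 mm Nodule.",
#'                         data.frame(start = 8, end = 11))
#' @export
normalize_after_tagging <- function(text, protected_spans = NULL) {
  if (is.null(protected_spans) || nrow(protected_spans) == 0) {
    protected_spans <- data.frame(start = integer(), end = integer())
  }
  if (!nzchar(text)) return(list(text = "", offset_map = integer(0)))
  ps <- protected_spans[order(protected_spans$start), , drop = FALSE]
  if (nrow(ps) > 1 && any(ps$start[-1] <= ps$end[-nrow(ps)])) {
    stop("protected spans overlap: tagger inconsistency", call. = FALSE)
  }
  n <- nchar(text)
  protected <- rep(FALSE, n)
  for (i in seq_len(nrow(ps))) {
    protected[ps$start[i]:ps$end[i]] <- TRUE
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_punct <- grepl("[[:punct:]]", chars) & !protected
  keep <- !is_punct
  # collapse whitespace runs (outside protected spans) to a single space
  out_chars <- character(0)
  out_map <- integer(0)
  last_space <- TRUE  # drop leading whitespace
  for (i in seq_len(n)) {
    if (!keep[i]) next
    ch <- chars[i]
    if (grepl("^\\s$", ch) && !protected[i]) {
      if (last_space) next
      out_chars <- c(out_chars, " ")
      out_map <- c(out_map, i)
      last_space <- TRUE
    } else {
      out_chars <- c(out_chars, tolower(ch))
      out_map <- c(out_map, i)
      last_space <- FALSE
    }
  }
  # drop trailing space
  while (length(out_chars) > 0 && out_chars[length(out_chars)] == " " &&
         !protected[out_map[length(out_map)]]) {
    out_chars <- out_chars[-length(out_chars)]
    out_map <- out_map[-length(out_map)]
  }
  list(text = paste(out_chars, collapse = ""), offset_map = out_map)
}
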