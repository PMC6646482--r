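# The multi-nodule worked example: one Findings sentence carrying five
# current measurements, each with a parenthesized prior, a shared leading
# series reference and sentence-initial modifiers.  It ships as a fixture
# because it exercises every rule of the linking grammar at once, and its
# inferred gold standard is the package's reference case for the
# full/partial/no-match evaluation.

#' Path to the multi-nodule example report
#'
#' A single-sentence Findings section with five current/prior measurement
#' pairs, image references for every current measurement, one shared
#' series reference, and sentence-initial modifiers ("scattered",
#' "enhancing") that describe all the nodules but are written only once.
#'
#' @return File path of the example report.
#' @examples
#' frames <- build_frames(paste(readLines(multi_nodule_example()),
#'                              collapse = "\n"))
#' length(frames)
#' @export
multi_nodule_example <- function() {
  system.file("extdata", "multi_nodule_example.txt", package = "lesionext",
              mustWork = TRUE)
}

#' Inferred gold frames for the multi-nodule example
#'
#' The reference annotation for [multi_nodule_example()]: ten frames (five
#' `CURRENT`, five `PRIOR`).  Every frame carries its size, temporality,
#' laterality/location, observation (`nodule`), the shared series number
#' 11, and — following the reading under which a sentence-initial modifier
#' describes every lesion it governs — the modifiers `scattered` (RadLex
#' descriptor) and `enhancing` (imaging observation) on *all ten* frames.
#' Image numbers sit on the current frames only (the prior measurements
#' were made on an earlier study).  Against this gold a sub-sentence-scoped
#' linker attaches the two sentence-initial modifiers only to the first
#' frame, so frames 2-10 are partial matches.
#'
#' This assignment of the shared modifiers is an annotation *choice*, made
#' here deliberately; it is constructed in code rather than shipped as
#' data.
#'
#' @return A list of ten `measurement_frame` objects whose spans resolve
#'   inside the example report text.
#' @export
multi_nodule_gold <- function() {
  text <- paste(readLines(multi_nodule_example(), encoding = "UTF-8",
                          warn = FALSE), collapse = "\n")
  # locate the real spans in the fixture so gold never drifts from it
  mentions <- tag_measurements(text)
  stopifnot(nrow(mentions) == 10L)
  mentions <- tag_temporality(text, mentions)
  sites <- list(
    list(ae = "left frontal", image = 127L),
    list(ae = "right frontal", image = 124L),
    list(ae = "right frontal", image = 114L),
    list(ae = "lateral right frontal", image = 118L),
    list(ae = "left cerebellar", image = 53L)
  )
  frames <- list()
  for (s in seq_along(sites)) {
    cur <- mentions[2L * s - 1L, , drop = FALSE]
    pri <- mentions[2L * s, , drop = FALSE]
    stopifnot(cur$temporality == "CURRENT", pri$temporality == "PRIOR")
    mk <- function(m, k, image) {
      new_frame(
        frame_id = paste0("gold.", k), doc_id = "multi_nodule_example",
        sentence_id = 1L, surface = m$surface, start = m$start,
        end = m$end, dims = m$dims[[1]], temporality = m$temporality,
        anatomical_entity = sites[[s]]$ae,
        imaging_observation = c("enhancing", "nodule"),
        radlex_descriptor = "scattered",
        image_number = image, series_number = 11L,
        segment = NA_integer_
      )
    }
    frames[[2L * s - 1L]] <- mk(cur, 2L * s - 1L, sites[[s]]$image)
    frames[[2L * s]] <- mk(pri, 2L * s, NA_integer_)
  }
  frames
}
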