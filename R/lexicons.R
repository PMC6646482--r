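#' Built-in entity lexicons
#'
#' Small curated word lists used by the dictionary tagger, the CRF feature
#' extractor (dictionary-map features) and the synthetic report generator.
#' Three lists are shipped: anatomical entities (body structures and
#' locations, including laterality phrases), imaging observations (the
#' findings being measured) and RadLex-style descriptors (qualifiers of a
#' finding).  All entries are lowercase; matching elsewhere is
#' case-insensitive.  Users can replace any list via the pipeline config
#' (see [lex_config()]).
#'
#' @return A named list with character vectors `anatomical_entity`,
#'   `imaging_observation` and `radlex_descriptor`.
#' @examples
#' lex <- default_lexicons()
#' "nodule" %in% lex$imaging_observation
#' @export
default_lexicons <- function() {
  anatomical_entity <- c(
    # neuro, with laterality
    "left frontal", "right frontal", "lateral right frontal",
    "lateral left frontal", "left parietal", "right parietal",
    "left temporal", "right temporal", "left occipital", "right occipital",
    "left cerebellar", "right cerebellar", "cerebellum", "pons", "brainstem",
    "corpus callosum", "pineal region", "sella",
    # chest
    "left upper lobe", "left lower lobe", "right upper lobe",
    "right middle lobe", "right lower lobe", "lingula", "left hilum",
    "right hilum", "mediastinum", "subcarinal region", "left pleura",
    "right pleura", "main pulmonary artery", "ascending aorta",
    "descending aorta", "aortic arch",
    # abdomen / pelvis
    "liver", "left hepatic lobe", "right hepatic lobe", "caudate lobe",
    "porta hepatis", "gallbladder", "spleen", "pancreas", "pancreatic head",
    "pancreatic body", "pancreatic tail", "left kidney", "right kidney",
    "left adrenal gland", "right adrenal gland", "left ovary", "right ovary",
    "uterus", "cervix", "prostate", "bladder", "rectum", "sigmoid colon",
    "cecum", "appendix", "stomach", "duodenum", "retroperitoneum",
    "omentum", "peritoneum", "abdominal wall", "periportal region",
    # nodes / neck / breast / msk
    "left axilla", "right axilla", "left iliac chain", "right iliac chain",
    "paraaortic region", "left groin", "right groin", "left neck",
    "right neck", "thyroid", "left thyroid lobe", "right thyroid lobe",
    "left breast", "right breast", "left humerus", "right humerus",
    "left iliac bone", "sacrum", "lumbar vertebral body",
    "thoracic vertebral body"
  )
  imaging_observation <- c(
    "nodule", "mass", "lesion", "cyst", "lymph node", "lymphadenopathy",
    "opacity", "ground-glass opacity", "consolidation", "effusion",
    "pleural effusion", "granuloma", "metastasis", "hemangioma",
    "adenoma", "fibroid", "polyp", "stone", "calculus", "calcification",
    "thrombus", "aneurysm", "stricture", "thickening", "wall thickening",
    "fluid collection", "abscess", "hematoma", "pseudocyst", "infiltrate",
    "density", "focus", "enhancement", "enhancing", "nonenhancing",
    "cavitation", "atelectasis", "scarring", "emphysema", "edema",
    "diverticulum", "hernia", "defect", "erosion", "sclerosis",
    "asymmetry", "distortion", "microcalcifications", "duct dilatation"
  )
  radlex_descriptor <- c(
    "scattered", "multiple", "solitary", "diffuse", "focal", "bilateral",
    "unilateral", "ill-defined", "well-defined", "well-circumscribed",
    "hypodense", "hyperdense", "isodense", "hypoechoic", "hyperechoic",
    "hypointense", "hyperintense", "heterogeneous", "homogeneous",
    "calcified", "noncalcified", "cystic", "solid", "complex",
    "spiculated", "lobulated", "round", "oval", "irregular", "linear",
    "punctate", "subtle", "prominent", "stable", "new", "enlarged",
    "decreased", "increased", "necrotic", "peripheral", "central",
    "exophytic", "infiltrative", "rim-enhancing", "septated", "tiny"
  )
  list(
    anatomical_entity = anatomical_entity,
    imaging_observation = imaging_observation,
    radlex_descriptor = radlex_descriptor
  )
}

#' Pipeline configuration
#'
#' Assembles the configuration object consumed by every stage of the
#' pipeline: section-header patterns, the measurement grammar options,
#' temporality cue lists, scan-reference dialects, lexicons, CRF training
#' options and the default random seed.  All arguments have working
#' defaults; pass replacements to override individual pieces.  A config can
#' also be loaded from a JSON file with [load_config()], in which case keys
#' present in the file override these defaults.
#'
#' @param header_patterns Named character vector mapping section names
#'   (`COMPARISON`, `TECHNIQUE`, `CLINICAL_HISTORY`, `FINDINGS`,
#'   `CONCLUSIONS`) to regular expressions (case-insensitive, applied to
#'   header text without the trailing colon).
#' @param units Named character vector mapping unit surface patterns to the
#'   canonical unit (`"mm"` or `"cm"`).
#' @param prior_cues,current_cues Character vectors of regular expressions;
#'   a measurement falls under the most recent cue to its left (scope is
#'   reset by `)` and `;`), defaulting to current.
#' @param lexicons As returned by [default_lexicons()].
#' @param crf List of CRF training options: `l2` (L2 regularization
#'   strength), `maxit` (L-BFGS iteration cap), `window` (feature context
#'   window, in tokens, on each side).
#' @param seed Default seed for stochastic steps (CRF tie-breaking plays no
#'   role; this mainly seeds the synthetic generator when none is given).
#' @return A list of class `"lex_config"`.
#' @seealso [load_config()], [default_lexicons()]
#' @export
lex_config <- function(header_patterns = NULL,
                       units = NULL,
                       prior_cues = NULL,
                       current_cues = NULL,
                       lexicons = default_lexicons(),
                       crf = list(l2 = 1.0, maxit = 100L, window = 2L),
                       seed = 42L) {
  if (is.null(header_patterns)) {
    header_patterns <- c(
      COMPARISON       = "comparison",
      TECHNIQUE        = "technique|procedure",
      CLINICAL_HISTORY = "clinical\\s+history|history|indication",
      FINDINGS         = "findings?",
      CONCLUSIONS      = "conclusions?|impression"
    )
  }
  if (is.null(units)) {
    units <- c(
      "millimeters?" = "mm", "centimeters?" = "cm", "mm" = "mm", "cm" = "cm"
    )
  }
  if (is.null(prior_cues)) {
    prior_cues <- c(
      "\\bpreviously\\b", "\\bprevious\\b", "\\bprior\\b", "\\bwas\\b",
      "\\bwere\\b", "\\bcompared\\s+(?:to|with)\\b",
      "\\bfrom\\s+\\d{1,2}[/-]\\d{1,2}(?:[/-]\\d{2,4})?\\b"
    )
  }
  if (is.null(current_cues)) {
    current_cues <- c("\\bnow\\b", "\\bcurrently\\b", "\\btoday\\b")
  }
  structure(
    list(
      header_patterns = header_patterns,
      units = units,
      prior_cues = prior_cues,
      current_cues = current_cues,
      lexicons = lexicons,
      crf = crf,
      seed = as.integer(seed)
    ),
    class = "lex_config"
  )
}

#' Load a pipeline configuration from JSON
#'
#' Reads a JSON file whose top-level keys correspond to the arguments of
#' [lex_config()] and merges them over the defaults.  Unknown keys are
#' rejected so a typo in a config file fails loudly rather than being
#' silently ignored.
#'
#' @param path Path to a JSON config file.
#' @return A `"lex_config"` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("header_patterns", "units", "prior_cues", "current_cues",
               "lexicons", "crf", "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- lex_config()
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k == "crf") {
      cfg$crf[names(v)] <- v
    } else if (k == "lexicons") {
      cfg$lexicons[names(v)] <- v
    } else if (k %in% c("header_patterns", "units")) {
      cfg[[k]] <- unlist(v)
    } else {
      cfg[[k]] <- if (k == "seed") as.integer(v) else v
    }
  }
  cfg
}
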