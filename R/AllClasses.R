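#' @import methods
NULL

LATERALITIES <- c("left", "right", "midline")
TISSUE_CLASSES <- c("tissue", "ventricle", "sulcus")
LOBE_NAMES <- c("frontal", "parietal", "temporal", "occipital", "limbic")

#' Anatomic structure ontology
#'
#' An \code{OntologyHierarchy} holds the structure vocabulary used by the
#' pipeline: base (level-0) segmentation labels plus multi-level
#' superstructures defined as unions of children (gyri into lobes, lobes into
#' hemispheres, ...).  The child graph is a DAG: a base label may sit under
#' several independent superstructures, but the base-level descendant sets of
#' one superstructure's children never overlap, so aggregated volumes are
#' never double counted.
#'
#' @slot labels data.frame with columns \code{id}, \code{name},
#'   \code{laterality} (left/right/midline), \code{tissue_class}
#'   (tissue/ventricle/sulcus) and \code{level} (0 = base).
#' @slot children named list mapping each superstructure id to the character
#'   vector of its child ids.
#' @seealso [defaultHierarchy()], [aggregateSuperstructures()]
#' @export
setClass("OntologyHierarchy",
         slots = c(labels = "data.frame", children = "list"))

setValidity("OntologyHierarchy", function(object) {
  lb <- object@labels
  need <- c("id", "name", "laterality", "tissue_class", "level")
  if (!all(need %in% names(lb)))
    return(paste("labels must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(lb$id)) return("duplicated structure ids")
  if (!all(lb$laterality %in% LATERALITIES)) return("invalid laterality")
  if (!all(lb$tissue_class %in% TISSUE_CLASSES)) return("invalid tissue_class")
  if (any(lb$level < 0) || any(lb$level != round(lb$level)))
    return("level must be a non-negative integer")
  ch <- object@children
  if (length(ch) && is.null(names(ch))) return("children must be named")
  kids <- unlist(ch, use.names = FALSE)
  if (!all(kids %in% lb$id)) {
    bad <- setdiff(kids, lb$id)
    return(paste("unknown child ids:", paste(bad, collapse = ", ")))
  }
  if (!all(names(ch) %in% lb$id)) return("children keyed by unknown id")
  sup <- lb$id[lb$level > 0]
  if (!all(sup %in% names(ch)))
    return("every level > 0 label needs at least one child")
  if (any(lengths(ch[sup]) < 1)) return("superstructure with no children")
  base <- lb$id[lb$level == 0]
  if (any(base %in% names(ch))) return("level-0 labels cannot have children")
  cyc <- .findCycle(ch)
  if (!is.null(cyc)) return(paste("cycle in child graph at:", cyc))
  # disjoint base-descendant sets among one superstructure's children
  desc <- .baseDescendantsAll(lb$id, ch)
  for (s in names(ch)) {
    d <- unlist(desc[ch[[s]]], use.names = FALSE)
    if (anyDuplicated(d))
      return(paste0("base structure counted twice under '", s, "'"))
  }
  # laterality consistency: a lateralized parent never spans the midline's
  # opposite side
  lat <- stats::setNames(lb$laterality, lb$id)
  for (s in names(ch)) {
    dl <- unique(lat[desc[[s]]])
    if (lat[s] == "left" && "right" %in% dl)
      return(paste0("right descendant under left parent '", s, "'"))
    if (lat[s] == "right" && "left" %in% dl)
      return(paste0("left descendant under right parent '", s, "'"))
  }
  TRUE
})

#' One case's structure volumes
#'
#' Maps structure ids to volumes for a single case, together with the case id
#' and age.  The same container carries raw volumes (\code{units = "mm3"}) and
#' total-brain-normalized volume ratios (\code{units = "ratio"}).
#'
#' @slot case_id single character case identifier.
#' @slot age age in years (positive).
#' @slot volumes named non-negative numeric vector, structure id -> value.
#' @slot units "mm3" or "ratio".
#' @export
setClass("VolumeTable",
         slots = c(case_id = "character", age = "numeric",
                   volumes = "numeric", units = "character"))

setValidity("VolumeTable", function(object) {
  if (length(object@case_id) != 1L) return("case_id must be length 1")
  if (length(object@age) != 1L || !is.finite(object@age) || object@age <= 0)
    return("age must be a single positive finite number")
  v <- object@volumes
  if (is.null(names(v)) || anyDuplicated(names(v)))
    return("volumes must be uniquely named by structure id")
  if (any(!is.finite(v)) || any(v < 0))
    return("volumes must be finite and non-negative")
  if (!object@units %in% c("mm3", "ratio")) return("units must be mm3 or ratio")
  TRUE
})

#' Age-linear normative model of volume ratios
#'
#' Per-structure ordinary least squares fit of total-brain-normalized volume
#' ratio on age, over a control cohort, with homoscedastic residual SD.  A
#' case z-score is \code{(ratio - (intercept + slope * age)) / residual_sd}.
#'
#' @slot coef data.frame with columns \code{structure_id}, \code{intercept},
#'   \code{slope}, \code{residual_sd}, \code{n_controls}.
#' @slot age_range numeric length 2, control-cohort age span in years.
#' @slot units scale the model was fitted on ("ratio" or "mm3").
#' @export
setClass("NormativeModel",
         slots = c(coef = "data.frame", age_range = "numeric",
                   units = "character"))

setValidity("NormativeModel", function(object) {
  cf <- object@coef
  need <- c("structure_id", "intercept", "slope", "residual_sd", "n_controls")
  if (!all(need %in% names(cf)))
    return(paste("coef must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(cf$structure_id)) return("duplicated structure ids")
  if (any(cf$residual_sd <= 0)) return("residual_sd must be > 0")
  if (any(cf$n_controls < 3)) return("n_controls must be >= 3")
  if (length(object@age_range) != 2L || object@age_range[1] > object@age_range[2])
    return("age_range must be (min, max)")
  TRUE
})

#' Per-structure z-scores for one case
#'
#' @slot case_id,age case identity.
#' @slot ratio named numeric, structure id -> normalized volume ratio.
#' @slot z named numeric, structure id -> z-score (NA where the normative
#'   model does not cover the structure).
#' @slot extrapolated TRUE when the case age lies outside the normative
#'   cohort's age range (scores still returned).
#' @export
setClass("ZScoreTable",
         slots = c(case_id = "character", age = "numeric", ratio = "numeric",
                   z = "numeric", extrapolated = "logical"))

setValidity("ZScoreTable", function(object) {
  if (!identical(names(object@ratio), names(object@z)))
    return("ratio and z must share names")
  if (any(is.infinite(object@z))) return("z must be finite or NA")
  TRUE
})

#' Clinical knowledge filter configuration
#'
#' The curated set of reported structures and the trigger rules.  Tissue
#' structures trigger on atrophy (z < -threshold); ventricles and deep sulci
#' on enlargement/prominence (z > +threshold).  Hemispheres and lobes feed
#' the relational rules (hemispheric, prominent, lobe-specific sentences);
#' the remaining tissue structures trigger directly.
#'
#' @slot threshold positive trigger threshold on |z| (default 2).
#' @slot prominence_max_lobes largest affected-lobe subset still called
#'   "prominent" under hemispheric atrophy (default 2).
#' @slot hemispheres named character c(left = id, right = id).
#' @slot lobes list(left =, right =) of named character vectors, lobe name ->
#'   structure id, in canonical order frontal, parietal, temporal, occipital,
#'   limbic.
#' @slot direct tissue structures reported by direct triggering.
#' @slot ventricular ventricle/sulcus structures reported on enlargement.
#' @export
setClass("ClinicalKnowledgeFilter",
         slots = c(threshold = "numeric", prominence_max_lobes = "integer",
                   hemispheres = "character", lobes = "list",
                   direct = "character", ventricular = "character"))

setValidity("ClinicalKnowledgeFilter", function(object) {
  if (length(object@threshold) != 1L || object@threshold <= 0)
    return("threshold must be a single positive number")
  if (object@prominence_max_lobes < 0L)
    return("prominence_max_lobes must be >= 0")
  if (!identical(sort(names(object@hemispheres)), c("left", "right")))
    return("hemispheres must be named left, right")
  if (!identical(sort(names(object@lobes)), c("left", "right")))
    return("lobes must be a list with elements left, right")
  for (side in c("left", "right")) {
    lb <- object@lobes[[side]]
    if (!identical(names(lb), LOBE_NAMES))
      return("each lobe set must be named frontal, parietal, temporal, occipital, limbic")
  }
  all_ids <- c(object@hemispheres, unlist(object@lobes), object@direct,
               object@ventricular)
  if (anyDuplicated(all_ids)) return("duplicated reported structure")
  TRUE
})

#' Machine-readable abnormality pattern for one case
#'
#' Intermediate result between thresholded z-scores and rendered sentences.
#'
#' @slot hemispheric_state one of none/left/right/bilateral.
#' @slot affected_lobes list(left =, right =) lobe names with z below the
#'   atrophy threshold.
#' @slot prominent_lobes per-hemisphere lobe subsets qualifying as
#'   "prominent" (only under hemispheric atrophy).
#' @slot specific_combo per-hemisphere lobe subsets qualifying as lobe
#'   "specific" atrophy (only without hemispheric atrophy).
#' @slot direct_findings data.frame(structure, polarity) for direct triggers.
#' @slot ventricular_findings character, enlarged ventricle/sulcus ids.
#' @export
setClass("FindingPattern",
         slots = c(hemispheric_state = "character", affected_lobes = "list",
                   prominent_lobes = "list", specific_combo = "list",
                   direct_findings = "data.frame",
                   ventricular_findings = "character"))

setValidity("FindingPattern", function(object) {
  st <- object@hemispheric_state
  if (!st %in% c("none", "left", "right", "bilateral"))
    return("invalid hemispheric_state")
  if (st == "none" && any(lengths(object@prominent_lobes) > 0))
    return("prominent lobes require hemispheric atrophy")
  if (st != "none" && any(lengths(object@specific_combo) > 0))
    return("specific combinations are suppressed under hemispheric atrophy")
  for (side in c("left", "right")) {
    if (!all(object@prominent_lobes[[side]] %in% object@affected_lobes[[side]]))
      return("prominent lobes must be affected lobes")
  }
  TRUE
})

#' Rendered sentence report
#'
#' @slot sentences ordered rendered sentence strings.
#' @slot assertions data.frame(term, qualifier, polarity), one row per
#'   sentence; qualifier is plain/prominent/specific.
#' @export
setClass("SentenceReport",
         slots = c(sentences = "character", assertions = "data.frame"))

setValidity("SentenceReport", function(object) {
  if (nrow(object@assertions) != length(object@sentences))
    return("one assertion per sentence")
  TRUE
})

#' 2x2 contingency counts between two finding sources
#'
#' @slot tp,fp,fn,tn non-negative integer counts (test-positive/
#'   reference-positive etc.) over a fixed case-by-structure universe.
#' @export
setClass("ContingencyCounts",
         slots = c(tp = "integer", fp = "integer", fn = "integer",
                   tn = "integer"))

setValidity("ContingencyCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0))
    return("counts must be single non-negative integers")
  TRUE
})

#' Synthetic control-cohort specification
#'
#' Generative model for a normative cohort: per base structure, volume ratio
#' is linear in age with Gaussian noise; volumes are ratios times a
#' case-level total brain volume.  Structures are independent.
#'
#' @slot n number of controls.
#' @slot age_range uniform age distribution bounds in years.
#' @slot model data.frame(structure_id, intercept, slope, noise_sd) on the
#'   ratio scale, one row per base structure.
#' @slot tbv_mean,tbv_sd case-level total brain volume distribution (mm3).
#' @slot seed default RNG seed (overridable per call).
#' @export
setClass("CohortSpec",
         slots = c(n = "integer", age_range = "numeric", model = "data.frame",
                   tbv_mean = "numeric", tbv_sd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@n < 3L) return("n must be >= 3")
  if (length(object@age_range) != 2L || object@age_range[1] >= object@age_range[2])
    return("age_range must be (min, max), min < max")
  m <- object@model
  need <- c("structure_id", "intercept", "slope", "noise_sd")
  if (!all(need %in% names(m)))
    return(paste("model must have columns:", paste(need, collapse = ", ")))
  if (any(m$noise_sd <= 0)) return("noise_sd must be > 0")
  mu_lo <- m$intercept + m$slope * object@age_range[1]
  mu_hi <- m$intercept + m$slope * object@age_range[2]
  if (any(pmin(mu_lo, mu_hi) <= 0))
    return("mean ratio must stay positive over age_range")
  TRUE
})

#' Injected abnormality pattern for a synthetic patient
#'
#' @slot targets named numeric: structure id -> shift in residual-SD units of
#'   the generative model (negative = atrophy, positive = enlargement).
#' @slot pattern_name label for the pattern.
#' @export
setClass("AtrophySpec",
         slots = c(targets = "numeric", pattern_name = "character"))

setValidity("AtrophySpec", function(object) {
  t <- object@targets
  if (length(t) && (is.null(names(t)) || anyDuplicated(names(t))))
    return("targets must be uniquely named by structure id")
  if (any(!is.finite(t))) return("shifts must be finite")
  TRUE
})
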