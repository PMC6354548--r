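#' @rdname OntologyHierarchy-class
#' @param object,x an object.
#' @export
setGeneric("structureIds", function(x) standardGeneric("structureIds"))

#' @rdname OntologyHierarchy-class
#' @export
setGeneric("baseStructures", function(x) standardGeneric("baseStructures"))

#' @rdname OntologyHierarchy-class
#' @export
setGeneric("superStructures", function(x) standardGeneric("superStructures"))

#' @rdname OntologyHierarchy-class
#' @param id a structure id.
#' @export
setGeneric("childrenOf", function(x, id) standardGeneric("childrenOf"))

#' @rdname OntologyHierarchy-class
#' @export
setGeneric("baseDescendants", function(x, id) standardGeneric("baseDescendants"))

#' @rdname OntologyHierarchy-class
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname VolumeTable-class
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname VolumeTable-class
#' @export
setGeneric("caseAge", function(x) standardGeneric("caseAge"))

#' @rdname VolumeTable-class
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname VolumeTable-class
#' @export
setGeneric("volumeUnits", function(x) standardGeneric("volumeUnits"))

#' @rdname ZScoreTable-class
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' @rdname ZScoreTable-class
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))

#' @rdname NormativeModel-class
#' @export
setGeneric("modelCoefs", function(x) standardGeneric("modelCoefs"))

#' @rdname NormativeModel-class
#' @export
setGeneric("ageRange", function(x) standardGeneric("ageRange"))

#' @rdname ContingencyCounts-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' Agreement metrics from contingency counts
#'
#' @param x a [ContingencyCounts-class] object.
#' @return named numeric with \code{accuracy}, \code{sensitivity},
#'   \code{precision}, \code{specificity} as proportions in [0, 1];
#'   a metric whose denominator is zero is \code{NA}.
#' @export
setGeneric("agreementMetrics", function(x) standardGeneric("agreementMetrics"))

#' Cohen's kappa from contingency counts
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' marginal-product expected agreement.  \code{NA} when \eqn{p_e = 1}.
#'
#' @param x a [ContingencyCounts-class] object.
#' @return a number in [-1, 1], or NA.
#' @export
setGeneric("cohenKappa", function(x) standardGeneric("cohenKappa"))

#' @rdname ClinicalKnowledgeFilter-class
#' @export
setGeneric("reportedStructures", function(x) standardGeneric("reportedStructures"))

#' @rdname ClinicalKnowledgeFilter-class
#' @export
setGeneric("triggerThreshold", function(x) standardGeneric("triggerThreshold"))

#' @rdname ClinicalKnowledgeFilter-class
#' @export
setGeneric("triggerDirections", function(x) standardGeneric("triggerDirections"))

#' @rdname SentenceReport-class
#' @export
setGeneric("sentences", function(x) standardGeneric("sentences"))

#' @rdname SentenceReport-class
#' @export
setGeneric("assertions", function(x) standardGeneric("assertions"))
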