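#' Construct a volume table for one case
#'
#' @param case_id case identifier.
#' @param age age in years.
#' @param volumes named numeric vector, structure id -> value.
#' @param units "mm3" (default) or "ratio".
#' @return a [VolumeTable-class].
#' @examples
#' VolumeTable("case1", 72, c(hippocampus_L = 4000, hippocampus_R = 4100))
#' @export
VolumeTable <- function(case_id, age, volumes, units = "mm3") {
  new("VolumeTable", case_id = as.character(case_id), age = as.numeric(age),
      volumes = volumes, units = units)
}

#' @rdname VolumeTable-class
#' @export
setMethod("caseId", "VolumeTable", function(x) x@case_id)

#' @rdname VolumeTable-class
#' @export
setMethod("caseAge", "VolumeTable", function(x) x@age)

#' @rdname VolumeTable-class
#' @export
setMethod("volumes", "VolumeTable", function(x) x@volumes)

#' @rdname VolumeTable-class
#' @export
setMethod("volumeUnits", "VolumeTable", function(x) x@units)

setMethod("show", "VolumeTable", function(object) {
  cat("VolumeTable for case '", object@case_id, "' (age ",
      format(object@age), " y): ", length(object@volumes), " structures [",
      object@units, "]\n", sep = "")
  v <- utils::head(object@volumes, 4L)
  cat(paste0("  ", names(v), " = ", signif(v, 6), collapse = "\n"), "\n")
  if (length(object@volumes) > 4L) cat("  ...\n")
})

#' @rdname ZScoreTable-class
#' @export
setMethod("caseId", "ZScoreTable", function(x) x@case_id)

#' @rdname ZScoreTable-class
#' @export
setMethod("caseAge", "ZScoreTable", function(x) x@age)

#' @rdname ZScoreTable-class
#' @export
setMethod("zscores", "ZScoreTable", function(x) x@z)

#' @rdname ZScoreTable-class
#' @export
setMethod("ratios", "ZScoreTable", function(x) x@ratio)

setMethod("show", "ZScoreTable", function(object) {
  cat("ZScoreTable for case '", object@case_id, "' (age ",
      format(object@age), " y): ", length(object@z), " structures",
      if (object@extrapolated) " [age outside normative range]", "\n",
      sep = "")
  z <- object@z[order(abs(object@z), decreasing = TRUE)]
  z <- utils::head(z[!is.na(z)], 4L)
  cat(paste0("  ", names(z), ": z = ", sprintf("%+.2f", z), collapse = "\n"),
      "\n")
})
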