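#' Normalize volumes to total-brain volume ratios
#'
#' Divides every structure volume by the case denominator
#' \eqn{D = \sum \mathrm{base\ tissue} + \sum \mathrm{ventricles} +
#' \sum \mathrm{deep\ sulci}}, i.e. the sum over all level-0 labels of the
#' hierarchy.  Because every superstructure is a disjoint union of base
#' labels, the base-label ratios of each tissue class partition their share
#' of 1.
#'
#' @param v an aggregated [VolumeTable-class] in mm3 (every label of \code{h}
#'   present; base-only tables are aggregated on the fly).
#' @param h an [OntologyHierarchy-class].
#' @return a [VolumeTable-class] with \code{units = "ratio"}.
#' @examples
#' h <- defaultHierarchy()
#' v <- VolumeTable("c", 70, stats::setNames(
#'   rep(30000, length(baseStructures(h))), baseStructures(h)))
#' r <- computeRatios(aggregateSuperstructures(v, h), h)
#' sum(ratios <- volumes(r)[baseStructures(h)])  # 1
#' @export
computeRatios <- function(v, h) {
  stopifnot(is(v, "VolumeTable"), is(h, "OntologyHierarchy"))
  if (v@units == "ratio") return(v)
  if (!all(structureIds(h) %in% names(v@volumes)))
    v <- aggregateSuperstructures(v, h)
  D <- sum(v@volumes[baseStructures(h)])
  if (!is.finite(D) || D <= 0)
    stop("total brain volume denominator is not positive for case '",
         v@case_id, "'")
  new("VolumeTable", case_id = v@case_id, age = v@age,
      volumes = v@volumes / D, units = "ratio")
}

# volumes -> ratio table, tolerating base-only input
.asRatios <- function(v, h) {
  if (v@units == "ratio") v else computeRatios(v, h)
}

.SD_FLOOR <- 1e-12

#' Fit the age-linear normative model on a control cohort
#'
#' Per structure, ordinary least squares of total-brain-normalized volume
#' ratio on age; the residual spread is the homoscedastic estimate
#' \eqn{\sqrt{RSS/(n-2)}} (floored at a tiny epsilon so that degenerate
#' noiseless cohorts still yield a valid model).
#'
#' @param controls list of [VolumeTable-class] (mm3, base-level or
#'   aggregated; or ratio tables).
#' @param h an [OntologyHierarchy-class].
#' @param normalize fit on total-brain-normalized ratios (default TRUE, the
#'   recommended scale) or on raw mm3 volumes.
#' @return a [NormativeModel-class].
#' @export
fitNormative <- function(controls, h, normalize = TRUE) {
  stopifnot(is.list(controls), length(controls) >= 3L,
            is(h, "OntologyHierarchy"))
  ages <- vapply(controls, caseAge, 0)
  if (length(unique(ages)) < 2L)
    stop("control ages are constant; the age slope is unidentifiable")
  tabs <- lapply(controls, function(v) {
    v <- if (normalize) .asRatios(v, h) else {
      if (!all(structureIds(h) %in% names(v@volumes)))
        aggregateSuperstructures(v, h) else v
    }
    v@volumes
  })
  ids <- structureIds(h)
  for (i in seq_along(tabs)) {
    miss <- setdiff(ids, names(tabs[[i]]))
    if (length(miss))
      stop("structure '", miss[1], "' missing in control '",
           caseId(controls[[i]]), "'")
  }
  Y <- vapply(tabs, function(v) v[ids], numeric(length(ids)))  # ids x n
  X <- cbind(1, ages)
  fit <- stats::lm.fit(X, t(Y))
  cf <- t(fit$coefficients)
  rss <- colSums(as.matrix(fit$residuals)^2)
  n <- length(ages)
  coef <- data.frame(structure_id = ids,
                     intercept = cf[, 1], slope = cf[, 2],
                     residual_sd = pmax(sqrt(rss / (n - 2)), .SD_FLOOR),
                     n_controls = n, stringsAsFactors = FALSE,
                     row.names = NULL)
  new("NormativeModel", coef = coef, age_range = range(ages),
      units = if (normalize) "ratio" else "mm3")
}

#' @rdname NormativeModel-class
#' @export
setMethod("modelCoefs", "NormativeModel", function(x) x@coef)

#' @rdname NormativeModel-class
#' @export
setMethod("ageRange", "NormativeModel", function(x) x@age_range)

setMethod("show", "NormativeModel", function(object) {
  cat("NormativeModel:", nrow(object@coef), "structures on the",
      object@units, "scale\n")
  cat("  n_controls =", object@coef$n_controls[1],
      "; age range", object@age_range[1], "-", object@age_range[2], "y\n")
})

#' Predicted normative mean for structures at an age
#'
#' @param m a [NormativeModel-class].
#' @param age age in years.
#' @param ids structure ids (default: all modeled).
#' @return named numeric of predicted mean ratios (or volumes).
#' @export
predictNormative <- function(m, age, ids = NULL) {
  cf <- m@coef
  if (!is.null(ids)) {
    miss <- setdiff(ids, cf$structure_id)
    if (length(miss))
      stop("structure(s) not in normative model: ",
           paste(miss, collapse = ", "))
    cf <- cf[match(ids, cf$structure_id), ]
  }
  stats::setNames(cf$intercept + cf$slope * age, cf$structure_id)
}

#' Score one case against the normative model
#'
#' \eqn{z = (\mathrm{ratio} - (\alpha + \beta\,\mathrm{age})) / \sigma_{res}}
#' per structure.  Atrophy of a tissue structure gives negative z;
#' ventricular enlargement gives positive z.  Structures absent from the
#' model get \code{NA} z (with the ratio still carried); an age outside the
#' normative cohort's range sets the extrapolation flag and warns, but
#' scores are still returned.
#'
#' @param case a [VolumeTable-class] (mm3 base/aggregated, or ratio).
#' @param m a [NormativeModel-class].
#' @param h an [OntologyHierarchy-class].
#' @return a [ZScoreTable-class].
#' @export
zscoreCase <- function(case, m, h) {
  stopifnot(is(case, "VolumeTable"), is(m, "NormativeModel"),
            is(h, "OntologyHierarchy"))
  v <- if (m@units == "ratio") .asRatios(case, h) else {
    if (!all(structureIds(h) %in% names(case@volumes)))
      aggregateSuperstructures(case, h) else case
  }
  extra <- case@age < m@age_range[1] || case@age > m@age_range[2]
  if (extra)
    warning("case '", case@case_id, "' age ", case@age,
            " lies outside the normative age range [",
            m@age_range[1], ", ", m@age_range[2], "]; z-scores extrapolate")
  ids <- names(v@volumes)
  cf <- m@coef[match(ids, m@coef$structure_id), ]
  pred <- cf$intercept + cf$slope * case@age
  z <- (v@volumes - pred) / cf$residual_sd   # NA where unmodeled
  new("ZScoreTable", case_id = case@case_id, age = case@age,
      ratio = v@volumes, z = stats::setNames(as.numeric(z), ids),
      extrapolated = extra)
}

#' Vectorized cohort scoring
#'
#' Matrix fast path for scoring many cases at once: aggregates base volumes
#' through the hierarchy, normalizes each case by its total-brain
#' denominator, and returns the z-score matrix.  Equivalent to calling
#' [aggregateSuperstructures()], [computeRatios()] and [zscoreCase()] per
#' case.
#'
#' @param vols numeric matrix, base structures x cases (rownames = base ids).
#' @param ages numeric vector of case ages (length = ncol(vols)).
#' @param m a [NormativeModel-class] on the ratio scale.
#' @param h an [OntologyHierarchy-class].
#' @return numeric matrix, all hierarchy labels x cases, of z-scores.
#' @export
scoreCohort <- function(vols, ages, m, h) {
  stopifnot(is.matrix(vols), length(ages) == ncol(vols),
            m@units == "ratio")
  base <- baseStructures(h)
  if (!all(base %in% rownames(vols)))
    stop("vols must have one row per base structure")
  A <- .aggregationMatrix(h)
  agg <- A %*% vols[base, , drop = FALSE]
  D <- colSums(vols[base, , drop = FALSE])
  if (any(D <= 0)) stop("non-positive total brain volume denominator")
  rat <- sweep(agg, 2, D, "/")
  ids <- rownames(rat)
  cf <- m@coef[match(ids, m@coef$structure_id), ]
  pred <- outer(cf$intercept, rep(1, length(ages))) +
    outer(cf$slope, ages)
  (rat - pred) / cf$residual_sd
}

#' Read / write a normative model as structured JSON
#'
#' One record per structure plus the cohort age range and the scale; the
#' writer/reader pair round-trips losslessly (full double precision).
#'
#' @param path file path.
#' @return \code{readNormativeModel} returns a [NormativeModel-class];
#'   \code{writeNormativeModel} returns \code{path} invisibly.
#' @export
readNormativeModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new("NormativeModel",
      coef = as.data.frame(obj$structures, stringsAsFactors = FALSE),
      age_range = as.numeric(obj$age_range), units = obj$units)
}

#' @rdname readNormativeModel
#' @param m a [NormativeModel-class] to serialize.
#' @export
writeNormativeModel <- function(m, path) {
  stopifnot(is(m, "NormativeModel"))
  jsonlite::write_json(
    list(units = m@units, age_range = m@age_range, structures = m@coef),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
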