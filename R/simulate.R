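#' Construct a synthetic cohort specification
#'
#' @param n number of controls (default 179, a typical multi-site normative
#'   cohort size).
#' @param age_range uniform age bounds in years (default 20-96, adult span).
#' @param model data.frame(structure_id, intercept, slope, noise_sd) on the
#'   ratio scale, one row per base structure.
#' @param tbv_mean,tbv_sd case-level total brain volume (mm3).
#' @param seed default RNG seed.
#' @return a [CohortSpec-class].
#' @export
CohortSpec <- function(n, age_range, model, tbv_mean = 1.47e6,
                       tbv_sd = 8e4, seed = 1L) {
  new("CohortSpec", n = as.integer(n), age_range = as.numeric(age_range),
      model = as.data.frame(model, stringsAsFactors = FALSE),
      tbv_mean = tbv_mean, tbv_sd = tbv_sd, seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec: n =", object@n, ", ages", object@age_range[1], "-",
      object@age_range[2], "y,", nrow(object@model), "base structures\n")
})

# mean volume (mm3) of each base structure of the default hierarchy at the
# anchor age; the generative ratio model is derived from these.
.DEFAULT_VOLUMES <- c(
  superior_frontal_gyrus = 70000, middle_frontal_gyrus = 60000,
  inferior_frontal_gyrus = 40000, precentral_gyrus = 50000,
  postcentral_gyrus = 40000, superior_parietal_lobule = 50000,
  supramarginal_gyrus = 30000, angular_gyrus = 30000,
  superior_temporal_gyrus = 40000, middle_temporal_gyrus = 50000,
  inferior_temporal_gyrus = 40000, fusiform_gyrus = 30000,
  superior_occipital_gyrus = 24000, middle_occipital_gyrus = 30000,
  inferior_occipital_gyrus = 20000, cuneus = 20000,
  cingulate_gyrus = 40000, parahippocampal_gyrus = 16000,
  entorhinal_area = 3000, hippocampus = 4000, amygdala = 1800,
  caudate = 4000, lateral_ventricle = 12000)

.ANCHOR_AGE <- 58  # midpoint of the default age range

#' Default synthetic-cohort specification
#'
#' Generative model emulating an adult normative cohort: per base structure,
#' volume ratio is linear in age with Gaussian noise (structures
#' independent).  Anchor mean ratios reflect typical adult regional volumes
#' (total ~1.47 L; hippocampus ~4 mL, ratio ~0.0027).  Aging slopes are
#' -0.2\%/year of the anchor mean for tissue, +1.5\%/year for ventricles and
#' +1\%/year for deep sulci; noise SD is 8\% of the anchor mean.
#'
#' @param h an [OntologyHierarchy-class] (default [defaultHierarchy()]).
#' @param n cohort size (default 179).
#' @param age_range age bounds (default c(20, 96)).
#' @param noise_frac noise SD as a fraction of the anchor mean ratio.
#' @param seed default seed.
#' @return a [CohortSpec-class].
#' @export
defaultCohortSpec <- function(h = defaultHierarchy(), n = 179L,
                              age_range = c(20, 96), noise_frac = 0.08,
                              seed = 1L) {
  base <- baseStructures(h)
  cls <- .tissueClass(h)[base]
  vol <- vapply(base, function(id) {
    key <- sub("_(L|R)$", "", id)
    if (id == "third_ventricle") 1500
    else if (id == "deep_sulci") 60000
    else .DEFAULT_VOLUMES[[key]]
  }, 0)
  mu <- vol / sum(vol)  # anchor ratios sum to 1
  slope_frac <- c(tissue = -0.002, ventricle = 0.015, sulcus = 0.01)[cls]
  slope <- unname(slope_frac) * mu
  model <- data.frame(structure_id = base,
                      intercept = mu - slope * .ANCHOR_AGE,
                      slope = slope,
                      noise_sd = noise_frac * mu,
                      stringsAsFactors = FALSE, row.names = NULL)
  CohortSpec(n = n, age_range = age_range, model = model, seed = seed)
}

# ratio matrix (base x n) drawn from the generative model at given ages
.drawRatios <- function(model, ages) {
  p <- nrow(model)
  n <- length(ages)
  mu <- outer(model$intercept, rep(1, n)) + outer(model$slope, ages)
  r <- mu + matrix(stats::rnorm(p * n, sd = model$noise_sd), p, n)
  r <- pmax(r, 1e-8)  # generated ratios must stay positive
  rownames(r) <- model$structure_id
  r
}

#' Simulate a normative control cohort
#'
#' Draws \code{spec@n} controls: age uniform over the spec's range, each
#' base structure's ratio from its linear-in-age Gaussian model
#' (independently), scaled by a case-level total brain volume to mm3.
#' Deterministic given the seed.
#'
#' @param spec a [CohortSpec-class].
#' @param h an [OntologyHierarchy-class]; the spec must model every base
#'   structure.
#' @param seed RNG seed (default: the spec's).
#' @return list of base-level [VolumeTable-class] objects (mm3).
#' @export
simulateControls <- function(spec, h, seed = spec@seed) {
  stopifnot(is(spec, "CohortSpec"), is(h, "OntologyHierarchy"))
  miss <- setdiff(baseStructures(h), spec@model$structure_id)
  if (length(miss))
    stop("cohort spec does not model base structure(s): ",
         paste(miss, collapse = ", "))
  set.seed(seed)
  ages <- stats::runif(spec@n, spec@age_range[1], spec@age_range[2])
  tbv <- pmax(stats::rnorm(spec@n, spec@tbv_mean, spec@tbv_sd),
              spec@tbv_mean / 2)
  r <- .drawRatios(spec@model, ages)
  lapply(seq_len(spec@n), function(i)
    VolumeTable(sprintf("ctrl_%04d", i), ages[i], r[, i] * tbv[i]))
}

#' True aggregate normative model of a cohort spec
#'
#' Propagates the generative base-structure model through the hierarchy:
#' each label's intercept and slope are sums over its base descendants and
#' its SD is the root of the summed variances (structures independent).
#' This is the noiseless reference against which ground-truth patterns of
#' simulated patients are computed.
#'
#' @param spec a [CohortSpec-class].
#' @param h an [OntologyHierarchy-class].
#' @return a [NormativeModel-class] on the ratio scale.
#' @export
trueAggregateModel <- function(spec, h) {
  stopifnot(is(spec, "CohortSpec"), is(h, "OntologyHierarchy"))
  A <- .aggregationMatrix(h)
  m <- spec@model[match(colnames(A), spec@model$structure_id), ]
  coef <- data.frame(structure_id = rownames(A),
                     intercept = as.numeric(A %*% m$intercept),
                     slope = as.numeric(A %*% m$slope),
                     residual_sd = sqrt(as.numeric(A %*% m$noise_sd^2)),
                     n_controls = spec@n, stringsAsFactors = FALSE,
                     row.names = NULL)
  new("NormativeModel", coef = coef, age_range = spec@age_range,
      units = "ratio")
}

#' Construct an atrophy/enlargement injection pattern
#'
#' @param targets named numeric: structure id -> shift in SD units of the
#'   generative model (negative = atrophy).
#' @param pattern_name label.
#' @return an [AtrophySpec-class].
#' @examples
#' AtrophySpec(c(hippocampus_L = -3), "left hippocampal atrophy")
#' @export
AtrophySpec <- function(targets = numeric(0), pattern_name = "custom") {
  if (length(targets) == 0L) targets <- stats::setNames(numeric(0), character(0))
  new("AtrophySpec", targets = targets, pattern_name = pattern_name)
}

setMethod("show", "AtrophySpec", function(object) {
  cat("AtrophySpec '", object@pattern_name, "': ", length(object@targets),
      " target(s)\n", sep = "")
  if (length(object@targets))
    cat(paste0("  ", names(object@targets), ": ",
               sprintf("%+.1f SD", object@targets), collapse = "\n"), "\n")
})

# per-base multiplicative factors realizing the injected shifts at an age
.shiftFactors <- function(spec, atrophy, age, h, true_model) {
  base <- baseStructures(h)
  fac <- stats::setNames(rep(1, length(base)), base)
  if (!length(atrophy@targets)) return(fac)
  bad <- setdiff(names(atrophy@targets), structureIds(h))
  if (length(bad))
    stop("atrophy target(s) not in hierarchy: ", paste(bad, collapse = ", "))
  cf <- true_model@coef
  for (t in names(atrophy@targets)) {
    i <- match(t, cf$structure_id)
    mu_t <- cf$intercept[i] + cf$slope[i] * age
    f <- (mu_t + atrophy@targets[[t]] * cf$residual_sd[i]) / mu_t
    if (!is.finite(f) || f < 0)
      stop("infeasible shift for target '", t, "'")
    d <- baseDescendants(h, t)
    fac[d] <- fac[d] * f
  }
  fac
}

#' Simulate a patient case with an injected abnormality pattern
#'
#' The patient is a random subject from the cohort model (same age-linear
#' mean and Gaussian noise as the controls) whose target structures' mean
#' ratios are shifted by the stated multiples of the generative SD; a shift
#' on a superstructure scales all its base descendants proportionally.  The
#' ground-truth pattern is computed from the noiseless shifted means scored
#' against the true aggregate model, through [detectPattern()].
#'
#' @param spec a [CohortSpec-class].
#' @param atrophy an [AtrophySpec-class].
#' @param age patient age in years.
#' @param seed RNG seed.
#' @param h an [OntologyHierarchy-class].
#' @param ckf the [ClinicalKnowledgeFilter-class] used for the ground-truth
#'   pattern.
#' @param case_id case identifier.
#' @return list with \code{case} (base-level [VolumeTable-class], mm3),
#'   \code{truth} (the ground-truth [FindingPattern-class]) and
#'   \code{true_z} (the noiseless [ZScoreTable-class]).
#' @examples
#' h <- defaultHierarchy()
#' spec <- defaultCohortSpec(h, n = 50)
#' p <- simulatePatient(spec, AtrophySpec(c(hippocampus_L = -3)), 72,
#'                      seed = 7, h = h)
#' patternKeys(p$truth)
#' @export
simulatePatient <- function(spec, atrophy = AtrophySpec(), age, seed,
                            h = defaultHierarchy(), ckf = defaultCKF(h),
                            case_id = "patient") {
  stopifnot(is(spec, "CohortSpec"), is(atrophy, "AtrophySpec"))
  tm <- trueAggregateModel(spec, h)
  fac <- .shiftFactors(spec, atrophy, age, h, tm)
  m <- spec@model
  mu <- (m$intercept + m$slope * age) * fac[m$structure_id]
  set.seed(seed)
  tbv <- max(stats::rnorm(1, spec@tbv_mean, spec@tbv_sd), spec@tbv_mean / 2)
  r <- pmax(mu + stats::rnorm(nrow(m), sd = m$noise_sd), 1e-8)
  case <- VolumeTable(case_id, age,
                      stats::setNames(r * tbv, m$structure_id))
  # noiseless ground truth through the same pipeline, true model
  star <- VolumeTable(paste0(case_id, "_truth"), age,
                      stats::setNames(mu * spec@tbv_mean, m$structure_id))
  true_z <- zscoreCase(star, tm, h)
  list(case = case, truth = detectPattern(true_z, ckf), true_z = true_z)
}

#' Sample null cases from a fitted normative model
#'
#' Draws base-structure ratios from the fitted model itself (mean at the
#' sampled age plus Gaussian residual noise) and scales by a case total
#' brain volume, so the cases are exactly null with respect to the model
#' they will be scored against.  Used for trigger-rate calibration.
#'
#' @param m a [NormativeModel-class] on the ratio scale.
#' @param h an [OntologyHierarchy-class].
#' @param n number of cases.
#' @param age_range uniform age bounds for the sampled cases.
#' @param tbv_mean,tbv_sd total brain volume distribution (mm3).
#' @param seed RNG seed.
#' @return list with \code{vols} (base structures x n volume matrix, mm3)
#'   and \code{ages}; feed to [scoreCohort()].
#' @export
simulateNullCases <- function(m, h, n, age_range = ageRange(m),
                              tbv_mean = 1.47e6, tbv_sd = 8e4, seed = 1L) {
  stopifnot(is(m, "NormativeModel"), m@units == "ratio")
  base <- baseStructures(h)
  cf <- m@coef[match(base, m@coef$structure_id), ]
  if (anyNA(cf$intercept))
    stop("normative model does not cover all base structures")
  set.seed(seed)
  ages <- stats::runif(n, age_range[1], age_range[2])
  tbv <- pmax(stats::rnorm(n, tbv_mean, tbv_sd), tbv_mean / 2)
  gen <- data.frame(structure_id = base, intercept = cf$intercept,
                    slope = cf$slope, noise_sd = cf$residual_sd)
  r <- .drawRatios(gen, ages)
  list(vols = sweep(r, 2, tbv, "*"), ages = ages)
}

#' Read / write cohort and atrophy specs as JSON
#'
#' @param path file path.
#' @return the deserialized spec object; writers return \code{path}
#'   invisibly.
#' @export
readCohortSpec <- function(path) {
  obj <- jsonlite::fromJSON(path)
  CohortSpec(n = obj$n, age_range = obj$age_range,
             model = as.data.frame(obj$model), tbv_mean = obj$tbv_mean,
             tbv_sd = obj$tbv_sd, seed = obj$seed)
}

#' @rdname readCohortSpec
#' @param spec a [CohortSpec-class].
#' @export
writeCohortSpec <- function(spec, path) {
  jsonlite::write_json(
    list(n = spec@n, age_range = spec@age_range, model = spec@model,
         tbv_mean = spec@tbv_mean, tbv_sd = spec@tbv_sd, seed = spec@seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname readCohortSpec
#' @export
readAtrophySpec <- function(path) {
  obj <- jsonlite::fromJSON(path)
  AtrophySpec(stats::setNames(as.numeric(obj$shift), obj$structure_id),
              pattern_name = obj$pattern_name %||% "custom")
}

#' @rdname readCohortSpec
#' @param atrophy an [AtrophySpec-class].
#' @export
writeAtrophySpec <- function(atrophy, path) {
  jsonlite::write_json(
    list(pattern_name = atrophy@pattern_name,
         structure_id = names(atrophy@targets),
         shift = unname(atrophy@targets)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
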