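#' Construct contingency counts
#'
#' @param tp,fp,fn,tn non-negative counts: test-positive/reference-positive,
#'   test-only, reference-only, neither.
#' @return a [ContingencyCounts-class].
#' @examples
#' cc <- ContingencyCounts(45, 12, 15, 20)
#' agreementMetrics(cc)
#' cohenKappa(ContingencyCounts(23, 94, 98, 1901))
#' @export
ContingencyCounts <- function(tp, fp, fn, tn) {
  new("ContingencyCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

#' @rdname ContingencyCounts-class
#' @export
setMethod("counts", "ContingencyCounts", function(x)
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))

setMethod("show", "ContingencyCounts", function(object) {
  cat("ContingencyCounts: TP =", object@tp, " FP =", object@fp,
      " FN =", object@fn, " TN =", object@tn, "\n")
})

#' @rdname agreementMetrics
#' @export
setMethod("agreementMetrics", "ContingencyCounts", function(x) {
  tp <- x@tp; fp <- x@fp; fn <- x@fn; tn <- x@tn
  N <- tp + fp + fn + tn
  if (N == 0L) stop("empty contingency table")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (tp + tn) / N,
    sensitivity = safe(tp, tp + fn),
    precision = safe(tp, tp + fp),
    specificity = safe(tn, tn + fp))
})

#' @rdname cohenKappa
#' @export
setMethod("cohenKappa", "ContingencyCounts", function(x) {
  tp <- x@tp; fp <- x@fp; fn <- x@fn; tn <- x@tn
  N <- tp + fp + fn + tn
  if (N == 0L) stop("empty contingency table")
  po <- (tp + tn) / N
  pe <- ((tp + fp) / N) * ((tp + fn) / N) +
    ((fn + tn) / N) * ((fp + tn) / N)
  if (abs(1 - pe) < .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
})

# positive (case, term) key set of a coded-findings frame, restricted to the
# universe; out-of-universe terms are dropped and reported via message().
.positiveKeys <- function(findings, universe, cases, label = "findings") {
  stopifnot(is.data.frame(findings))
  pos <- findings[findings$polarity == "positive", , drop = FALSE]
  out <- !(pos$structure_term %in% universe)
  if (any(out))
    message(label, ": excluded ", sum(out),
            " finding(s) with term(s) outside the universe: ",
            paste(unique(pos$structure_term[out]), collapse = ", "))
  pos <- pos[!out & pos$case_id %in% cases, , drop = FALSE]
  unique(paste(pos$case_id, pos$structure_term, sep = "\r"))
}

#' Build a contingency table between two finding sources
#'
#' Over the fixed universe of (case, structure term) entries, an entry is TP
#' when both sources mark it positive, FP when only the test source does, FN
#' when only the reference does, TN otherwise (silence is negative).  Counts
#' always sum to \code{length(cases) * length(universe)}.
#'
#' @param ref_findings,test_findings data.frames of coded findings with
#'   columns \code{case_id}, \code{structure_term}, \code{polarity}
#'   ("positive"/"negative"); the reference is the gold standard.
#' @param universe character vector of structure terms to evaluate.
#' @param cases character vector of case ids.
#' @return a [ContingencyCounts-class].
#' @export
buildContingency <- function(ref_findings, test_findings, universe, cases) {
  stopifnot(length(universe) > 0L, length(cases) > 0L)
  universe <- unique(universe)
  cases <- unique(as.character(cases))
  refK <- .positiveKeys(ref_findings, universe, cases, "reference")
  tstK <- .positiveKeys(test_findings, universe, cases, "test")
  tp <- length(intersect(refK, tstK))
  fp <- length(setdiff(tstK, refK))
  fn <- length(setdiff(refK, tstK))
  tn <- length(cases) * length(universe) - tp - fp - fn
  ContingencyCounts(tp, fp, fn, tn)
}

#' Majority vote over three raters' coded findings
#'
#' A (case, term) entry is positive for the consensus source when at least
#' two of the three raters mark it positive.
#'
#' @param findings data.frame of coded findings from exactly three sources
#'   (columns \code{case_id}, \code{source}, \code{structure_term},
#'   \code{polarity}).
#' @param universe structure terms to evaluate.
#' @param cases case ids.
#' @param source name of the consensus source (default "RRm").
#' @return data.frame of positive coded findings for the consensus source.
#' @export
majorityVote <- function(findings, universe, cases, source = "RRm") {
  raters <- unique(findings$source)
  if (length(raters) != 3L)
    stop("majority voting requires exactly 3 rater sources; got ",
         length(raters))
  keys <- lapply(raters, function(r)
    .positiveKeys(findings[findings$source == r, , drop = FALSE],
                  universe, cases, label = r))
  all_keys <- unique(unlist(keys))
  votes <- vapply(all_keys, function(k)
    sum(vapply(keys, function(s) k %in% s, logical(1))), 0L)
  win <- all_keys[votes >= 2L]
  parts <- strsplit(win, "\r", fixed = TRUE)
  data.frame(case_id = vapply(parts, `[`, "", 1L),
             source = rep(source, length(win)),
             structure_term = vapply(parts, `[`, "", 2L),
             polarity = rep("positive", length(win)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Metric summary rows for a set of comparisons
#'
#' @param cc_list named list of [ContingencyCounts-class] objects.
#' @return data.frame with one row per comparison: counts, the four
#'   agreement metrics (percent) and Cohen's kappa.
#' @export
metricsTable <- function(cc_list) {
  stopifnot(is.list(cc_list), length(names(cc_list)) == length(cc_list))
  rows <- lapply(names(cc_list), function(nm) {
    cc <- cc_list[[nm]]
    m <- agreementMetrics(cc)
    data.frame(comparison = nm, tp = cc@tp, fp = cc@fp, fn = cc@fn,
               tn = cc@tn, accuracy_pct = 100 * m[["accuracy"]],
               sensitivity_pct = 100 * m[["sensitivity"]],
               precision_pct = 100 * m[["precision"]],
               specificity_pct = 100 * m[["specificity"]],
               kappa = cohenKappa(cc), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# is `a` a (strict) hierarchy ancestor of `b`?
.isAncestor <- function(h, a, b) {
  if (identical(a, b)) return(FALSE)
  db <- baseDescendants(h, b)
  da <- baseDescendants(h, a)
  all(db %in% da) && length(da) > length(db)
}

#' Categorize one automated-vs-human discrepancy
#'
#' Semi-automated decision tree over an FP or FN entry, applied in fixed
#' order; categories are mutually exclusive by tree order:
#' \enumerate{
#'   \item term not representable in the hierarchy (after alias mapping);
#'   \item[2-1] FP on a reported structure the raters never used;
#'   \item[2-2] FN on a structure absent from the clinical knowledge filter;
#'   \item[3] FN although the z-score supports the human finding (the
#'     relational rules suppressed the sentence);
#'   \item[4] the two sources' terms differ only in hierarchy extent
#'     (ancestor/descendant);
#'   \item[5] annotated segmentation error (a radiologist's visual
#'     judgment, supplied via the \code{flags} field);
#'   \item[6] otherwise: triggering-threshold disagreement, split by
#'     direction (6-FP / 6-FN).
#' }
#'
#' @param record list with fields \code{direction} ("FP" or "FN"),
#'   \code{term} (the discrepant structure term), and optionally
#'   \code{counterpart_term} (the other source's term for the same case),
#'   \code{aliases} (named character mapping report vocabulary to hierarchy
#'   ids), \code{rater_terms} (vocabulary ever used by the raters),
#'   \code{zscores} (a [ZScoreTable-class]), \code{flags} (character).
#' @param h an [OntologyHierarchy-class].
#' @param ckf a [ClinicalKnowledgeFilter-class].
#' @return list with \code{category} (one of "1", "2-1", "2-2", "3", "4",
#'   "5", "6-FP", "6-FN") and \code{rationale}.
#' @export
categorizeDiscrepancy <- function(record, h = defaultHierarchy(),
                                  ckf = defaultCKF(h)) {
  dir <- record$direction
  if (!identical(dir, "FP") && !identical(dir, "FN"))
    stop("record must refer to an FP or FN entry; got '", dir, "'")
  result <- function(category, rationale) list(category = category,
                                               rationale = rationale)
  mapTerm <- function(term) {
    if (is.null(term)) return(NULL)
    if (term %in% structureIds(h)) return(term)
    al <- record$aliases
    if (!is.null(al) && term %in% names(al) && al[[term]] %in% structureIds(h))
      return(al[[term]])
    NA_character_
  }
  id <- mapTerm(record$term)
  if (is.na(id))
    return(result("1", paste0("term '", record$term,
                              "' is not representable in the hierarchy")))
  if (dir == "FP" && !is.null(record$rater_terms)) {
    rater_ids <- vapply(record$rater_terms, mapTerm, "")
    if (!(id %in% record$rater_terms) && !(id %in% rater_ids))
      return(result("2-1", paste0("structure '", id,
                                  "' was never used by the raters")))
  }
  if (dir == "FN" && !(id %in% reportedStructures(ckf)))
    return(result("2-2", paste0("structure '", id,
                                "' is absent from the clinical knowledge filter")))
  if (dir == "FN" && !is.null(record$zscores)) {
    z <- zscores(record$zscores)
    if (id %in% names(z) && !is.na(z[[id]])) {
      dirn <- triggerDirections(ckf)
      supports <- if (identical(unname(dirn[id]), "enlargement"))
        z[[id]] > ckf@threshold else z[[id]] < -ckf@threshold
      if (isTRUE(supports))
        return(result("3", paste0("z(", id, ") = ", round(z[[id]], 2),
                                  " supports the finding but the relational ",
                                  "rules suppressed the sentence")))
    }
  }
  cp <- mapTerm(record$counterpart_term)
  if (!is.null(cp) && !is.na(cp) &&
      (.isAncestor(h, id, cp) || .isAncestor(h, cp, id)))
    return(result("4", paste0("terms '", id, "' and '", cp,
                              "' differ only in hierarchy extent")))
  if ("segmentation_error" %in% record$flags)
    return(result("5", "annotated segmentation error"))
  result(paste0("6-", dir),
         "triggering-threshold disagreement with the human report")
}

#' Read coded report findings from TSV
#'
#' Expected columns: \code{case_id}, \code{source}, \code{structure_term},
#' \code{polarity}; an optional \code{flags} column carries
#' comma-separated annotation flags (e.g. \code{segmentation_error}).
#'
#' @param path TSV file path.
#' @return data.frame of coded findings.
#' @export
readCodedFindings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("case_id", "source", "structure_term", "polarity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("coded findings file is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!df$polarity %in% c("positive", "negative"))
  if (length(bad))
    stop("invalid polarity at data row ", bad[1])
  df$case_id <- as.character(df$case_id)
  df
}

#' Reference reader-study contingency counts
#'
#' Loads the contingency counts reported by the feasibility reader study
#' this pipeline models (92 memory-clinic cases read by three
#' neuroradiologists versus the automated sentences), shipped as a
#' plain-text fixture.  Regions: \code{brain_tissue} and \code{ventricle}
#' (case-level, any-comment coding) and \code{structurewise} (the 92 cases x
#' 23 structure-term universe).
#'
#' @param region one of "brain_tissue", "ventricle", "structurewise", or
#'   "all".
#' @return named list of [ContingencyCounts-class] keyed by comparison
#'   (e.g. "AS-RR1"); for \code{region = "all"}, a data.frame of the raw
#'   counts.
#' @export
referenceAgreementCounts <- function(region = c("structurewise",
                                                "brain_tissue", "ventricle",
                                                "all")) {
  region <- match.arg(region)
  path <- system.file("extdata", "agreement_counts.tsv",
                      package = "BrainVolReport", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (region == "all") return(df)
  df <- df[df$region == region, , drop = FALSE]
  stats::setNames(lapply(seq_len(nrow(df)), function(i)
    ContingencyCounts(df$tp[i], df$fp[i], df$fn[i], df$tn[i])),
    df$comparison)
}
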