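#' Construct a clinical knowledge filter
#'
#' @param h an [OntologyHierarchy-class] providing the structure vocabulary;
#'   the default configuration reports 20 structures: 2 hemispheres, 10
#'   lobes, hippocampus and caudate left/right (16 tissue entries), the
#'   lateral ventricles, third ventricle and deep sulci (4 non-tissue
#'   entries).
#' @param threshold trigger threshold on |z| (default 2).
#' @param prominence_max_lobes largest affected-lobe subset reported as
#'   "prominent" under hemispheric atrophy (default 2).
#' @param direct tissue structure ids for direct triggering.
#' @param ventricular ventricle/sulcus structure ids triggered on z >
#'   +threshold.
#' @return a [ClinicalKnowledgeFilter-class].
#' @examples
#' ckf <- defaultCKF()
#' reportedStructures(ckf)
#' @export
ClinicalKnowledgeFilter <- function(h = defaultHierarchy(), threshold = 2,
                                    prominence_max_lobes = 2L,
                                    direct = c("hippocampus_L",
                                               "hippocampus_R",
                                               "caudate_L", "caudate_R"),
                                    ventricular = c("lateral_ventricle_L",
                                                    "lateral_ventricle_R",
                                                    "third_ventricle",
                                                    "deep_sulci")) {
  ids <- structureIds(h)
  lobes <- lapply(c(left = "L", right = "R"), function(side)
    stats::setNames(paste0(LOBE_NAMES, "_", side), LOBE_NAMES))
  hemis <- c(left = "hemisphere_L", right = "hemisphere_R")
  miss <- setdiff(c(hemis, unlist(lobes), direct, ventricular), ids)
  if (length(miss))
    stop("reported structure(s) not in hierarchy: ",
         paste(miss, collapse = ", "))
  new("ClinicalKnowledgeFilter", threshold = threshold,
      prominence_max_lobes = as.integer(prominence_max_lobes),
      hemispheres = hemis, lobes = lobes, direct = direct,
      ventricular = ventricular)
}

#' @rdname ClinicalKnowledgeFilter
#' @param ... passed to [ClinicalKnowledgeFilter()].
#' @export
defaultCKF <- function(...) ClinicalKnowledgeFilter(...)

#' @rdname ClinicalKnowledgeFilter-class
#' @export
setMethod("reportedStructures", "ClinicalKnowledgeFilter", function(x)
  unname(c(x@hemispheres, unlist(x@lobes), x@direct, x@ventricular)))

#' @rdname ClinicalKnowledgeFilter-class
#' @export
setMethod("triggerThreshold", "ClinicalKnowledgeFilter", function(x)
  x@threshold)

#' @rdname ClinicalKnowledgeFilter-class
#' @export
setMethod("triggerDirections", "ClinicalKnowledgeFilter", function(x) {
  ids <- reportedStructures(x)
  stats::setNames(ifelse(ids %in% x@ventricular, "enlargement", "atrophy"),
                  ids)
})

setMethod("show", "ClinicalKnowledgeFilter", function(object) {
  cat("ClinicalKnowledgeFilter:", length(reportedStructures(object)),
      "reported structures, |z| threshold", object@threshold,
      ", prominence_max_lobes", object@prominence_max_lobes, "\n")
})

# indicator ids used by the relational rule engine (2 hemispheres + 10 lobes)
.indicatorIds <- function(ckf) unname(c(ckf@hemispheres, unlist(ckf@lobes)))

# lobe subsets of sizes lo..hi, in canonical order, as a list of char vectors
.lobeSubsets <- function(lo, hi) {
  out <- list()
  if (hi < lo) return(out)
  for (k in lo:hi)
    out <- c(out, lapply(seq_len(ncol(utils::combn(LOBE_NAMES, k))),
                         function(i) utils::combn(LOBE_NAMES, k)[, i]))
  out
}

#' Detect the abnormality pattern of a scored case
#'
#' Applies the clinical knowledge filter to a z-score table: hemispheric
#' state from the hemisphere z-scores against -threshold; affected lobes per
#' hemisphere; "prominent" lobe subsets only under hemispheric atrophy, when
#' the atrophic hemisphere's affected-lobe set is a nonempty proper subset
#' of its five lobes with at most \code{prominence_max_lobes} members;
#' lobe-"specific" combinations only without any hemispheric atrophy (the
#' suppression rule), for nonempty proper subsets; direct tissue findings at
#' z < -threshold and ventricular/sulcal findings at z > +threshold.
#'
#' @param z a [ZScoreTable-class] covering both hemispheres and all 10
#'   lobes.
#' @param ckf a [ClinicalKnowledgeFilter-class].
#' @return a [FindingPattern-class].
#' @export
detectPattern <- function(z, ckf = defaultCKF()) {
  stopifnot(is(z, "ZScoreTable"), is(ckf, "ClinicalKnowledgeFilter"))
  need <- .indicatorIds(ckf)
  zz <- z@z
  miss <- need[!(need %in% names(zz)) | is.na(zz[need])]
  if (length(miss))
    stop("z-scores missing for required structure(s): ",
         paste(miss, collapse = ", "))
  T <- ckf@threshold
  hemi <- stats::setNames(zz[ckf@hemispheres] < -T, names(ckf@hemispheres))
  state <- if (all(hemi)) "bilateral" else if (hemi[["left"]]) "left" else
    if (hemi[["right"]]) "right" else "none"
  aff <- lapply(ckf@lobes, function(lb) names(lb)[zz[lb] < -T])
  empty <- list(left = character(0), right = character(0))
  prominent <- empty
  specific <- empty
  maxProm <- min(4L, ckf@prominence_max_lobes)
  if (state != "none") {
    sides <- switch(state, left = "left", right = "right",
                    bilateral = c("left", "right"))
    for (side in sides) {
      S <- aff[[side]]
      if (length(S) >= 1L && length(S) <= maxProm)
        prominent[[side]] <- S
    }
  } else {
    for (side in c("left", "right")) {
      S <- aff[[side]]
      if (length(S) >= 1L && length(S) <= 4L)
        specific[[side]] <- S
    }
  }
  dz <- zz[ckf@direct]
  hit <- !is.na(dz) & dz < -T
  direct <- data.frame(structure = ckf@direct[hit],
                       polarity = rep("atrophy", sum(hit)),
                       stringsAsFactors = FALSE)
  vz <- zz[ckf@ventricular]
  vent <- ckf@ventricular[!is.na(vz) & vz > T]
  new("FindingPattern", hemispheric_state = state, affected_lobes = aff,
      prominent_lobes = prominent, specific_combo = specific,
      direct_findings = direct, ventricular_findings = vent)
}

setMethod("show", "FindingPattern", function(object) {
  cat("FindingPattern: hemispheric state =", object@hemispheric_state, "\n")
  for (side in c("left", "right")) {
    a <- object@affected_lobes[[side]]
    if (length(a)) cat("  affected", side, "lobes:",
                       paste(a, collapse = ", "), "\n")
  }
  if (nrow(object@direct_findings))
    cat("  direct:", paste(object@direct_findings$structure, collapse = ", "),
        "\n")
  if (length(object@ventricular_findings))
    cat("  enlarged:", paste(object@ventricular_findings, collapse = ", "),
        "\n")
})

# canonical sentence keys of the relational layer of a pattern
.relationalKeys <- function(p) {
  keys <- character(0)
  if (p@hemispheric_state != "none")
    keys <- paste0("hemispheric:", p@hemispheric_state)
  for (side in c("left", "right")) {
    if (length(p@prominent_lobes[[side]]))
      keys <- c(keys, paste0("prominent:", side, ":",
                             paste(p@prominent_lobes[[side]], collapse = "+")))
    if (length(p@specific_combo[[side]]))
      keys <- c(keys, paste0("specific:", side, ":",
                             paste(p@specific_combo[[side]], collapse = "+")))
  }
  keys
}

#' Canonical sentence keys triggered by a pattern
#'
#' Stable machine-readable keys, one per sentence the pattern will render:
#' relational keys (\code{hemispheric:}, \code{prominent:}, \code{specific:})
#' followed by \code{direct:<id>} and \code{ventricular:<id>} keys.
#'
#' @param p a [FindingPattern-class].
#' @return character vector of keys (possibly empty).
#' @export
patternKeys <- function(p) {
  stopifnot(is(p, "FindingPattern"))
  c(.relationalKeys(p),
    if (nrow(p@direct_findings))
      paste0("direct:", p@direct_findings$structure),
    if (length(p@ventricular_findings))
      paste0("ventricular:", p@ventricular_findings))
}

#' Expand the relational rule engine into an explicit Boolean rule table
#'
#' Emits the fully expanded rule set equivalent to [detectPattern()] over
#' the 12 hemisphere/lobe threshold indicators, for audit and exact
#' equivalence testing.  Each rule is a conjunction: all ids in
#' \code{require_true} below -threshold, all in \code{require_false} not;
#' unmentioned indicators are wildcards.
#'
#' @param ckf a [ClinicalKnowledgeFilter-class].
#' @return data.frame with columns \code{key}, \code{class},
#'   \code{laterality}, \code{lobes}, \code{require_true},
#'   \code{require_false} (id lists joined with "+").
#' @export
enumerateRuleTable <- function(ckf = defaultCKF()) {
  stopifnot(is(ckf, "ClinicalKnowledgeFilter"))
  hemi <- ckf@hemispheres
  rules <- list()
  addRule <- function(key, class, laterality, lobes, rt, rf) {
    rules[[length(rules) + 1L]] <<- data.frame(
      key = key, class = class, laterality = laterality,
      lobes = paste(lobes, collapse = "+"),
      require_true = paste(rt, collapse = "+"),
      require_false = paste(rf, collapse = "+"), stringsAsFactors = FALSE)
  }
  # hemispheric: the four assignments of the two hemisphere indicators,
  # three of which carry a sentence (the fourth, "none", is silent)
  addRule("hemispheric:left", "hemispheric", "left", character(0),
          hemi["left"], hemi["right"])
  addRule("hemispheric:right", "hemispheric", "right", character(0),
          hemi["right"], hemi["left"])
  addRule("hemispheric:bilateral", "hemispheric", "bilateral", character(0),
          hemi, character(0))
  states <- list(left = list(rt = hemi["left"], rf = hemi["right"],
                             sides = "left"),
                 right = list(rt = hemi["right"], rf = hemi["left"],
                              sides = "right"),
                 bilateral = list(rt = unname(hemi), rf = character(0),
                                  sides = c("left", "right")))
  maxProm <- min(4L, ckf@prominence_max_lobes)
  if (maxProm >= 1L) {
    for (st in names(states)) {
      for (side in states[[st]]$sides) {
        lb <- ckf@lobes[[side]]
        for (S in .lobeSubsets(1L, maxProm))
          addRule(paste0("prominent:", side, ":", paste(S, collapse = "+")),
                  "prominent", side, S,
                  c(states[[st]]$rt, unname(lb[S])),
                  c(states[[st]]$rf, unname(lb[setdiff(LOBE_NAMES, S)])))
      }
    }
  }
  for (side in c("left", "right")) {
    lb <- ckf@lobes[[side]]
    for (S in .lobeSubsets(1L, 4L))
      addRule(paste0("specific:", side, ":", paste(S, collapse = "+")),
              "specific", side, S, unname(lb[S]),
              c(unname(hemi), unname(lb[setdiff(LOBE_NAMES, S)])))
  }
  out <- do.call(rbind, rules)
  rownames(out) <- NULL
  out
}

# rules -> pair of 0/1 matrices (rules x indicator ids)
.compileRules <- function(rules, ids) {
  mk <- function(col) {
    M <- matrix(0, nrow(rules), length(ids), dimnames = list(NULL, ids))
    for (i in seq_len(nrow(rules))) {
      v <- strsplit(col[i], "+", fixed = TRUE)[[1]]
      M[i, v[nzchar(v)]] <- 1
    }
    M
  }
  list(needT = mk(rules$require_true), needF = mk(rules$require_false))
}

#' Evaluate the rule table on indicator assignments
#'
#' @param rules a rule table from [enumerateRuleTable()].
#' @param indicators named logical over the 12 hemisphere/lobe ids; TRUE
#'   means the structure's z-score is below -threshold.
#' @return character vector of fired (deduplicated) sentence keys.
#' @export
applyRuleTable <- function(rules, indicators) {
  cm <- .compileRules(rules, names(indicators))
  x <- as.numeric(indicators)
  fired <- (cm$needT %*% x == rowSums(cm$needT)) & (cm$needF %*% x == 0)
  unique(rules$key[fired])
}

#' @rdname applyRuleTable
#' @param assignments logical matrix, one assignment per row, columns named
#'   by the 12 indicator ids.
#' @return \code{applyRuleTableAll} returns a list of fired key sets, one
#'   per assignment row.
#' @export
applyRuleTableAll <- function(rules, assignments) {
  cm <- .compileRules(rules, colnames(assignments))
  X <- t(assignments * 1)                     # ids x assignments
  hitT <- cm$needT %*% X == rowSums(cm$needT) # rules x assignments
  hitF <- cm$needF %*% X == 0
  fired <- hitT & hitF
  lapply(seq_len(ncol(fired)), function(j) unique(rules$key[fired[, j]]))
}

#' Default sentence dictionary
#'
#' Templates with named slots \code{{laterality}}, \code{{lobes}} and
#' \code{{structure}}, keyed by sentence family.  Wording (or language) is
#' swappable by supplying another dictionary to [renderReport()];
#' [readDictionary()]/[writeDictionary()] persist one as JSON.
#'
#' @return named list of template strings.
#' @export
defaultDictionary <- function() {
  list(
    hemispheric_atrophy = "There is {laterality} hemispheric atrophy.",
    prominent_atrophy = "The atrophy is prominent in the {lobes}.",
    prominent_atrophy_lateralized =
      "The {laterality} hemispheric atrophy is prominent in the {lobes}.",
    specific_atrophy = "There is {laterality} {lobes} specific atrophy.",
    direct_atrophy = "The {structure} has atrophy.",
    ventricular_enlargement = "The {structure} is enlarged.",
    sulcal_prominence = "The {structure} are prominent.")
}

#' @rdname defaultDictionary
#' @param path file path of a JSON dictionary.
#' @export
readDictionary <- function(path) {
  d <- jsonlite::fromJSON(path)
  lapply(d, as.character)
}

#' @rdname defaultDictionary
#' @param dictionary a named list of templates.
#' @export
writeDictionary <- function(dictionary, path) {
  jsonlite::write_json(dictionary, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.fillTemplate <- function(tmpl, slots) {
  for (nm in names(slots))
    tmpl <- gsub(paste0("{", nm, "}"), slots[[nm]], tmpl, fixed = TRUE)
  tmpl
}

.lobePhrase <- function(lobes, hyphenate = FALSE) {
  if (hyphenate)
    return(paste0(paste(lobes, collapse = "-"), " lobe"))
  word <- if (length(lobes) > 1L) "lobes" else "lobe"
  if (length(lobes) > 1L)
    paste(paste(c(paste(utils::head(lobes, -1L), collapse = ", "), "and",
                  utils::tail(lobes, 1L)), collapse = " "), word)
  else paste(lobes, word)
}

#' Render a finding pattern into sentences
#'
#' Deterministic ordering: hemispheric sentence first, then prominence
#' clauses, then lobe-specific combinations, then direct findings, then
#' ventricular/sulcal findings.  Assertions mirror sentences one to one.
#'
#' @param p a [FindingPattern-class].
#' @param dictionary named list of templates (see [defaultDictionary()]).
#' @param h the [OntologyHierarchy-class] supplying display names.
#' @return a [SentenceReport-class].
#' @examples
#' h <- defaultHierarchy()
#' p <- new("FindingPattern", hemispheric_state = "left",
#'          affected_lobes = list(left = "frontal", right = character(0)),
#'          prominent_lobes = list(left = "frontal", right = character(0)),
#'          specific_combo = list(left = character(0), right = character(0)),
#'          direct_findings = data.frame(structure = character(0),
#'                                       polarity = character(0)),
#'          ventricular_findings = character(0))
#' sentences(renderReport(p, h = h))
#' @export
renderReport <- function(p, dictionary = defaultDictionary(),
                         h = defaultHierarchy()) {
  stopifnot(is(p, "FindingPattern"))
  needKey <- function(key) {
    if (is.null(dictionary[[key]]))
      stop("dictionary is missing sentence key '", key, "'")
    dictionary[[key]]
  }
  nameOf <- stats::setNames(h@labels$name, h@labels$id)
  sent <- character(0)
  ast <- list()
  addOut <- function(s, term, qualifier, polarity) {
    sent <<- c(sent, s)
    ast[[length(ast) + 1L]] <<- data.frame(
      term = term, qualifier = qualifier, polarity = polarity,
      stringsAsFactors = FALSE)
  }
  st <- p@hemispheric_state
  if (st != "none") {
    term <- switch(st, left = "hemisphere_L", right = "hemisphere_R",
                   bilateral = "hemisphere_L|hemisphere_R")
    addOut(.fillTemplate(needKey("hemispheric_atrophy"),
                         list(laterality = st)),
           term, "plain", "atrophy")
    for (side in c("left", "right")) {
      S <- p@prominent_lobes[[side]]
      if (!length(S)) next
      key <- if (st == "bilateral") "prominent_atrophy_lateralized" else
        "prominent_atrophy"
      ids <- paste0(S, "_", if (side == "left") "L" else "R")
      addOut(.fillTemplate(needKey(key),
                           list(laterality = side,
                                lobes = .lobePhrase(S))),
             paste(ids, collapse = "|"), "prominent", "atrophy")
    }
  } else {
    for (side in c("left", "right")) {
      S <- p@specific_combo[[side]]
      if (!length(S)) next
      ids <- paste0(S, "_", if (side == "left") "L" else "R")
      addOut(.fillTemplate(needKey("specific_atrophy"),
                           list(laterality = side,
                                lobes = .lobePhrase(S, hyphenate = TRUE))),
             paste(ids, collapse = "|"), "specific", "atrophy")
    }
  }
  if (nrow(p@direct_findings)) {
    for (i in seq_len(nrow(p@direct_findings))) {
      id <- p@direct_findings$structure[i]
      addOut(.fillTemplate(needKey("direct_atrophy"),
                           list(structure = nameOf[[id]])),
             id, "plain", "atrophy")
    }
  }
  cls <- .tissueClass(h)
  for (id in p@ventricular_findings) {
    key <- if (identical(cls[[id]], "sulcus")) "sulcal_prominence" else
      "ventricular_enlargement"
    addOut(.fillTemplate(needKey(key), list(structure = nameOf[[id]])),
           id, "plain", "enlargement")
  }
  assertions <- if (length(ast)) do.call(rbind, ast) else
    data.frame(term = character(0), qualifier = character(0),
               polarity = character(0), stringsAsFactors = FALSE)
  new("SentenceReport", sentences = sent, assertions = assertions)
}

#' @rdname SentenceReport-class
#' @export
setMethod("sentences", "SentenceReport", function(x) x@sentences)

#' @rdname SentenceReport-class
#' @export
setMethod("assertions", "SentenceReport", function(x) x@assertions)

setMethod("show", "SentenceReport", function(object) {
  if (!length(object@sentences)) {
    cat("SentenceReport: no findings\n")
  } else {
    cat("SentenceReport (", length(object@sentences), " sentences):\n",
        sep = "")
    cat(paste0("  ", object@sentences, collapse = "\n"), "\n")
  }
})
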