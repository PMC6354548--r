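#' Construct an ontology hierarchy
#'
#' @param labels data.frame with columns id, name, laterality, tissue_class,
#'   level (see [OntologyHierarchy-class]).
#' @param children named list: superstructure id -> character vector of child
#'   ids.
#' @return an [OntologyHierarchy-class] object.
#' @examples
#' h <- OntologyHierarchy(
#'   labels = data.frame(id = c("A", "P"), name = c("a", "parent"),
#'                       laterality = "left", tissue_class = "tissue",
#'                       level = c(0L, 1L)),
#'   children = list(P = "A"))
#' baseDescendants(h, "P")
#' @export
OntologyHierarchy <- function(labels, children = list()) {
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  labels$level <- as.integer(labels$level)
  rownames(labels) <- NULL
  new("OntologyHierarchy", labels = labels, children = children)
}

#' @rdname OntologyHierarchy-class
#' @export
setMethod("structureIds", "OntologyHierarchy", function(x) x@labels$id)

#' @rdname OntologyHierarchy-class
#' @export
setMethod("baseStructures", "OntologyHierarchy",
          function(x) x@labels$id[x@labels$level == 0L])

#' @rdname OntologyHierarchy-class
#' @export
setMethod("superStructures", "OntologyHierarchy",
          function(x) x@labels$id[x@labels$level > 0L])

#' @rdname OntologyHierarchy-class
#' @export
setMethod("childrenOf", "OntologyHierarchy", function(x, id) {
  stopifnot(id %in% x@labels$id)
  kids <- x@children[[id]]
  if (is.null(kids)) character(0) else kids
})

#' @rdname OntologyHierarchy-class
#' @export
setMethod("baseDescendants", "OntologyHierarchy", function(x, id) {
  stopifnot(id %in% x@labels$id)
  .baseDescendantsAll(id, x@children)[[id]]
})

#' @rdname OntologyHierarchy-class
#' @export
setMethod("labelData", "OntologyHierarchy", function(x) x@labels)

setMethod("show", "OntologyHierarchy", function(object) {
  lb <- object@labels
  cat("OntologyHierarchy with", nrow(lb), "structures (",
      sum(lb$level == 0L), "base +", sum(lb$level > 0L),
      "superstructures )\n")
  cat("  levels:", paste(sort(unique(lb$level)), collapse = ", "), "\n")
  cat("  classes:",
      paste(sprintf("%s=%d", names(table(lb$tissue_class)),
                    table(lb$tissue_class)), collapse = " "), "\n")
})

# tissue_class lookup, named by id
.tissueClass <- function(h) {
  stats::setNames(h@labels$tissue_class, h@labels$id)
}

#' Built-in neuroanatomy hierarchy fixture
#'
#' A deterministic three-level ontology approximating the granularity levels
#' used in clinical volumetric reporting: per-hemisphere gyral base labels
#' (level 0), five lobes per hemisphere plus deep gray and ventricular base
#' labels, lobes at level 1, and hemispheres plus a ventricular system label
#' at level 2.  The hippocampus and amygdala sit under the limbic lobe
#' (the ontology convention for medial temporal structures); the caudate sits
#' directly under its hemisphere.  A single midline deep-sulci label carries
#' the sulcal compartment of the total-brain denominator.
#'
#' @return an [OntologyHierarchy-class] object.
#' @examples
#' h <- defaultHierarchy()
#' h
#' childrenOf(h, "hemisphere_L")
#' @export
defaultHierarchy <- function() {
  gyri <- list(
    frontal   = c("superior_frontal_gyrus", "middle_frontal_gyrus",
                  "inferior_frontal_gyrus", "precentral_gyrus"),
    parietal  = c("postcentral_gyrus", "superior_parietal_lobule",
                  "supramarginal_gyrus", "angular_gyrus"),
    temporal  = c("superior_temporal_gyrus", "middle_temporal_gyrus",
                  "inferior_temporal_gyrus", "fusiform_gyrus"),
    occipital = c("superior_occipital_gyrus", "middle_occipital_gyrus",
                  "inferior_occipital_gyrus", "cuneus"),
    limbic    = c("cingulate_gyrus", "parahippocampal_gyrus",
                  "entorhinal_area", "hippocampus", "amygdala"))
  rows <- list()
  children <- list()
  addRow <- function(id, name, lat, cls, lvl) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, name = name, laterality = lat, tissue_class = cls,
      level = as.integer(lvl), stringsAsFactors = FALSE)
  }
  for (side in c("L", "R")) {
    lat <- if (side == "L") "left" else "right"
    latName <- lat
    lobe_ids <- character(0)
    for (lobe in LOBE_NAMES) {
      g_ids <- paste0(gyri[[lobe]], "_", side)
      for (i in seq_along(g_ids))
        addRow(g_ids[i], paste(latName, gsub("_", " ", gyri[[lobe]][i])),
               lat, "tissue", 0L)
      lobe_id <- paste0(lobe, "_", side)
      addRow(lobe_id, paste(latName, lobe, "lobe"), lat, "tissue", 1L)
      children[[lobe_id]] <- g_ids
      lobe_ids <- c(lobe_ids, lobe_id)
    }
    caud <- paste0("caudate_", side)
    addRow(caud, paste(latName, "caudate nucleus"), lat, "tissue", 0L)
    hemi <- paste0("hemisphere_", side)
    addRow(hemi, paste(latName, "hemisphere"), lat, "tissue", 2L)
    children[[hemi]] <- c(lobe_ids, caud)
    lv <- paste0("lateral_ventricle_", side)
    addRow(lv, paste(latName, "lateral ventricle"), lat, "ventricle", 0L)
  }
  addRow("third_ventricle", "third ventricle", "midline", "ventricle", 0L)
  addRow("ventricles", "ventricular system", "midline", "ventricle", 1L)
  children[["ventricles"]] <- c("lateral_ventricle_L", "lateral_ventricle_R",
                                "third_ventricle")
  addRow("deep_sulci", "deep cerebral sulci", "midline", "sulcus", 0L)
  OntologyHierarchy(do.call(rbind, rows), children)
}

#' Aggregate base volumes into superstructure volumes
#'
#' Bottom-up union-of-children aggregation: every superstructure's volume is
#' the sum of its children's volumes, computed in topological order (children
#' before parents).  Base entries pass through unchanged; entries already
#' present for superstructures are overwritten by the recomputed sums, so the
#' operation is idempotent.
#'
#' @param base a [VolumeTable-class] containing a volume for every level-0
#'   label of \code{h}.
#' @param h an [OntologyHierarchy-class].
#' @return a [VolumeTable-class] covering every label of \code{h}.
#' @examples
#' h <- defaultHierarchy()
#' v <- VolumeTable("case1", 70,
#'                  stats::setNames(rep(1000, length(baseStructures(h))),
#'                                  baseStructures(h)))
#' agg <- aggregateSuperstructures(v, h)
#' volumes(agg)[["hemisphere_L"]]
#' @export
aggregateSuperstructures <- function(base, h) {
  stopifnot(is(base, "VolumeTable"), is(h, "OntologyHierarchy"))
  vols <- base@volumes
  missing <- setdiff(baseStructures(h), names(vols))
  if (length(missing))
    stop("missing base structure volume(s): ", paste(missing, collapse = ", "))
  for (s in .topoOrder(h@children))
    vols[s] <- sum(vols[h@children[[s]]])
  vols <- vols[structureIds(h)]
  new("VolumeTable", case_id = base@case_id, age = base@age,
      volumes = vols, units = base@units)
}

# 0/1 aggregation matrix: (all labels) x (base labels); row s has 1 at the
# base descendants of s.  Used by the vectorized cohort scoring path.
.aggregationMatrix <- function(h) {
  ids <- structureIds(h)
  base <- baseStructures(h)
  desc <- .baseDescendantsAll(ids, h@children)
  A <- matrix(0, nrow = length(ids), ncol = length(base),
              dimnames = list(ids, base))
  for (s in ids) A[s, desc[[s]]] <- 1
  A
}

#' Read / write a hierarchy as structured JSON
#'
#' The file holds one record per structure with fields \code{id},
#' \code{name}, \code{laterality}, \code{tissue_class} and (for
#' superstructures) \code{children}; levels are recomputed from the child
#' graph on read, so the pair round-trips losslessly.
#'
#' @param path file path.
#' @return \code{readHierarchy} returns an [OntologyHierarchy-class];
#'   \code{writeHierarchy} returns \code{path} invisibly.
#' @export
readHierarchy <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  ids <- vapply(recs, `[[`, "", "id")
  children <- list()
  for (r in recs)
    if (length(r$children)) children[[r$id]] <- unlist(r$children)
  # level = longest chain to a base label
  lvl <- stats::setNames(integer(length(ids)), ids)
  depth <- function(id) {
    kids <- children[[id]]
    if (is.null(kids)) return(0L)
    1L + max(vapply(kids, depth, 0L))
  }
  for (id in ids) lvl[id] <- depth(id)
  labels <- data.frame(
    id = ids,
    name = vapply(recs, `[[`, "", "name"),
    laterality = vapply(recs, `[[`, "", "laterality"),
    tissue_class = vapply(recs, `[[`, "", "tissue_class"),
    level = lvl, stringsAsFactors = FALSE)
  OntologyHierarchy(labels, children)
}

#' @rdname readHierarchy
#' @param h an [OntologyHierarchy-class] to serialize.
#' @export
writeHierarchy <- function(h, path) {
  stopifnot(is(h, "OntologyHierarchy"))
  recs <- lapply(seq_len(nrow(h@labels)), function(i) {
    row <- h@labels[i, ]
    rec <- list(id = row$id, name = row$name, laterality = row$laterality,
                tissue_class = row$tissue_class)
    kids <- h@children[[row$id]]
    if (length(kids)) rec$children <- kids
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
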