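# Fixtures and independent oracles shared across the suite.

# two base tissue structures whose volumes sum to 1e6, so that the
# normalized ratio of A equals volume_A / 1e6 exactly
tinyHierarchy <- function() {
  OntologyHierarchy(
    labels = data.frame(
      id = c("A", "B", "P"),
      name = c("structure A", "structure B", "parent"),
      laterality = "midline", tissue_class = "tissue",
      level = c(0L, 0L, 1L), stringsAsFactors = FALSE),
    children = list(P = c("A", "B")))
}

tinyControls <- function(n, intercept, slope, noise_sd, seed,
                         age_range = c(20, 96)) {
  set.seed(seed)
  ages <- runif(n, age_range[1], age_range[2])
  rA <- intercept + slope * ages + rnorm(n, sd = noise_sd)
  lapply(seq_len(n), function(i)
    VolumeTable(sprintf("c%03d", i), ages[i],
                c(A = rA[i] * 1e6, B = (1 - rA[i]) * 1e6)))
}

# random multi-level hierarchy: n_base base labels, random disjoint
# groupings at each level (a tree, which is also a valid DAG)
randomHierarchy <- function(seed, n_base = 20, n_levels = 3) {
  set.seed(seed)
  labels <- data.frame(id = sprintf("b%02d", seq_len(n_base)),
                       name = sprintf("base %d", seq_len(n_base)),
                       laterality = "midline", tissue_class = "tissue",
                       level = 0L, stringsAsFactors = FALSE)
  children <- list()
  current <- labels$id
  for (lvl in seq_len(n_levels - 1)) {
    n_groups <- max(1L, ceiling(length(current) / 3))
    grp <- sample(rep(seq_len(n_groups), length.out = length(current)))
    ids <- sprintf("s%d_%02d", lvl, seq_len(n_groups))
    for (g in seq_len(n_groups)) {
      kids <- current[grp == g]
      if (!length(kids)) next
      children[[ids[g]]] <- kids
      labels <- rbind(labels, data.frame(
        id = ids[g], name = ids[g], laterality = "midline",
        tissue_class = "tissue", level = lvl, stringsAsFactors = FALSE))
    }
    current <- intersect(ids, names(children))
  }
  OntologyHierarchy(labels, children)
}

# independent aggregation oracle: recursive brute-force enumeration of the
# base descendant set, then a direct sum (no topological pass)
oracleDescendants <- function(h, id) {
  kids <- childrenOf(h, id)
  if (!length(kids)) return(id)
  unique(unlist(lapply(kids, oracleDescendants, h = h)))
}

oracleAggregate <- function(h, base_vols, id) {
  sum(base_vols[oracleDescendants(h, id)])
}

# z-score table over arbitrary structures, defaulting to 0
makeZ <- function(values = numeric(0), h = defaultHierarchy(),
                  age = 70, case_id = "t") {
  ids <- structureIds(h)
  z <- stats::setNames(rep(0, length(ids)), ids)
  z[names(values)] <- values
  new("ZScoreTable", case_id = case_id, age = age,
      ratio = stats::setNames(rep(0.01, length(ids)), ids), z = z,
      extrapolated = FALSE)
}

# random coded findings for given sources over a universe
randomFindings <- function(seed, sources, universe, cases, p = 0.3) {
  set.seed(seed)
  rows <- expand.grid(case_id = cases, source = sources,
                      structure_term = universe,
                      stringsAsFactors = FALSE)
  rows$polarity <- ifelse(runif(nrow(rows)) < p, "positive", "negative")
  rows
}

# the twelve relational indicator ids of the default filter
indicatorIdsDefault <- function() {
  c("hemisphere_L", "hemisphere_R",
    paste0(rep(c("frontal", "parietal", "temporal", "occipital", "limbic"),
               2), rep(c("_L", "_R"), each = 5)))
}

# structure ids asserted by a pattern (decomposed from its keys)
assertedIds <- function(p) {
  keys <- patternKeys(p)
  out <- character(0)
  for (k in keys) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    if (parts[1] == "hemispheric") {
      out <- c(out, switch(parts[2], left = "hemisphere_L",
                           right = "hemisphere_R",
                           bilateral = c("hemisphere_L", "hemisphere_R")))
    } else if (parts[1] %in% c("prominent", "specific")) {
      side <- if (parts[2] == "left") "_L" else "_R"
      out <- c(out, paste0(strsplit(parts[3], "+", fixed = TRUE)[[1]], side))
    } else {
      out <- c(out, parts[2])
    }
  }
  unique(out)
}
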