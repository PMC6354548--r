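# DAG helpers over the child map (named list: parent id -> child ids).

# Returns the id where a cycle was detected, or NULL.
.findCycle <- function(children) {
  state <- new.env(parent = emptyenv())  # 1 = visiting, 2 = done
  visit <- function(id) {
    s <- get0(id, envir = state, ifnotfound = 0L)
    if (s == 1L) return(id)
    if (s == 2L) return(NULL)
    assign(id, 1L, envir = state)
    for (k in children[[id]]) {
      hit <- visit(k)
      if (!is.null(hit)) return(hit)
    }
    assign(id, 2L, envir = state)
    NULL
  }
  for (id in names(children)) {
    hit <- visit(id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# Base-level descendant sets for every id (a base id's set is itself).
.baseDescendantsAll <- function(ids, children) {
  memo <- new.env(parent = emptyenv())
  walk <- function(id) {
    got <- get0(id, envir = memo)
    if (!is.null(got)) return(got)
    kids <- children[[id]]
    res <- if (is.null(kids)) id else
      unique(unlist(lapply(kids, walk), use.names = FALSE))
    assign(id, res, envir = memo)
    res
  }
  out <- lapply(ids, walk)
  names(out) <- ids
  out
}

# Topological order of superstructures (children before parents).
.topoOrder <- function(children) {
  order <- character(0)
  seen <- new.env(parent = emptyenv())
  visit <- function(id) {
    if (isTRUE(get0(id, envir = seen))) return(invisible())
    assign(id, TRUE, envir = seen)
    for (k in children[[id]]) if (k %in% names(children)) visit(k)
    order <<- c(order, id)
  }
  for (id in names(children)) visit(id)
  order
}
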