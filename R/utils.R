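# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Kahn topological order of an OntologyDAG (children before parents when
# traversing child->parent edges forward); NULL if cyclic.
topoOrderOrNull <- function(dag) {
  terms <- dag@terms
  n <- length(terms)
  if (n == 0L) return(character())
  idx <- stats::setNames(seq_len(n), terms)
  # out-degree along child->parent edges
  outdeg <- vapply(dag@parents[terms], length, 0L)
  children <- vector("list", n)  # parent -> children indices
  for (i in seq_len(n)) {
    for (p in dag@parents[[terms[i]]]) {
      j <- idx[[p]]
      children[[j]] <- c(children[[j]], i)
    }
  }
  # reverse order: start from roots (outdeg 0), peel towards leaves
  order_rev <- integer(0)
  queue <- which(outdeg == 0L)
  deg <- outdeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_rev <- c(order_rev, v)
    for (c in children[[v]]) {
      deg[c] <- deg[c] - 1L
      if (deg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order_rev) != n) return(NULL)
  terms[rev(order_rev)]  # children before parents
}

# All ancestors (transitive parents) of a term.
#' Ancestor terms of an ontology term
#' @param dag an [OntologyDAG-class].
#' @param term a term ID.
#' @return character vector of all ancestors (term excluded).
#' @export
ancestors <- function(dag, term) {
  seen <- character()
  frontier <- dag@parents[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag@parents[new], use.names = FALSE))
  }
  seen
}

# Derived-name scheme: parent name + "_" + short op code (repo convention).
deriveName <- function(name, code) paste0(name, "_", code)

fmtNum <- function(x) {
  if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  else as.character(x)
}
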