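# Set operations on feature-ID collections.

memberVector <- function(s) {
  if (is(s, "GeneSet")) s@members
  else if (is(s, "CountMatrix") || is(s, "DiffExpTable")) featureIDs(s)
  else if (is.character(s)) unique(s)
  else stop("unsupported set input of class ", class(s)[1])
}

setInputName <- function(s, i) {
  if (is(s, "GeneSet")) s@name
  else if (is(s, "CountMatrix") || is(s, "DiffExpTable")) tableName(s)
  else paste0("set", i)
}

#' Set operations on gene sets and tables
#'
#' Performs union, intersection, difference (first input is the reference),
#' symmetric difference, or a majority-vote intersection keeping IDs present
#' in at least `ceiling(majority_fraction * number_of_sets)` inputs.  Inputs
#' may be [GeneSet-class] objects, tables, or character vectors.
#'
#' @param sets list of >= 2 inputs.
#' @param op one of `union`, `intersection`, `difference`,
#'   `symmetric_difference`, `majority`.
#' @param majority_fraction fraction in (0, 1] for `op = "majority"`.
#' @return A [GeneSet-class] whose name encodes the operation.
#' @export
setOperation <- function(sets, op = c("union", "intersection", "difference",
                                      "symmetric_difference", "majority"),
                         majority_fraction = 0.5) {
  op <- match.arg(op)
  if (length(sets) < 2L) stop("need at least 2 sets")
  members <- lapply(sets, memberVector)
  names_in <- mapply(setInputName, sets, seq_along(sets))
  result <- switch(op,
    union = Reduce(union, members),
    intersection = Reduce(intersect, members),
    difference = Reduce(setdiff, members),
    symmetric_difference = {
      all_ids <- unique(unlist(members))
      cnt <- rowSums(vapply(members, function(m) all_ids %in% m,
                            logical(length(all_ids))))
      all_ids[cnt %% 2L == 1L]
    },
    majority = {
      if (majority_fraction <= 0 || majority_fraction > 1)
        stop("majority_fraction must be in (0, 1]")
      all_ids <- unique(unlist(members))
      cnt <- rowSums(vapply(members, function(m) all_ids %in% m,
                            logical(length(all_ids))))
      need <- ceiling(majority_fraction * length(members))
      all_ids[cnt >= need]
    })
  code <- switch(op, union = "union", intersection = "inter",
                 difference = "diff", symmetric_difference = "symdiff",
                 majority = paste0("maj", fmtNum(majority_fraction)))
  GeneSet(paste0(paste(names_in, collapse = "+"), "_", code), result)
}

#' Sizes of all Venn regions of a collection of sets
#'
#' Classifies every element of the union by its membership pattern across the
#' inputs.  Patterns are encoded as inclusion bit-strings (first character =
#' first set); region sizes partition the union.
#'
#' @param sets list of 2 to 10 inputs (as in [setOperation()]).
#' @return data.frame with columns `pattern` and `size`, one row per
#'   non-empty region.
#' @export
intersectionCounts <- function(sets) {
  if (length(sets) < 2L || length(sets) > 10L)
    stop("intersectionCounts supports 2 to 10 sets")
  members <- lapply(sets, memberVector)
  all_ids <- unique(unlist(members))
  inc <- vapply(members, function(m) all_ids %in% m,
                logical(length(all_ids)))
  if (length(all_ids) == 1L) inc <- matrix(inc, nrow = 1L)
  pattern <- apply(inc, 1L, function(row) paste(as.integer(row), collapse = ""))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), size = as.integer(tab))
  out[order(out$pattern, decreasing = TRUE), , drop = FALSE]
}
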