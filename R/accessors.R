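#' Feature identifiers and counts of a table
#'
#' @param x a table object.
#' @return `featureIDs`: character vector; `nFeatures`: integer.
#' @name featureIDs
NULL

#' @rdname featureIDs
#' @export
setMethod("featureIDs", "CountMatrix", function(x) rownames(x@values))

#' @rdname featureIDs
#' @export
setMethod("featureIDs", "DiffExpTable", function(x) x@feature_ids)

#' @rdname featureIDs
#' @export
setMethod("featureIDs", "AttributeTable", function(x) x@feature_ids)

#' @rdname featureIDs
#' @export
setMethod("featureIDs", "GeneSet", function(x) x@members)

#' @rdname featureIDs
#' @export
setMethod("nFeatures", "CountMatrix", function(x) nrow(x@values))

#' @rdname featureIDs
#' @export
setMethod("nFeatures", "DiffExpTable", function(x) length(x@feature_ids))

#' Sample identifiers of a count matrix
#' @param x a [CountMatrix-class].
#' @return character vector of sample IDs.
#' @export
sampleIDs <- function(x) colnames(x@values)

#' Expression values of a count matrix
#' @param x a [CountMatrix-class].
#' @return numeric matrix, features x samples.
#' @export
counts <- function(x) x@values

#' Whether a count matrix holds normalized units
#' @param x a [CountMatrix-class].
#' @return logical.
#' @export
isNormalized <- function(x) x@normalized

#' Table name
#'
#' @param x a table object.
#' @param value replacement name.
#' @return the name, or the modified object.
#' @name tableName
NULL

#' @rdname tableName
#' @export
setMethod("tableName", "CountMatrix", function(x) x@name)

#' @rdname tableName
#' @export
setMethod("tableName", "DiffExpTable", function(x) x@name)

#' @rdname tableName
#' @export
setMethod("tableName", "GeneSet", function(x) x@name)

#' @rdname tableName
#' @export
setMethod("tableName<-", "CountMatrix", function(x, value) {
  x@name <- value; x
})

#' @rdname tableName
#' @export
setMethod("tableName<-", "DiffExpTable", function(x, value) {
  x@name <- value; x
})

#' Audit trail of a table
#'
#' @param x a [CountMatrix-class] or [DiffExpTable-class].
#' @return data.frame with columns `op`, `n_before`, `n_after` and a
#'   `params` list-column.
#' @name historyLog
NULL

historyAsFrame <- function(h) {
  recs <- h@records
  data.frame(op = vapply(recs, `[[`, "", "op"),
             n_before = vapply(recs, function(r) as.integer(r$n_before), 0L),
             n_after = vapply(recs, function(r) as.integer(r$n_after), 0L),
             params = I(lapply(recs, `[[`, "params")))
}

#' @rdname historyLog
#' @export
setMethod("historyLog", "CountMatrix", function(x) historyAsFrame(x@history))

#' @rdname historyLog
#' @export
setMethod("historyLog", "DiffExpTable", function(x) historyAsFrame(x@history))

#' Gene-set view of a table's features
#'
#' @param x a table object.
#' @param name set name; defaults to the table name.
#' @return A [GeneSet-class] of the table's feature IDs.
#' @name asGeneSet
NULL

#' @rdname asGeneSet
#' @export
setMethod("asGeneSet", "CountMatrix", function(x, name) {
  if (missing(name)) name <- x@name
  GeneSet(name, featureIDs(x))
})

#' @rdname asGeneSet
#' @export
setMethod("asGeneSet", "DiffExpTable", function(x, name) {
  if (missing(name)) name <- x@name
  GeneSet(name, featureIDs(x))
})

#' DiffExpTable as a data.frame
#' @param x a [DiffExpTable-class].
#' @return data.frame with feature, log2fc, pval, padj.
#' @export
diffExpFrame <- function(x) {
  data.frame(feature = x@feature_ids, log2fc = x@log2fc,
             pval = x@pval, padj = x@padj)
}

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix '%s': %d features x %d samples (%s)\n",
              object@name, nrow(object@values), ncol(object@values),
              if (object@normalized) "normalized" else "raw"))
  cat(sprintf("  history: %d operation(s)\n", length(object@history@records)))
})

setMethod("show", "DiffExpTable", function(object) {
  cat(sprintf("DiffExpTable '%s': %d features\n",
              object@name, length(object@feature_ids)))
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s': %d members\n",
              object@name, length(object@members)))
})

setMethod("show", "NormFactors", function(object) {
  cat(sprintf("NormFactors (%s):\n", object@method))
  print(round(object@factors, 4))
})

setMethod("show", "ClusteringSolution", function(object) {
  lab <- object@labels
  k <- length(unique(lab[lab != -1L]))
  cat(sprintf("ClusteringSolution: %d features, %d clusters, %d noise [%s]\n",
              length(lab), k, sum(lab == -1L),
              if (is.null(object@setup$algorithm)) "ensemble"
              else object@setup$algorithm))
})

setMethod("show", "GapResult", function(object) {
  cat(sprintf("GapResult: chosen k = %d over k in [%d, %d]\n",
              object@chosen_k, min(object@k), max(object@k)))
})

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms, %d edges\n", length(object@terms),
              length(unlist(object@parents, use.names = FALSE))))
})

setMethod("show", "Pipeline", function(object) {
  cat(sprintf("Pipeline '%s' (format %s), %d step(s)\n",
              object@name, object@version, length(object@steps)))
  for (i in seq_along(object@steps)) {
    st <- object@steps[[i]]
    p <- paste(names(st$params),
               vapply(st$params, function(v) paste(format(v), collapse = ","), ""),
               sep = "=", collapse = ", ")
    cat(sprintf("  %d. %s(%s)\n", i, st$op, p))
  }
})
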