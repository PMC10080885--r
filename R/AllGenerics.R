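#' @rdname featureIDs
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname featureIDs
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname tableName
#' @export
setGeneric("tableName", function(x) standardGeneric("tableName"))

#' @rdname tableName
#' @export
setGeneric("tableName<-", function(x, value) standardGeneric("tableName<-"))

#' @rdname historyLog
#' @export
setGeneric("historyLog", function(x) standardGeneric("historyLog"))

#' @rdname undoLast
#' @export
setGeneric("undoLast", function(x) standardGeneric("undoLast"))

#' @rdname writeTable
#' @export
setGeneric("writeTable", function(x, path, ...) standardGeneric("writeTable"))

#' @rdname filterBiotype
#' @export
setGeneric("filterBiotype", function(x, map, keep) standardGeneric("filterBiotype"))

#' @rdname asGeneSet
#' @export
setGeneric("asGeneSet", function(x, name) standardGeneric("asGeneSet"))
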