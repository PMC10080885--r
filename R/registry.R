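# Operation registry: the single source of truth for which operations a
# Pipeline (and history replay) can run, which table kinds they accept, and
# how their parameters are validated before run time.

OP_REGISTRY <- new.env(parent = emptyenv())

registerOp <- function(name, kinds, fun, validate = function(params) NULL) {
  assign(name, list(kinds = kinds, fun = fun, validate = validate),
         envir = OP_REGISTRY)
}

getOp <- function(name) {
  if (!exists(name, envir = OP_REGISTRY, inherits = FALSE))
    stop("unknown operation: ", name)
  get(name, envir = OP_REGISTRY)
}

#' Names of all registered pipeline operations
#' @return character vector.
#' @export
registeredOps <- function() sort(ls(OP_REGISTRY))

# Validate a step without running it; NULL when fine, message otherwise.
validateOpStep <- function(op, params) {
  entry <- tryCatch(getOp(op), error = function(e) NULL)
  if (is.null(entry)) return(paste0("unknown operation: ", op))
  if (is.null(params)) params <- list()
  if (length(params)) {
    if (is.null(names(params)) || any(!nzchar(names(params))))
      return("all parameters must be named")
    allowed <- names(formals(entry$fun))[-1L]
    unknown <- setdiff(names(params), allowed)
    if (length(unknown))
      return(paste0("unknown parameter(s) for ", op, ": ",
                    paste(unknown, collapse = ", ")))
  }
  entry$validate(params)
}

applyRegisteredOp <- function(table, op, params) {
  entry <- getOp(op)
  if (!class(table)[1] %in% entry$kinds)
    stop("operation ", op, " is not applicable to a ", class(table)[1])
  do.call(entry$fun, c(list(table), params))
}

needNumber <- function(params, key, lo, hi, required = TRUE) {
  v <- params[[key]]
  if (is.null(v)) {
    if (required) return(paste0("missing parameter: ", key)) else return(NULL)
  }
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi)
    return(sprintf("parameter %s must be a number in [%s, %s]",
                   key, format(lo), format(hi)))
  NULL
}

registerBuiltinOps <- function() {
  registerOp("filter_low_expression", "CountMatrix",
    function(m, threshold, mode = "sum") filterLowExpression(m, threshold, mode),
    function(p) {
      err <- needNumber(p, "threshold", 0, Inf)
      if (!is.null(err)) return(err)
      if (!is.null(p$mode) && !p$mode %in% c("sum", "min_per_sample", "mean"))
        return("mode must be sum, min_per_sample or mean")
      NULL
    })
  registerOp("drop_missing", "CountMatrix",
    function(m) dropMissing(m))
  registerOp("filter_significant", "DiffExpTable",
    function(t, alpha) filterSignificant(t, alpha),
    function(p) needNumber(p, "alpha", .Machine$double.xmin, 1))
  registerOp("filter_fold_change", "DiffExpTable",
    function(t, magnitude, direction = "both")
      filterFoldChange(t, magnitude, direction),
    function(p) {
      err <- needNumber(p, "magnitude", 0, Inf)
      if (!is.null(err)) return(err)
      if (!is.null(p$direction) && !p$direction %in% c("up", "down", "both"))
        return("direction must be up, down or both")
      NULL
    })
  registerOp("drop_zero_fc", "DiffExpTable",
    function(t) subsetDiffExp(t, t@log2fc < 0, "drop_zero_fc", list(),
                              "nonzero"))
  registerOp("filter_biotype", c("CountMatrix", "DiffExpTable"),
    function(x, keep, map) filterBiotype(x, map, keep),
    function(p) {
      if (is.null(p$keep) || !length(p$keep))
        return("keep must be a non-empty set of biotype labels")
      NULL
    })
  registerOp("normalize_cpm", "CountMatrix",
    function(m) applyNormalization(m, cpmFactors(m)))
  registerOp("normalize_median_of_ratios", "CountMatrix",
    function(m) applyNormalization(m, sizeFactorsMedianOfRatios(m)))
  registerOp("normalize_tmm", "CountMatrix",
    function(m, logratio_trim = 0.3, abs_trim = 0.05)
      applyNormalization(m, tmmFactors(m, logratio_trim, abs_trim)),
    function(p) {
      err <- needNumber(p, "logratio_trim", 0, 0.45, required = FALSE)
      if (!is.null(err)) return(err)
      needNumber(p, "abs_trim", 0, 0.45, required = FALSE)
    })
  registerOp("quantile_normalize", "CountMatrix",
    function(m) quantileNormalize(m))
  registerOp("power_transform_standardize", "CountMatrix",
    function(m) powerTransformStandardize(m))
}
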