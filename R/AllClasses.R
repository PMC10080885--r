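#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Per-table audit trail
#'
#' Append-only log of operations applied to a table, together with the
#' snapshot of the table as it was first loaded or constructed.  Each record
#' stores the operation name, its parameters, and the feature counts before
#' and after.  The snapshot makes single-step undo possible by replaying the
#' history (see [undoLast()]).
#'
#' @slot records list of records, each a list with elements `op`, `params`,
#'   `n_before`, `n_after`.
#' @slot snapshot the table as loaded (with an empty history), or `NULL`.
#' @export
setClass("HistoryLog",
         representation(records = "list", snapshot = "ANY"),
         prototype(records = list(), snapshot = NULL))

#' Expression count matrix with provenance
#'
#' Features x samples table of non-negative expression values (raw counts or
#' normalized units).  Feature and sample identifiers are unique; values may
#' be missing (`NA`).
#'
#' @slot values numeric matrix, features in rows, samples in columns.
#' @slot normalized logical flag, `TRUE` after a normalization has been applied.
#' @slot name character name used to derive output names.
#' @slot history a [HistoryLog-class] audit trail.
#' @export
setClass("CountMatrix",
         representation(values = "matrix", normalized = "logical",
                        name = "character", history = "HistoryLog"))

setValidity("CountMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have feature (row) and sample (column) names")
  else {
    dupf <- unique(rownames(v)[duplicated(rownames(v))])
    dups <- unique(colnames(v)[duplicated(colnames(v))])
    if (length(dupf))
      msgs <- c(msgs, paste0("duplicated feature IDs: ",
                             paste(utils::head(dupf, 5), collapse = ", ")))
    if (length(dups))
      msgs <- c(msgs, paste0("duplicated sample IDs: ",
                             paste(utils::head(dups, 5), collapse = ", ")))
  }
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  else if (!isTRUE(object@normalized) && any(v < 0, na.rm = TRUE)) {
    # raw tables must be non-negative; normalized units (e.g. standardized
    # log-scale values) may legitimately be negative
    bad <- rownames(v)[apply(v < 0, 1, any, na.rm = TRUE)]
    msgs <- c(msgs, paste0("negative values in features: ",
                           paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (length(object@name) != 1L) msgs <- c(msgs, "name must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Differential expression results table
#'
#' Per-feature log2 fold change with raw and adjusted p-values.  `padj >=
#' pval` is not enforced (it depends on the correction method used upstream).
#'
#' @slot feature_ids unique character feature identifiers.
#' @slot log2fc numeric log2 fold changes.
#' @slot pval,padj numeric in \[0, 1\] or `NA`.
#' @slot name table name.
#' @slot history a [HistoryLog-class].
#' @export
setClass("DiffExpTable",
         representation(feature_ids = "character", log2fc = "numeric",
                        pval = "numeric", padj = "numeric",
                        name = "character", history = "HistoryLog"))

setValidity("DiffExpTable", function(object) {
  msgs <- character()
  n <- length(object@feature_ids)
  dup <- unique(object@feature_ids[duplicated(object@feature_ids)])
  if (length(dup))
    msgs <- c(msgs, paste0("duplicated feature IDs: ",
                           paste(utils::head(dup, 5), collapse = ", ")))
  if (length(object@log2fc) != n || length(object@pval) != n ||
      length(object@padj) != n)
    msgs <- c(msgs, "log2fc, pval, padj must match feature_ids in length")
  inunit <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!inunit(object@pval)) msgs <- c(msgs, "pval outside [0, 1]")
  if (!inunit(object@padj)) msgs <- c(msgs, "padj outside [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Named set of feature identifiers
#'
#' @slot name non-empty set name.
#' @slot members unique feature identifiers.
#' @export
setClass("GeneSet",
         representation(name = "character", members = "character"))

setValidity("GeneSet", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  if (anyDuplicated(object@members))
    msgs <- c(msgs, "members must be unique")
  if (length(msgs)) msgs else TRUE
})

#' User-defined feature attributes
#'
#' Features x attributes table; every column is wholly boolean (set
#' membership) or wholly numeric (ordinal/continuous).  Missing values are
#' allowed.
#'
#' @slot feature_ids unique feature identifiers.
#' @slot attributes data.frame of logical or numeric columns.
#' @export
setClass("AttributeTable",
         representation(feature_ids = "character", attributes = "data.frame"))

setValidity("AttributeTable", function(object) {
  msgs <- character()
  if (anyDuplicated(object@feature_ids))
    msgs <- c(msgs, "duplicated feature IDs")
  if (nrow(object@attributes) != length(object@feature_ids))
    msgs <- c(msgs, "attributes rows must match feature_ids")
  ok <- vapply(object@attributes, function(col)
    is.logical(col) || is.numeric(col), logical(1))
  if (!all(ok))
    msgs <- c(msgs, paste0("non-boolean, non-numeric columns: ",
                           paste(names(object@attributes)[!ok], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Feature-to-biotype mapping
#'
#' @slot mapping named character vector: names are feature IDs, values are
#'   biotype labels (e.g. `protein_coding`, `piRNA`).
#' @export
setClass("BiotypeMap", representation(mapping = "character"))

setValidity("BiotypeMap", function(object) {
  if (anyDuplicated(names(object@mapping)))
    "duplicated feature IDs in biotype map" else TRUE
})

#' Per-sample normalization factors
#'
#' @slot factors named positive numeric vector, one factor per sample.
#' @slot method one of `median_of_ratios`, `rle`, `tmm`, `cpm`, `quantile`.
#' @export
setClass("NormFactors",
         representation(factors = "numeric", method = "character"))

setValidity("NormFactors", function(object) {
  msgs <- character()
  if (any(!is.finite(object@factors)) || any(object@factors <= 0))
    msgs <- c(msgs, "all factors must be finite and > 0")
  if (!object@method %in% c("median_of_ratios", "rle", "tmm", "cpm", "quantile"))
    msgs <- c(msgs, paste0("unknown method: ", object@method))
  if (length(msgs)) msgs else TRUE
})

#' Principal component analysis result
#'
#' @slot scores samples x components matrix.
#' @slot loadings features x components matrix.
#' @slot variance_fraction fraction of total variance per component,
#'   non-increasing.
#' @export
setClass("PCAResult",
         representation(scores = "matrix", loadings = "matrix",
                        variance_fraction = "numeric"))

setValidity("PCAResult", function(object) {
  vf <- object@variance_fraction
  if (any(diff(vf) > 1e-9)) "variance fractions must be non-increasing"
  else if (any(vf < -1e-12 | vf > 1 + 1e-9)) "variance fractions outside [0, 1]"
  else TRUE
})

#' Distance specification for expression profiles
#'
#' @slot metric one of `euclidean`, `pearson`, `spearman`, `cosine`, `ys1`,
#'   `yr1`, `jackknife`.
#' @slot weights length-3 non-negative weights summing to 1, used by the
#'   `ys1`/`yr1` composite time-course metrics.
#' @export
setClass("DistanceSpec",
         representation(metric = "character", weights = "numeric"))

setValidity("DistanceSpec", function(object) {
  msgs <- character()
  if (!object@metric %in% c("euclidean", "pearson", "spearman", "cosine",
                            "ys1", "yr1", "jackknife"))
    msgs <- c(msgs, paste0("unrecognized metric: ", object@metric))
  if (length(object@weights) != 3L || any(object@weights < 0) ||
      abs(sum(object@weights) - 1) > 1e-12)
    msgs <- c(msgs, "weights must be 3 non-negative values summing to 1")
  if (length(msgs)) msgs else TRUE
})

#' Cluster assignment of features
#'
#' @slot labels integer labels (>= 1), named by feature; `-1L` marks noise
#'   (unclustered) features from density-based or ensemble methods.
#' @slot setup descriptor list of the algorithm, parameters, and seed.
#' @export
setClass("ClusteringSolution",
         representation(labels = "integer", setup = "list"))

setValidity("ClusteringSolution", function(object) {
  if (is.null(names(object@labels))) "labels must be named by feature"
  else if (any(object@labels < 1L & object@labels != -1L))
    "labels must be >= 1 or -1 (noise)"
  else TRUE
})

#' Configuration of the ensemble clusterer
#'
#' @slot setups list of at least two base clustering setups (see
#'   [clusterSetup()]).
#' @slot evidence_threshold fraction in (0, 1].
#' @slot min_cluster_size integer >= 1.
#' @slot attach_unclustered logical.
#' @slot seed integer seed.
#' @export
setClass("EnsembleConfig",
         representation(setups = "list", evidence_threshold = "numeric",
                        min_cluster_size = "integer",
                        attach_unclustered = "logical", seed = "integer"))

setValidity("EnsembleConfig", function(object) {
  msgs <- character()
  if (length(object@setups) < 2L) msgs <- c(msgs, "need at least 2 setups")
  if (object@evidence_threshold <= 0 || object@evidence_threshold > 1)
    msgs <- c(msgs, "evidence_threshold must be in (0, 1]")
  if (object@min_cluster_size < 1L) msgs <- c(msgs, "min_cluster_size must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Gap-statistic model selection result
#'
#' @slot k evaluated numbers of clusters.
#' @slot gap gap value per k.
#' @slot log_w observed log within-cluster dispersion per k.
#' @slot log_w_ref mean reference log dispersion per k.
#' @slot se standard error of the reference dispersion per k.
#' @slot chosen_k selected number of clusters.
#' @export
setClass("GapResult",
         representation(k = "integer", gap = "numeric", log_w = "numeric",
                        log_w_ref = "numeric", se = "numeric",
                        chosen_k = "integer"))

setValidity("GapResult", function(object) {
  if (!object@chosen_k %in% object@k) "chosen_k must be in the evaluated range"
  else TRUE
})

#' Ontology term graph
#'
#' Directed acyclic graph of terms with child-to-parent `is_a` (and
#' optionally `part_of`) edges.
#'
#' @slot terms term identifiers.
#' @slot names term names, parallel to `terms`.
#' @slot namespaces optional namespace per term.
#' @slot parents list, per term, of parent term IDs.
#' @export
setClass("OntologyDAG",
         representation(terms = "character", names = "character",
                        namespaces = "character", parents = "list"))

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  all_parents <- unique(unlist(object@parents, use.names = FALSE))
  if (length(all_parents) && !all(all_parents %in% object@terms))
    msgs <- c(msgs, "edge endpoints must be known terms")
  if (is.null(topoOrderOrNull(object)))
    msgs <- c(msgs, "term graph contains a cycle")
  if (length(msgs)) msgs else TRUE
})

#' Term-to-gene annotation mapping
#'
#' @slot annotations list mapping term ID to a character vector of annotated
#'   feature IDs.
#' @slot propagated `TRUE` once annotations have been propagated to ancestor
#'   terms (see [propagateAnnotations()]).
#' @export
setClass("AnnotationSet",
         representation(annotations = "list", propagated = "logical"))

#' Ordered, serializable bundle of operations
#'
#' @slot name pipeline name.
#' @slot version format version tag.
#' @slot steps list of steps, each a list with elements `op` and `params`.
#' @export
setClass("Pipeline",
         representation(name = "character", version = "character",
                        steps = "list"))

setValidity("Pipeline", function(object) {
  for (i in seq_along(object@steps)) {
    st <- object@steps[[i]]
    if (!is.list(st) || is.null(st$op))
      return(sprintf("step %d is malformed", i))
    err <- validateOpStep(st$op, st$params)
    if (!is.null(err)) return(sprintf("step %d (%s): %s", i, st$op, err))
  }
  TRUE
})

#' Synthetic count-data design
#'
#' Design of a synthetic RNA-seq experiment: negative-binomial counts with
#' planted cluster profiles and differential expression.
#'
#' @slot n_features,n_samples,n_clusters integers.
#' @slot profiles matrix (clusters x samples) of per-sample relative mean
#'   profiles (positive).
#' @slot dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @slot libsize_range length-2 range of library-size scalars.
#' @slot de_fraction fraction of features that are truly differential.
#' @slot effect_size log2 effect size of true differential features.
#' @slot seed mandatory integer seed.
#' @export
setClass("SimSpec",
         representation(n_features = "integer", n_samples = "integer",
                        n_clusters = "integer", profiles = "matrix",
                        dispersion = "numeric", libsize_range = "numeric",
                        de_fraction = "numeric", effect_size = "numeric",
                        seed = "integer"))

setValidity("SimSpec", function(object) {
  msgs <- character()
  if (object@n_features < 1L || object@n_samples < 2L)
    msgs <- c(msgs, "need >= 1 feature and >= 2 samples")
  if (any(object@profiles <= 0)) msgs <- c(msgs, "profile means must be > 0")
  if (nrow(object@profiles) != object@n_clusters ||
      ncol(object@profiles) != object@n_samples)
    msgs <- c(msgs, "profiles must be n_clusters x n_samples")
  if (object@dispersion <= 0) msgs <- c(msgs, "dispersion must be > 0")
  if (length(object@libsize_range) != 2L || any(object@libsize_range <= 0))
    msgs <- c(msgs, "libsize_range must be 2 positive values")
  if (object@de_fraction < 0 || object@de_fraction > 1)
    msgs <- c(msgs, "de_fraction must be in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})
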