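#' Construct a CountMatrix
#'
#' @param values numeric matrix with feature row names and sample column
#'   names; values must be non-negative or `NA`.
#' @param name table name (used to derive output names).
#' @param normalized whether the values are already normalized units.
#' @return A [CountMatrix-class].
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cm <- CountMatrix(m, name = "toy")
#' nFeatures(cm)
#' @export
CountMatrix <- function(values, name = "counts", normalized = FALSE) {
  storage.mode(values) <- "double"
  x <- new("CountMatrix", values = values, normalized = normalized,
           name = name, history = new("HistoryLog"))
  initHistory(x, "loaded")
}

#' Construct a DiffExpTable
#'
#' @param feature_ids unique feature identifiers.
#' @param log2fc log2 fold changes.
#' @param pval,padj raw and adjusted p-values in \[0, 1\] (`NA` allowed).
#' @param name table name.
#' @return A [DiffExpTable-class].
#' @export
DiffExpTable <- function(feature_ids, log2fc, pval = NA_real_,
                         padj = NA_real_, name = "diffexp") {
  n <- length(feature_ids)
  x <- new("DiffExpTable", feature_ids = as.character(feature_ids),
           log2fc = as.numeric(log2fc),
           pval = rep_len(as.numeric(pval), n),
           padj = rep_len(as.numeric(padj), n),
           name = name, history = new("HistoryLog"))
  initHistory(x, "loaded")
}

#' Construct a GeneSet
#'
#' Duplicated members are collapsed.
#'
#' @param name non-empty set name.
#' @param members character feature IDs.
#' @return A [GeneSet-class].
#' @export
GeneSet <- function(name, members) {
  new("GeneSet", name = name, members = unique(as.character(members)))
}

#' Construct an AttributeTable
#'
#' @param feature_ids unique feature identifiers.
#' @param attributes data.frame of logical or numeric columns (one row per
#'   feature).
#' @return An [AttributeTable-class].
#' @export
AttributeTable <- function(feature_ids, attributes) {
  new("AttributeTable", feature_ids = as.character(feature_ids),
      attributes = as.data.frame(attributes))
}

#' Construct a BiotypeMap
#'
#' @param mapping named character vector mapping feature ID to biotype label.
#' @return A [BiotypeMap-class].
#' @export
BiotypeMap <- function(mapping) new("BiotypeMap", mapping = mapping)

#' Specify a profile distance
#'
#' @param metric one of `euclidean`, `pearson`, `spearman`, `cosine`, `ys1`,
#'   `yr1`, `jackknife`.
#' @param weights for `ys1`/`yr1`: non-negative weights of the correlation,
#'   extremum-agreement and slope-concordance terms; must sum to 1.
#' @return A [DistanceSpec-class].
#' @export
distanceSpec <- function(metric = "euclidean",
                         weights = c(0.5, 0.25, 0.25)) {
  new("DistanceSpec", metric = metric, weights = as.numeric(weights))
}

#' Describe a base clustering setup
#'
#' A setup names one of the base algorithms together with its parameters and
#' seed; it is consumed by [runClusterer()], [gapStatistic()] and
#' [clicomEnsemble()].
#'
#' @param algorithm `kmeans`, `kmedoids`, `hierarchical` or `hdbscan`.
#' @param k number of clusters (kmeans/kmedoids/hierarchical).
#' @param linkage hierarchical linkage: `average`, `complete` or `ward`
#'   (ward requires the euclidean metric).
#' @param min_cluster_size smallest cluster size (hdbscan).
#' @param metric a [DistanceSpec-class] (kmedoids/hierarchical/hdbscan).
#' @param seed integer seed for stochastic algorithms.
#' @return A named list descriptor.
#' @export
clusterSetup <- function(algorithm, k = NULL, linkage = "average",
                         min_cluster_size = 5L,
                         metric = distanceSpec("euclidean"), seed = 0L) {
  if (!algorithm %in% c("kmeans", "kmedoids", "hierarchical", "hdbscan"))
    stop("unknown algorithm: ", algorithm)
  list(algorithm = algorithm, k = k, linkage = linkage,
       min_cluster_size = as.integer(min_cluster_size), metric = metric,
       seed = as.integer(seed))
}

#' Configure the ensemble clusterer
#'
#' @param setups list of >= 2 setups from [clusterSetup()].
#' @param evidence_threshold fraction in (0, 1] of base clusterings that must
#'   co-cluster two features for them to count as associated.
#' @param min_cluster_size clusters smaller than this are dropped.
#' @param attach_unclustered reattach leftover features to the best cluster
#'   when their mean evidence passes the threshold.
#' @param seed integer seed.
#' @return An [EnsembleConfig-class].
#' @export
ensembleConfig <- function(setups, evidence_threshold = 0.5,
                           min_cluster_size = 1L,
                           attach_unclustered = FALSE, seed = 0L) {
  new("EnsembleConfig", setups = setups,
      evidence_threshold = evidence_threshold,
      min_cluster_size = as.integer(min_cluster_size),
      attach_unclustered = attach_unclustered, seed = as.integer(seed))
}

#' Design a synthetic RNA-seq experiment
#'
#' Defaults emulate a small time-course experiment: smooth unimodal/monotone
#' cluster mean profiles, negative-binomial noise at moderate dispersion, and
#' 2-fold library-size variation.
#'
#' @param n_features,n_samples,n_clusters design dimensions.
#' @param profiles optional clusters x samples matrix of positive relative
#'   means; generated smooth shapes by default.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param libsize_range range of per-sample library-size scalars.
#' @param de_fraction fraction of truly differential features (for
#'   [simulateDiffExp()]).
#' @param effect_size |log2 fold change| of true differential features.
#' @param seed mandatory integer seed.
#' @return A [SimSpec-class].
#' @export
simSpec <- function(n_features = 300L, n_samples = 6L, n_clusters = 3L,
                    profiles = NULL, dispersion = 0.1,
                    libsize_range = c(0.7, 1.4), de_fraction = 0.1,
                    effect_size = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(profiles))
    profiles <- defaultProfiles(n_clusters, n_samples)
  new("SimSpec", n_features = as.integer(n_features),
      n_samples = as.integer(n_samples), n_clusters = as.integer(n_clusters),
      profiles = profiles, dispersion = dispersion,
      libsize_range = as.numeric(libsize_range),
      de_fraction = de_fraction, effect_size = effect_size,
      seed = as.integer(seed))
}

# Smooth, well-separated relative mean shapes across samples/timepoints:
# rising, falling, and bell-shaped variants spaced on a log scale.
defaultProfiles <- function(n_clusters, n_samples) {
  t <- seq(0, 1, length.out = n_samples)
  shapes <- lapply(seq_len(n_clusters), function(c) {
    phase <- (c - 1) / max(1, n_clusters - 1)
    exp(2.5 * cos(pi * (t - phase)))
  })
  p <- do.call(rbind, shapes)
  p / rowMeans(p)
}
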