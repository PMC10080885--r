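# Base clustering algorithms behind a single setup-descriptor interface.

#' Run a base clustering setup
#'
#' Dispatches on the setup's `algorithm`:
#' * `kmeans` (Euclidean, seeded restarts),
#' * `kmedoids` (partitioning around medoids; any [DistanceSpec-class]),
#' * `hierarchical` (`average`/`complete` linkage with any metric, or `ward`
#'   with the Euclidean metric only), cut at `k`,
#' * `hdbscan` (density-based; `min_cluster_size`; may label noise).
#'
#' Results are deterministic given the setup's seed.
#'
#' @param m a (transformed) [CountMatrix-class] or numeric matrix whose rows
#'   are the objects to cluster.
#' @param setup a descriptor from [clusterSetup()].
#' @return A [ClusteringSolution-class].
#' @export
runClusterer <- function(m, setup) {
  v <- if (is(m, "CountMatrix")) m@values else m
  n <- nrow(v)
  if (is.null(rownames(v))) rownames(v) <- paste0("f", seq_len(n))
  alg <- setup$algorithm
  if (alg %in% c("kmeans", "kmedoids", "hierarchical")) {
    if (is.null(setup$k)) stop(alg, " requires k")
    if (setup$k > n) stop("k must be <= number of features (", n, ")")
  }
  labels <- switch(alg,
    kmeans = {
      if (setup$k == n) {  # every object its own cluster; kmeans refuses k = n
        stats::setNames(seq_len(n), rownames(v))
      } else {
        fit <- withSeed(setup$seed,
                        stats::kmeans(v, centers = setup$k, nstart = 10L,
                                      iter.max = 100L))
        stats::setNames(as.integer(fit$cluster), rownames(v))
      }
    },
    kmedoids = {
      d <- distanceMatrix(v, setup$metric)
      fit <- cluster::pam(d, k = setup$k, diss = TRUE)
      stats::setNames(as.integer(fit$clustering), rownames(v))
    },
    hierarchical = {
      if (setup$linkage == "ward" && setup$metric@metric != "euclidean")
        stop("ward linkage requires the euclidean metric")
      d <- distanceMatrix(v, setup$metric)
      method <- switch(setup$linkage, average = "average",
                       complete = "complete", ward = "ward.D2",
                       stop("unknown linkage: ", setup$linkage))
      hc <- stats::hclust(d, method = method)
      stats::setNames(as.integer(stats::cutree(hc, k = setup$k)), rownames(v))
    },
    hdbscan = {
      d <- distanceMatrix(v, setup$metric)
      hdbscanLabels(d, min_cluster_size = setup$min_cluster_size)
    },
    stop("unknown algorithm: ", alg))
  new("ClusteringSolution", labels = labels, setup = setup)
}

#' Total objective of a k-medoids solution (sum of distances to medoids)
#' @keywords internal
kmedoidsObjective <- function(d, medoids) {
  dm <- as.matrix(d)
  sum(apply(dm[, medoids, drop = FALSE], 1L, min))
}
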