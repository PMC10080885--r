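# Profile distance metrics, including composite time-course metrics that
# combine correlation with agreement of extremum positions and of the signs
# of consecutive changes (YS1/YR1), and the outlier-robust jackknife
# correlation distance.

#' Distance between two expression profiles
#'
#' * `euclidean`: standard Euclidean distance.
#' * `pearson`/`spearman`/`cosine`: 1 - coefficient (range \[0, 2\]).
#' * `ys1`/`yr1`: 1 - composite similarity
#'   `w1 * (cor + 1)/2 + w2 * A + w3 * M`, where `cor` is the Spearman (YS1)
#'   or Pearson (YR1) correlation, `A` is the mean agreement of the argmax
#'   and argmin positions, and `M` is the fraction of consecutive intervals
#'   whose changes have equal sign.  With weights summing to 1 the distance
#'   lies in \[0, 1\].
#' * `jackknife`: 1 - minimum over all leave-one-out Pearson correlations.
#'
#' @param x,y numeric profiles of equal length (>= 2; `ys1`, `yr1` and
#'   `jackknife` need >= 3).
#' @param spec a [DistanceSpec-class].
#' @return non-negative distance.
#' @export
profileDistance <- function(x, y, spec = distanceSpec("euclidean")) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  n <- length(x)
  if (n < 2L) stop("profiles must have length >= 2")
  metric <- spec@metric
  if (metric %in% c("ys1", "yr1", "jackknife") && n < 3L)
    stop(metric, " requires profiles of length >= 3")
  if (metric %in% c("pearson", "spearman", "ys1", "yr1", "jackknife") &&
      (stats::sd(x) == 0 || stats::sd(y) == 0))
    stop("correlation-based metrics are undefined for constant profiles")
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    pearson = 1 - stats::cor(x, y),
    spearman = 1 - stats::cor(x, y, method = "spearman"),
    cosine = 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
    ys1 = 1 - ysSimilarity(x, y, spec@weights, method = "spearman"),
    yr1 = 1 - ysSimilarity(x, y, spec@weights, method = "pearson"),
    jackknife = 1 - jackknifeCor(x, y))
}

ysSimilarity <- function(x, y, w, method) {
  rho <- stats::cor(x, y, method = method)
  agree <- (as.numeric(which.max(x) == which.max(y)) +
            as.numeric(which.min(x) == which.min(y))) / 2
  slope <- mean(sign(diff(x)) == sign(diff(y)))
  w[1] * (rho + 1) / 2 + w[2] * agree + w[3] * slope
}

jackknifeCor <- function(x, y) {
  n <- length(x)
  min(vapply(seq_len(n), function(i) stats::cor(x[-i], y[-i]), 0))
}

#' Pairwise distance matrix of feature profiles
#'
#' @param m a [CountMatrix-class] (rows are profiles) or a numeric matrix.
#' @param spec a [DistanceSpec-class].
#' @return a `dist` object over the rows.
#' @export
distanceMatrix <- function(m, spec = distanceSpec("euclidean")) {
  v <- if (is(m, "CountMatrix")) m@values else m
  if (spec@metric == "euclidean") return(stats::dist(v))
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  if (spec@metric %in% c("pearson", "spearman")) {
    cc <- stats::cor(t(v), method = spec@metric)
    d <- 1 - cc
  } else if (spec@metric == "cosine") {
    nrm <- sqrt(rowSums(v^2))
    d <- 1 - (v %*% t(v)) / outer(nrm, nrm)
  } else {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- profileDistance(v[i, ], v[j, ], spec)
      }
    }
  }
  diag(d) <- 0
  stats::as.dist(pmax(d, 0))
}
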