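# Gap-statistic model selection: compare the log within-cluster dispersion to
# its expectation under a null reference drawn uniformly from the PCA-aligned
# bounding box of the data.

withinDispersion <- function(v, labels) {
  # sum over clusters of (sum of pairwise squared distances) / (2 * size),
  # computed via the equivalent centroid form
  sum(vapply(split(seq_len(nrow(v)), labels), function(idx) {
    sub <- v[idx, , drop = FALSE]
    ctr <- colMeans(sub)
    sum(sweep(sub, 2L, ctr)^2)
  }, 0))
}

#' Gap statistic for choosing the number of clusters
#'
#' For each k in `k_range`, runs the clusterer on the data and on `n_refs`
#' null datasets drawn uniformly inside the PCA-aligned bounding box of the
#' data.  `Gap(k)` is the mean reference `log W*_k` minus the observed
#' `log W_k`; the chosen k is the smallest k with
#' `Gap(k) >= Gap(k+1) - s(k+1)` (standard one-standard-error rule), falling
#' back to the k maximizing the gap.
#'
#' @param m a [CountMatrix-class] or numeric matrix (rows are objects).
#' @param setup a [clusterSetup()] descriptor used as a template; its `k` is
#'   replaced by each candidate value.
#' @param k_range contiguous positive integers to evaluate.
#' @param n_refs number of reference datasets (>= 10).
#' @param seed integer seed for the reference draws.
#' @return A [GapResult-class].
#' @export
gapStatistic <- function(m, setup, k_range = 1:8, n_refs = 50L, seed = 0L) {
  v <- if (is(m, "CountMatrix")) m@values else m
  k_range <- sort(as.integer(k_range))
  if (!length(k_range) || any(diff(k_range) != 1L))
    stop("k_range must be non-empty contiguous integers")
  if (max(k_range) >= nrow(v)) stop("max of k_range must be < n")
  if (n_refs < 10L) stop("n_refs must be >= 10")
  clusterK <- function(x, k) {
    if (k == 1L) return(rep(1L, nrow(x)))
    s <- setup; s$k <- k
    runClusterer(x, s)@labels
  }
  log_w <- vapply(k_range, function(k)
    log(withinDispersion(v, clusterK(v, k))), 0)
  # PCA-aligned bounding box of the data
  ctr <- colMeans(v)
  xc <- sweep(v, 2L, ctr)
  sv <- svd(xc, nu = 0)
  vp <- xc %*% sv$v
  lo <- apply(vp, 2L, min); hi <- apply(vp, 2L, max)
  ref_log_w <- withSeed(seed, {
    vapply(seq_len(n_refs), function(b) {
      zp <- vapply(seq_along(lo), function(j)
        stats::runif(nrow(v), lo[j], hi[j]), numeric(nrow(v)))
      z <- zp %*% t(sv$v)
      vapply(k_range, function(k)
        log(withinDispersion(z, clusterK(z, k))), 0)
    }, numeric(length(k_range)))
  })
  ref_log_w <- matrix(ref_log_w, nrow = length(k_range))
  log_w_ref <- rowMeans(ref_log_w)
  se <- apply(ref_log_w, 1L, stats::sd) * sqrt(1 + 1 / n_refs)
  gap <- log_w_ref - log_w
  chosen <- NA_integer_
  if (length(k_range) > 1L) {
    for (i in seq_len(length(k_range) - 1L)) {
      if (gap[i] >= gap[i + 1L] - se[i + 1L]) { chosen <- k_range[i]; break }
    }
  }
  if (is.na(chosen)) chosen <- k_range[which.max(gap)]
  new("GapResult", k = k_range, gap = gap, log_w = log_w,
      log_w_ref = log_w_ref, se = se, chosen_k = chosen)
}
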