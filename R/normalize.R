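# Between-sample normalization and variance-stabilizing transforms.

#' Median-of-ratios size factors
#'
#' For every reference feature (a feature with positive counts in all
#' samples), the ratio of each sample's count to the feature's geometric mean
#' across samples is formed; the size factor of a sample is the median of
#' those ratios.  Also known as relative-log-expression (RLE) factors;
#' [sizeFactorsRLE()] is an alias.
#'
#' @param m a [CountMatrix-class].
#' @return A [NormFactors-class] with method `median_of_ratios`.
#' @export
sizeFactorsMedianOfRatios <- function(m) {
  v <- m@values
  ok <- apply(v, 1L, function(r) all(!is.na(r)) && all(r > 0))
  if (!any(ok))
    stop("no feature is positive in all samples; ",
         "filter lowly-expressed features first")
  ref <- v[ok, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  factors <- apply(ref / geo, 2L, stats::median)
  new("NormFactors", factors = factors, method = "median_of_ratios")
}

#' @rdname sizeFactorsMedianOfRatios
#' @export
sizeFactorsRLE <- sizeFactorsMedianOfRatios

#' Counts-per-million factors
#'
#' Placeholder factors (all 1) carrying the CPM method tag;
#' [applyNormalization()] scales each sample to one million.
#'
#' @param m a [CountMatrix-class].
#' @return A [NormFactors-class] with method `cpm`.
#' @export
cpmFactors <- function(m) {
  new("NormFactors",
      factors = stats::setNames(rep(1, ncol(m@values)), colnames(m@values)),
      method = "cpm")
}

#' Trimmed mean of M-values (TMM) composition factors
#'
#' For sample k against reference r (library sizes N):
#' \deqn{M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}, \quad
#'       A_g = \tfrac12 \log_2\left(\frac{y_{gk}}{N_k}\cdot\frac{y_{gr}}{N_r}\right)}
#' computed on features positive in both samples, doubly trimmed by M
#' (`logratio_trim` per tail) and A (`abs_trim` per tail), and combined with
#' inverse-variance (delta-method) weights
#' \eqn{w_g = (N_k - y_{gk})/(N_k y_{gk}) + (N_r - y_{gr})/(N_r y_{gr})} as
#' \eqn{f_k = 2^{\sum w_g M_g / \sum w_g}}.  Factors are renormalized to
#' geometric mean 1.  The default reference is the sample whose
#' upper-quartile/library-size ratio is closest to the mean of that ratio.
#'
#' @param m a [CountMatrix-class].
#' @param logratio_trim fraction of M values trimmed per tail.
#' @param abs_trim fraction of A values trimmed per tail.
#' @param ref_sample optional reference sample ID.
#' @return A [NormFactors-class] with method `tmm`.
#' @export
tmmFactors <- function(m, logratio_trim = 0.3, abs_trim = 0.05,
                       ref_sample = NULL) {
  v <- m@values
  if (anyNA(v)) stop("missing values: apply dropMissing() first")
  N <- colSums(v)
  if (any(N <= 0)) stop("all library sizes must be > 0")
  if (is.null(ref_sample)) {
    uq <- apply(v, 2L, stats::quantile, probs = 0.75) / N
    ref_sample <- colnames(v)[which.min(abs(uq - mean(uq)))]
  }
  r <- v[, ref_sample]
  Nr <- N[ref_sample]
  f <- vapply(colnames(v), function(k) {
    if (k == ref_sample) return(1)
    y <- v[, k]; Nk <- N[k]
    pos <- y > 0 & r > 0
    if (!any(pos))
      stop("sample ", k, " shares no positive feature with the reference")
    yk <- y[pos]; yr <- r[pos]
    M <- log2((yk / Nk) / (yr / Nr))
    A <- 0.5 * log2((yk / Nk) * (yr / Nr))
    w <- (Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, 0)
  f <- f / exp(mean(log(f)))
  new("NormFactors", factors = stats::setNames(f, colnames(v)), method = "tmm")
}

#' Apply normalization factors to a count matrix
#'
#' `median_of_ratios`/`rle` factors divide each sample's counts by its
#' factor.  `cpm` scales each sample to one million (each column sums to
#' exactly 1e6).  `tmm` computes CPM on effective library sizes (counts
#' divided by factor x library size / 1e6).
#'
#' @param m a [CountMatrix-class].
#' @param f a [NormFactors-class] with a factor for every sample.
#' @return normalized [CountMatrix-class] with the `normalized` flag set.
#' @export
applyNormalization <- function(m, f) {
  v <- m@values
  if (!all(colnames(v) %in% names(f@factors)))
    stop("missing factor for sample(s): ",
         paste(setdiff(colnames(v), names(f@factors)), collapse = ", "))
  fac <- f@factors[colnames(v)]
  out <- m
  out@values <- switch(f@method,
    median_of_ratios = ,
    rle = sweep(v, 2L, fac, "/"),
    cpm = sweep(v, 2L, colSums(v, na.rm = TRUE) / 1e6, "/"),
    tmm = sweep(v, 2L, fac * colSums(v, na.rm = TRUE) / 1e6, "/"),
    quantile = stop("use quantileNormalize() for quantile normalization"))
  out@normalized <- TRUE
  out@name <- deriveName(m@name, paste0("norm", f@method))
  appendHistory(out, paste0("normalize_", f@method), list(),
                nrow(v), nrow(v))
}

#' Quantile normalization
#'
#' Makes every sample's value distribution identical: values are replaced by
#' the mean, across samples, of the values at the same rank; ties receive the
#' mean of their rank-values.
#'
#' @param m a [CountMatrix-class] without missing values.
#' @return normalized [CountMatrix-class].
#' @export
quantileNormalize <- function(m) {
  v <- m@values
  if (anyNA(v)) stop("missing values: apply dropMissing() first")
  sorted <- apply(v, 2L, sort)
  target <- rowMeans(sorted)
  out_v <- apply(v, 2L, function(col) {
    o <- order(col)
    # tied values share the mean of the rank-values their ranks span
    g <- cumsum(c(TRUE, diff(col[o]) != 0))
    grp_mean <- tapply(target, g, mean)
    res <- numeric(length(col))
    res[o] <- grp_mean[g]
    res
  })
  dimnames(out_v) <- dimnames(v)
  out <- m
  out@values <- out_v
  out@normalized <- TRUE
  out@name <- deriveName(m@name, "normquantile")
  appendHistory(out, "quantile_normalize", list(), nrow(v), nrow(v))
}

# Profile log-likelihood Box-Cox MLE of lambda for positive data.
boxcoxLambda <- function(y, interval = c(-2, 5)) {
  n <- length(y)
  slog <- sum(log(y))
  negll <- function(lambda) {
    z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
    s2 <- stats::var(z) * (n - 1) / n
    (n / 2) * log(s2) - (lambda - 1) * slog
  }
  stats::optimize(negll, interval = interval)$minimum
}

boxcoxTransform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

#' Power-transform and standardize a count matrix
#'
#' Applies a Box-Cox transform to value + 1 with lambda fitted per sample by
#' maximum likelihood, standardizes each sample (so that library depth and
#' the sample-specific transform scale drop out), then standardizes each
#' feature to mean 0 and standard deviation 1.  Features with zero variance
#' after transformation are set to all-zeros and recorded in the history
#' record (`degenerate` in the info field).  Multiplying all counts of one
#' sample by a positive constant leaves the output invariant up to the
#' (re-)fitted lambda.
#'
#' @param m a [CountMatrix-class] with non-negative values.
#' @return transformed [CountMatrix-class] (normalized flag set).
#' @export
powerTransformStandardize <- function(m) {
  v <- m@values
  if (anyNA(v)) stop("missing values: apply dropMissing() first")
  lambdas <- apply(v + 1, 2L, boxcoxLambda)
  tv <- vapply(seq_len(ncol(v)), function(j)
    boxcoxTransform(v[, j] + 1, lambdas[j]), numeric(nrow(v)))
  tv <- matrix(tv, nrow = nrow(v), dimnames = dimnames(v))
  csd <- apply(tv, 2L, stats::sd)
  tv <- sweep(tv, 2L, colMeans(tv))
  tv <- sweep(tv, 2L, ifelse(csd < 1e-12, 1, csd), "/")
  mu <- rowMeans(tv)
  sd <- apply(tv, 1L, stats::sd)
  degenerate <- sd < 1e-12
  z <- (tv - mu) / ifelse(degenerate, 1, sd)
  z[degenerate, ] <- 0
  out <- m
  out@values <- z
  out@normalized <- TRUE
  out@name <- deriveName(m@name, "powerstd")
  appendHistory(out, "power_transform_standardize", list(),
                nrow(v), nrow(v),
                info = list(lambdas = unname(lambdas),
                            degenerate = rownames(v)[degenerate]))
}
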