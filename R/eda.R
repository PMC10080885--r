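# Exploratory summaries: PCA over samples, pairwise sample correlation, and
# volcano-style classification of differential-expression results.

#' Principal component analysis of samples
#'
#' Samples are the observations and features the variables; the matrix is
#' centered but not rescaled (compose with [powerTransformStandardize()] for
#' standardized input).  Signs are fixed so that each component's
#' largest-magnitude loading is positive, making results deterministic.
#'
#' @param m a [CountMatrix-class] without missing values.
#' @param n_components number of components, at most
#'   `min(samples, features)`.
#' @return A [PCAResult-class].
#' @export
runPCA <- function(m, n_components = 2L) {
  v <- m@values
  if (anyNA(v)) stop("missing values: apply dropMissing() first")
  kmax <- min(ncol(v), nrow(v))
  if (n_components > kmax)
    stop("n_components must be <= min(#samples, #features) = ", kmax)
  x <- t(v)  # samples x features
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  vf <- pc$sdev^2 / total_var
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  # sign convention: largest-|loading| positive
  for (j in k) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  new("PCAResult", scores = scores, loadings = loadings,
      variance_fraction = vf[k])
}

#' Pairwise sample correlation matrix
#'
#' @param m a [CountMatrix-class] with at least 3 features.
#' @param method `spearman` or `pearson`.
#' @return symmetric samples x samples correlation matrix with unit diagonal.
#'   A constant sample under `pearson` yields `NA` entries with a warning.
#' @export
sampleCorrelation <- function(m, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- m@values
  if (nrow(v) < 3L) stop("need at least 3 features")
  const <- apply(v, 2L, function(col) stats::sd(col, na.rm = TRUE) == 0)
  if (method == "pearson" && any(const))
    warning("constant sample(s): ",
            paste(colnames(v)[const], collapse = ", "),
            "; correlations recorded as NA")
  cc <- suppressWarnings(
    stats::cor(v, method = method, use = "pairwise.complete.obs"))
  diag(cc) <- 1
  cc
}

#' Classify differential-expression results volcano-style
#'
#' `up` means padj <= alpha and log2fc >= magnitude; `down` means padj <=
#' alpha and log2fc <= -magnitude; everything else (including missing padj)
#' is `not_significant`.
#'
#' @param t a [DiffExpTable-class].
#' @param alpha significance cutoff in (0, 1].
#' @param magnitude non-negative log2 fold-change cutoff.
#' @return data.frame with columns `feature` and `class` plus the thresholds
#'   as attributes.
#' @export
volcanoClassify <- function(t, alpha = 0.05, magnitude = 1) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (magnitude < 0) stop("magnitude must be >= 0")
  sig <- !is.na(t@padj) & t@padj <= alpha
  cls <- rep("not_significant", length(t@feature_ids))
  cls[sig & !is.na(t@log2fc) & t@log2fc >= magnitude] <- "up"
  cls[sig & !is.na(t@log2fc) & t@log2fc <= -magnitude &
        (magnitude > 0 | t@log2fc < 0)] <- "down"
  out <- data.frame(feature = t@feature_ids, class = cls)
  attr(out, "alpha") <- alpha
  attr(out, "magnitude") <- magnitude
  out
}

# ---- figure writers (renderings of tested numbers; smoke-tested only) ----

openDevice <- function(path, width = 7, height = 7) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 120),
    svg = grDevices::svg(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop("unsupported image format: .", ext))
}

#' Write a PCA scatter plot
#'
#' @param pca a [PCAResult-class].
#' @param path output image path (`.png`, `.svg`, or `.pdf`).
#' @param components two component indices.
#' @param labels optional point labels (e.g. cluster assignment).
#' @return the path, invisibly.
#' @export
plotPCA <- function(pca, path, components = c(1L, 2L), labels = NULL) {
  s <- pca@scores
  openDevice(path)
  on.exit(grDevices::dev.off())
  col <- if (is.null(labels)) "steelblue"
         else as.integer(factor(labels)) + 1L
  graphics::plot(s[, components[1]], s[, components[2]], col = col, pch = 19,
       xlab = sprintf("PC%d (%.1f%%)", components[1],
                      100 * pca@variance_fraction[components[1]]),
       ylab = sprintf("PC%d (%.1f%%)", components[2],
                      100 * pca@variance_fraction[components[2]]),
       main = "PCA projection")
  invisible(path)
}

#' Write a volcano plot
#'
#' @param t a [DiffExpTable-class].
#' @param path output image path.
#' @param alpha,magnitude classification thresholds (see [volcanoClassify()]).
#' @return the path, invisibly.
#' @export
plotVolcano <- function(t, path, alpha = 0.05, magnitude = 1) {
  cls <- volcanoClassify(t, alpha, magnitude)$class
  col <- c(up = "red", down = "blue", not_significant = "grey50")[cls]
  p <- t@padj
  p[is.na(p) | p <= 0] <- NA
  openDevice(path)
  on.exit(grDevices::dev.off())
  graphics::plot(t@log2fc, -log10(p), col = col, pch = 19, cex = 0.6,
       xlab = "log2 fold change", ylab = "-log10 adjusted p",
       main = "Volcano plot")
  graphics::abline(v = c(-magnitude, magnitude), h = -log10(alpha), lty = 2)
  invisible(path)
}

#' Write a sample-correlation heatmap
#'
#' @param cc correlation matrix from [sampleCorrelation()].
#' @param path output image path.
#' @return the path, invisibly.
#' @export
plotCorrelationHeatmap <- function(cc, path) {
  openDevice(path)
  on.exit(grDevices::dev.off())
  n <- ncol(cc)
  graphics::image(seq_len(n), seq_len(n), t(cc[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Sample correlation",
                  col = grDevices::hcl.colors(64, "viridis"))
  graphics::axis(1, seq_len(n), colnames(cc), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(n), rev(rownames(cc)), las = 2, cex.axis = 0.8)
  invisible(path)
}

#' Write per-cluster expression profile plots
#'
#' One panel per cluster: every member profile in grey, the cluster mean as a
#' center line with +-1 standard deviation.
#'
#' @param m the (transformed) [CountMatrix-class] that was clustered.
#' @param solution a [ClusteringSolution-class].
#' @param path output image path.
#' @return the path, invisibly.
#' @export
plotClusterProfiles <- function(m, solution, path) {
  lab <- solution@labels[rownames(m@values)]
  ks <- sort(unique(lab[lab != -1L]))
  openDevice(path, width = 8, height = 2.6 * max(1, ceiling(length(ks) / 3)))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(max(1, ceiling(length(ks) / 3)), min(3, length(ks))),
                mar = c(3, 3, 2, 1))
  xs <- seq_len(ncol(m@values))
  for (k in ks) {
    vv <- m@values[lab == k, , drop = FALSE]
    mu <- colMeans(vv); sdv <- apply(vv, 2L, stats::sd)
    graphics::matplot(xs, t(vv), type = "l", lty = 1,
                      col = grDevices::adjustcolor("grey", 0.4),
                      xlab = "", ylab = "",
                      main = sprintf("Cluster %d (n=%d)", k, nrow(vv)))
    graphics::lines(xs, mu, lwd = 2, col = "darkblue")
    graphics::lines(xs, mu + sdv, lty = 2, col = "darkblue")
    graphics::lines(xs, mu - sdv, lty = 2, col = "darkblue")
  }
  invisible(path)
}
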