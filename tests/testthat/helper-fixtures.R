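# Shared fixtures, built in code.

# 6-row DE table: at alpha 0.05 / |log2FC| >= 1 it has exactly 2 significant
# up-regulated rows, 1 significant down-regulated row, and 3 others.
toyDiffExp <- function() {
  DiffExpTable(
    feature_ids = paste0("g", 1:6),
    log2fc = c(2, 1.5, -2, 2, 0.5, -0.3),
    pval = c(0.005, 0.02, 0.01, 0.15, 0.004, NA),
    padj = c(0.01, 0.04, 0.02, 0.20, 0.01, NA),
    name = "toy")
}

toyCounts <- function(n = 20, s = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n * s, mu = 50, size = 5), n, s,
                dimnames = list(sprintf("g%02d", seq_len(n)),
                                paste0("s", seq_len(s))))
    CountMatrix(m, name = "toycounts")
  })
}

# 2-D Gaussian blobs with distinct centers
makeBlobs <- function(n_per, centers, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
    rownames(pts) <- paste0("p", seq_len(nrow(pts)))
    list(x = pts, truth = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# chain DAG root <- P <- C with C annotated to the first n_ann of n_genes
toyChainDag <- function() {
  terms <- c("root", "P", "C")
  new("OntologyDAG", terms = terms,
      names = stats::setNames(terms, terms),
      namespaces = stats::setNames(rep(NA_character_, 3), terms),
      parents = list(root = character(), P = "root", C = "P"))
}

# independent upper-tail hypergeometric oracle by PMF summation
hyperTailOracle <- function(x, N, n, M) {
  ks <- x:min(N, n)
  ks <- ks[ks >= max(0, N - (M - n))]
  if (!length(ks)) return(0)
  sum(choose(n, ks) * choose(M - n, N - ks)) / choose(M, N)
}

# independent BH/BY step-up oracle
fdrOracle <- function(p, method) {
  m <- length(p)
  o <- order(p)
  cm <- if (method == "by") sum(1 / seq_len(m)) else 1
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
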