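# Base clusterers, HDBSCAN, gap statistic, and the ensemble consensus.

test_that("kmeans recovers well-separated blobs and respects trivial cases", {
  blobs <- makeBlobs(30, rbind(c(0, 0), c(12, 0), c(0, 12)), sd = 1, seed = 41)
  sol <- runClusterer(blobs$x, clusterSetup("kmeans", k = 3L, seed = 7L))
  expect_equal(adjustedRandIndex(sol@labels, blobs$truth), 1)
  expect_equal(names(sol@labels), rownames(blobs$x))

  # k = n gives all singletons
  small <- blobs$x[1:6, ]
  singl <- runClusterer(small, clusterSetup("kmeans", k = 6L, seed = 1L))
  expect_equal(sort(unname(singl@labels)), 1:6)
  expect_error(runClusterer(small, clusterSetup("kmeans", k = 7L, seed = 1L)),
               "k must be")
  expect_error(runClusterer(small, clusterSetup("kmeans")), "requires k")

  # deterministic given the seed
  again <- runClusterer(blobs$x, clusterSetup("kmeans", k = 3L, seed = 7L))
  expect_identical(sol@labels, again@labels)
})

test_that("kmedoids matches or beats random medoid sets on its objective", {
  blobs <- makeBlobs(15, rbind(c(0, 0), c(8, 8)), sd = 1.5, seed = 42)
  d <- distanceMatrix(blobs$x, distanceSpec("euclidean"))
  sol <- runClusterer(blobs$x, clusterSetup("kmedoids", k = 2L))
  expect_equal(adjustedRandIndex(sol@labels, blobs$truth), 1)
  # pam's medoids minimize total distance at least as well as random pairs
  dm <- as.matrix(d)
  fit <- cluster::pam(d, k = 2, diss = TRUE)
  ours <- rnakit:::kmedoidsObjective(d, fit$id.med)
  rand <- withr::with_seed(43, replicate(1000, {
    med <- sample(nrow(dm), 2)
    rnakit:::kmedoidsObjective(d, med)
  }))
  expect_true(all(ours <= rand + 1e-9))
})

test_that("kmedoids and hierarchical accept correlation metrics", {
  cm <- counts(simulateCounts(simSpec(n_features = 60, seed = 44))$counts)
  z <- t(scale(t(log1p(cm))))
  for (setup in list(
    clusterSetup("kmedoids", k = 3L, metric = distanceSpec("spearman")),
    clusterSetup("hierarchical", k = 3L, metric = distanceSpec("pearson")),
    clusterSetup("hierarchical", k = 3L, linkage = "complete",
                 metric = distanceSpec("ys1")))) {
    sol <- runClusterer(z, setup)
    expect_length(unique(sol@labels), 3L)
  }
  expect_error(
    runClusterer(z, clusterSetup("hierarchical", k = 3L, linkage = "ward",
                                 metric = distanceSpec("pearson"))),
    "euclidean")
})

test_that("hierarchical within-dispersion is non-increasing in k", {
  blobs <- makeBlobs(20, rbind(c(0, 0), c(6, 6), c(-6, 6)), sd = 2, seed = 45)
  w <- vapply(1:8, function(k) {
    sol <- runClusterer(blobs$x,
                        clusterSetup("hierarchical", k = k,
                                     linkage = "average"))
    rnakit:::withinDispersion(blobs$x, sol@labels)
  }, 0)
  expect_true(all(diff(w) <= 1e-9))
})

test_that("hdbscan recovers blobs and labels distant points as noise", {
  blobs <- makeBlobs(30, rbind(c(0, 0), c(15, 0), c(0, 15)), sd = 1, seed = 46)
  x <- rbind(blobs$x, far1 = c(200, 200), far2 = c(-200, 150))
  sol <- runClusterer(x, clusterSetup("hdbscan", min_cluster_size = 10L))
  lab <- sol@labels
  expect_equal(unname(lab[c("far1", "far2")]), c(-1L, -1L))
  core <- lab[seq_len(90)]
  expect_true(all(core != -1L))
  expect_equal(adjustedRandIndex(core, blobs$truth), 1)
  # cluster 1 is the largest (here all equal size, numbering still 1..3)
  expect_setequal(unique(unname(core)), 1:3)
})

test_that("gap statistic picks k=3 on blobs and k=1 on one Gaussian", {
  blobs <- makeBlobs(25, rbind(c(0, 0), c(10, 0), c(5, 9)), sd = 1, seed = 47)
  g3 <- gapStatistic(blobs$x, clusterSetup("kmeans", seed = 3L),
                     k_range = 1:6, n_refs = 25L, seed = 48L)
  expect_equal(g3@chosen_k, 3L)
  one <- withr::with_seed(49, matrix(rnorm(120), 60, 2,
    dimnames = list(paste0("p", 1:60), c("d1", "d2"))))
  g1 <- gapStatistic(one, clusterSetup("kmeans", seed = 3L),
                     k_range = 1:5, n_refs = 25L, seed = 50L)
  expect_equal(g1@chosen_k, 1L)
  expect_error(gapStatistic(one, clusterSetup("kmeans"), k_range = c(1, 3)),
               "contiguous")
  expect_error(gapStatistic(one, clusterSetup("kmeans"), n_refs = 5L),
               "n_refs")
})

test_that("evidence matrix counts co-clustering fractions exactly", {
  lm <- rbind(c(1L, 1L, 2L, 2L),
              c(1L, 2L, 2L, 2L),
              c(1L, 1L, 1L, -1L))
  colnames(lm) <- letters[1:4]
  E <- evidenceMatrix(lm)
  expect_equal(E["a", "b"], 2 / 3)
  expect_equal(E["c", "d"], 2 / 3)
  expect_equal(E["a", "d"], 0)      # noise never co-clusters
  expect_equal(E["b", "c"], 2 / 3)
  expect_equal(unname(diag(E)), rep(1, 4))
  expect_equal(E, t(E))
  expect_true(all(E >= 0 & E <= 1))
})

test_that("consensus of identical solutions returns that solution", {
  lm <- rbind(rep(c(1L, 2L), each = 5),
              rep(c(1L, 2L), each = 5),
              rep(c(3L, 9L), each = 5))  # same partition, other label names
  colnames(lm) <- paste0("f", 1:10)
  cfg <- ensembleConfig(list(clusterSetup("kmeans", k = 2L),
                             clusterSetup("kmeans", k = 2L)),
                        evidence_threshold = 0.5)
  sol <- rnakit:::consensusFromLabels(lm, cfg, colnames(lm))
  expect_equal(adjustedRandIndex(sol@labels, lm[1, ]), 1)
  expect_true(all(sol@labels != -1L))
})

test_that("consensus resolves the worked two-group example", {
  # 3 solutions over a..f: two agree on {a,b,c}/{d,e,f}, one splits c off
  lm <- rbind(c(1L, 1L, 1L, 2L, 2L, 2L),
              c(1L, 1L, 1L, 2L, 2L, 2L),
              c(1L, 1L, 2L, 3L, 3L, 3L))
  colnames(lm) <- letters[1:6]
  cfg <- ensembleConfig(list(clusterSetup("kmeans", k = 2L),
                             clusterSetup("kmeans", k = 2L)),
                        evidence_threshold = 0.5, min_cluster_size = 2L)
  sol <- rnakit:::consensusFromLabels(lm, cfg, colnames(lm))
  expect_equal(adjustedRandIndex(sol@labels,
                                 c(1L, 1L, 1L, 2L, 2L, 2L)), 1)
})

test_that("consensus is invariant to base-solution label permutation", {
  blobs <- makeBlobs(20, rbind(c(0, 0), c(9, 9)), sd = 1, seed = 51)
  base <- lapply(1:4, function(i)
    runClusterer(blobs$x,
                 clusterSetup("kmeans", k = 2L, seed = i))@labels)
  lm1 <- do.call(rbind, base)
  colnames(lm1) <- rownames(blobs$x)
  lm2 <- lm1
  lm2[2, ] <- 3L - lm2[2, ]  # swap labels 1 <-> 2 in one solution
  cfg <- ensembleConfig(list(clusterSetup("kmeans", k = 2L),
                             clusterSetup("kmeans", k = 2L)),
                        evidence_threshold = 0.5)
  s1 <- rnakit:::consensusFromLabels(lm1, cfg, colnames(lm1))
  s2 <- rnakit:::consensusFromLabels(lm2, cfg, colnames(lm2))
  expect_identical(s1@labels, s2@labels)
})

test_that("min_cluster_size drops small consensus clusters", {
  lm <- rbind(c(1L, 1L, 1L, 1L, 2L),
              c(1L, 1L, 1L, 1L, 2L))
  colnames(lm) <- paste0("f", 1:5)
  cfg <- ensembleConfig(list(clusterSetup("kmeans", k = 2L),
                             clusterSetup("kmeans", k = 2L)),
                        evidence_threshold = 0.5, min_cluster_size = 3L)
  sol <- rnakit:::consensusFromLabels(lm, cfg, colnames(lm))
  expect_equal(unname(sol@labels), c(1L, 1L, 1L, 1L, -1L))
  tiny <- ensembleConfig(list(clusterSetup("kmeans", k = 2L),
                              clusterSetup("kmeans", k = 2L)),
                         evidence_threshold = 0.5, min_cluster_size = 10L)
  expect_warning(empty <- rnakit:::consensusFromLabels(lm, tiny,
                                                       colnames(lm)),
                 "min_cluster_size")
  expect_true(all(empty@labels == -1L))
})

test_that("clicomEnsemble recovers planted expression clusters", {
  spec <- simSpec(n_features = 120L, n_samples = 8L, n_clusters = 3L,
                  dispersion = 0.05, seed = 52L)
  sim <- simulateCounts(spec)
  truth <- sim$labels
  z <- counts(powerTransformStandardize(sim$counts))
  cfg <- ensembleConfig(
    list(clusterSetup("kmeans", k = 3L, seed = 1L),
         clusterSetup("kmedoids", k = 3L, metric = distanceSpec("spearman")),
         clusterSetup("hierarchical", k = 3L,
                      metric = distanceSpec("pearson")),
         clusterSetup("kmeans", k = 4L, seed = 2L),
         clusterSetup("hdbscan", min_cluster_size = 15L)),
    evidence_threshold = 0.5, min_cluster_size = 10L,
    attach_unclustered = TRUE)
  sol <- clicomEnsemble(z, cfg)
  keep <- sol@labels != -1L
  expect_gt(adjustedRandIndex(sol@labels[keep], truth[keep]), 0.9)
  expect_gt(mean(keep), 0.8)
})

test_that("clusterReplicates pools batches and checks the feature universe", {
  spec1 <- simSpec(n_features = 90L, n_samples = 6L, n_clusters = 2L,
                   dispersion = 0.05, seed = 53L)
  spec2 <- simSpec(n_features = 90L, n_samples = 6L, n_clusters = 2L,
                   dispersion = 0.05, seed = 54L)
  sim1 <- simulateCounts(spec1)
  sim2 <- simulateCounts(spec2)
  b1 <- counts(powerTransformStandardize(sim1$counts))
  b2 <- counts(powerTransformStandardize(sim2$counts))
  rownames(b2) <- rownames(b1)
  truth <- sim1$labels
  cfg <- ensembleConfig(
    list(clusterSetup("kmeans", k = 2L, seed = 1L),
         clusterSetup("hierarchical", k = 2L,
                      metric = distanceSpec("pearson"))),
    evidence_threshold = 0.5, min_cluster_size = 5L)
  sol <- clusterReplicates(list(b1, b2), cfg)
  keep <- sol@labels != -1L
  expect_gt(adjustedRandIndex(sol@labels[keep], truth[keep]), 0.9)

  bad <- b2[-1, , drop = FALSE]
  expect_error(clusterReplicates(list(b1, bad), cfg), "feature mismatch")
})

test_that("adjustedRandIndex behaves on identities, permutations and noise", {
  a <- rep(1:3, each = 10)
  expect_equal(adjustedRandIndex(a, a), 1)
  perm <- c(2L, 3L, 1L)[a]
  expect_equal(adjustedRandIndex(a, perm), 1)
  b <- withr::with_seed(55, sample(1:3, 30, replace = TRUE))
  expect_lt(abs(adjustedRandIndex(a, b)), 0.35)
  expect_equal(adjustedRandIndex(rep(1L, 10), rep(1L, 10)), 1)
})
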