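# Enrichment tests: hypergeometric, permutation, ELIM, mHG, FDR, continuous.

test_that("hypergeomTest matches PMF-summation oracles", {
  # 10 of 100 genes annotated, 5 of 10 drawn
  expect_equal(hypergeomTest(5, 10, 10, 100), hyperTailOracle(5, 10, 10, 100),
               tolerance = 1e-12)
  # 1 of 3 drawn from 5/20 annotated
  expect_equal(hypergeomTest(1, 3, 5, 20), hyperTailOracle(1, 3, 5, 20),
               tolerance = 1e-12)
  expect_equal(hypergeomTest(0, 3, 5, 20), 1)
  expect_error(hypergeomTest(4, 3, 5, 20), "impossible")
  expect_error(hypergeomTest(2, 3, 5, 2), "impossible")
})

test_that("permutation p-values agree with the exact test within MC error", {
  bg <- sprintf("g%03d", 1:60)
  annotated <- bg[1:15]
  test <- c(bg[1:6], bg[40:45])  # 6 annotated of 12 drawn
  exact <- hypergeomTest(6, 12, 15, 60)
  r <- 4999L
  res <- categoricalEnrichment(GeneSet("t", test),
                               list(A = annotated), GeneSet("bg", bg),
                               method = "permutation",
                               perm = permConfig(repeats = r, seed = 7L))
  se <- sqrt(exact * (1 - exact) / r)
  expect_lt(abs(res$pval - exact), 3 * se + 2 / r)
  # hypergeometric route on the same data
  hy <- categoricalEnrichment(GeneSet("t", test),
                              list(A = annotated), GeneSet("bg", bg))
  expect_equal(hy$pval, exact, tolerance = 1e-12)
  expect_equal(hy$x, 6L)
  expect_equal(hy$expected, 12 * 15 / 60)
  expect_equal(hy$log2_fold_enrichment, log2((6 / 12) / (15 / 60)))
})

test_that("permutation estimator is conservative under the null", {
  # drawing the test set uniformly from the background makes every p-value
  # super-uniform for the (s+1)/(r+1) estimator: P(p <= a) <= a
  bg <- sprintf("g%03d", 1:40)
  annotated <- bg[1:10]
  r <- 499L
  alpha <- 0.05
  rejections <- withr::with_seed(71, vapply(1:200, function(i) {
    ts <- sample(bg, 8)
    p <- categoricalEnrichment(GeneSet("t", ts), list(A = annotated),
                               GeneSet("bg", bg), method = "permutation",
                               perm = permConfig(repeats = r, seed = i))$pval
    p <= alpha
  }, TRUE))
  # binomial(200, 0.05) has sd ~ 3.1; allow 3 sd above the mean
  expect_lte(sum(rejections), 200 * alpha + 3 * sqrt(200 * alpha * 0.95))
})

test_that("adjustPvalues matches hand values and a step-up oracle", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(adjustPvalues(p, "bh"), c(0.03, 0.03, 0.03))
  expect_equal(adjustPvalues(p, "by"), c(0.03, 0.03, 0.03) * (1 + 1/2 + 1/3))
  expect_equal(adjustPvalues(p, "bonferroni"), c(0.03, 0.06, 0.09))
  expect_error(adjustPvalues(c(0.5, 1.2)), "0, 1")

  rp <- withr::with_seed(72, runif(200))
  for (m in c("bh", "by")) {
    expect_equal(adjustPvalues(rp, m), fdrOracle(rp, m), tolerance = 1e-12,
                 info = m)
  }
  # monotone: adjusted order preserves p order
  adj <- adjustPvalues(rp, "bh")
  expect_true(all(diff(adj[order(rp)]) >= -1e-12))
  expect_true(all(adj >= rp))
})

test_that("ELIM removes explained signal from ancestors", {
  dag <- toyChainDag()
  genes <- sprintf("g%02d", 1:50)
  # C carries all the signal; P and root only inherit it
  ann0 <- new("AnnotationSet",
              annotations = list(C = genes[1:10]), propagated = FALSE)
  ann <- propagateAnnotations(ann0, dag)
  expect_setequal(ann@annotations$root, genes[1:10])
  test <- genes[1:10]
  res_elim <- goEnrichmentElim(dag, ann, test, genes, elim_alpha = 0.01)
  res_classic <- goEnrichmentElim(dag, ann, test, genes, elim_alpha = 0)
  re <- stats::setNames(res_elim$pval, res_elim$term)
  rc <- stats::setNames(res_classic$pval, res_classic$term)
  # classic: all three terms significant (same annotation set)
  expect_lt(rc[["root"]], 1e-10)
  expect_equal(rc[["P"]], rc[["C"]])
  # elim: C keeps the signal, ancestors fall back to p = 1 (n = 0)
  expect_lt(re[["C"]], 1e-10)
  expect_equal(re[["P"]], 1)
  expect_equal(re[["root"]], 1)
  expect_true(all(re >= rc - 1e-12))
  expect_equal(res_elim$padj, adjustPvalues(res_elim$pval, "by"))
  expect_error(goEnrichmentElim(dag, ann0, test, genes), "propagated")
})

test_that("ELIM p-values never undercut classic ones on random ontologies", {
  for (seed in c(81, 82, 83, 84, 85)) {
    sim <- simulateOntology(n_terms = 12L, depth = 3L, n_genes = 60L,
                            seed = seed)
    ann <- propagateAnnotations(sim$ann, sim$dag)
    test <- withr::with_seed(seed + 1000L, sample(sim$genes, 12))
    elim <- goEnrichmentElim(sim$dag, ann, test, sim$genes,
                             elim_alpha = 0.05)
    classic <- goEnrichmentElim(sim$dag, ann, test, sim$genes,
                                elim_alpha = 0)
    shared <- intersect(elim$term, classic$term)
    pe <- stats::setNames(elim$pval, elim$term)[shared]
    pc <- stats::setNames(classic$pval, classic$term)[shared]
    expect_true(all(pe >= pc - 1e-12), info = seed)
  }
})

test_that("mHG reproduces the worked example and an enumeration oracle", {
  # ranked list of 6, positives at the first 2 ranks
  ranked <- paste0("g", 1:6)
  res <- mhgTest(ranked, c("g1", "g2"))
  expect_equal(res$stat, 1 / 15)
  expect_equal(res$pval, 1 / 15, tolerance = 1e-12)
  expect_equal(res$best_prefix, 2L)

  # enumeration oracle: every placement of n positives among M ranks
  mhgStat <- function(is_pos) {
    M <- length(is_pos); n <- sum(is_pos); h <- cumsum(is_pos)
    min(vapply(seq_len(M), function(l) hypergeomTest(h[l], l, n, M), 0))
  }
  for (cfg in list(c(M = 7, n = 2), c(M = 8, n = 3))) {
    M <- cfg[["M"]]; n <- cfg[["n"]]
    combos <- utils::combn(M, n)
    stats_all <- apply(combos, 2, function(idx) {
      v <- logical(M); v[idx] <- TRUE; mhgStat(v)
    })
    # test a few observed placements against exhaustive enumeration
    for (j in c(1, ncol(combos) %/% 2, ncol(combos))) {
      ranked <- paste0("x", seq_len(M))
      pos <- ranked[combos[, j]]
      res <- mhgTest(ranked, pos)
      oracle <- mean(stats_all <= res$stat * (1 + 1e-12))
      expect_equal(res$pval, oracle, tolerance = 1e-10,
                   info = paste(M, n, j))
    }
  }
  expect_warning(deg <- mhgTest(paste0("g", 1:5), paste0("g", 1:5)),
                 "degenerate")
  expect_equal(deg$pval, 1)
  expect_error(mhgTest(paste0("g", 1:5), "nope"), "must all appear")
})

test_that("XL-mHG constraints restrict the scored prefixes", {
  ranked <- paste0("g", 1:10)
  pos <- c("g1", "g5", "g6")
  free <- mhgTest(ranked, pos)
  lmax <- mhgTest(ranked, pos, l_max = 3L)
  xmin <- mhgTest(ranked, pos, x_min = 2L)
  # constraints can only weaken (raise) the statistic
  expect_gte(lmax$stat, free$stat)
  expect_gte(xmin$stat, free$stat)
  expect_lte(lmax$best_prefix, 3L)
  expect_gte(free$pval, free$stat - 1e-12)  # p >= stat always for mHG
})

test_that("continuous enrichment flags shifted test sets and not null ones", {
  genes <- sprintf("g%03d", 1:100)
  vals <- withr::with_seed(91, stats::setNames(rnorm(100), genes))
  shifted <- genes[1:15]
  vals[shifted] <- vals[shifted] + 2
  hit <- continuousEnrichment(GeneSet("t", shifted), vals, genes,
                              perm = permConfig(repeats = 1999L, seed = 2L))
  expect_lt(hit$pval, 0.01)
  expect_gt(hit$mean_test, hit$mean_background)
  par <- continuousEnrichment(GeneSet("t", shifted), vals, genes,
                              parametric = TRUE)
  expect_lt(par$pval, 1e-4)
  nullset <- genes[51:65]
  miss <- continuousEnrichment(GeneSet("t", nullset), vals, genes,
                               perm = permConfig(repeats = 999L, seed = 3L))
  expect_gt(miss$pval, 0.05)
  expect_warning(
    flat <- continuousEnrichment(GeneSet("t", genes[1:5]),
                                 stats::setNames(rep(1, 100), genes), genes),
    "constant")
  expect_equal(flat$pval, 1)
})

test_that("GAF reading honors NOT, taxon, and evidence filters", {
  gaf <- withr::local_tempfile(fileext = ".gaf")
  row <- function(gene, qual, term, ev, tax)
    paste(c("DB", gene, gene, qual, term, "REF", ev, "", "P", gene, "",
            "gene", tax, "20260101", "SRC", "", ""), collapse = "\t")
  writeLines(c("!gaf-version: 2.2",
               row("gA", "involved_in", "T:1", "IEA", "taxon:6239"),
               row("gB", "NOT|involved_in", "T:1", "IEA", "taxon:6239"),
               row("gC", "involved_in", "T:1", "IDA", "taxon:9606"),
               row("gD", "involved_in", "T:2", "IDA",
                   "taxon:6239|taxon:9606")), gaf)
  ann <- readGaf(gaf, taxon = 6239)
  expect_setequal(ann@annotations[["T:1"]], "gA")      # NOT and taxon dropped
  expect_setequal(ann@annotations[["T:2"]], "gD")      # multi-taxon matched
  keep_not <- readGaf(gaf, taxon = 6239, exclude_not = FALSE)
  expect_setequal(keep_not@annotations[["T:1"]], c("gA", "gB"))
  ida_only <- readGaf(gaf, evidence_codes = "IDA")
  expect_setequal(names(ida_only@annotations), c("T:1", "T:2"))
  expect_setequal(ida_only@annotations[["T:1"]], "gC")
  bad <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!x", "short\tline"), bad)
  expect_error(readGaf(bad), "malformed GAF line 2")
})

test_that("OBO reading, ancestors, and DOT export work on a toy ontology", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: T:1", "name: root", "",
               "[Term]", "id: T:2", "name: mid", "is_a: T:1 ! root", "",
               "[Term]", "id: T:3", "name: leaf", "is_a: T:2 ! mid",
               "relationship: part_of T:1", "",
               "[Term]", "id: T:4", "name: gone", "is_obsolete: true", "",
               "[Term]", "id: T:5", "name: dangling", "is_a: T:4 ! gone",
               ""), obo)
  dag <- readObo(obo)
  expect_setequal(dag@terms, c("T:1", "T:2", "T:3", "T:5"))
  expect_equal(dag@parents[["T:3"]], "T:2")          # part_of ignored
  expect_length(dag@parents[["T:5"]], 0)             # edge to obsolete dropped
  expect_setequal(ancestors(dag, "T:3"), c("T:2", "T:1"))
  withpo <- readObo(obo, include_part_of = TRUE)
  expect_setequal(withpo@parents[["T:3"]], c("T:2", "T:1"))

  dot <- withr::local_tempfile(fileext = ".dot")
  dagToDot(dag, dot)
  txt <- readLines(dot)
  expect_true(any(grepl("\"T:3\" -> \"T:2\"", txt)))
  expect_equal(txt[1], "digraph ontology {")
})

test_that("enrichment drops test features outside the background", {
  bg <- paste0("g", 1:20)
  expect_warning(
    res <- categoricalEnrichment(GeneSet("t", c(bg[1:5], "alien")),
                                 list(A = bg[1:10]), GeneSet("bg", bg)),
    "outside the background")
  expect_equal(res$N, 5L)
  expect_error(
    suppressWarnings(categoricalEnrichment(GeneSet("t", "alien"),
                                           list(A = bg[1:10]),
                                           GeneSet("bg", bg))),
    "no test features")
  expect_error(categoricalEnrichment(GeneSet("t", bg[1:3]),
                                     list(A = bg[1:5]), GeneSet("bg", character())),
               "background is empty")
})

test_that("attribute sources normalize consistently", {
  at <- AttributeTable(paste0("g", 1:4),
                       data.frame(isX = c(TRUE, FALSE, TRUE, NA),
                                  score = c(1, 2, 3, 4)))
  sets <- rnakit:::attributeSets(at)
  expect_equal(names(sets), "isX")                 # numeric column skipped
  expect_setequal(sets$isX, c("g1", "g3"))
  expect_equal(rnakit:::attributeSets(GeneSet("S", c("a", "b"))),
               list(S = c("a", "b")))
  expect_error(rnakit:::attributeSets(42), "unsupported")
})
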