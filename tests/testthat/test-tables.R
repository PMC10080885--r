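# Tabular data model: readers, filters, set operations, history.

test_that("readTable loads and validates count matrices", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,s1,s2", "g1,1,2", "g2,0,10", "g3,5,0"), path)
  cm <- readTable(path, "counts")
  expect_s4_class(cm, "CountMatrix")
  expect_equal(nFeatures(cm), 3L)
  expect_equal(sampleIDs(cm), c("s1", "s2"))
  expect_equal(historyLog(cm)$op, "loaded")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,s1", "g1,1", "g1,2"), dup)
  expect_error(readTable(dup, "counts"), "g1")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,s1", "g1,-3"), neg)
  expect_error(readTable(neg, "counts"), "negative")

  expect_error(readTable(path, "frobnicate"), "unknown kind")
})

test_that("GMT parsing matches a hand-written line parser", {
  path <- withr::local_tempfile(fileext = ".gmt")
  lines <- c("setA\tdesc\tg1\tg2",
             "setB\tanother desc\tg2\tg3\tg4")
  writeLines(lines, path)
  sets <- readGmt(path)
  # oracle: split on tabs by hand
  oracle <- lapply(lines, function(l) strsplit(l, "\t")[[1]])
  expect_equal(sets[["setA"]]@members, oracle[[1]][-(1:2)])
  expect_equal(sets[["setB"]]@members, oracle[[2]][-(1:2)])
  expect_equal(names(sets), c("setA", "setB"))

  rt <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(sets, rt)
  expect_equal(readGmt(rt)[["setB"]]@members, sets[["setB"]]@members)
})

test_that("filterLowExpression keeps rows passing the row-statistic cutoff", {
  m <- CountMatrix(matrix(c(0, 0, 4, 6, 50, 50), 3, 2, byrow = TRUE,
                          dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  expect_equal(featureIDs(filterLowExpression(m, 10, "sum")), c("b", "c"))
  expect_equal(featureIDs(filterLowExpression(m, 0, "sum")), c("a", "b", "c"))
  expect_error(filterLowExpression(m, -1), ">= 0")

  # brute-force row scan oracle on a random NB matrix, all modes
  cm <- withr::with_seed(7, CountMatrix(matrix(
    rnbinom(200, mu = 8, size = 2), 50, 4,
    dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))))
  for (mode in c("sum", "min_per_sample", "mean")) {
    stat <- apply(counts(cm), 1, switch(mode, sum = sum,
                                        min_per_sample = min, mean = mean))
    expect_equal(featureIDs(filterLowExpression(cm, 7, mode)),
                 rownames(counts(cm))[stat >= 7], info = mode)
  }
})

test_that("dropMissing removes exactly the rows flagged by a brute scan", {
  v <- withr::with_seed(3, {
    v <- matrix(runif(60), 15, 4,
                dimnames = list(sprintf("g%02d", 1:15), paste0("s", 1:4)))
    v[sample(length(v), 8)] <- NA
    v
  })
  m <- CountMatrix(v)
  kept <- featureIDs(dropMissing(m))
  oracle <- rownames(v)[apply(v, 1, function(r) !any(is.na(r)))]
  expect_equal(kept, oracle)
  complete <- CountMatrix(matrix(1:6, 3, 2,
    dimnames = list(letters[1:3], c("s1", "s2"))))
  expect_equal(counts(dropMissing(complete)), counts(complete))
})

test_that("significance and fold-change filters follow their predicates", {
  t <- DiffExpTable(paste0("g", 1:4), log2fc = c(-2, -0.5, 0.5, 2),
                    padj = c(0.01, 0.05, 0.2, NA))
  expect_equal(featureIDs(filterSignificant(t, 0.05)), c("g1", "g2"))
  expect_equal(featureIDs(filterSignificant(t, 1)), c("g1", "g2", "g3"))
  expect_error(filterSignificant(t, 0), "alpha")
  expect_error(filterSignificant(t, 1.5), "alpha")

  expect_equal(featureIDs(filterFoldChange(t, 1, "both")), c("g1", "g4"))
  expect_equal(featureIDs(filterFoldChange(t, 0, "both")), featureIDs(t))
  expect_error(filterFoldChange(t, -1), "magnitude")

  # random table, each direction, against a brute predicate scan
  rt <- withr::with_seed(5, DiffExpTable(
    sprintf("g%03d", 1:100), log2fc = rnorm(100, 0, 2),
    padj = runif(100)))
  for (dir in c("up", "down", "both")) {
    pred <- switch(dir, up = rt@log2fc >= 1, down = rt@log2fc <= -1,
                   both = abs(rt@log2fc) >= 1)
    expect_equal(featureIDs(filterFoldChange(rt, 1, dir)),
                 featureIDs(rt)[pred], info = dir)
  }
  oracle_sig <- sum(!is.na(rt@padj) & rt@padj <= 0.1)
  expect_equal(nFeatures(filterSignificant(rt, 0.1)), oracle_sig)
})

test_that("splitByDirection partitions into disjoint up/down tables", {
  sp <- splitByDirection(toyDiffExp(), alpha = 0.05, magnitude = 1)
  expect_equal(featureIDs(sp$up), c("g1", "g2"))
  expect_equal(featureIDs(sp$down), "g3")
  expect_length(intersect(featureIDs(sp$up), featureIDs(sp$down)), 0)

  rt <- withr::with_seed(9, DiffExpTable(
    sprintf("g%03d", 1:50), log2fc = rnorm(50), padj = runif(50)))
  sp2 <- splitByDirection(rt, alpha = 1, magnitude = 0)
  expect_length(intersect(featureIDs(sp2$up), featureIDs(sp2$down)), 0)
  expect_setequal(c(featureIDs(sp2$up), featureIDs(sp2$down)),
                  featureIDs(rt)[!is.na(rt@padj)])
})

test_that("filterBiotype keeps mapped features of requested types", {
  map <- BiotypeMap(c(g1 = "protein_coding", g2 = "piRNA"))
  m <- CountMatrix(matrix(1:6, 3, 2,
    dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
  out <- filterBiotype(m, map, "protein_coding")
  expect_equal(featureIDs(out), "g1")
  all_types <- filterBiotype(m, map, c("protein_coding", "piRNA"))
  expect_equal(featureIDs(all_types), c("g1", "g2"))  # only unmapped dropped
  expect_error(filterBiotype(m, map, character()), "non-empty")

  # GTF-derived map equals an independent line-parse oracle
  mapping <- c(g1 = "protein_coding", g2 = "piRNA", g3 = "lincRNA")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeBiotypeGtf(mapping, gtf)
  parsed <- readTable(gtf, "biotype")
  oracle <- vapply(grep("gene_id", readLines(gtf), value = TRUE), function(l)
    sub('.*gene_biotype "([^"]+)".*', "\\1", l), "")
  names(oracle) <- vapply(grep("gene_id", readLines(gtf), value = TRUE),
                          function(l) sub('.*gene_id "([^"]+)".*', "\\1", l), "")
  expect_equal(parsed@mapping[names(oracle)], oracle)
})

test_that("set operations follow set semantics and majority voting", {
  s1 <- GeneSet("A", c("1", "2", "3"))
  s2 <- GeneSet("B", c("2", "3", "4"))
  s3 <- GeneSet("C", c("3", "4", "5"))
  expect_setequal(setOperation(list(s1, s2, s3), "majority",
                               majority_fraction = 2 / 3)@members,
                  c("2", "3", "4"))
  expect_setequal(setOperation(list(s1, s2, s3), "majority",
                               majority_fraction = 1)@members,
                  setOperation(list(s1, s2, s3), "intersection")@members)
  expect_setequal(setOperation(list(s1, s2, s3), "majority",
                               majority_fraction = 1e-9)@members,
                  setOperation(list(s1, s2, s3), "union")@members)
  expect_setequal(setOperation(list(s1, GeneSet("D", "2")), "difference")@members,
                  c("1", "3"))
  expect_error(setOperation(list(s1), "union"), "at least 2")
  expect_error(setOperation(list(s1, s2), "majority", majority_fraction = 0),
               "majority_fraction")

  # majority is monotone non-increasing in the fraction
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8, 1),
                  function(f) length(setOperation(list(s1, s2, s3), "majority",
                                                  majority_fraction = f)@members),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("intersectionCounts partitions the union", {
  out <- intersectionCounts(list(GeneSet("A", c("1", "2")),
                                 GeneSet("B", c("2", "3"))))
  sizes <- stats::setNames(out$size, out$pattern)
  expect_equal(sizes[["10"]], 1L)
  expect_equal(sizes[["01"]], 1L)
  expect_equal(sizes[["11"]], 1L)

  same <- intersectionCounts(list(GeneSet("A", letters[1:4]),
                                  GeneSet("B", letters[1:4]),
                                  GeneSet("C", letters[1:4])))
  expect_equal(same$pattern, "111")
  expect_equal(same$size, 4L)

  # element-wise oracle on random sets
  rs <- withr::with_seed(11, lapply(1:3, function(i)
    GeneSet(paste0("S", i), sample(letters, sample(5:15, 1)))))
  res <- intersectionCounts(rs)
  uni <- unique(unlist(lapply(rs, featureIDs)))
  expect_equal(sum(res$size), length(uni))
  oracle <- table(vapply(uni, function(el)
    paste(as.integer(vapply(rs, function(s) el %in% s@members, TRUE)),
          collapse = ""), ""))
  expect_equal(stats::setNames(res$size, res$pattern)[names(oracle)],
               stats::setNames(as.integer(oracle), names(oracle)))
})

test_that("filters are idempotent, preserve order, and log history", {
  t <- toyDiffExp()
  once <- filterSignificant(t, 0.05)
  twice <- filterSignificant(once, 0.05)
  expect_equal(featureIDs(twice), featureIDs(once))
  expect_equal(once@log2fc, twice@log2fc)

  # row order of survivors preserved
  m <- toyCounts()
  f <- filterLowExpression(m, 150, "sum")
  expect_equal(featureIDs(f),
               featureIDs(m)[featureIDs(m) %in% featureIDs(f)])
  expect_equal(sampleIDs(f), sampleIDs(m))

  # one history record per op; counts consistent
  h <- historyLog(f)
  expect_equal(nrow(h), 2L)
  expect_equal(h$n_before[2], nFeatures(m))
  expect_equal(h$n_after[2], nFeatures(f))
  h2 <- historyLog(filterLowExpression(f, 150, "sum"))
  expect_equal(nrow(h2), 3L)
})
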