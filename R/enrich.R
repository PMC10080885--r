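# Enrichment engine: categorical (hypergeometric / permutation),
# ontology-aware (ELIM), ranked-list (minimum-hypergeometric) and
# continuous-attribute tests, with FDR control.

#' Configure a permutation test
#'
#' @param repeats number of random draws (>= 100).
#' @param seed integer seed.
#' @param alternative `greater`, `less` or `two_sided`.
#' @return validated configuration list.
#' @export
permConfig <- function(repeats = 10000L, seed = 0L,
                       alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  repeats <- as.integer(repeats)
  if (repeats < 100L) stop("repeats must be >= 100")
  list(repeats = repeats, seed = as.integer(seed), alternative = alternative)
}

#' Upper-tail hypergeometric test
#'
#' P(X >= x) for X hypergeometric with population `M`, `n` annotated
#' successes, and `N` draws.
#'
#' @param x observed overlap.
#' @param N draws (test-set size).
#' @param n annotated features in the population.
#' @param M population (background) size.
#' @return upper-tail p-value.
#' @export
hypergeomTest <- function(x, N, n, M) {
  if (any(c(x, N, n, M) < 0) || x > N || N > M || n > M || x > n)
    stop("impossible hypergeometric parameters (need 0 <= x <= min(N, n), ",
         "N <= M, n <= M)")
  stats::phyper(x - 1, n, M - n, N, lower.tail = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up (`bh`), Benjamini-Yekutieli for general or
#' negatively correlated tests (`by`), or Bonferroni.  Outputs are clipped to
#' \[0, 1\] and returned in the input order.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @param method `bh`, `by` or `bonferroni`.
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(pvals, method = c("bh", "by", "bonferroni")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = c(bh = "BH", by = "BY",
                                    bonferroni = "bonferroni")[method])
}

# Normalize an attribute source into a named list of member-ID vectors.
attributeSets <- function(attrs) {
  if (is(attrs, "AnnotationSet")) return(attrs@annotations)
  if (is(attrs, "AttributeTable")) {
    bool <- vapply(attrs@attributes, is.logical, TRUE)
    sets <- lapply(attrs@attributes[bool], function(col)
      attrs@feature_ids[!is.na(col) & col])
    return(sets)
  }
  if (is(attrs, "GeneSet"))
    return(stats::setNames(list(attrs@members), attrs@name))
  if (is.list(attrs)) {
    return(lapply(attrs, function(s)
      if (is(s, "GeneSet")) s@members else as.character(s)))
  }
  stop("unsupported attribute source of class ", class(attrs)[1])
}

enrichRow <- function(id, x, N, n, M, pval) {
  expected <- N * n / M
  l2fe <- if (N == 0 || n == 0) NA_real_
          else log2((x / N) / (n / M))
  data.frame(term = id, N = N, n = n, x = x, expected = expected,
             log2_fold_enrichment = l2fe, pval = pval)
}

#' Categorical enrichment of a gene set
#'
#' For every boolean attribute (or annotation term), tests whether the test
#' set contains more annotated features than expected from the background.
#' Test features outside the background are dropped with a warning.  The
#' permutation test draws `repeats` uniform subsets of the background of the
#' test-set size and estimates `p = (successes + 1) / (repeats + 1)`, where a
#' success is a draw with an annotated proportion greater than or equal to
#' the observed one (ties count as successes: a positively-biased,
#' conservative estimator).
#'
#' @param test a [GeneSet-class] (or character vector).
#' @param attrs an [AttributeTable-class], [AnnotationSet-class],
#'   [GeneSet-class], or named list of ID vectors.
#' @param background a [GeneSet-class] (or character vector): the universe.
#' @param method `hypergeom` or `permutation`.
#' @param perm a [permConfig()] (used when `method = "permutation"`).
#' @param adjust p-value adjustment method (see [adjustPvalues()]).
#' @return data.frame of enrichment rows with `padj` over the attribute
#'   family.
#' @export
categoricalEnrichment <- function(test, attrs, background,
                                  method = c("hypergeom", "permutation"),
                                  perm = permConfig(), adjust = "bh") {
  method <- match.arg(method)
  bg <- unique(memberVector(background))
  ts <- unique(memberVector(test))
  M <- length(bg)
  if (M == 0L) stop("background is empty")
  outside <- setdiff(ts, bg)
  if (length(outside)) {
    warning(length(outside), " test feature(s) outside the background ",
            "were dropped")
    ts <- intersect(ts, bg)
  }
  N <- length(ts)
  if (N == 0L) stop("no test features remain within the background")
  sets <- attributeSets(attrs)
  if (length(sets) == 0L) stop("no boolean attributes to test")
  anns <- lapply(sets, function(s) intersect(s, bg))
  xs <- vapply(anns, function(a) length(intersect(a, ts)), 0L)
  ns <- vapply(anns, length, 0L)
  if (method == "hypergeom") {
    pv <- vapply(seq_along(anns), function(i)
      hypergeomTest(xs[i], N, ns[i], M), 0)
  } else {
    pv <- withSeed(perm$seed, {
      draws <- matrix("", perm$repeats, N)
      for (r in seq_len(perm$repeats))
        draws[r, ] <- sample(bg, N, replace = FALSE)
      vapply(seq_along(anns), function(i) {
        memb <- matrix(draws %in% anns[[i]], nrow = perm$repeats)
        cnt <- rowSums(memb)
        s <- switch(perm$alternative,
          greater = sum(cnt >= xs[i]),
          less = sum(cnt <= xs[i]),
          two_sided = {
            e <- N * ns[i] / M
            sum(abs(cnt - e) >= abs(xs[i] - e))
          })
        (s + 1) / (perm$repeats + 1)
      }, 0)
    })
  }
  rows <- do.call(rbind, lapply(seq_along(anns), function(i)
    enrichRow(names(sets)[i], xs[i], N, ns[i], M, pv[i])))
  rows$padj <- adjustPvalues(rows$pval, adjust)
  rownames(rows) <- NULL
  rows
}

#' Ontology enrichment with ELIM decorrelation
#'
#' Terms are visited children-before-parents (reverse topological order) and
#' tested with the hypergeometric test on their current annotation set
#' (intersected with the background).  When a term's p-value passes
#' `elim_alpha`, its currently annotated background genes are eliminated from
#' every ancestor's annotation set before those ancestors are tested, so
#' ancestors are only called on signal of their own.  `elim_alpha = 0`
#' reproduces the classic propagated test.  Adjusted p-values use the
#' Benjamini-Yekutieli procedure (terms in a DAG are not independent).
#'
#' @param dag an [OntologyDAG-class].
#' @param ann a propagated [AnnotationSet-class].
#' @param test a [GeneSet-class] (or character vector), subset of background.
#' @param background a [GeneSet-class] (or character vector).
#' @param elim_alpha elimination cutoff (default 0.01).
#' @param adjust adjustment method (default `by`).
#' @return data.frame of enrichment rows (one per testable term), with
#'   attribute `skipped` listing terms with zero background annotations.
#' @export
goEnrichmentElim <- function(dag, ann, test, background, elim_alpha = 0.01,
                             adjust = "by") {
  if (!isTRUE(ann@propagated))
    stop("annotations must be propagated first (propagateAnnotations)")
  bg <- unique(memberVector(background))
  ts <- intersect(unique(memberVector(test)), bg)
  M <- length(bg); N <- length(ts)
  if (M == 0L || N == 0L) stop("empty background or test set")
  order <- topoOrderOrNull(dag)
  if (is.null(order)) stop("term graph contains a cycle")
  current <- lapply(ann@annotations, function(a) intersect(a, bg))
  # terms with no background annotations at all are skipped; terms whose
  # annotations were fully eliminated are still tested (n = 0 gives p = 1)
  testable <- names(current)[lengths(current) > 0L]
  rows <- list(); skipped <- setdiff(names(current), testable)
  for (term in order) {
    if (!term %in% testable) next
    genes <- current[[term]]
    n <- length(genes)
    x <- length(intersect(genes, ts))
    p <- hypergeomTest(x, N, n, M)
    rows[[term]] <- enrichRow(term, x, N, n, M, p)
    if (p <= elim_alpha) {
      for (anc in ancestors(dag, term)) {
        if (!is.null(current[[anc]]))
          current[[anc]] <- setdiff(current[[anc]], genes)
      }
    }
  }
  if (!length(rows)) {
    out <- enrichRow(character(0), integer(0), integer(0), integer(0),
                     integer(0), numeric(0))
    out$padj <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$name <- dag@names[match(out$term, dag@terms)]
  out$padj <- adjustPvalues(out$pval, adjust)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Minimum-hypergeometric (mHG) ranked-list enrichment
#'
#' Background-free test on a ranked feature list: the statistic is the best
#' (smallest) hypergeometric upper-tail probability over all list prefixes;
#' the exact p-value is the probability, under uniform random placement of
#' the positives, that the statistic is at most the observed one, computed by
#' dynamic programming over the (rank, hits) lattice.
#'
#' @param ranked ordered character vector of features (best first).
#' @param positives a [GeneSet-class] or character vector, subset of
#'   `ranked`.
#' @param x_min only prefixes with at least this many hits are scored
#'   (XL-mHG lower bound; 0 imposes no constraint).
#' @param l_max only prefixes up to this length are scored (`NULL` imposes no
#'   constraint).
#' @return list with `stat`, `pval`, and `best_prefix` (the prefix length
#'   achieving the statistic).
#' @export
mhgTest <- function(ranked, positives, x_min = 0L, l_max = NULL) {
  pos <- unique(memberVector(positives))
  M <- length(ranked)
  if (M < 2L) stop("ranked list must have >= 2 entries")
  if (!all(pos %in% ranked)) stop("positives must all appear in the ranked list")
  n <- length(pos)
  if (n == 0L || n == M) {
    warning("degenerate positive set; p-value is 1")
    return(list(stat = 1, pval = 1, best_prefix = NA_integer_))
  }
  if (is.null(l_max)) l_max <- M
  is_pos <- ranked %in% pos
  hits <- cumsum(is_pos)
  scored <- which(seq_len(M) <= l_max & hits >= x_min)
  hgt <- vapply(scored, function(l) hypergeomTest(hits[l], l, n, M), 0)
  stat <- min(hgt)
  best_prefix <- scored[which.min(hgt)]
  # DP over the (rank, hits) lattice: count placements never entering a cell
  # whose hypergeometric tail is <= the observed statistic
  eps <- 1e-12
  bad <- function(l, b) {
    if (l > l_max || b < x_min) return(FALSE)
    hypergeomTest(b, l, n, M) <= stat * (1 + eps)
  }
  w <- numeric(n + 1L); w[1L] <- 1  # w[b + 1] = scaled path count with b hits
  logscale <- 0
  for (l in seq_len(M)) {
    bmax <- min(l, n)
    bmin <- max(0L, l - (M - n))
    new_w <- numeric(n + 1L)
    for (b in bmin:bmax) {
      if (bad(l, b)) next
      acc <- 0
      if (b <= l - 1L) acc <- acc + w[b + 1L]           # rank l is negative
      if (b >= 1L) acc <- acc + w[b]                    # rank l is positive
      new_w[b + 1L] <- acc
    }
    mx <- max(new_w)
    if (mx > 1e250) {
      new_w <- new_w / 1e250
      logscale <- logscale + log(1e250)
    }
    w <- new_w
  }
  log_good <- if (w[n + 1L] > 0) log(w[n + 1L]) + logscale else -Inf
  pval <- 1 - exp(log_good - lchoose(M, n))
  pval <- min(max(pval, 0), 1)
  list(stat = stat, pval = pval, best_prefix = best_prefix)
}

#' Enrichment of a numeric attribute in a gene set
#'
#' Tests whether the mean attribute value of the test set differs from the
#' background mean.  Non-parametric: permutation of same-size subsets of the
#' background with `p = (successes + 1) / (repeats + 1)` (ties count as
#' successes); parametric: one-sample t-test of the test values against the
#' background mean.
#'
#' @param test a [GeneSet-class] or character vector.
#' @param attr named numeric vector (values per feature).
#' @param background a [GeneSet-class] or character vector.
#' @param perm a [permConfig()]; its `alternative` applies to both modes.
#' @param parametric use the t-test instead of permutation.
#' @return one-row data.frame with the observed mean, background mean, and
#'   p-value.
#' @export
continuousEnrichment <- function(test, attr, background, perm = permConfig(),
                                 parametric = FALSE) {
  bg <- unique(memberVector(background))
  ts <- intersect(unique(memberVector(test)), bg)
  vals <- attr[bg]
  if (anyNA(vals)) {
    bg <- bg[!is.na(vals)]
    ts <- intersect(ts, bg)
    vals <- attr[bg]
  }
  if (length(ts) == 0L) stop("no test features within the background")
  mu_bg <- mean(vals)
  obs <- mean(attr[ts])
  if (length(unique(vals)) < 2L) {
    warning("constant attribute; p-value is 1")
    p <- 1
  } else if (parametric) {
    alt <- switch(perm$alternative, greater = "greater", less = "less",
                  two_sided = "two.sided")
    p <- stats::t.test(attr[ts], mu = mu_bg, alternative = alt)$p.value
  } else {
    p <- withSeed(perm$seed, {
      means <- vapply(seq_len(perm$repeats), function(r)
        mean(sample(vals, length(ts), replace = FALSE)), 0)
      s <- switch(perm$alternative,
        greater = sum(means >= obs),
        less = sum(means <= obs),
        two_sided = sum(abs(means - mu_bg) >= abs(obs - mu_bg)))
      (s + 1) / (perm$repeats + 1)
    })
  }
  data.frame(attribute = "continuous", N = length(ts), mean_test = obs,
             mean_background = mu_bg, pval = p)
}

#' Write an enrichment bar plot
#'
#' Horizontal bars of log2 fold enrichment per term, significant terms
#' highlighted.
#'
#' @param rows data.frame from [categoricalEnrichment()] or
#'   [goEnrichmentElim()].
#' @param path output image path.
#' @param alpha significance cutoff on `padj`.
#' @return the path, invisibly.
#' @export
plotEnrichmentBars <- function(rows, path, alpha = 0.05) {
  openDevice(path)
  on.exit(grDevices::dev.off())
  fe <- rows$log2_fold_enrichment
  fe[!is.finite(fe)] <- 0
  col <- ifelse(!is.na(rows$padj) & rows$padj <= alpha, "firebrick", "grey60")
  graphics::par(mar = c(4, 10, 2, 1))
  graphics::barplot(fe, names.arg = rows$term, horiz = TRUE, las = 1,
                    col = col, xlab = "log2 fold enrichment",
                    main = "Enrichment")
  invisible(path)
}
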