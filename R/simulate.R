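# Synthetic-data generators: negative-binomial count matrices with planted
# cluster structure, differential-expression tables with known up/down/null
# membership, and toy ontologies with annotations, all written in the
# standard formats the rest of the package reads.

#' Simulate a count matrix with planted cluster structure
#'
#' Feature i in cluster c draws sample j from a negative binomial with mean
#' `libsize_j * profile_c(j) * scalar_i`, where the gene-specific scalar is
#' log-normal and the dispersion is the spec's.  Deterministic under the
#' spec's seed.
#'
#' @param spec a [simSpec()].
#' @return list with `counts` (a [CountMatrix-class]) and `labels` (named
#'   integer ground-truth cluster per feature).
#' @export
simulateCounts <- function(spec) {
  validObject(spec)
  nf <- spec@n_features; ns <- spec@n_samples; K <- spec@n_clusters
  withSeed(spec@seed, {
    libs <- stats::runif(ns, spec@libsize_range[1], spec@libsize_range[2])
    labels <- rep(seq_len(K), length.out = nf)
    scalar <- exp(stats::rnorm(nf, mean = log(100), sd = 0.4))
    mu <- spec@profiles[labels, , drop = FALSE] *
      matrix(libs, nf, ns, byrow = TRUE) * scalar
    counts <- matrix(stats::rnbinom(nf * ns, mu = mu,
                                    size = 1 / spec@dispersion), nf, ns)
    ids <- sprintf("gene%04d", seq_len(nf))
    dimnames(counts) <- list(ids, sprintf("s%d", seq_len(ns)))
    names(labels) <- ids
    list(counts = CountMatrix(counts, name = "simulated"), labels = labels)
  })
}

#' Simulate a differential-expression table with planted truth
#'
#' Null features get `p ~ Uniform(0, 1)` and `log2fc ~ Normal(0, 0.1)`; true
#' features get the designed effect (half up, half down) and a very small
#' p-value.  Adjusted p-values use Benjamini-Hochberg.
#'
#' @param spec a [simSpec()].
#' @return list with `table` (a [DiffExpTable-class]) and `truth` (character
#'   vector per feature: `up`, `down` or `null`).
#' @export
simulateDiffExp <- function(spec) {
  validObject(spec)
  nf <- spec@n_features
  withSeed(spec@seed, {
    ids <- sprintf("gene%04d", seq_len(nf))
    n_true <- round(spec@de_fraction * nf)
    truth <- rep("null", nf)
    if (n_true > 0) {
      idx <- sample.int(nf, n_true)
      half <- ceiling(n_true / 2)
      truth[idx[seq_len(half)]] <- "up"
      if (n_true > half) truth[idx[(half + 1):n_true]] <- "down"
    }
    lfc <- stats::rnorm(nf, 0, 0.1)
    lfc[truth == "up"] <- spec@effect_size + stats::rnorm(sum(truth == "up"), 0, 0.1)
    lfc[truth == "down"] <- -spec@effect_size + stats::rnorm(sum(truth == "down"), 0, 0.1)
    p <- stats::runif(nf)
    p[truth != "null"] <- stats::runif(sum(truth != "null"), 0, 1e-8)
    padj <- adjustPvalues(p, "bh")
    names(truth) <- ids
    list(table = DiffExpTable(ids, lfc, pval = p, padj = padj,
                              name = "simulated_de"),
         truth = truth)
  })
}

#' Simulate a toy ontology with annotations
#'
#' Builds a random tree-plus-shortcuts DAG of the requested depth (terms are
#' only linked to strictly shallower levels, so the graph is acyclic by
#' construction), annotates leaf terms with random gene subsets, and writes
#' the ontology and annotations as OBO and GAF files that round-trip through
#' [readObo()]/[readGaf()].
#'
#' @param n_terms number of terms.
#' @param depth tree depth (>= 2).
#' @param n_genes size of the gene universe.
#' @param seed integer seed.
#' @param dir output directory for the OBO/GAF files (default `tempdir()`).
#' @param taxon taxon ID written to (and expected from) the GAF.
#' @return list with `dag`, `ann` (unpropagated), `genes`, `obo`, `gaf`.
#' @export
simulateOntology <- function(n_terms = 20L, depth = 3L, n_genes = 100L,
                             seed = 0L, dir = tempdir(), taxon = 6239) {
  if (depth < 2L) stop("depth must be >= 2")
  withSeed(seed, {
    terms <- sprintf("T:%04d", seq_len(n_terms))
    # level 1 = root; spread remaining terms over levels 2..depth
    level <- c(1L, sort(sample(2:depth, n_terms - 1L, replace = TRUE)))
    parents <- rep(list(character(0)), n_terms)
    names(parents) <- terms
    for (i in seq_len(n_terms)[-1L]) {
      shallower <- which(level < level[i])
      parents[[i]] <- terms[sample(shallower, 1L)]
      # occasional shortcut to another strictly shallower term
      if (length(shallower) > 1L && stats::runif(1) < 0.3) {
        extra <- terms[sample(shallower, 1L)]
        parents[[i]] <- unique(c(parents[[i]], extra))
      }
    }
    dag <- new("OntologyDAG", terms = terms,
               names = stats::setNames(paste("term", seq_len(n_terms)), terms),
               namespaces = stats::setNames(rep("biological_process", n_terms),
                                            terms),
               parents = parents)
    genes <- sprintf("gene%04d", seq_len(n_genes))
    is_parent <- terms %in% unlist(parents, use.names = FALSE)
    ann <- list()
    for (t in terms[!is_parent]) {
      sz <- sample(3:max(3L, n_genes %/% 10L), 1L)
      ann[[t]] <- sample(genes, min(sz, n_genes))
    }
    aset <- new("AnnotationSet", annotations = ann, propagated = FALSE)
    obo <- file.path(dir, sprintf("sim_%d.obo", seed))
    gaf <- file.path(dir, sprintf("sim_%d.gaf", seed))
    writeObo(dag, obo)
    writeGaf(aset, gaf, taxon = taxon)
    list(dag = dag, ann = aset, genes = genes, obo = obo, gaf = gaf)
  })
}

#' Write an ontology as OBO 1.2
#' @param dag an [OntologyDAG-class].
#' @param path output path.
#' @export
writeObo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in dag@terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", dag@names[[t]]))
    if (!is.na(dag@namespaces[[t]]))
      out <- c(out, paste0("namespace: ", dag@namespaces[[t]]))
    for (p in dag@parents[[t]])
      out <- c(out, paste0("is_a: ", p, " ! ", dag@names[[p]]))
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Write annotations as GAF 2.2
#' @param ann an [AnnotationSet-class].
#' @param path output path.
#' @param taxon taxon ID for column 13.
#' @export
writeGaf <- function(ann, path, taxon = 6239) {
  out <- "!gaf-version: 2.2"
  for (t in names(ann@annotations)) {
    for (g in ann@annotations[[t]]) {
      out <- c(out, paste(c("SIM", g, g, "involved_in", t, "SIM:0001",
                            "IEA", "", "P", g, "", "gene",
                            paste0("taxon:", taxon), "20260101", "SIM",
                            "", ""), collapse = "\t"))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Write a minimal GTF carrying gene biotypes
#'
#' One `gene` line per feature with `gene_id` and `gene_biotype` attributes;
#' readable by `readTable(kind = "biotype")`.
#'
#' @param map a [BiotypeMap-class] or named character vector.
#' @param path output path.
#' @export
writeBiotypeGtf <- function(map, path) {
  mapping <- if (is(map, "BiotypeMap")) map@mapping else map
  lines <- c("#!genome-build simulated",
             vapply(seq_along(mapping), function(i) {
               paste(c("I", "sim", "gene", as.character(i * 1000),
                       as.character(i * 1000 + 500), ".", "+", ".",
                       sprintf('gene_id "%s"; gene_biotype "%s";',
                               names(mapping)[i], mapping[[i]])),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
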