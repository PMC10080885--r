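# OBO 1.2 ontology graphs and GAF 2.x annotation files.

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas (`id`, `name`, `namespace`, `is_a`, and optionally
#' `relationship: part_of`); obsolete terms are dropped, as are edges whose
#' endpoint is unknown after dropping them.
#'
#' @param path OBO file path.
#' @param include_part_of also load `part_of` relationships as edges.
#' @return An [OntologyDAG-class].
#' @export
readObo <- function(path, include_part_of = FALSE) {
  lines <- readLines(path)
  terms <- character(); nm <- character(); ns <- character()
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && nzchar(cur$id)) {
      terms[[length(terms) + 1L]] <<- cur$id
      nm[[length(nm) + 1L]] <<- cur$name
      ns[[length(ns) + 1L]] <<- cur$namespace
      parents[[cur$id]] <<- cur$parents
    }
  }
  in_term <- FALSE
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (l == "[Term]") {
      flush()
      cur <- list(id = "", name = "", namespace = NA_character_,
                  parents = character(), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", l)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term && nzchar(l)) {
      if (startsWith(l, "id:")) {
        cur$id <- trimws(sub("^id:", "", l))
      } else if (startsWith(l, "name:")) {
        cur$name <- trimws(sub("^name:", "", l))
      } else if (startsWith(l, "namespace:")) {
        cur$namespace <- trimws(sub("^namespace:", "", l))
      } else if (startsWith(l, "is_a:")) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", l)))
        if (!nzchar(tgt)) stop("malformed is_a at line ", i)
        cur$parents <- c(cur$parents, tgt)
      } else if (include_part_of && startsWith(l, "relationship:")) {
        f <- strsplit(trimws(sub("^relationship:", "", l)), "[ \t]+")[[1L]]
        if (length(f) >= 2L && f[1L] == "part_of")
          cur$parents <- c(cur$parents, sub("!.*$", "", f[2L]))
      } else if (startsWith(l, "is_obsolete:")) {
        cur$obsolete <- grepl("true", l)
      }
    }
  }
  flush()
  parents <- lapply(parents, function(p) intersect(unique(p), terms))
  parents <- parents[terms]
  names(ns) <- names(nm) <- names(parents) <- terms
  new("OntologyDAG", terms = terms, names = nm, namespaces = ns,
      parents = parents)
}

#' Read a GAF 2.x annotation file
#'
#' Tab-separated, 17 columns, `!` comment lines.  Rows whose qualifier
#' contains `NOT` are excluded by default; a taxon filter keeps only rows
#' matching `taxon:<id>`; an optional evidence-code filter keeps only the
#' listed codes.
#'
#' @param path GAF file path.
#' @param taxon optional numeric/character taxon ID to keep (e.g. `6239`).
#' @param exclude_not drop negated annotations (default `TRUE`).
#' @param evidence_codes optional character vector of evidence codes to keep.
#' @return An [AnnotationSet-class] (not yet propagated).
#' @export
readGaf <- function(path, taxon = NULL, exclude_not = TRUE,
                    evidence_codes = NULL) {
  lines <- readLines(path)
  ann <- list()
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (startsWith(l, "!") || !nzchar(trimws(l))) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 13L)
      stop("malformed GAF line ", i, ": expected >= 13 columns, got ",
           length(f))
    gene <- f[2L]; qualifier <- f[4L]; term <- f[5L]
    evidence <- f[7L]; taxon_field <- f[13L]
    if (exclude_not && grepl("(^|\\|)NOT($|\\|)", qualifier)) next
    if (!is.null(taxon) &&
        !any(paste0("taxon:", taxon) == strsplit(taxon_field, "\\|")[[1L]]))
      next
    if (!is.null(evidence_codes) && !evidence %in% evidence_codes) next
    ann[[term]] <- c(ann[[term]], gene)
  }
  ann <- lapply(ann, unique)
  new("AnnotationSet", annotations = ann, propagated = FALSE)
}

#' Propagate annotations up the ontology
#'
#' After propagation, a feature annotated to a term is annotated to all of
#' the term's ancestors.
#'
#' @param ann an [AnnotationSet-class].
#' @param dag an [OntologyDAG-class].
#' @return propagated [AnnotationSet-class].
#' @export
propagateAnnotations <- function(ann, dag) {
  order <- topoOrderOrNull(dag)
  if (is.null(order)) stop("term graph contains a cycle")
  a <- ann@annotations
  for (term in order) {  # children before parents
    genes <- a[[term]]
    if (is.null(genes)) next
    for (p in dag@parents[[term]])
      a[[p]] <- unique(c(a[[p]], genes))
  }
  new("AnnotationSet", annotations = a, propagated = TRUE)
}

#' Write an ontology DAG as DOT text
#'
#' Emits a Graphviz DOT rendering of the term graph; when enrichment results
#' are supplied, node labels carry the log2 fold enrichment.
#'
#' @param dag an [OntologyDAG-class].
#' @param path output path for the DOT text.
#' @param enrichment optional data.frame from [goEnrichmentElim()].
#' @return the path, invisibly.
#' @export
dagToDot <- function(dag, path, enrichment = NULL) {
  esc <- function(x) gsub("\"", "\\\\\"", x)
  lab <- stats::setNames(dag@names, dag@terms)
  if (!is.null(enrichment)) {
    hit <- match(dag@terms, enrichment$term)
    extra <- ifelse(is.na(hit), "",
                    sprintf("\\nlog2FE=%.2f", enrichment$log2_fold_enrichment[hit]))
    lab <- paste0(lab, extra)
  }
  out <- c("digraph ontology {",
           sprintf("  \"%s\" [label=\"%s\"];", esc(dag@terms), esc(lab)))
  for (t in dag@terms) {
    for (p in dag@parents[[t]])
      out <- c(out, sprintf("  \"%s\" -> \"%s\";", esc(t), esc(p)))
  }
  out <- c(out, "}")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
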