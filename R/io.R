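#' Read a typed table from disk
#'
#' Reads CSV/TSV files with a header row and the feature ID in the first
#' column.  The delimiter is chosen by extension (`.csv` comma, `.tsv`/`.txt`
#' tab) and falls back to sniffing the header line.  Empty cells, `NA` and
#' `NaN` are treated as missing.
#'
#' @param path file path.
#' @param kind one of `counts`, `diffexp`, `attributes`, `geneset`,
#'   `biotype`.  `geneset` accepts one-ID-per-line files or GMT files (GMT
#'   returns a named list of [GeneSet-class]); `biotype` accepts a two-column
#'   table or a GTF/GFF3 file with `gene_biotype`/`biotype` attributes.
#' @param name table name; defaults to the file base name.
#' @return the typed object for `kind`.
#' @export
readTable <- function(path, kind = c("counts", "diffexp", "attributes",
                                     "geneset", "biotype"),
                      name = NULL) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown kind: ", kind[1]))
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  switch(kind,
    counts = readCountMatrix(path, name),
    diffexp = readDiffExp(path, name),
    attributes = readAttributes(path),
    geneset = readGeneSetFile(path, name),
    biotype = readBiotype(path))
}

sniffSep <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "csv") return(",")
  if (ext %in% c("tsv", "txt", "gmt")) return("\t")
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

readDelimFrame <- function(path) {
  sep <- sniffSep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("", "NA", "NaN"), check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

checkUniqueIDs <- function(ids, path) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature IDs in ", basename(path), ": ",
         paste(utils::head(dup, 5), collapse = ", "))
}

readCountMatrix <- function(path, name) {
  df <- readDelimFrame(path)
  ids <- as.character(df[[1L]])
  checkUniqueIDs(ids, path)
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE)) {
    bad <- ids[apply(m < 0, 1L, any, na.rm = TRUE)]
    stop("negative counts in features: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  CountMatrix(m, name = name)
}

pickColumn <- function(df, candidates) {
  hit <- which(tolower(names(df)) %in% candidates)
  if (length(hit)) df[[hit[1L]]] else NULL
}

readDiffExp <- function(path, name) {
  df <- readDelimFrame(path)
  ids <- as.character(df[[1L]])
  checkUniqueIDs(ids, path)
  lfc <- pickColumn(df, c("log2fc", "log2foldchange", "logfc", "log2_fold_change"))
  if (is.null(lfc)) stop("no log2 fold change column found in ", basename(path))
  p <- pickColumn(df, c("pval", "pvalue", "p", "p.value"))
  q <- pickColumn(df, c("padj", "adj.p", "adj_p", "fdr", "qvalue", "padjust"))
  DiffExpTable(ids, as.numeric(lfc),
               pval = if (is.null(p)) NA_real_ else as.numeric(p),
               padj = if (is.null(q)) NA_real_ else as.numeric(q),
               name = name)
}

readAttributes <- function(path) {
  df <- readDelimFrame(path)
  ids <- as.character(df[[1L]])
  checkUniqueIDs(ids, path)
  attrs <- df[-1L]
  # columns of 0/1 or TRUE/FALSE strings become logical
  for (j in seq_along(attrs)) {
    col <- attrs[[j]]
    if (is.character(col)) {
      u <- unique(stats::na.omit(col))
      if (all(toupper(u) %in% c("TRUE", "FALSE")))
        attrs[[j]] <- as.logical(toupper(col))
      else attrs[[j]] <- suppressWarnings(as.numeric(col))
    } else if (is.numeric(col) && all(stats::na.omit(col) %in% c(0, 1))) {
      attrs[[j]] <- col == 1
    }
  }
  AttributeTable(ids, attrs)
}

readGeneSetFile <- function(path, name) {
  if (grepl("\\.gmt$", tolower(path))) return(readGmt(path))
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  GeneSet(name, ids)
}

#' Read and write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member IDs.
#'
#' @param path file path.
#' @return `readGmt`: a named list of [GeneSet-class] objects.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    GeneSet(f[1L], f[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, function(s) s@name, ""))
}

#' @rdname readGmt
#' @param sets list of [GeneSet-class] objects.
#' @param descriptions optional descriptions, recycled.
#' @export
writeGmt <- function(sets, path, descriptions = "") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(s, d) {
    paste(c(s@name, d, s@members), collapse = "\t")
  }, sets, descriptions)
  writeLines(lines, path, useBytes = TRUE)
}

readBiotype <- function(path) {
  if (grepl("\\.(gtf|gff3?|gff)$", tolower(path)))
    return(readBiotypeGtf(path))
  df <- readDelimFrame(path)
  mapping <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  BiotypeMap(mapping)
}

# Extract gene_id -> biotype from GTF/GFF3 attribute fields.
readBiotypeGtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  ids <- character(0); types <- character(0)
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) next
    attr <- f[9L]
    gid <- gtfAttr(attr, "gene_id")
    bt <- gtfAttr(attr, "gene_biotype")
    if (is.na(bt)) bt <- gtfAttr(attr, "biotype")
    if (is.na(bt)) bt <- gtfAttr(attr, "gene_type")
    if (!is.na(gid) && !is.na(bt)) {
      ids <- c(ids, gid); types <- c(types, bt)
    }
  }
  keep <- !duplicated(ids)
  BiotypeMap(stats::setNames(types[keep], ids[keep]))
}

gtfAttr <- function(attr, key) {
  # GTF: key "value"; GFF3: key=value
  m <- regmatches(attr, regexec(paste0(key, "[ =]+\"?([^\";]+)\"?"), attr))[[1L]]
  if (length(m) == 2L) m[2L] else NA_character_
}

#' Write tables to disk
#'
#' Writers emit UTF-8, newline-terminated files in the package's standard
#' dialect: header row, feature ID in the first column, comma- or
#' tab-separated by the `sep` argument.
#'
#' @param x object to write.
#' @param path output path.
#' @param ... further arguments; `sep` selects the delimiter (default comma).
#' @name writeTable
NULL

writeFrame <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
}

#' @rdname writeTable
#' @export
setMethod("writeTable", "CountMatrix", function(x, path, ...) {
  args <- list(...)
  sep <- if (is.null(args$sep)) "," else args$sep
  df <- data.frame(feature = rownames(x@values), x@values,
                   check.names = FALSE)
  writeFrame(df, path, sep)
  invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "DiffExpTable", function(x, path, ...) {
  args <- list(...)
  sep <- if (is.null(args$sep)) "," else args$sep
  writeFrame(diffExpFrame(x), path, sep)
  invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "GeneSet", function(x, path, ...) {
  writeLines(x@members, path, useBytes = TRUE)
  invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "AttributeTable", function(x, path, ...) {
  args <- list(...)
  sep <- if (is.null(args$sep)) "," else args$sep
  df <- data.frame(feature = x@feature_ids, x@attributes, check.names = FALSE)
  writeFrame(df, path, sep)
  invisible(path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "ClusteringSolution", function(x, path, ...) {
  df <- data.frame(feature = names(x@labels), cluster = unname(x@labels))
  writeFrame(df, path, "\t")
  invisible(path)
})

#' Write normalization factors as a two-column TSV
#' @param f a [NormFactors-class].
#' @param path output path.
#' @export
writeNormFactors <- function(f, path) {
  df <- data.frame(sample = names(f@factors), factor = unname(f@factors))
  writeFrame(df, path, "\t")
  invisible(path)
}
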