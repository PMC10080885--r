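# Row filters. Filters only remove rows: the column set and the row order of
# survivors are preserved, the history gains exactly one record, and the
# derived name encodes the operation.

subsetCounts <- function(m, keep, op, params, suffix, info = NULL) {
  n_before <- nrow(m@values)
  out <- m
  out@values <- m@values[keep, , drop = FALSE]
  out@name <- deriveName(m@name, suffix)
  appendHistory(out, op, params, n_before, nrow(out@values), info = info)
}

subsetDiffExp <- function(t, keep, op, params, suffix, info = NULL) {
  n_before <- length(t@feature_ids)
  out <- t
  out@feature_ids <- t@feature_ids[keep]
  out@log2fc <- t@log2fc[keep]
  out@pval <- t@pval[keep]
  out@padj <- t@padj[keep]
  out@name <- deriveName(t@name, suffix)
  appendHistory(out, op, params, n_before, length(out@feature_ids),
                info = info)
}

#' Filter lowly-expressed features
#'
#' Keeps features whose row sum, row minimum, or row mean is at least
#' `threshold`.  Missing values are ignored in the summary.
#'
#' @param m a [CountMatrix-class].
#' @param threshold non-negative expression cutoff.
#' @param mode `sum`, `min_per_sample`, or `mean`.
#' @return filtered [CountMatrix-class].
#' @export
filterLowExpression <- function(m, threshold,
                                mode = c("sum", "min_per_sample", "mean")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be >= 0")
  stat <- switch(mode,
    sum = rowSums(m@values, na.rm = TRUE),
    min_per_sample = apply(m@values, 1L, min, na.rm = TRUE),
    mean = rowMeans(m@values, na.rm = TRUE))
  keep <- stat >= threshold
  subsetCounts(m, keep, "filter_low_expression",
               list(threshold = threshold, mode = mode),
               paste0("lowexp", fmtNum(threshold), mode))
}

#' Drop features with missing values
#'
#' Removes every feature with at least one missing value.
#'
#' @param m a [CountMatrix-class].
#' @return filtered [CountMatrix-class].
#' @export
dropMissing <- function(m) {
  keep <- stats::complete.cases(m@values)
  subsetCounts(m, keep, "drop_missing", list(), "nomissing")
}

#' Filter by statistical significance
#'
#' Keeps features whose adjusted p-value is present and at most `alpha`.
#' Rows with a missing adjusted p-value are excluded (recorded in the
#' history, not an error).
#'
#' @param t a [DiffExpTable-class].
#' @param alpha significance cutoff in (0, 1].
#' @return filtered [DiffExpTable-class].
#' @export
filterSignificant <- function(t, alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  keep <- !is.na(t@padj) & t@padj <= alpha
  subsetDiffExp(t, keep, "filter_significant", list(alpha = alpha),
                paste0("sig", fmtNum(alpha)))
}

#' Filter by fold-change magnitude and direction
#'
#' @param t a [DiffExpTable-class].
#' @param magnitude non-negative log2 fold-change cutoff.
#' @param direction `up` keeps log2fc >= magnitude, `down` keeps
#'   log2fc <= -magnitude, `both` keeps |log2fc| >= magnitude.
#' @return filtered [DiffExpTable-class].
#' @export
filterFoldChange <- function(t, magnitude, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!is.numeric(magnitude) || magnitude < 0)
    stop("magnitude must be >= 0")
  keep <- switch(direction,
    up = t@log2fc >= magnitude,
    down = t@log2fc <= -magnitude,
    both = abs(t@log2fc) >= magnitude)
  keep[is.na(keep)] <- FALSE
  subsetDiffExp(t, keep, "filter_fold_change",
                list(magnitude = magnitude, direction = direction),
                paste0("fc", fmtNum(magnitude), direction))
}

#' Split into significantly up- and down-regulated tables
#'
#' Applies the significance and fold-change filters in both directions; the
#' two outputs are disjoint by construction.
#'
#' @param t a [DiffExpTable-class].
#' @param alpha significance cutoff in (0, 1].
#' @param magnitude non-negative log2 fold-change cutoff.
#' @return list with elements `up` and `down`, both [DiffExpTable-class].
#' @export
splitByDirection <- function(t, alpha = 0.05, magnitude = 0) {
  up <- filterFoldChange(filterSignificant(t, alpha), magnitude, "up")
  down <- filterFoldChange(filterSignificant(t, alpha), magnitude, "down")
  if (magnitude == 0) {
    # a log2fc of exactly 0 is neither up- nor down-regulated
    keep <- down@log2fc < 0
    down <- subsetDiffExp(down, keep, "drop_zero_fc", list(), "nonzero")
  }
  list(up = up, down = down)
}

#' Filter features by biotype
#'
#' Keeps features whose biotype is in `keep`.  Features absent from the map
#' are dropped; their count is recorded in the history record.
#'
#' @param x a [CountMatrix-class] or [DiffExpTable-class].
#' @param map a [BiotypeMap-class].
#' @param keep non-empty character vector of biotype labels to keep.
#' @return filtered object of the same kind.
#' @name filterBiotype
NULL

biotypeKeep <- function(ids, map, keep) {
  if (length(keep) == 0L) stop("keep must be a non-empty set of labels")
  bt <- map@mapping[ids]
  list(keep = !is.na(bt) & bt %in% keep, n_unmapped = sum(is.na(bt)))
}

#' @rdname filterBiotype
#' @export
setMethod("filterBiotype", "CountMatrix", function(x, map, keep) {
  sel <- biotypeKeep(rownames(x@values), map, keep)
  subsetCounts(x, sel$keep, "filter_biotype",
               list(keep = keep, map = map), "bt",
               info = list(n_unmapped = sel$n_unmapped))
})

#' @rdname filterBiotype
#' @export
setMethod("filterBiotype", "DiffExpTable", function(x, map, keep) {
  sel <- biotypeKeep(x@feature_ids, map, keep)
  subsetDiffExp(x, sel$keep, "filter_biotype",
                list(keep = keep, map = map), "bt",
                info = list(n_unmapped = sel$n_unmapped))
})
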