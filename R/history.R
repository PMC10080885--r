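# History bookkeeping: every table keeps an append-only log plus the snapshot
# of its initial state; undo replays the log minus its last entry onto the
# snapshot through the operation registry.

initHistory <- function(x, op, params = list()) {
  n <- nFeatures(x)
  rec <- list(op = op, params = params, n_before = n, n_after = n)
  h <- new("HistoryLog", records = list(rec), snapshot = NULL)
  x@history <- h
  snap <- x
  x@history@snapshot <- snap
  x
}

appendHistory <- function(x, op, params, n_before, n_after, info = NULL) {
  # params must be replayable through the op registry; diagnostics go in info
  rec <- list(op = op, params = params, n_before = n_before,
              n_after = n_after, info = info)
  x@history@records <- c(x@history@records, list(rec))
  x
}

#' Undo the last operation applied to a table
#'
#' Restores the table state preceding the last operation by replaying the
#' recorded history (minus its last entry) onto the snapshot taken when the
#' table was loaded.  Stochastic steps recorded their seeds, so the replay is
#' exact.  With nothing to undo beyond the load record, the table is returned
#' unchanged with a warning.
#'
#' @param x a [CountMatrix-class] or [DiffExpTable-class].
#' @return the table as it was before the last operation; its history ends in
#'   an `undo` record.
#' @name undoLast
NULL

undoImpl <- function(x) {
  recs <- x@history@records
  if (length(recs) <= 1L) {
    warning("nothing to undo")
    return(x)
  }
  snap <- x@history@snapshot
  out <- snap
  replay <- recs[-c(1L, length(recs))]
  for (rec in replay) out <- applyRegisteredOp(out, rec$op, rec$params)
  undone <- recs[[length(recs)]]$op
  out@history@records <- c(out@history@records,
                           list(list(op = "undo", params = list(undone = undone),
                                     n_before = nFeatures(x),
                                     n_after = nFeatures(out))))
  out@history@snapshot <- snap
  out
}

#' @rdname undoLast
#' @export
setMethod("undoLast", "CountMatrix", undoImpl)

#' @rdname undoLast
#' @export
setMethod("undoLast", "DiffExpTable", undoImpl)
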