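# Serializable, shareable, ordered bundles of operations applied uniformly to
# tables.

PIPELINE_FORMAT_VERSION <- "1.0"

#' Create an empty Pipeline
#'
#' @param name pipeline name.
#' @return A [Pipeline-class] with no steps.
#' @export
Pipeline <- function(name = "pipeline") {
  new("Pipeline", name = name, version = PIPELINE_FORMAT_VERSION,
      steps = list())
}

#' Append a step to a Pipeline
#'
#' The operation name and parameters are validated immediately (at add time,
#' not run time); the original pipeline is not modified (value semantics).
#'
#' @param p a [Pipeline-class].
#' @param op_name a registered operation name (see [registeredOps()]).
#' @param params named list of parameters for the operation.
#' @return a new [Pipeline-class] with the step appended.
#' @export
pipelineAdd <- function(p, op_name, params = list()) {
  err <- validateOpStep(op_name, params)
  if (!is.null(err)) stop(err)
  p@steps <- c(p@steps, list(list(op = op_name, params = params)))
  p
}

#' Apply a Pipeline to a list of tables
#'
#' Steps are applied in order to each table independently; each result's
#' history contains the steps.  On a kind mismatch (or any step failure) at
#' table t, processing stops with the results of the earlier tables still
#' returned and the failure described in the report.
#'
#' @param p a [Pipeline-class].
#' @param tables list of tables (or a single table).
#' @return list with `results` (named list of output tables), `report`
#'   (data.frame of per-table before/after feature counts and status), and
#'   `error` (`NULL`, or the failure message).
#' @export
pipelineApply <- function(p, tables) {
  if (!is.list(tables)) tables <- list(tables)
  results <- list()
  rep_rows <- list()
  err_msg <- NULL
  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    tname <- tryCatch(tableName(tab), error = function(e) paste0("table", ti))
    out <- tab
    failed <- NULL
    for (si in seq_along(p@steps)) {
      st <- p@steps[[si]]
      out <- tryCatch(applyRegisteredOp(out, st$op, st$params),
                      error = function(e) {
                        failed <<- sprintf(
                          "table '%s': step %d (%s) failed: %s",
                          tname, si, st$op, conditionMessage(e))
                        NULL
                      })
      if (!is.null(failed)) break
    }
    if (is.null(failed)) {
      results[[tname]] <- out
      rep_rows[[ti]] <- data.frame(table = tname,
                                   n_before = nFeatures(tab),
                                   n_after = nFeatures(out),
                                   status = "ok")
    } else {
      rep_rows[[ti]] <- data.frame(table = tname,
                                   n_before = nFeatures(tab),
                                   n_after = NA_integer_,
                                   status = failed)
      err_msg <- failed
      warning(failed)
      break
    }
  }
  list(results = results, report = do.call(rbind, rep_rows), error = err_msg)
}

#' Export and import Pipelines
#'
#' Pipelines are stored as JSON documents `{name, version, steps: [{op,
#' params}]}` with a semantic format-version tag; YAML files are accepted on
#' import for hand-authoring.  Operation names and parameters are validated
#' at import time; a file written by a newer format version is refused.
#'
#' @param p a [Pipeline-class].
#' @param path file path (`.json`, `.yaml`/`.yml`).
#' @return `pipelineImport`: a validated [Pipeline-class].
#' @export
pipelineExport <- function(p, path) {
  steps <- lapply(p@steps, function(st) {
    if (any(vapply(st$params, isS4, TRUE)))
      stop("step '", st$op, "' has non-serializable parameters")
    list(op = st$op, params = st$params)
  })
  doc <- list(name = p@name, version = p@version, steps = steps)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname pipelineExport
#' @export
pipelineImport <- function(path) {
  if (grepl("\\.ya?ml$", tolower(path))) {
    doc <- yaml::read_yaml(path)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(doc$version)) stop("pipeline file lacks a version tag")
  vfile <- as.integer(strsplit(as.character(doc$version), ".", fixed = TRUE)[[1L]][1L])
  vown <- as.integer(strsplit(PIPELINE_FORMAT_VERSION, ".", fixed = TRUE)[[1L]][1L])
  if (is.na(vfile) || vfile > vown)
    stop("pipeline format version ", doc$version,
         " is newer than supported (", PIPELINE_FORMAT_VERSION, ")")
  p <- Pipeline(name = if (is.null(doc$name)) "pipeline" else doc$name)
  for (si in seq_along(doc$steps)) {
    st <- doc$steps[[si]]
    params <- if (is.null(st$params)) list() else
      lapply(st$params, function(v) if (is.list(v)) unlist(v) else v)
    ok <- tryCatch({ p <- pipelineAdd(p, st$op, params); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop("invalid step ", si, ": ", ok)
  }
  p
}
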