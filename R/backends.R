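#' Training specification
#'
#' Bundles everything a backend needs for one training task: the
#' hyperparameter configuration (one row of a \code{hyperparameter_configs}
#' table), the epoch budget, the task-level seed, the task identity
#' (\code{i}, \code{j}, \code{m}; NA where undefined), the class set, and an
#' optional resume point (\code{list(epoch, state)}) from which training
#' continues instead of starting fresh.
#'
#' @param config one-row data.frame of hyperparameters (may be empty).
#' @param epochs total epochs to train (>= 1).
#' @param seed integer task seed.
#' @param task list with elements i, j, m (use NA where undefined).
#' @param classes character vector of class names.
#' @param resumeFrom optional list(epoch, state) with epoch < epochs.
#' @return a list of class \code{train_spec}.
#' @export
trainSpec <- function(config = NULL, epochs = 10L, seed = 0L,
                      task = list(i = NA, j = NA, m = NA),
                      classes = character(), resumeFrom = NULL) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!is.null(resumeFrom) && resumeFrom$epoch >= epochs)
    stop("resume epoch must be < total epochs")
  structure(list(config = config, epochs = as.integer(epochs),
                 seed = as.integer(seed), task = task, classes = classes,
                 resumeFrom = resumeFrom),
            class = "train_spec")
}

#' @rdname ModelState-class
#' @param params,provenance slots of the new state.
#' @export
modelState <- function(params = list(), provenance = list()) {
  new("ModelState", params = params, provenance = provenance)
}

setMethod("show", "ModelState", function(object) {
  p <- object@provenance
  cat("ModelState:", if (length(p$backend)) p$backend else "unknown backend",
      "\n")
  if (length(p$config_index))
    cat("  config index:", p$config_index, "\n")
  if (length(p$folds)) cat("  trained on folds:",
                           paste(p$folds, collapse = ", "), "\n")
  if (length(p$epochs)) cat("  epochs completed:", p$epochs, "\n")
})

# ---- replay backend -------------------------------------------------------

#' Replay backend driven by tabulated accuracies
#'
#' Training is a no-op; evaluation looks up the accuracy for the task
#' identity and returns a synthetic confusion matrix carrying exactly that
#' accuracy (denominator 100, matching two-decimal tabulated values). This
#' lets the full NACHOS/DACHOS engines be verified against published
#' benchmark tables without any model training.
#'
#' Lookup rules for a validation task (i, j, m): an exact (i, j, m) row is
#' preferred; otherwise an (i, j) row with m = NA applies to every
#' validation fold (used for tables that publish per-cell means). DACHOS
#' tasks have i = NA. Test (retrain) tasks are looked up in
#' \code{testTable} by test fold i.
#'
#' @param cvTable data.frame(i, j, m, accuracy); i and/or m may be NA.
#' @param testTable data.frame(i, j, accuracy); may be empty for
#'   deployment-only replays.
#' @param classes class names for the synthetic confusion matrices.
#' @return a [ReplayBackend-class].
#' @seealso [makeReplayTables()], [replayStudy()]
#' @export
replayBackend <- function(cvTable,
                          testTable = data.frame(i = integer(),
                                                 j = integer(),
                                                 accuracy = numeric()),
                          classes = c("class0", "class1")) {
  cvTable <- as.data.frame(cvTable)
  for (col in c("i", "m"))
    if (!col %in% names(cvTable)) cvTable[[col]] <- NA_integer_
  new("ReplayBackend", cvTable = cvTable,
      testTable = as.data.frame(testTable), classNames = classes)
}

setMethod("trainModel", "ReplayBackend",
  function(backend, records, payloads, spec, onEpochEnd = NULL) {
    modelState(provenance = list(backend = "replay", task = spec$task,
                                 config_index = spec$task$j,
                                 epochs = spec$epochs, seed = spec$seed))
  })

setMethod("evaluateModel", "ReplayBackend",
  function(backend, model, records, payloads) {
    task <- model@provenance$task
    i <- task$i; j <- task$j; m <- task$m
    same <- function(col, val) if (is.na(val)) is.na(col) else
      !is.na(col) & col == val
    if (!is.na(m)) {  # validation task
      tab <- backend@cvTable
      hit <- same(tab$i, i) & same(tab$j, j) & same(tab$m, m)
      if (!any(hit))  # per-cell mean row applies to all validation folds
        hit <- same(tab$i, i) & same(tab$j, j) & is.na(tab$m)
      if (!any(hit))
        stop("replay table has no entry for (i=", i, ", j=", j,
             ", m=", m, ")")
      acc <- tab$accuracy[which(hit)[1]]
    } else {          # test task: keyed by test fold
      tab <- backend@testTable
      hit <- same(tab$i, i)
      if (!any(hit))
        stop("replay test table has no entry for i=", i)
      acc <- tab$accuracy[which(hit)[1]]
    }
    .syntheticConfusion(acc, backend@classNames, 100L)
  })

# ---- mock backend ---------------------------------------------------------

#' Mock backend with accuracy as a function of the task identity
#'
#' Evaluation accuracy is \code{fn(i, j, m)} (\code{m = NA} for test tasks),
#' making engine behaviour independently enumerable by brute force. Every
#' training call is appended to \code{backend@trace$calls} as
#' \code{list(task, ids)} so tests can audit exactly which records each task
#' trained on. Synthetic confusion matrices use denominator 100, so
#' functions returning multiples of 0.01 are represented exactly.
#'
#' @param fn function(i, j, m) -> accuracy in [0, 1].
#' @return a [MockBackend-class].
#' @export
mockBackend <- function(fn) {
  tr <- new.env(parent = emptyenv())
  tr$calls <- list()
  new("MockBackend", fn = fn, trace = tr)
}

setMethod("trainModel", "MockBackend",
  function(backend, records, payloads, spec, onEpochEnd = NULL) {
    backend@trace$calls[[length(backend@trace$calls) + 1L]] <-
      list(task = spec$task, ids = records$image_id)
    cls <- if (length(spec$classes)) spec$classes else
      sort(unique(records$label))
    modelState(provenance = list(backend = "mock", task = spec$task,
                                 classes = cls,
                                 config_index = spec$task$j,
                                 epochs = spec$epochs, seed = spec$seed))
  })

setMethod("evaluateModel", "MockBackend",
  function(backend, model, records, payloads) {
    task <- model@provenance$task
    acc <- backend@fn(task$i, task$j, task$m)
    .syntheticConfusion(acc, model@provenance$classes, 100L)
  })
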