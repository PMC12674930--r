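#' Train a model on a set of records
#'
#' Backend contract: train on \code{records} (rows of a manifest's record
#' table) with payloads \code{payloads}, honouring the hyperparameters,
#' epoch count and seed in \code{spec}, and invoke \code{onEpochEnd(epoch,
#' state)} after every completed epoch (the checkpoint hook). Training must
#' be deterministic given (records, spec), and resuming from an intermediate
#' state via \code{spec$resumeFrom} must reproduce the uninterrupted result
#' for deterministic backends.
#'
#' @param backend a [ModelBackend-class].
#' @param records data.frame of image records (manifest rows).
#' @param payloads named list of pixel matrices keyed by image_id.
#' @param spec a [trainSpec()] list: config (one-row data.frame), epochs,
#'   seed, task (list with i, j, m), optional resumeFrom = list(epoch, state).
#' @param onEpochEnd optional function(epoch, state) called after each epoch.
#' @return a [ModelState-class].
#' @export
setGeneric("trainModel", function(backend, records, payloads, spec,
                                  onEpochEnd = NULL)
  standardGeneric("trainModel"))

#' Evaluate a trained model
#'
#' Returns a confusion matrix (true classes in rows, predicted in columns)
#' over the backend's class set. For real backends the total count equals
#' \code{nrow(records)}; the replay backend returns a synthetic matrix with
#' a fixed denominator of 100 so that tabulated two-decimal accuracies are
#' represented exactly.
#'
#' @inheritParams trainModel
#' @param model a [ModelState-class] produced by [trainModel()].
#' @return an integer confusion matrix with class dimnames.
#' @export
setGeneric("evaluateModel", function(backend, model, records, payloads)
  standardGeneric("evaluateModel"))

#' @rdname DataManifest-class
#' @param x,object a \code{DataManifest}.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname DataManifest-class
#' @export
setGeneric("hierarchy", function(x) standardGeneric("hierarchy"))

#' @rdname DataManifest-class
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname DataManifest-class
#' @export
setGeneric("payloads", function(x) standardGeneric("payloads"))

#' @rdname DataManifest-class
#' @param level a hierarchy level name.
#' @export
setGeneric("groupIds", function(x, level) standardGeneric("groupIds"))

#' @rdname FoldAssignment-class
#' @param x a \code{FoldAssignment}.
#' @export
setGeneric("foldOf", function(x) standardGeneric("foldOf"))

#' @rdname FoldAssignment-class
#' @export
setGeneric("foldCount", function(x) standardGeneric("foldCount"))

#' @rdname BenchmarkReport-class
#' @param x a report object.
#' @export
setGeneric("aggregateStats", function(x) standardGeneric("aggregateStats"))

#' @rdname BenchmarkReport-class
#' @export
setGeneric("foldSummary", function(x) standardGeneric("foldSummary"))

#' @rdname BenchmarkReport-class
#' @export
setGeneric("selectedConfig", function(x) standardGeneric("selectedConfig"))
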