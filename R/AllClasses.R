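#' @import methods
NULL

#' Labeled image collection with a group hierarchy
#'
#' A \code{DataManifest} holds the records of a labeled image dataset together
#' with its group hierarchy (coarsest to finest; the finest level is always
#' \code{"image"}). Each record carries one identifier per hierarchy level, a
#' class label, a payload locator and the pixel dimensions. Pixel payloads may
#' optionally be attached in-memory as a named list of matrices keyed by
#' \code{image_id}.
#'
#' Records are stored as a data.frame with columns \code{image_id}, one column
#' per non-image hierarchy level, \code{label}, \code{payload_ref},
#' \code{height} and \code{width}.
#'
#' @slot records data.frame of per-image records.
#' @slot hierarchy character vector of level names, coarsest first, ending in
#'   \code{"image"}.
#' @slot classNames character vector of permitted class labels.
#' @slot payloads named list of numeric matrices (may be empty; keyed by
#'   \code{image_id}).
#'
#' @seealso [dataManifest()], [assignFolds()], [generateDataset()]
#' @export
setClass("DataManifest",
  slots = c(
    records = "data.frame",
    hierarchy = "character",
    classNames = "character",
    payloads = "list"
  )
)

setValidity("DataManifest", function(object) {
  rec <- object@records
  hier <- object@hierarchy
  msgs <- character()
  if (length(hier) < 1L || hier[length(hier)] != "image")
    msgs <- c(msgs, "hierarchy must end in 'image'")
  need <- c("image_id", setdiff(hier, "image"), "label")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$image_id))
    msgs <- c(msgs, "image_id values must be unique")
  if (!all(rec$label %in% object@classNames))
    msgs <- c(msgs, "every label must belong to classNames")
  # nesting: records sharing a finer group id share all coarser group ids
  grp <- setdiff(hier, "image")
  if (length(grp) > 1L) {
    for (lv in seq(2L, length(grp))) {
      fine <- rec[[grp[lv]]]
      coarse <- do.call(paste, c(rec[grp[seq_len(lv - 1L)]], sep = "\r"))
      if (any(vapply(split(coarse, fine), function(x) length(unique(x)), 1L) > 1L))
        msgs <- c(msgs, sprintf("level '%s' is not nested within coarser levels", grp[lv]))
    }
  }
  if (length(object@payloads)) {
    bad <- setdiff(names(object@payloads), rec$image_id)
    if (length(bad)) msgs <- c(msgs, "payload keys must be image_ids")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Fold assignment of a manifest at a hierarchy level
#'
#' Maps every \code{image_id} of a [DataManifest-class] to one of \code{k}
#' folds \code{F0..Fk-1}, with group integrity guaranteed at the declared
#' hierarchy level: all records sharing a group identifier at that level sit
#' in the same fold.
#'
#' @slot k integer fold count.
#' @slot level hierarchy level at which integrity is enforced.
#' @slot foldOf named integer vector, image_id -> fold index in 0..k-1.
#' @slot seed integer seed used for the group shuffle.
#'
#' @seealso [assignFolds()], [auditAssignment()]
#' @export
setClass("FoldAssignment",
  slots = c(k = "integer", level = "character", foldOf = "integer",
            seed = "integer")
)

setValidity("FoldAssignment", function(object) {
  if (length(object@k) != 1L || object@k < 2L) return("k must be a single integer >= 2")
  if (is.null(names(object@foldOf))) return("foldOf must be named by image_id")
  f <- object@foldOf
  if (any(f < 0L | f >= object@k)) return("fold indices must lie in 0..k-1")
  TRUE
})

#' Serialized model with provenance
#'
#' Opaque trained-model parameters plus the provenance of the task that
#' produced them (configuration index, training folds, epochs completed,
#' seed). States round-trip through [saveRDS()] bit-identically.
#'
#' @slot params list of backend-specific parameters.
#' @slot provenance list with (at least) \code{config_index}, \code{folds},
#'   \code{epochs}, \code{seed}.
#' @export
setClass("ModelState", slots = c(params = "list", provenance = "list"))

#' Training backends
#'
#' \code{ModelBackend} is the virtual parent of all training backends; the
#' engine only talks to backends through [trainModel()] and
#' [evaluateModel()]. Three implementations ship with the package:
#' \describe{
#'   \item{\code{ReplayBackend}}{training is a no-op; evaluation returns a
#'     synthetic confusion matrix whose accuracy equals a tabulated value
#'     keyed by (test fold, configuration, validation fold). Used to drive
#'     the engines with published benchmark tables.}
#'   \item{\code{ReferenceBackend}}{a small multinomial softmax classifier
#'     (optionally with one hidden layer) trained by mini-batch SGD that
#'     honours every hyperparameter dimension; runs on a CPU in seconds.}
#'   \item{\code{MockBackend}}{accuracy is a deterministic arithmetic
#'     function of (i, j, m); used for brute-force engine oracles. Records
#'     every training call in its \code{trace} environment.}
#' }
#' @aliases ReplayBackend-class ReferenceBackend-class MockBackend-class
#' @export
setClass("ModelBackend", representation("VIRTUAL"))

#' @rdname ModelBackend-class
#' @slot cvTable data.frame(i, j, m, accuracy); \code{i}/\code{m} may be NA.
#' @slot testTable data.frame(i, j, accuracy).
#' @slot classNames classes used for the synthetic confusion matrices.
#' @export
setClass("ReplayBackend", contains = "ModelBackend",
  slots = c(cvTable = "data.frame", testTable = "data.frame",
            classNames = "character"))

#' @rdname ModelBackend-class
#' @slot epochs default epoch count.
#' @slot architectures named list mapping architecture names to topology
#'   descriptions (hidden-layer sizes).
#' @export
setClass("ReferenceBackend", contains = "ModelBackend",
  slots = c(epochs = "integer", architectures = "list"))

#' @rdname ModelBackend-class
#' @slot fn function(i, j, m) -> accuracy in [0,1] (m = NA for test tasks).
#' @slot trace environment accumulating training-call records.
#' @export
setClass("MockBackend", contains = "ModelBackend",
  slots = c(fn = "function", trace = "environment"))

#' Nested cross-validation benchmark report
#'
#' The result of [runNachos()]: per-test-fold selections and test accuracies,
#' the full grid of validation accuracies, and the aggregate statistics
#' (mean, sample SD, SE = SD/sqrt(k), Student-t confidence interval with
#' k-1 degrees of freedom) plus the average confusion matrix with per-cell
#' SDs.
#'
#' @slot folds data.frame(i, jStar, cvAccuracy, testAccuracy).
#' @slot trials data.frame(i, j, m, accuracy) of all validation results.
#' @slot cvMeans data.frame(i, j, meanValAccuracy).
#' @slot aggregate list(mean, sd, se, ci, level, k).
#' @slot confusions list of per-fold test confusion matrices.
#' @slot meta list (k, n, partition level, seed, task counts, timing).
#' @export
setClass("BenchmarkReport",
  slots = c(folds = "data.frame", trials = "data.frame",
            cvMeans = "data.frame", aggregate = "list",
            confusions = "list", meta = "list"))

#' Deployment (full-dataset) report
#'
#' The result of [runDachos()]: the k-fold validation accuracies of every
#' configuration, their unrounded means, the selected configuration and the
#' final production model trained on the entire dataset. The final model's
#' test performance is unknown by construction — no held-out evaluation is
#' performed or fabricated.
#'
#' @slot validation data.frame(j, m, accuracy).
#' @slot cvMeans data.frame(j, meanValAccuracy).
#' @slot jStar selected configuration index.
#' @slot finalModel [ModelState-class] trained on all folds.
#' @slot meta list (k, n, seed, task counts).
#' @export
setClass("DeploymentReport",
  slots = c(validation = "data.frame", cvMeans = "data.frame",
            jStar = "integer", finalModel = "ModelState", meta = "list"))
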