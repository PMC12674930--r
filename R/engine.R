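# The nested cross-validation engine: a cross-testing (CT) loop holding out
# each fold Fi in turn, an AHPO loop over configurations hj, and an inner CV
# loop over validation folds Fm. Selection per test fold maximises the
# unrounded mean validation accuracy; the winning configuration is retrained
# on all folds except Fi and scored on Fi. The deployment variant drops the
# CT loop, selects one configuration by plain k-fold CV over the full
# dataset, and retrains it on everything.

.foldIdSets <- function(assignment) {
  f <- foldOf(assignment)
  split(names(f), f)
}

.configRow <- function(configs, j) {
  row <- configs[configs$index == j, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown configuration index ", j)
  row
}

#' Execute one engine task
#'
#' Resolves a task's training and evaluation record sets from the fold
#' assignment, trains through the backend and evaluates. Validation tasks
#' train on the folds excluding the test fold \code{i} and validation fold
#' \code{m} and are scored on \code{Fm}; retrain tasks train on all folds
#' except \code{i} and are scored on \code{Fi}; deploy tasks train on every
#' record and return the model unevaluated. For any task with a test fold,
#' the engine asserts on record-id sets that \code{Fi} never intersects the
#' training or validation set.
#'
#' @param manifest a [DataManifest-class].
#' @param assignment a [FoldAssignment-class] over the manifest.
#' @param configs a \code{hyperparameter_configs} data.frame.
#' @param backend a [ModelBackend-class].
#' @param task list(kind, i, j, m, id).
#' @param seed global run seed (mixed per task via [taskSeed()]).
#' @param epochs epoch budget per task.
#' @param resume optional list(epoch, state) to continue from.
#' @param onEpochEnd optional checkpoint hook.
#' @return for cv/retrain: list(task, confusion, accuracy); for deploy:
#'   list(task, model).
#' @export
executeTask <- function(manifest, assignment, configs, backend, task,
                        seed = 0L, epochs = 1L, resume = NULL,
                        onEpochEnd = NULL) {
  sets <- .foldIdSets(assignment)
  fold <- function(x) sets[[as.character(x)]]
  rec <- records(manifest)
  pick <- function(ids) rec[match(ids, rec$image_id), , drop = FALSE]
  i <- task$i; j <- task$j; m <- task$m
  if (task$kind == "cv") {
    keep <- setdiff(names(sets), as.character(c(i, m)))
    trainIds <- unlist(sets[keep], use.names = FALSE)
    evalIds <- fold(m)
  } else if (task$kind == "retrain") {
    keep <- setdiff(names(sets), as.character(i))
    trainIds <- unlist(sets[keep], use.names = FALSE)
    evalIds <- fold(i)
  } else {  # deploy
    trainIds <- unlist(sets, use.names = FALSE)
    evalIds <- character()
  }
  if (!is.na(i)) {
    test <- fold(i)
    leaked <- intersect(test, if (task$kind == "cv")
      c(trainIds, evalIds) else trainIds)
    if (length(leaked))
      stop("leakage: test fold F", i, " intersects the training/validation ",
           "set (", length(leaked), " records)")
  }
  spec <- trainSpec(config = .configRow(configs, j), epochs = epochs,
                    seed = taskSeed(seed, i, j, m),
                    task = task, classes = classNames(manifest),
                    resumeFrom = resume)
  model <- tryCatch(
    trainModel(backend, pick(trainIds), payloads(manifest), spec,
               onEpochEnd = onEpochEnd),
    error = function(e) stop("task '", task$id, "': ", conditionMessage(e),
                             call. = FALSE))
  if (task$kind == "deploy")
    return(list(task = task, model = model))
  cm <- evaluateModel(backend, model, pick(evalIds), payloads(manifest))
  out <- list(task = task, confusion = cm, accuracy = accuracy(cm))
  if (task$kind == "retrain") out$model <- model
  out
}

# argmax over unrounded means with lowest-index tie-break
.selectBest <- function(means, js) {
  best <- max(means)
  js[means >= best][which.min(js[means >= best])]
}

#' Summarize inner-CV results and select configurations
#'
#' Computes, per test fold i, the cross-validation accuracy of each
#' configuration — the unrounded mean of its k-1 validation accuracies —
#' and selects j* as the argmax, breaking ties by the lowest configuration
#' index. Rounding happens only at presentation; selection always compares
#' unrounded means.
#'
#' @param trials data.frame(i, j, m, accuracy) with exactly one row per
#'   (i, j, m) triple, i != m.
#' @param k,n fold and configuration counts.
#' @return list with \code{cvMeans} data.frame(i, j, meanValAccuracy) and
#'   \code{selection} data.frame(i, jStar, cvAccuracy).
#' @export
summarizeCv <- function(trials, k, n) {
  expect <- enumerateNcvTasks(k, n)
  key <- paste(trials$i, trials$j, trials$m)
  ekey <- paste(expect$i, expect$j, expect$m)
  missing <- setdiff(ekey, key)
  if (length(missing))
    stop("incomplete results: missing (i j m) triple(s) ",
         paste(utils::head(missing, 3), collapse = "; "))
  if (anyDuplicated(key))
    stop("incomplete results: duplicated triple(s)")
  agg <- stats::aggregate(accuracy ~ i + j, data = trials, FUN = mean)
  agg <- agg[order(agg$i, agg$j), ]
  sel <- do.call(rbind, lapply(split(agg, agg$i), function(d) {
    js <- .selectBest(d$accuracy, d$j)
    data.frame(i = d$i[1], jStar = js,
               cvAccuracy = d$accuracy[d$j == js])
  }))
  rownames(sel) <- NULL
  names(agg)[names(agg) == "accuracy"] <- "meanValAccuracy"
  list(cvMeans = agg[, c("i", "j", "meanValAccuracy")], selection = sel)
}

.engineExecutor <- function(manifest, assignment, configs, backend, seed,
                            epochs) {
  force(manifest); force(assignment); force(configs); force(backend)
  function(task, resume, onEpochEnd)
    executeTask(manifest, assignment, configs, backend, task,
                seed = seed, epochs = epochs, resume = resume,
                onEpochEnd = onEpochEnd)
}

.defaultEpochs <- function(backend, epochs) {
  if (!is.null(epochs)) return(as.integer(epochs))
  if (is(backend, "ReferenceBackend")) backend@epochs else 1L
}

#' Run the nested cross-validation benchmark
#'
#' Executes the full engine: all \eqn{k(k-1)n} validation tasks through the
#' scheduler, per-test-fold selection of the best configuration by
#' unrounded mean validation accuracy, one retrain task per test fold
#' scoring \eqn{t_i} on the held-out \eqn{F_i}, and aggregation of the test
#' accuracies into mean, sample SD, SE = SD/\eqn{\sqrt k} and a Student-t
#' confidence interval with k-1 degrees of freedom. Records of \eqn{F_i}
#' never enter any training or validation set of CT iteration i.
#'
#' @param manifest a [DataManifest-class].
#' @param assignment a [FoldAssignment-class]; must pass
#'   [auditAssignment()].
#' @param configs a \code{hyperparameter_configs} data.frame (n rows).
#' @param backend a [ModelBackend-class].
#' @param g worker count for the scheduler.
#' @param seed global run seed.
#' @param epochs per-task epoch budget (default: backend's own default).
#' @param store optional [checkpointStore()] for fault tolerance; with a
#'   populated store the run resumes instead of recomputing.
#' @param confidence confidence level of the aggregate interval.
#' @return a [BenchmarkReport-class].
#' @examples
#' rs <- replayStudy("xray_ncv")
#' aggregateStats(rs)$mean  # 0.7525
#' @export
runNachos <- function(manifest, assignment, configs, backend, g = 1L,
                      seed = 0L, epochs = NULL, store = NULL,
                      confidence = 0.95) {
  audit <- auditAssignment(assignment, manifest)
  if (!audit$pass)
    stop("invalid assignment: ",
         paste(unique(audit$violations$rule), collapse = ", "))
  k <- foldCount(assignment)
  n <- nrow(configs)
  if (!n) stop("configs must be non-empty")
  epochs <- .defaultEpochs(backend, epochs)
  exec <- .engineExecutor(manifest, assignment, configs, backend, seed,
                          epochs)
  cvTasks <- enumerateNcvTasks(k, n)
  t0 <- Sys.time()
  cvResults <- runTasks(cvTasks, g = g, execute = exec, store = store)
  trials <- do.call(rbind, lapply(cvResults, function(r)
    data.frame(i = r$task$i, j = r$task$j, m = r$task$m,
               accuracy = r$accuracy)))
  rownames(trials) <- NULL
  summ <- summarizeCv(trials, k, n)
  retrain <- data.frame(kind = "retrain", i = summ$selection$i,
                        j = summ$selection$jStar, m = NA_integer_,
                        stringsAsFactors = FALSE)
  retrain$id <- mapply(taskId, retrain$kind, retrain$i, retrain$j,
                       retrain$m)
  rtResults <- runTasks(retrain, g = g, execute = exec, store = store)
  ord <- order(vapply(rtResults, function(r) r$task$i, 0L))
  rtResults <- rtResults[ord]
  tvals <- vapply(rtResults, function(r) r$accuracy, 0)
  confusions <- lapply(rtResults, function(r) r$confusion)
  names(confusions) <- paste0("F", vapply(rtResults,
                                          function(r) r$task$i, 0L))
  folds <- data.frame(summ$selection,
                      testAccuracy = unname(tvals))
  agg <- aggregateTestStats(tvals, confidence)
  avg <- averageConfusion(confusions)
  new("BenchmarkReport",
      folds = folds, trials = trials, cvMeans = summ$cvMeans,
      aggregate = c(agg, list(confusion_mean = avg$mean,
                              confusion_sd = avg$sd)),
      confusions = confusions,
      meta = list(k = k, n = n, level = assignment@level, seed = seed,
                  epochs = epochs, g = g,
                  cv_tasks = nrow(cvTasks), retrain_tasks = nrow(retrain),
                  elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))))
}

#' Run the deployment workflow
#'
#' Plain k-fold cross-validation over the full dataset for every
#' configuration (\eqn{kn} tasks, each training on k-1 folds — one more
#' than the nested engine's validation tasks use), selection of the single
#' best configuration by unrounded mean validation accuracy (lowest index
#' on ties), and training of the production model on every record. The
#' production model is never evaluated on held-out data here: its test
#' performance is unknown by construction, and the report says so rather
#' than fabricating a score.
#'
#' @inheritParams runNachos
#' @return a [DeploymentReport-class].
#' @examples
#' ds <- replayStudy("oct_dachos", algorithm = "dachos")
#' ds@jStar  # 2
#' @export
runDachos <- function(manifest, assignment, configs, backend, g = 1L,
                      seed = 0L, epochs = NULL, store = NULL) {
  audit <- auditAssignment(assignment, manifest)
  if (!audit$pass)
    stop("invalid assignment: ",
         paste(unique(audit$violations$rule), collapse = ", "))
  k <- foldCount(assignment)
  n <- nrow(configs)
  if (!n) stop("configs must be non-empty")
  epochs <- .defaultEpochs(backend, epochs)
  exec <- .engineExecutor(manifest, assignment, configs, backend, seed,
                          epochs)
  cvTasks <- enumerateDachosTasks(k, n)
  cvResults <- runTasks(cvTasks, g = g, execute = exec, store = store)
  validation <- do.call(rbind, lapply(cvResults, function(r)
    data.frame(j = r$task$j, m = r$task$m, accuracy = r$accuracy)))
  rownames(validation) <- NULL
  agg <- stats::aggregate(accuracy ~ j, data = validation, FUN = mean)
  agg <- agg[order(agg$j), ]
  jStar <- .selectBest(agg$accuracy, agg$j)
  deploy <- data.frame(kind = "deploy", i = NA_integer_, j = jStar,
                       m = NA_integer_, stringsAsFactors = FALSE)
  deploy$id <- taskId("deploy", NA, jStar, NA)
  dep <- runTasks(deploy, g = 1L, execute = exec, store = store)[[1]]
  names(agg)[names(agg) == "accuracy"] <- "meanValAccuracy"
  new("DeploymentReport",
      validation = validation, cvMeans = agg, jStar = as.integer(jStar),
      finalModel = dep$model,
      meta = list(k = k, n = n, seed = seed, epochs = epochs, g = g,
                  cv_tasks = nrow(cvTasks),
                  test_performance = "unknown (no held-out data)"))
}

# ---- report accessors and display ----------------------------------------

#' @rdname BenchmarkReport-class
#' @export
setMethod("aggregateStats", "BenchmarkReport", function(x) x@aggregate)

#' @rdname BenchmarkReport-class
#' @export
setMethod("foldSummary", "BenchmarkReport", function(x) x@folds)

#' @rdname BenchmarkReport-class
#' @export
setMethod("selectedConfig", "BenchmarkReport",
          function(x) x@folds$jStar)

#' @rdname DeploymentReport-class
#' @aliases aggregateStats,DeploymentReport-method
#' @param x a \code{DeploymentReport}.
#' @export
setMethod("selectedConfig", "DeploymentReport", function(x) x@jStar)

#' @rdname DeploymentReport-class
#' @export
setMethod("foldSummary", "DeploymentReport", function(x) x@cvMeans)

setMethod("show", "BenchmarkReport", function(object) {
  a <- object@aggregate
  cat(sprintf("BenchmarkReport: k = %d folds, n = %d configurations (level '%s')\n",
              object@meta$k, object@meta$n, object@meta$level))
  f <- object@folds
  cat("  per-fold selections:\n")
  for (r in seq_len(nrow(f)))
    cat(sprintf("    F%d: h%d (cv %.2f) -> test %.2f\n", f$i[r],
                f$jStar[r], f$cvAccuracy[r], f$testAccuracy[r]))
  cat(sprintf("  test accuracy %.2f +/- %.2f (SE); SD %.2f; %d%% CI [%.2f, %.2f]\n",
              a$mean, a$se, a$sd, round(100 * a$level), a$ci[1], a$ci[2]))
})

setMethod("show", "DeploymentReport", function(object) {
  cat(sprintf("DeploymentReport: k = %d folds, n = %d configurations\n",
              object@meta$k, object@meta$n))
  m <- object@cvMeans
  for (r in seq_len(nrow(m)))
    cat(sprintf("    h%d: cv %.2f%s\n", m$j[r], m$meanValAccuracy[r],
                if (m$j[r] == object@jStar) "  <- selected" else ""))
  cat("  production model trained on the full dataset;",
      "test performance unknown (no held-out data).\n")
})

#' Write engine reports to disk
#'
#' Writes the per-task trial CSV (i, j, m, accuracy), the per-fold summary
#' CSV (selection and test accuracy per test fold), and the aggregate JSON
#' (mean, sd, se, ci and the average confusion matrix).
#'
#' @param report a [BenchmarkReport-class] or [DeploymentReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (is(report, "BenchmarkReport")) {
    p1 <- file.path(dir, "trials.csv")
    utils::write.csv(report@trials, p1, row.names = FALSE)
    p2 <- file.path(dir, "fold_summary.csv")
    utils::write.csv(report@folds, p2, row.names = FALSE)
    a <- report@aggregate
    p3 <- file.path(dir, "aggregate.json")
    jsonlite::write_json(list(
      mean = a$mean, sd = a$sd, se = a$se, ci = a$ci, level = a$level,
      k = a$k, confusion_mean = a$confusion_mean,
      confusion_sd = a$confusion_sd), p3, auto_unbox = TRUE, digits = NA)
    paths <- c(p1, p2, p3)
  } else {
    p1 <- file.path(dir, "validation.csv")
    utils::write.csv(report@validation, p1, row.names = FALSE)
    p2 <- file.path(dir, "cv_means.csv")
    utils::write.csv(report@cvMeans, p2, row.names = FALSE)
    p3 <- file.path(dir, "selection.json")
    jsonlite::write_json(list(jStar = report@jStar, meta = report@meta),
                         p3, auto_unbox = TRUE, digits = NA)
    paths <- c(p1, p2, p3)
  }
  invisible(paths)
}
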