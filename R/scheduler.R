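# Manager-worker task scheduler with checkpoint-based fault tolerance.
#
# Transport: local forked worker processes (parallel::mcparallel) driven by
# a manager loop implementing the request/assign/complete contract — an idle
# worker slot receives the next unassigned task; a finished task frees its
# slot immediately. g = 1 runs sequentially in-process. The contract is
# transport-agnostic: any point-to-point message layer with the same three
# messages could replace the fork-based pool.
#
# Checkpoint store layout (one directory):
#   <id>.meta.json    task identity, attempts, last completed epoch, status
#   <id>.model.rds    the latest model checkpoint (at most one per task;
#                     replaced every epoch, deleted on completion)
#   <id>.result.rds   the task result, written once on completion
#   events.log        manager-side structured log (start/finish/skip lines)
# Metadata writes are atomic (tempfile + rename) so a crash never leaves a
# truncated record.

#' Create or open a checkpoint store
#'
#' @param dir directory to hold per-task metadata, model checkpoints and
#'   results; created if needed.
#' @return an object of class \code{checkpoint_store}.
#' @export
checkpointStore <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structure(list(dir = dir), class = "checkpoint_store")
}

.ckptPath <- function(store, id, what)
  file.path(store$dir, paste0(id, ".", what))

.ckptReadMeta <- function(store, id) {
  p <- .ckptPath(store, id, "meta.json")
  if (!file.exists(p)) return(NULL)
  tryCatch(jsonlite::read_json(p, simplifyVector = TRUE),
           error = function(e) NULL)
}

.ckptWriteMeta <- function(store, id, meta) {
  p <- .ckptPath(store, id, "meta.json")
  tmp <- tempfile(tmpdir = store$dir)
  jsonlite::write_json(meta, tmp, auto_unbox = TRUE, null = "null")
  file.rename(tmp, p)
  invisible(NULL)
}

.ckptLog <- function(store, event, id, worker = NA) {
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), event, id,
                  worker)
  cat(line, "\n", sep = "", file = file.path(store$dir, "events.log"),
      append = TRUE)
}

#' Checkpoint hook for one task
#'
#' Returns a \code{function(epoch, state)} suitable as a backend's
#' \code{onEpochEnd}: it replaces the task's single model checkpoint
#' atomically and records the epoch in the metadata checkpoint. The
#' previous model checkpoint is overwritten, so store usage stays at one
#' model file per in-flight task regardless of epoch count.
#'
#' @param store a [checkpointStore()].
#' @param task a task row (list with id, i, j, m).
#' @export
epochCheckpointer <- function(store, task) {
  force(store); force(task)
  function(epoch, state) {
    mp <- .ckptPath(store, task$id, "model.rds")
    tmp <- tempfile(tmpdir = store$dir)
    saveRDS(state, tmp)
    file.rename(tmp, mp)
    meta <- .ckptReadMeta(store, task$id)
    if (is.null(meta))
      meta <- list(id = task$id, i = task$i, j = task$j, m = task$m,
                   attempts = 1L)
    meta$status <- "in_progress"
    meta$epoch <- epoch
    .ckptWriteMeta(store, task$id, meta)
  }
}

.taskRow <- function(tasks, r) {
  row <- as.list(tasks[r, , drop = FALSE])
  lapply(row, function(x) x[[1]])
}

# Prepare one task against the store: returns list(action, resume, result)
.ckptPlan <- function(store, task) {
  if (is.null(store)) return(list(action = "run", resume = NULL))
  meta <- .ckptReadMeta(store, task$id)
  if (is.null(meta)) return(list(action = "run", resume = NULL))
  if (identical(meta$status, "complete")) {
    rp <- .ckptPath(store, task$id, "result.rds")
    if (file.exists(rp))
      return(list(action = "skip", result = readRDS(rp)))
    return(list(action = "run", resume = NULL))
  }
  mp <- .ckptPath(store, task$id, "model.rds")
  if (file.exists(mp) && !is.null(meta$epoch))
    return(list(action = "resume",
                resume = list(epoch = as.integer(meta$epoch),
                              state = readRDS(mp))))
  list(action = "run", resume = NULL)
}

.ckptComplete <- function(store, task, result, finalEpoch = NA) {
  if (is.null(store)) return(invisible(NULL))
  saveRDS(result, .ckptPath(store, task$id, "result.rds"))
  meta <- .ckptReadMeta(store, task$id)
  if (is.null(meta))
    meta <- list(id = task$id, i = task$i, j = task$j, m = task$m,
                 attempts = 1L)
  meta$status <- "complete"
  if (!is.na(finalEpoch)) meta$epoch <- finalEpoch
  .ckptWriteMeta(store, task$id, meta)
  unlink(.ckptPath(store, task$id, "model.rds"))
  invisible(NULL)
}

.ckptStart <- function(store, task) {
  if (is.null(store)) return(invisible(NULL))
  meta <- .ckptReadMeta(store, task$id)
  if (is.null(meta))
    meta <- list(id = task$id, i = task$i, j = task$j, m = task$m,
                 attempts = 0L)
  meta$attempts <- (if (is.null(meta$attempts)) 0L else meta$attempts) + 1L
  if (is.null(meta$status)) meta$status <- "in_progress"
  .ckptWriteMeta(store, task$id, meta)
  invisible(NULL)
}

#' Run tasks through the manager-worker scheduler
#'
#' Executes every task exactly once via dynamic assignment: an idle worker
#' slot receives the next unassigned task, so long tasks do not block short
#' ones. The returned result map is keyed by task id and is independent of
#' the worker count and of completion order. With a checkpoint store
#' attached, completed tasks found in the store are skipped (their stored
#' results are returned), partially trained tasks resume from their last
#' model checkpoint, and every task's progress is checkpointed for crash
#' recovery.
#'
#' @param tasks data.frame of tasks with a unique \code{id} column (plus
#'   \code{i}, \code{j}, \code{m} columns for engine tasks).
#' @param g worker count (>= 1); g > 1 uses forked worker processes.
#' @param execute \code{function(task, resume, onEpochEnd)} returning the
#'   task result; \code{resume} is NULL or \code{list(epoch, state)};
#'   \code{onEpochEnd} is the checkpoint hook (or NULL without a store).
#'   Must be deterministic given the task.
#' @param store optional [checkpointStore()].
#' @return named list of results (one per task id), with attribute
#'   \code{"schedule"}: a data.frame logging (seq, id, worker, skipped).
#' @export
runTasks <- function(tasks, g = 1L, execute, store = NULL) {
  if (anyDuplicated(tasks$id))
    stop("invalid task list: duplicate task identities")
  g <- as.integer(g)
  results <- vector("list", nrow(tasks))
  names(results) <- tasks$id
  sched <- data.frame(seq = integer(), id = character(),
                      worker = integer(), skipped = logical(),
                      stringsAsFactors = FALSE)
  pending <- seq_len(nrow(tasks))
  seqno <- 0L
  # resolve skips and build the run list up front
  plans <- vector("list", nrow(tasks))
  torun <- integer()
  for (r in pending) {
    task <- .taskRow(tasks, r)
    plans[[r]] <- .ckptPlan(store, task)
    if (plans[[r]]$action == "skip") {
      results[[r]] <- plans[[r]]$result
      seqno <- seqno + 1L
      sched <- rbind(sched, data.frame(seq = seqno, id = task$id,
                                       worker = NA_integer_,
                                       skipped = TRUE))
      if (!is.null(store)) .ckptLog(store, "skip", task$id)
    } else torun <- c(torun, r)
  }
  runOne <- function(r, worker) {
    task <- .taskRow(tasks, r)
    .ckptStart(store, task)
    if (!is.null(store))
      .ckptLog(store, if (is.null(plans[[r]]$resume)) "start" else "resume",
               task$id, worker)
    hook <- if (!is.null(store)) epochCheckpointer(store, task) else NULL
    res <- execute(task, plans[[r]]$resume, hook)
    .ckptComplete(store, task, res)
    if (!is.null(store)) .ckptLog(store, "finish", task$id, worker)
    res
  }
  if (g <= 1L || length(torun) <= 1L) {
    for (r in torun) {
      seqno <- seqno + 1L
      sched <- rbind(sched, data.frame(seq = seqno, id = tasks$id[r],
                                       worker = 1L, skipped = FALSE))
      results[[r]] <- runOne(r, 1L)
    }
  } else {
    slots <- vector("list", g)       # running mcparallel jobs per slot
    slotTask <- rep(NA_integer_, g)
    queue <- torun
    while (length(queue) || any(!vapply(slots, is.null, TRUE))) {
      free <- which(vapply(slots, is.null, TRUE))
      while (length(free) && length(queue)) {
        w <- free[1]; free <- free[-1]
        r <- queue[1]; queue <- queue[-1]
        seqno <- seqno + 1L
        sched <- rbind(sched, data.frame(seq = seqno, id = tasks$id[r],
                                         worker = w, skipped = FALSE))
        slots[[w]] <- parallel::mcparallel(runOne(r, w))
        slotTask[w] <- r
      }
      running <- slots[!vapply(slots, is.null, TRUE)]
      done <- parallel::mccollect(running, wait = FALSE, timeout = 0.02)
      if (!is.null(done)) {
        for (pid in names(done)) {
          w <- which(vapply(slots, function(s)
            !is.null(s) && as.character(s$pid) == pid, TRUE))
          if (!length(w)) next
          val <- done[[pid]]
          if (is.null(val)) next  # not actually finished yet
          if (inherits(val, "try-error"))
            stop("task '", tasks$id[slotTask[w]], "' failed: ",
                 attr(val, "condition")$message)
          results[[slotTask[w]]] <- val
          slots[w] <- list(NULL)
          slotTask[w] <- NA_integer_
        }
      }
    }
  }
  failed <- vapply(results, is.null, TRUE)
  if (any(failed))
    stop("tasks did not complete: ",
         paste(names(results)[failed], collapse = ", "))
  attr(results, "schedule") <- sched
  results
}

#' Resume an interrupted run
#'
#' Re-dispatches the full task list against an existing checkpoint store:
#' completed tasks are skipped (their stored results are reused, leaving
#' their execution counters untouched), in-progress tasks resume from their
#' last model checkpoint and epoch, and untouched tasks run fresh. For
#' deterministic backends the final result map equals that of an
#' uninterrupted run.
#'
#' @inheritParams runTasks
#' @export
resumeRun <- function(tasks, g = 1L, execute, store) {
  if (is.null(store)) stop("resume requires a checkpoint store")
  known <- sub("\\.meta\\.json$", "",
               list.files(store$dir, pattern = "\\.meta\\.json$"))
  stray <- setdiff(known, tasks$id)
  if (length(stray))
    stop("incompatible checkpoint store: unknown task(s) ",
         paste(utils::head(stray, 3), collapse = ", "))
  runTasks(tasks, g = g, execute = execute, store = store)
}

#' Inspect a checkpoint store
#'
#' @param store a [checkpointStore()].
#' @return data.frame(id, status, epoch, attempts, has_model, has_result).
#' @export
storeStatus <- function(store) {
  ids <- sub("\\.meta\\.json$", "",
             list.files(store$dir, pattern = "\\.meta\\.json$"))
  rows <- lapply(ids, function(id) {
    meta <- .ckptReadMeta(store, id)
    data.frame(id = id,
               status = if (is.null(meta$status)) NA_character_ else
                 meta$status,
               epoch = if (is.null(meta$epoch)) NA_integer_ else
                 as.integer(meta$epoch),
               attempts = if (is.null(meta$attempts)) NA_integer_ else
                 as.integer(meta$attempts),
               has_model = file.exists(.ckptPath(store, id, "model.rds")),
               has_result = file.exists(.ckptPath(store, id, "result.rds")),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(id = character(), status = character(),
                      epoch = integer(), attempts = integer(),
                      has_model = logical(), has_result = logical()))
  do.call(rbind, rows)
}
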