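mockTasks <- function(k = 3, n = 2) enumerateNcvTasks(k, n)

echoExec <- function(task, resume, hook)
  list(id = task$id, accuracy = gridAccuracy(task$i, task$j, task$m))

test_that("duplicate task identities are rejected", {
  tasks <- mockTasks()
  expect_error(runTasks(rbind(tasks, tasks[1, ]), 1, echoExec),
               "invalid task list")
})

test_that("a single worker executes tasks in list order", {
  tasks <- mockTasks()
  res <- runTasks(tasks, 1, echoExec)
  sched <- attr(res, "schedule")
  expect_identical(sched$id, tasks$id)
  expect_identical(names(res), tasks$id)
})

test_that("result maps are independent of the worker count", {
  tasks <- enumerateNcvTasks(4, 3)
  r1 <- runTasks(tasks, 1, echoExec)
  r4 <- runTasks(tasks, 4, echoExec)
  attr(r1, "schedule") <- NULL
  attr(r4, "schedule") <- NULL
  expect_identical(r1, r4)
})

test_that("unequal task durations complete with overlapping execution", {
  tasks <- data.frame(kind = "cv", i = 0L, j = 0:5, m = 1L,
                      id = paste0("t", 0:5))
  slowExec <- function(task, resume, hook) {
    Sys.sleep(if (task$id == "t0") 0.6 else 0.05)
    list(id = task$id)
  }
  t0 <- Sys.time()
  res <- runTasks(tasks, 3, slowExec)
  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_length(res, 6L)
  # sequential would need >= 0.85 s; dynamic assignment overlaps the
  # short tasks with the long one
  expect_lt(wall, 0.85)
  sched <- attr(res, "schedule")
  expect_gt(length(unique(sched$worker)), 1L)
})

test_that("a crash mid-run resumes with exactly-once completion", {
  tasks <- mockTasks(3, 2)  # 12 tasks
  store <- checkpointStore(withr::local_tempdir())
  cnt <- new.env(); cnt$n <- 0L
  crashExec <- function(task, resume, hook) {
    cnt$n <- cnt$n + 1L
    if (cnt$n == 6L) stop("simulated crash")
    echoExec(task, resume, hook)
  }
  expect_error(runTasks(tasks, 1, crashExec, store = store),
               "simulated crash")
  done_before <- sum(storeStatus(store)$status == "complete")
  expect_equal(done_before, 5L)
  res <- resumeRun(tasks, 1, function(task, resume, hook) {
    cnt$n <- cnt$n + 1L
    echoExec(task, resume, hook)
  }, store = store)
  expect_length(res, 12L)
  # 5 before the crash + 1 crashed attempt + 7 fresh = 13 executions
  expect_equal(cnt$n, 13L)
  st <- storeStatus(store)
  expect_true(all(st$status == "complete"))
  # completion count is 1 everywhere: only the crashed task has 2 attempts
  expect_equal(sum(st$attempts == 2L), 1L)
  expect_equal(sum(st$attempts == 1L), 11L)
  # results equal an uninterrupted run
  clean <- runTasks(tasks, 1, echoExec)
  expect_equal(lapply(res, `[[`, "accuracy"),
               lapply(clean, `[[`, "accuracy")[names(res)])
})

test_that("relaunch over a fully complete store executes nothing", {
  tasks <- mockTasks(2, 2)
  store <- checkpointStore(withr::local_tempdir())
  runTasks(tasks, 1, echoExec, store = store)
  cnt <- new.env(); cnt$n <- 0L
  res <- resumeRun(tasks, 1, function(task, resume, hook) {
    cnt$n <- cnt$n + 1L
    echoExec(task, resume, hook)
  }, store = store)
  expect_equal(cnt$n, 0L)
  expect_length(res, 4L)
  expect_true(all(attr(res, "schedule")$skipped))
})

test_that("a mid-epoch crash resumes from the checkpointed epoch", {
  m <- refManifest(seed = 8, per = 6)
  fa <- assignFolds(m, 4, "dataset", seed = 1)
  cfg <- sampleConfigs(defaultSearchSpace(), 1, seed = 1)
  be <- referenceBackend()
  task <- list(kind = "cv", i = 0L, j = 0L, m = 1L, id = "ct0_h0_val1")
  tasks <- data.frame(kind = "cv", i = 0L, j = 0L, m = 1L,
                      id = "ct0_h0_val1", stringsAsFactors = FALSE)
  store <- checkpointStore(withr::local_tempdir())
  mkExec <- function(crashAt = NA) function(task, resume, hook) {
    wrapped <- function(e, s) {
      hook(e, s)
      if (!is.na(crashAt) && e == crashAt) stop("power loss")
    }
    executeTask(m, fa, cfg, be, task, seed = 1, epochs = 5,
                resume = resume, onEpochEnd = wrapped)
  }
  expect_error(runTasks(tasks, 1, mkExec(crashAt = 3), store = store),
               "power loss")
  st <- storeStatus(store)
  expect_equal(st$status, "in_progress")
  expect_equal(st$epoch, 3L)
  expect_true(st$has_model)
  epochsRun <- integer()
  res <- resumeRun(tasks, 1, function(task, resume, hook) {
    executeTask(m, fa, cfg, be, task, seed = 1, epochs = 5,
                resume = resume,
                onEpochEnd = function(e, s) { epochsRun <<- c(epochsRun, e)
                  hook(e, s) })
  }, store = store)
  expect_identical(epochsRun, 4:5)  # epochs 1-3 are never retrained
  straight <- executeTask(m, fa, cfg, be, task, seed = 1, epochs = 5)
  expect_identical(res[[1]]$confusion, straight$confusion)
  expect_equal(res[[1]]$accuracy, straight$accuracy)
})

test_that("at most one model checkpoint per task is ever on disk", {
  m <- refManifest(seed = 9, per = 4)
  fa <- assignFolds(m, 4, "dataset", seed = 1)
  cfg <- sampleConfigs(defaultSearchSpace(), 1, seed = 1)
  store <- checkpointStore(withr::local_tempdir())
  tasks <- data.frame(kind = "cv", i = 0L, j = 0L, m = 1L, id = "ct0_h0_val1",
                      stringsAsFactors = FALSE)
  maxModels <- 0L
  runTasks(tasks, 1, function(task, resume, hook) {
    executeTask(m, fa, cfg, referenceBackend(), task, seed = 1, epochs = 6,
                resume = resume, onEpochEnd = function(e, s) {
                  hook(e, s)
                  nmod <- length(list.files(store$dir,
                                            pattern = "\\.model\\.rds$"))
                  maxModels <<- max(maxModels, nmod)
                })
  }, store = store)
  expect_equal(maxModels, 1L)
  # deleted on completion; the result is retained
  expect_equal(length(list.files(store$dir, pattern = "\\.model\\.rds$")), 0L)
  expect_true(storeStatus(store)$has_result)
})

test_that("a checkpoint store from a different task list is refused", {
  store <- checkpointStore(withr::local_tempdir())
  runTasks(mockTasks(2, 1), 1, echoExec, store = store)
  expect_error(resumeRun(enumerateDachosTasks(2, 1), 1, echoExec,
                         store = store),
               "incompatible checkpoint store")
})

test_that("a full engine run dispatches k(k-1)n + k tasks", {
  m <- tinyManifest(groups = 4)
  fa <- assignFolds(m, 4, "dataset", seed = 1)
  store <- checkpointStore(withr::local_tempdir())
  n <- 3
  runNachos(m, fa, sampleConfigs(defaultSearchSpace(), n, 1),
            mockBackend(gridAccuracy), seed = 1, epochs = 1,
            store = store)
  st <- storeStatus(store)
  expect_equal(nrow(st), 4 * 3 * n + 4)
  expect_true(all(st$attempts == 1L))
})
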