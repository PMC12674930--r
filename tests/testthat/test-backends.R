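# backend contract suite: determinism under a fixed seed, resume
# equivalence, confusion totals

test_that("reference backend training is deterministic under a fixed seed", {
  m <- refManifest(seed = 2)
  rec <- records(m)
  spec <- trainSpec(config = sampleConfigs(defaultSearchSpace(), 1, 1)[1, ],
                    epochs = 3, seed = 42,
                    task = list(kind = "cv", i = 0L, j = 0L, m = 1L),
                    classes = classNames(m))
  be <- referenceBackend()
  s1 <- trainModel(be, rec, payloads(m), spec)
  s2 <- trainModel(be, rec, payloads(m), spec)
  expect_identical(serialize(s1@params, NULL), serialize(s2@params, NULL))
})

test_that("training resumed at an intermediate epoch equals straight-through training", {
  m <- refManifest(seed = 3)
  rec <- records(m)
  be <- referenceBackend()
  mkspec <- function(resumeFrom = NULL)
    trainSpec(config = NULL, epochs = 5, seed = 7,
              task = list(kind = "cv", i = 0L, j = 0L, m = 1L),
              classes = classNames(m), resumeFrom = resumeFrom)
  snaps <- list()
  full <- trainModel(be, rec, payloads(m), mkspec(),
                     onEpochEnd = function(e, s) snaps[[e]] <<- s)
  resumed <- trainModel(be, rec, payloads(m),
                        mkspec(resumeFrom = list(epoch = 3L,
                                                 state = snaps[[3]])))
  expect_identical(serialize(full@params, NULL),
                   serialize(resumed@params, NULL))
  expect_equal(resumed@provenance$epochs, 5L)
})

test_that("epoch hook fires once per epoch with increasing epoch numbers", {
  m <- refManifest(seed = 4, per = 4)
  seen <- integer()
  trainModel(referenceBackend(), records(m), payloads(m),
             trainSpec(epochs = 4, seed = 1, classes = classNames(m)),
             onEpochEnd = function(e, s) seen <<- c(seen, e))
  expect_identical(seen, 1:4)
})

test_that("reference backend learns well-separated classes", {
  m <- refManifest(seed = 5, per = 40, classSignal = 3)
  rec <- records(m)
  train <- rec[rec$dataset != "dataset4", ]
  test <- rec[rec$dataset == "dataset4", ]
  model <- trainModel(referenceBackend(), train, payloads(m),
                      trainSpec(epochs = 8, seed = 1,
                                classes = classNames(m)))
  cm <- evaluateModel(referenceBackend(), model, test, payloads(m))
  expect_equal(sum(cm), nrow(test))
  expect_gt(accuracy(cm), 0.9)
})

test_that("degenerate and malformed inputs raise the documented errors", {
  m <- refManifest(seed = 6, per = 4)
  rec <- records(m)
  one <- rec[rec$label == "a", ]
  expect_error(trainModel(referenceBackend(), one, payloads(m),
                          trainSpec(epochs = 1, seed = 1)),
               "degenerate labels")
  expect_error(trainModel(referenceBackend(), rec, list(),
                          trainSpec(epochs = 1, seed = 1,
                                    classes = classNames(m))),
               "payload error")
  model <- trainModel(referenceBackend(), rec, payloads(m),
                      trainSpec(epochs = 1, seed = 1,
                                classes = classNames(m)))
  expect_error(evaluateModel(referenceBackend(), model, rec[0, ],
                             payloads(m)), "empty")
  bad <- rec[1, ]; bad$label <- "weird"
  expect_error(evaluateModel(referenceBackend(), model, bad, payloads(m)),
               "label mismatch")
})

test_that("replay training is a no-op stub tagged with the task identity", {
  tabs <- makeReplayTables("xray_ncv")
  be <- replayBackend(tabs$cv, tabs$test, classes = tabs$classes)
  st <- trainModel(be, data.frame(), list(),
                   trainSpec(task = list(kind = "cv", i = 1L, j = 2L,
                                         m = 3L)))
  expect_identical(st@provenance$task$i, 1L)
  cm <- evaluateModel(be, st, data.frame(), list())
  expect_equal(sum(cm), 100L)
  row <- tabs$cv[tabs$cv$i == 1 & tabs$cv$j == 2 & tabs$cv$m == 3, ]
  expect_equal(accuracy(cm), row$accuracy)
})

test_that("replay lookups fall back to per-cell means and fail loudly otherwise", {
  tabs <- makeReplayTables("oct_ncv")  # per-cell means, m = NA
  be <- replayBackend(tabs$cv, tabs$test, classes = tabs$classes)
  st <- trainModel(be, data.frame(), list(),
                   trainSpec(task = list(kind = "cv", i = 0L, j = 5L,
                                         m = 7L)))
  expect_equal(accuracy(evaluateModel(be, st, data.frame(), list())), 0.93)
  st2 <- trainModel(be, data.frame(), list(),
                    trainSpec(task = list(kind = "cv", i = 0L, j = 99L,
                                          m = 1L)))
  expect_error(evaluateModel(be, st2, data.frame(), list()), "no entry")
})

test_that("model states round-trip through serialization bit-identically", {
  m <- refManifest(seed = 7, per = 4)
  st <- trainModel(referenceBackend(), records(m), payloads(m),
                   trainSpec(epochs = 2, seed = 9,
                             classes = classNames(m)))
  p <- withr::local_tempfile(fileext = ".rds")
  saveRDS(st, p)
  expect_identical(serialize(readRDS(p)@params, NULL),
                   serialize(st@params, NULL))
})
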