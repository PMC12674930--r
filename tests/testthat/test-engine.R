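test_that("nested-CV task enumeration matches the k(k-1)n law", {
  expect_equal(nrow(enumerateNcvTasks(4, 9)), 108L)
  expect_equal(nrow(enumerateNcvTasks(10, 9)), 810L)
  t2 <- enumerateNcvTasks(2, 1)
  expect_equal(nrow(t2), 2L)
  expect_equal(t2$i, c(0L, 1L))
  expect_equal(t2$m, c(1L, 0L))
  expect_equal(t2$id, c("ct0_h0_val1", "ct1_h0_val0"))
  expect_error(enumerateNcvTasks(1, 9), "invalid dimensions")
  expect_error(enumerateNcvTasks(4, 0), "invalid dimensions")
})

test_that("full-dataset CV enumeration matches the kn law", {
  expect_equal(nrow(enumerateDachosTasks(4, 9)), 36L)
  expect_equal(nrow(enumerateDachosTasks(10, 9)), 90L)
  expect_equal(nrow(enumerateDachosTasks(2, 1)), 2L)
  expect_true(all(is.na(enumerateDachosTasks(3, 2)$i)))
})

test_that("inner-CV summary selects by unrounded means with lowest-index tie-break", {
  tabs <- makeReplayTables("xray_ncv")
  trials <- tabs$cv
  summ <- summarizeCv(trials, 4, 9)
  expect_equal(summ$selection$jStar, c(2L, 1L, 8L, 5L))
  expect_equal(round(summ$selection$cvAccuracy[1], 2), 0.72)
  # each mean is over exactly k-1 validation accuracies
  expect_equal(nrow(summ$cvMeans), 36L)
  # all-equal accuracies: the lowest configuration index wins
  flat <- enumerateNcvTasks(3, 4)
  flat$accuracy <- 0.5
  expect_equal(summarizeCv(flat, 3, 4)$selection$jStar, rep(0L, 3))
})

test_that("missing triples are reported by identity", {
  tr <- enumerateNcvTasks(3, 2)
  tr$accuracy <- 0.5
  expect_error(summarizeCv(tr[-5, ], 3, 2), "incomplete results")
  expect_error(summarizeCv(rbind(tr, tr[1, ]), 3, 2), "incomplete")
})

test_that("the engine equals a brute-force re-implementation on a mock backend", {
  for (k in c(3, 4)) {
    n <- 5
    m <- tinyManifest(groups = k)
    fa <- assignFolds(m, k, "dataset", seed = 1)
    cfg <- sampleConfigs(defaultSearchSpace(), n, seed = 1)
    rep <- runNachos(m, fa, cfg, mockBackend(gridAccuracy), seed = 1,
                     epochs = 1)
    bf <- bruteForceNcv(gridAccuracy, k, n)
    expect_equal(foldSummary(rep)$jStar, bf$selection)
    expect_equal(foldSummary(rep)$cvAccuracy, bf$cvAccuracy)
    expect_equal(foldSummary(rep)$testAccuracy, bf$t)
    a <- aggregateStats(rep)
    expect_equal(a$mean, bf$mean)
    expect_equal(a$sd, bf$sd)
    expect_equal(a$se, bf$se)
  }
})

test_that("no test-fold record enters training or validation in its CT iteration", {
  m <- tinyManifest(groups = 4, per = 2)
  fa <- assignFolds(m, 4, "dataset", seed = 2)
  be <- mockBackend(gridAccuracy)
  runNachos(m, fa, sampleConfigs(defaultSearchSpace(), 2, 1), be,
            seed = 1, epochs = 1)
  folds <- split(names(foldOf(fa)), foldOf(fa))
  calls <- be@trace$calls
  expect_gt(length(calls), 0L)
  for (cl in calls) {
    task <- cl$task
    if (is.na(task$i)) next
    test_ids <- folds[[as.character(task$i)]]
    expect_length(intersect(test_ids, cl$ids), 0L)
    if (task$kind == "cv") {
      # validation fold is excluded from training too
      expect_length(intersect(folds[[as.character(task$m)]], cl$ids), 0L)
    }
  }
})

test_that("k = 2 reduces the inner CV to a single validation fold", {
  m <- tinyManifest(groups = 2)
  fa <- assignFolds(m, 2, "dataset", seed = 1)
  rep <- runNachos(m, fa, sampleConfigs(defaultSearchSpace(), 3, 1),
                   mockBackend(gridAccuracy), seed = 1, epochs = 1)
  # cross-validation accuracy equals the single validation accuracy
  for (r in seq_len(nrow(foldSummary(rep)))) {
    i <- foldSummary(rep)$i[r]; j <- foldSummary(rep)$jStar[r]
    expect_equal(foldSummary(rep)$cvAccuracy[r],
                 gridAccuracy(i, j, 1 - i))
  }
})

test_that("an assignment failing its audit is rejected", {
  m <- tinyManifest(groups = 4)
  fa <- assignFolds(m, 4, "dataset", seed = 1)
  f <- foldOf(fa)
  f[1] <- (f[1] + 1L) %% 4L  # break group integrity
  bad <- new("FoldAssignment", k = 4L, level = "dataset", foldOf = f,
             seed = 1L)
  expect_error(runNachos(m, bad, sampleConfigs(defaultSearchSpace(), 1, 1),
                         mockBackend(gridAccuracy)),
               "invalid assignment")
})

test_that("test-accuracy aggregation reproduces the published summaries", {
  a <- aggregateTestStats(c(0.79, 0.71, 0.69, 0.82))
  expect_equal(round(a$mean, 2), 0.75)
  expect_equal(round(a$sd, 2), 0.06)
  expect_equal(round(a$se, 2), 0.03)
  b <- aggregateTestStats(c(0.73, 0.71, 0.79, 0.75, 0.88, 0.87, 0.94,
                            0.90, 0.96, 0.86))
  expect_equal(round(b$mean, 2), 0.84)
  expect_equal(round(b$sd, 2), 0.09)
  expect_equal(round(b$se, 2), 0.03)
  z <- aggregateTestStats(c(0.5, 0.5, 0.5))
  expect_equal(z$sd, 0)
  expect_equal(z$se, 0)
  expect_equal(diff(z$ci), 0)
  expect_error(aggregateTestStats(0.5), "insufficient folds")
})

test_that("SE = SD / sqrt(k) holds on every aggregate", {
  set.seed(31)
  for (k in c(3, 4, 10)) {
    t <- runif(k, 0.5, 1)
    a <- aggregateTestStats(t)
    expect_equal(a$se, a$sd / sqrt(k))
  }
})

test_that("engine results are invariant to scheduler worker count", {
  r1 <- replayStudy("xray_ncv", g = 1)
  r4 <- replayStudy("xray_ncv", g = 4)
  expect_equal(foldSummary(r1), foldSummary(r4))
  expect_equal(aggregateStats(r1)$mean, aggregateStats(r4)$mean)
  expect_equal(r1@trials, r4@trials)
})
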