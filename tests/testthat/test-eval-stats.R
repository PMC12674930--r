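test_that("accuracy is the trace over the total", {
  cm <- matrix(c(3L, 1L, 2L, 2L), 2, 2,
               dimnames = list(c("neg", "pos"), c("neg", "pos")))
  expect_equal(accuracy(cm), 5 / 8)
  expect_equal(accuracy(diag(c(10L, 7L, 3L))), 1)
  # three classes of 600 with diagonal (454, 512, 543)
  cm3 <- matrix(0L, 3, 3)
  diag(cm3) <- c(454L, 512L, 543L)
  cm3[1, 3] <- 600L - 454L; cm3[2, 1] <- 600L - 512L
  cm3[3, 1] <- 600L - 543L
  expect_equal(accuracy(cm3), (454 + 512 + 543) / 1800)
  expect_error(accuracy(matrix(0, 2, 2)), "empty evaluation")
})

test_that("confusionMatrix rejects labels outside the class set", {
  expect_error(confusionMatrix(c("a", "q"), c("a", "a"), c("a", "b")),
               "label mismatch")
  cm <- confusionMatrix(c("a", "b", "b"), c("a", "b", "a"), c("a", "b"))
  expect_equal(sum(cm), 3L)
})

test_that("confusion averaging gives per-cell means and n-1 SDs", {
  a <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  b <- matrix(c(3, 2, 2, 3), 2, 2, dimnames = dimnames(a))
  avg <- averageConfusion(list(a, b))
  expect_equal(avg$mean, matrix(c(2, 1, 1, 2), 2, 2,
                                dimnames = dimnames(a)))
  expect_equal(avg$sd, matrix(sqrt(2), 2, 2, dimnames = dimnames(a)))
  same <- averageConfusion(list(a, a))
  expect_equal(same$mean, a)
  expect_true(all(same$sd == 0))
  dimnames(b) <- list(c("p", "q"), c("p", "q"))
  expect_error(averageConfusion(list(a, b)), "class mismatch")
})

test_that("confusion averaging equals an independent per-cell loop", {
  set.seed(17)
  dn <- list(c("a", "b", "c"), c("a", "b", "c"))
  cms <- replicate(10, matrix(rpois(9, 20), 3, 3, dimnames = dn),
                   simplify = FALSE)
  avg <- averageConfusion(cms)
  for (r in 1:3) for (cc in 1:3) {
    cell <- vapply(cms, function(m) m[r, cc], 0)
    expect_equal(avg$mean[r, cc], mean(cell))
    expect_equal(avg$sd[r, cc], sd(cell))
  }
  # the mean matrix conserves the per-matrix total
  expect_equal(sum(avg$mean), mean(vapply(cms, sum, 0)))
})

test_that("pooled-SD Cohen's d reproduces the published partition contrasts", {
  expect_equal(round(cohensD(0.811, 0.008, 4, 0.750, 0.061, 4), 2), 1.40)
  expect_equal(round(cohensD(0.809, 0.009, 4, 0.750, 0.061, 4), 2), 1.35)
  expect_equal(cohensD(0.5, 0.1, 4, 0.5, 0.2, 4), 0)
  expect_equal(cohensD(0.8, 0.05, 4, 0.7, 0.02, 6),
               -cohensD(0.7, 0.02, 6, 0.8, 0.05, 4))
  expect_error(cohensD(0.5, 0, 4, 0.6, 0, 4), "degenerate groups")
  expect_error(cohensD(0.5, 0.1, 1, 0.6, 0.1, 4), "n >= 2")
})

test_that("identical accuracies across schemes give F = 0 and d = 0", {
  acc <- list(image = rep(0.8, 10), volume = rep(0.8, 10),
              kidney = rep(0.8, 10))
  cmp <- comparePartitionings(acc)
  expect_equal(cmp$anova$F, 0)
  expect_true(all(cmp$effect_sizes$d == 0))
  expect_equal(cmp$variance_components$treatment, 0)
})

test_that("the ANOVA matches a textbook recomputation and the SS identity", {
  set.seed(23)
  acc <- list(a = rnorm(8, 0.8, 0.05), b = rnorm(8, 0.75, 0.05),
              c = rnorm(8, 0.7, 0.05))
  cmp <- comparePartitionings(acc)
  all_x <- unlist(acc)
  grand <- mean(all_x)
  ssb <- sum(vapply(acc, function(x) length(x) * (mean(x) - grand)^2, 0))
  ssw <- sum(vapply(acc, function(x) sum((x - mean(x))^2), 0))
  sst <- sum((all_x - grand)^2)
  expect_equal(ssb + ssw, sst, tolerance = 1e-12)
  Fref <- (ssb / 2) / (ssw / (24 - 3))
  expect_equal(cmp$anova$F, Fref, tolerance = 1e-10)
  expect_equal(cmp$variance_components$residual, ssw / 21,
               tolerance = 1e-10)
  expect_equal(cmp$variance_components$treatment,
               max((ssb / 2 - ssw / 21) / 8, 0), tolerance = 1e-10)
  # Tukey differences equal pairwise mean differences
  expect_equal(sort(abs(cmp$tukey$diff)),
               sort(abs(c(mean(acc$b) - mean(acc$a),
                          mean(acc$c) - mean(acc$a),
                          mean(acc$c) - mean(acc$b)))))
})

test_that("negative method-of-moments treatment components truncate to zero", {
  set.seed(5)
  base <- rnorm(12, 0.8, 0.1)
  acc <- list(a = base[1:6], b = base[7:12])
  # force nearly identical group means so MSB < MSW
  acc$b <- acc$b - mean(acc$b) + mean(acc$a)
  cmp <- comparePartitionings(acc)
  expect_equal(cmp$variance_components$treatment, 0)
  expect_true(cmp$variance_components$treatment_truncated)
})

test_that("the null type-I error rate of the comparison is near 0.05", {
  set.seed(71)
  reject <- replicate(1000, {
    acc <- list(a = rnorm(4, 0.8, 0.05), b = rnorm(4, 0.8, 0.05),
                c = rnorm(4, 0.8, 0.05))
    comparePartitionings(acc)$anova$p < 0.05
  })
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("published X-ray partition summaries are reconstructed within rounding", {
  acc <- list(image = sampleWithMoments(0.811, 0.008, 4),
              patient = sampleWithMoments(0.809, 0.009, 4),
              dataset = sampleWithMoments(0.750, 0.061, 4))
  expect_equal(mean(acc$image), 0.811)
  expect_equal(sd(acc$image), 0.008)
  cmp <- comparePartitionings(acc)
  expect_lt(abs(cmp$anova$F - 3.70), 0.1)
  expect_equal(round(cmp$variance_components$treatment, 5), 0.00088)
  d <- cmp$effect_sizes
  expect_equal(round(d$d[d$group1 == "image" & d$group2 == "dataset"], 2),
               1.40)
  expect_equal(round(d$d[d$group1 == "patient" & d$group2 == "dataset"], 2),
               1.35)
})
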