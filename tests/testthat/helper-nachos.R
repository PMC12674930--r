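# shared fixtures, all built in code

# tiny grouped manifest: `groups` top-level groups x `classes` x `per`
tinyManifest <- function(groups = 4L, classes = c("a", "b"), per = 3L,
                         level = "dataset") {
  rec <- expand.grid(g = seq_len(groups), cls = classes,
                     r = seq_len(per), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  rec <- data.frame(
    image_id = sprintf("g%d_%s_%d", rec$g, rec$cls, rec$r),
    lvl = sprintf("g%d", rec$g), label = rec$cls,
    stringsAsFactors = FALSE)
  names(rec)[names(rec) == "lvl"] <- level
  dataManifest(rec, hierarchy = c(level, "image"), classNames = classes)
}

# deterministic mock accuracy on a 0.01 grid (exactly representable by the
# synthetic confusion matrices)
gridAccuracy <- function(i, j, m) {
  i2 <- if (is.na(i)) 5L else i
  m2 <- if (is.na(m)) 0L else m
  ((7 * i2 + 13 * j + 3 * m2) %% 41 + 30) / 100
}

# independent straight-line re-implementation of the nested-CV selection and
# aggregation for an accuracy function f(i, j, m)
bruteForceNcv <- function(f, k, n) {
  sel <- integer(k); cvacc <- numeric(k); tvals <- numeric(k)
  for (i in 0:(k - 1)) {
    best <- -Inf; bestj <- NA
    for (j in 0:(n - 1)) {
      accs <- sapply(setdiff(0:(k - 1), i), function(m) f(i, j, m))
      if (mean(accs) > best) { best <- mean(accs); bestj <- j }
    }
    sel[i + 1] <- bestj; cvacc[i + 1] <- best
    tvals[i + 1] <- f(i, bestj, NA)
  }
  list(selection = sel, cvAccuracy = cvacc, t = tvals,
       mean = mean(tvals), sd = sd(tvals), se = sd(tvals) / sqrt(k))
}

# a small trainable manifest with payloads for the reference backend
refManifest <- function(seed = 1, groups = 4L, per = 10L,
                        classSignal = 2, groupEffect = 0, size = 12L) {
  generateDataset(syntheticSpec(
    groupLevels = c(dataset = groups), imagesPerLeaf = per,
    classes = c("a", "b"), height = size, width = size,
    classSignal = classSignal,
    groupEffect = c(dataset = groupEffect), seed = seed))
}
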