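# Synthetic grouped image data. Each image is a class-specific geometric
# template plus one additive low-frequency appearance field per ancestor
# group (the group-level domain shift) plus i.i.d. pixel noise. Linear
# classifiers learn the class template easily but inherit the shift of the
# groups they trained on, so holding out whole groups at a coarse level
# degrades test accuracy — the regime grouped partitioning is meant to
# expose.

.hashSeed <- function(seed, a, b = 0L)
  as.integer((as.numeric(seed) + 7919 * as.numeric(a) +
                104729 * as.numeric(b)) %% 2147483647)

#' Specify a synthetic grouped image dataset
#'
#' The hierarchy has two zones: \code{groupLevels} (coarsest first) are
#' class-mixed — every group contains all classes (like a hospital dataset
#' or a kidney) — while \code{perClassLevels} sit below the class split and
#' are class-pure (like an OCT volume of one tissue). Each finest-level
#' unit contributes \code{imagesPerLeaf} images per class (for class-pure
#' leaves, per leaf group).
#'
#' \code{classSignal} is the amplitude of the class template in pixel-noise
#' SD units; \code{groupEffect} gives, per hierarchy level, the amplitude
#' of the group-specific appearance shift in the same units (0 = no domain
#' shift at that level).
#'
#' @param groupLevels named integer vector: class-mixed levels, counts per
#'   parent (e.g. \code{c(dataset = 4)} or \code{c(kidney = 10)}).
#' @param perClassLevels named integer vector: class-pure levels, counts
#'   per parent per class (e.g. \code{c(volume = 30)}); may be empty.
#' @param imagesPerLeaf images per finest unit per class.
#' @param classes class names (>= 2 for trainable data).
#' @param height,width image dimensions in pixels.
#' @param classSignal class-template amplitude (noise-SD units).
#' @param groupEffect named numeric vector of per-level shift amplitudes;
#'   defaults to 0 for every level.
#' @param noiseSD pixel noise standard deviation.
#' @param seed integer seed; generation is fully reproducible.
#' @return a list of class \code{synthetic_spec}.
#' @export
syntheticSpec <- function(groupLevels = c(dataset = 4L),
                          perClassLevels = integer(),
                          imagesPerLeaf = 15L,
                          classes = c("classA", "classB"),
                          height = 16L, width = 16L,
                          classSignal = 2, groupEffect = NULL,
                          noiseSD = 1, seed = 0L) {
  if (any(c(groupLevels, perClassLevels, imagesPerLeaf) < 1))
    stop("invalid spec: all counts must be >= 1")
  lv <- c(names(groupLevels), names(perClassLevels))
  if (is.null(groupEffect)) groupEffect <- stats::setNames(rep(0, length(lv)), lv)
  ge <- stats::setNames(rep(0, length(lv)), lv)
  ge[names(groupEffect)] <- groupEffect
  if (any(ge < 0) || classSignal < 0) stop("invalid spec: strengths must be >= 0")
  structure(list(groupLevels = groupLevels,
                 perClassLevels = perClassLevels,
                 imagesPerLeaf = as.integer(imagesPerLeaf),
                 classes = classes, height = as.integer(height),
                 width = as.integer(width), classSignal = classSignal,
                 groupEffect = ge, noiseSD = noiseSD,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Full-size chest X-ray structure emulation
#'
#' Four class-mixed datasets, two classes, 620 images per class per dataset
#' (4960 records). Intended for structure-level checks; generate payloads
#' only at reduced \code{imagesPerLeaf}.
#' @param imagesPerLeaf images per class per dataset.
#' @param ... overrides passed to [syntheticSpec()].
#' @export
xraySpec <- function(imagesPerLeaf = 620L, ...) {
  args <- list(groupLevels = c(dataset = 4L),
               perClassLevels = integer(),
               imagesPerLeaf = imagesPerLeaf,
               classes = c("no_finding", "cardiomegaly"))
  args[names(list(...))] <- list(...)
  do.call(syntheticSpec, args)
}

#' Full-size kidney OCT structure emulation
#'
#' Ten class-mixed kidneys, three tissue classes, 30 class-pure volumes per
#' kidney per class, 20 images per volume (18,000 records; 90 volumes per
#' kidney).
#' @param imagesPerLeaf images per volume.
#' @param volumesPerClass volumes per kidney per class.
#' @param ... overrides passed to [syntheticSpec()].
#' @export
octSpec <- function(imagesPerLeaf = 20L, volumesPerClass = 30L, ...) {
  args <- list(groupLevels = c(kidney = 10L),
               perClassLevels = c(volume = volumesPerClass),
               imagesPerLeaf = imagesPerLeaf,
               classes = c("cortex", "medulla", "pelvis"))
  args[names(list(...))] <- list(...)
  do.call(syntheticSpec, args)
}

#' Desk-scale default spec
#'
#' Small enough for a full nested-CV run with the reference backend in
#' seconds-to-minutes on one CPU: 4 datasets x 2 classes x 15 images at
#' 16 x 16 pixels.
#' @param ... overrides passed to [syntheticSpec()].
#' @export
deskSpec <- function(...) {
  args <- list(...)
  base <- list()
  base[names(args)] <- args
  do.call(syntheticSpec, base)
}

.lowFreqField <- function(h, w, seed) {
  old <- .Random.seed_exists()
  set.seed(seed)
  fr <- sample(1:2, 1); fc <- sample(1:2, 1)
  ph <- stats::runif(2, 0, 2 * pi)
  offset <- stats::rnorm(1)
  .restore_seed(old)
  f <- outer(sin(2 * pi * fr * seq_len(h) / h + ph[1]),
             sin(2 * pi * fc * seq_len(w) / w + ph[2]))
  (f + offset) / sqrt(1 + 1)  # roughly unit scale
}

.classTemplate <- function(h, w, classIndex) {
  r <- seq_len(h) / h; cc <- seq_len(w) / w
  switch((classIndex - 1L) %% 3L + 1L,
         outer(sin(2 * pi * r), cos(2 * pi * cc)),
         outer(cos(2 * pi * r), sin(2 * pi * cc)),
         outer(sin(4 * pi * r), sin(4 * pi * cc)) )
}

#' Generate a synthetic grouped dataset
#'
#' Builds the manifest (and optionally pixel payloads) for a
#' [syntheticSpec()]. The record count equals the product of the hierarchy
#' counts and the class count; the manifest satisfies every manifest
#' invariant (unique ids, nesting, labels in the class set). Payload
#' generation is reproducible per image regardless of order.
#'
#' @param spec a [syntheticSpec()].
#' @param payloads logical: attach pixel matrices? (skip for structure-only
#'   checks of large specs).
#' @return a [DataManifest-class].
#' @examples
#' m <- generateDataset(deskSpec(), payloads = FALSE)
#' length(m)  # 4 * 2 * 15
#' @export
generateDataset <- function(spec, payloads = TRUE) {
  if (!inherits(spec, "synthetic_spec")) stop("invalid spec")
  gl <- spec$groupLevels; pcl <- spec$perClassLevels
  classes <- spec$classes
  # enumerate class-mixed group combinations
  mixed <- expand.grid(lapply(gl, seq_len), KEEP.OUT.ATTRS = FALSE)
  if (!nrow(mixed)) mixed <- data.frame(row.names = 1)
  rows <- list()
  for (gidx in seq_len(max(nrow(mixed), 1L))) {
    gpath <- vapply(seq_along(gl), function(li) {
      pre <- if (li > 1)
        paste0(vapply(seq_len(li - 1), function(x)
          paste0(names(gl)[x], mixed[gidx, x]), ""), collapse = "_")
      else ""
      paste0(if (nzchar(pre)) paste0(pre, "_") else "",
             names(gl)[li], mixed[gidx, li])
    }, "")
    names(gpath) <- names(gl)
    for (ci in seq_along(classes)) {
      pure <- expand.grid(lapply(pcl, seq_len), KEEP.OUT.ATTRS = FALSE)
      npure <- max(nrow(pure), 1L)
      for (pidx in seq_len(npure)) {
        ppath <- character(0)
        if (length(pcl)) {
          pre <- if (length(gpath)) gpath[[length(gpath)]] else ""
          for (li in seq_along(pcl)) {
            ppath[li] <- paste0(if (nzchar(pre)) paste0(pre, "_") else "",
                                classes[ci], "_", names(pcl)[li],
                                pure[pidx, li])
            pre <- ppath[li]
          }
          names(ppath) <- names(pcl)
        }
        leaf <- if (length(ppath)) ppath[length(ppath)] else
          if (length(gpath)) paste0(gpath[length(gpath)], "_", classes[ci])
          else classes[ci]
        img <- seq_len(spec$imagesPerLeaf)
        df <- data.frame(image_id = paste0(leaf, "_img",
                                           formatC(img, width = 3,
                                                   flag = "0")),
                         stringsAsFactors = FALSE)
        for (nm in names(gpath)) df[[nm]] <- gpath[[nm]]
        for (nm in names(ppath)) df[[nm]] <- ppath[[nm]]
        df$label <- classes[ci]
        rows[[length(rows) + 1L]] <- df
      }
    }
  }
  rec <- do.call(rbind, rows)
  rec$height <- spec$height
  rec$width <- spec$width
  hier <- c(names(gl), names(pcl), "image")
  pl <- list()
  if (payloads) {
    h <- spec$height; w <- spec$width
    lvls <- c(names(gl), names(pcl))
    # one shift field per distinct group at each level with effect > 0
    shift <- list()
    for (nm in lvls) {
      if (spec$groupEffect[[nm]] <= 0) next
      ug <- unique(rec[[nm]])
      shift[[nm]] <- lapply(stats::setNames(seq_along(ug), ug), function(ix)
        .lowFreqField(h, w,
                      .hashSeed(spec$seed, ix, match(nm, lvls))) *
          spec$groupEffect[[nm]] * spec$noiseSD)
    }
    templates <- lapply(seq_along(classes), function(ci)
      .classTemplate(h, w, ci) * spec$classSignal * spec$noiseSD)
    pl <- vector("list", nrow(rec))
    names(pl) <- rec$image_id
    for (r in seq_len(nrow(rec))) {
      old <- .Random.seed_exists()
      set.seed(.hashSeed(spec$seed, r, 999983L))
      noise <- matrix(stats::rnorm(h * w, sd = spec$noiseSD), h, w)
      .restore_seed(old)
      img <- templates[[match(rec$label[r], classes)]] + noise
      for (nm in names(shift)) img <- img + shift[[nm]][[rec[[nm]][r]]]
      pl[[r]] <- 0.5 + 0.15 * img
    }
  }
  dataManifest(rec, hierarchy = hier, classNames = classes, payloads = pl)
}

# ---- replay fixtures ------------------------------------------------------

.replayMeta <- list(
  xray_ncv = list(k = 4L, algorithm = "nachos",
                  classes = c("no_finding", "cardiomegaly")),
  oct_ncv = list(k = 10L, algorithm = "nachos",
                 classes = c("cortex", "medulla", "pelvis")),
  xray_dachos = list(k = 4L, algorithm = "dachos",
                     classes = c("no_finding", "cardiomegaly")),
  oct_dachos = list(k = 10L, algorithm = "dachos",
                    classes = c("cortex", "medulla", "pelvis")))

#' Load the bundled replay lookup tables
#'
#' Returns the tabulated validation accuracies (and, for the nested-CV
#' sources, per-test-fold test accuracies) of the two worked-example
#' studies — a four-fold chest X-ray cardiomegaly benchmark and a ten-fold
#' kidney OCT tissue benchmark — in the (i, j, m, accuracy) form consumed
#' by [replayBackend()]. The X-ray nested-CV table carries all 108
#' individual validation accuracies; the OCT nested-CV table carries the 90
#' per-cell mean accuracies (m = NA applies to every validation fold of
#' that cell). The deployment sources carry k x n validation accuracies
#' with i = NA.
#'
#' @param source one of \code{"xray_ncv"}, \code{"oct_ncv"},
#'   \code{"xray_dachos"}, \code{"oct_dachos"}.
#' @return list(cv, test, k, algorithm, classes).
#' @export
makeReplayTables <- function(source) {
  meta <- .replayMeta[[source]]
  if (is.null(meta))
    stop("unknown replay source: '", source, "'")
  read <- function(what) {
    p <- system.file("extdata", paste0("replay_", source, "_", what,
                                       ".csv"), package = "nachos")
    if (!nzchar(p)) return(NULL)
    utils::read.csv(p)
  }
  cv <- read("cv")
  test <- read("test")
  if (is.null(test))
    test <- data.frame(i = integer(), j = integer(), accuracy = numeric())
  c(list(cv = cv, test = test), meta)
}

#' Replay a worked-example study through the full engine
#'
#' Builds the replay backend from [makeReplayTables()], a minimal manifest
#' with one group per fold, and runs the corresponding engine end to end —
#' the engine logic (task enumeration, selection, tie-breaks, aggregation)
#' is fully exercised; only training is replaced by table lookup.
#'
#' @param source a replay source name (see [makeReplayTables()]).
#' @param algorithm \code{"nachos"} or \code{"dachos"}; defaults to the
#'   source's own algorithm.
#' @param g scheduler worker count.
#' @return a [BenchmarkReport-class] or [DeploymentReport-class].
#' @export
replayStudy <- function(source, algorithm = NULL, g = 1L) {
  tabs <- makeReplayTables(source)
  if (is.null(algorithm)) algorithm <- tabs$algorithm
  k <- tabs$k
  classes <- tabs$classes
  rec <- expand.grid(fold = seq_len(k) - 1L, class = classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec <- data.frame(image_id = paste0("g", rec$fold, "_", rec$class),
                    group = paste0("g", rec$fold), label = rec$class,
                    stringsAsFactors = FALSE)
  manifest <- dataManifest(rec, hierarchy = c("group", "image"),
                           classNames = classes)
  f <- as.integer(sub("^g(\\d+)_.*$", "\\1", rec$image_id))
  names(f) <- rec$image_id
  assignment <- new("FoldAssignment", k = k, level = "group", foldOf = f,
                    seed = 0L)
  backend <- replayBackend(tabs$cv, tabs$test, classes = classes)
  n <- max(tabs$cv$j) + 1L
  configs <- data.frame(index = seq_len(n) - 1L)
  class(configs) <- c("hyperparameter_configs", "data.frame")
  if (algorithm == "nachos")
    runNachos(manifest, assignment, configs, backend, g = g, epochs = 1L)
  else
    runDachos(manifest, assignment, configs, backend, g = g, epochs = 1L)
}
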