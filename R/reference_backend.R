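# Reference backend: a small multinomial softmax classifier on flattened
# pixels, optionally with one tanh hidden layer, trained by mini-batch SGD.
# It exists to exercise every hyperparameter dimension (batch size, learning
# rate, time-based decay, momentum, Nesterov, architecture) deterministically
# on a CPU in seconds; large CNN architectures are deliberately not part of
# this package.

#' Reference training backend
#'
#' Hyperparameters honoured per configuration row: \code{batch_size},
#' \code{learning_rate}, \code{decay} (time-based decay
#' \eqn{lr_t = lr / (1 + decay \cdot t)} per update step t),
#' \code{momentum}, \code{nesterov}, and \code{architecture}, which selects
#' a topology from \code{architectures} (a named list of hidden-layer
#' widths; \code{integer(0)} means plain softmax regression). The canonical
#' CNN architecture names map deterministically onto the small topologies so
#' externally tabulated configuration lists run unchanged at desk scale.
#'
#' Determinism: parameter initialisation is seeded by the task seed and the
#' mini-batch shuffle of epoch e is seeded by \code{seed + e}, so training
#' resumed from the epoch-e checkpoint reproduces the uninterrupted run
#' bit-identically.
#'
#' @param epochs default epoch budget when the train spec does not override.
#' @param architectures named list mapping architecture names to hidden
#'   widths.
#' @return a [ReferenceBackend-class].
#' @export
referenceBackend <- function(epochs = 10L,
                             architectures = list(
                               softmax = integer(0), mlp16 = 16L,
                               mlp32 = 32L,
                               ResNet50 = integer(0), InceptionV3 = 16L,
                               Xception = 32L)) {
  new("ReferenceBackend", epochs = as.integer(epochs),
      architectures = architectures)
}

.refHyper <- function(config) {
  gv <- function(nm, default) {
    if (!is.null(config) && nm %in% names(config) && nrow(config) == 1L)
      config[[nm]][1] else default
  }
  list(batch_size = as.integer(gv("batch_size", 32L)),
       learning_rate = as.numeric(gv("learning_rate", 0.01)),
       decay = as.numeric(gv("decay", 0.001)),
       momentum = as.numeric(gv("momentum", 0.9)),
       nesterov = isTRUE(as.logical(gv("nesterov", FALSE))),
       architecture = as.character(gv("architecture", "softmax")))
}

.refDesign <- function(records, payloads) {
  miss <- setdiff(records$image_id, names(payloads))
  if (length(miss))
    stop("payload error: missing pixels for ",
         paste(utils::head(miss, 3), collapse = ", "))
  X <- t(vapply(records$image_id, function(id) as.numeric(payloads[[id]]),
                numeric(length(payloads[[records$image_id[1]]]))))
  scale(X, center = TRUE, scale = FALSE)  # per-feature centering
}

.refInit <- function(d, h, K, seed) {
  old <- .Random.seed_exists()
  set.seed(seed)
  par <- if (length(h) && h > 0L) {
    list(W1 = matrix(stats::rnorm(d * h, sd = 1 / sqrt(d)), d, h),
         b1 = numeric(h),
         W2 = matrix(stats::rnorm(h * K, sd = 1 / sqrt(h)), h, K),
         b2 = numeric(K))
  } else {
    list(W2 = matrix(stats::rnorm(d * K, sd = 1 / sqrt(d)), d, K),
         b2 = numeric(K))
  }
  .restore_seed(old)
  par
}

.refForward <- function(par, X) {
  if (!is.null(par$W1)) {
    H <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
    Z <- sweep(H %*% par$W2, 2, par$b2, "+")
    list(H = H, Z = Z)
  } else list(H = NULL, Z = sweep(X %*% par$W2, 2, par$b2, "+"))
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

setMethod("trainModel", "ReferenceBackend",
  function(backend, records, payloads, spec, onEpochEnd = NULL) {
    if (length(unique(records$label)) < 2L)
      stop("degenerate labels: training set has a single class")
    classes <- if (length(spec$classes)) spec$classes else
      sort(unique(records$label))
    hp <- .refHyper(spec$config)
    hidden <- backend@architectures[[hp$architecture]]
    if (is.null(hidden)) hidden <- integer(0)
    X <- .refDesign(records, payloads)
    y <- match(records$label, classes)
    K <- length(classes)
    N <- nrow(X); d <- ncol(X)
    Y <- matrix(0, N, K); Y[cbind(seq_len(N), y)] <- 1
    epochs <- spec$epochs
    if (!is.null(spec$resumeFrom)) {
      st <- spec$resumeFrom$state
      par <- st@params$par; vel <- st@params$vel; tstep <- st@params$tstep
      startEpoch <- spec$resumeFrom$epoch
    } else {
      par <- .refInit(d, hidden, K, spec$seed)
      vel <- lapply(par, function(p) p * 0)
      tstep <- 0L
      startEpoch <- 0L
    }
    bs <- max(1L, min(hp$batch_size, N))
    state <- NULL
    for (e in seq.int(startEpoch + 1L, epochs)) {
      old <- .Random.seed_exists()
      set.seed(spec$seed + e)
      ord <- sample.int(N)
      .restore_seed(old)
      for (start in seq(1L, N, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, N)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        fw <- .refForward(par, Xb)
        P <- .softmax(fw$Z)
        dZ <- (P - Yb) / length(idx)
        grad <- list()
        if (!is.null(par$W1)) {
          grad$W2 <- t(fw$H) %*% dZ
          grad$b2 <- colSums(dZ)
          dH <- (dZ %*% t(par$W2)) * (1 - fw$H^2)
          grad$W1 <- t(Xb) %*% dH
          grad$b1 <- colSums(dH)
        } else {
          grad$W2 <- t(Xb) %*% dZ
          grad$b2 <- colSums(dZ)
        }
        tstep <- tstep + 1L
        lr <- hp$learning_rate / (1 + hp$decay * tstep)
        for (nm in names(par)) {
          vel[[nm]] <- hp$momentum * vel[[nm]] + grad[[nm]]
          step <- if (hp$nesterov) grad[[nm]] + hp$momentum * vel[[nm]] else
            vel[[nm]]
          par[[nm]] <- par[[nm]] - lr * step
        }
      }
      state <- modelState(
        params = list(par = par, vel = vel, tstep = tstep,
                      center = attr(X, "scaled:center"),
                      hidden = hidden),
        provenance = list(backend = "reference", task = spec$task,
                          config_index = spec$task$j, classes = classes,
                          epochs = e, seed = spec$seed))
      if (!is.null(onEpochEnd)) onEpochEnd(e, state)
    }
    state
  })

setMethod("evaluateModel", "ReferenceBackend",
  function(backend, model, records, payloads) {
    if (!nrow(records)) stop("empty evaluation")
    classes <- model@provenance$classes
    bad <- setdiff(unique(records$label), classes)
    if (length(bad))
      stop("label mismatch: ", paste(bad, collapse = ", "))
    miss <- setdiff(records$image_id, names(payloads))
    if (length(miss)) stop("payload error")
    X <- t(vapply(records$image_id,
                  function(id) as.numeric(payloads[[id]]),
                  numeric(length(model@params$center))))
    X <- sweep(X, 2, model@params$center)
    fw <- .refForward(model@params$par, X)
    pred <- classes[max.col(fw$Z, ties.method = "first")]
    confusionMatrix(records$label, pred, classes)
  })
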