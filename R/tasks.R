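#' Task identity string
#'
#' Canonical identifiers used for checkpoint keys and log lines:
#' \code{ct{i}_h{j}_val{m}} for nested-CV validation tasks,
#' \code{cv_h{j}_val{m}} for full-dataset CV tasks (no test fold),
#' \code{ct{i}_test_h{j}} for per-test-fold retrain tasks and
#' \code{deploy_h{j}} for the final deployment task.
#'
#' @param kind one of "cv", "retrain", "deploy".
#' @param i,j,m task indices (NA where undefined).
#' @export
taskId <- function(kind, i, j, m) {
  switch(kind,
    cv = if (is.na(i)) sprintf("cv_h%d_val%d", j, m) else
      sprintf("ct%d_h%d_val%d", i, j, m),
    retrain = sprintf("ct%d_test_h%d", i, j),
    deploy = sprintf("deploy_h%d", j),
    stop("unknown task kind: ", kind))
}

#' Enumerate nested cross-validation tasks
#'
#' One validation task per triple (i, j, m) with test fold i, configuration
#' j and validation fold m != i — exactly \eqn{k (k-1) n} tasks, in
#' deterministic i-major, then j, then m order. The k retrain tasks (one
#' per test fold, after selection) are enumerated separately by the engine
#' and are not part of this count.
#'
#' @param k fold count (>= 2).
#' @param n configuration count (>= 1).
#' @return data.frame(kind, i, j, m, id).
#' @examples
#' nrow(enumerateNcvTasks(4, 9))  # 108
#' @export
enumerateNcvTasks <- function(k, n) {
  if (k < 2 || n < 1) stop("invalid dimensions: need k >= 2, n >= 1")
  grid <- expand.grid(m = 0:(k - 1), j = 0:(n - 1), i = 0:(k - 1),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$i != grid$m, c("i", "j", "m")]
  out <- data.frame(kind = "cv", grid, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$id <- mapply(taskId, out$kind, out$i, out$j, out$m)
  out
}

#' Enumerate full-dataset cross-validation tasks
#'
#' One validation task per pair (j, m) with no test fold — exactly
#' \eqn{k n} tasks in j-major order. The single final deployment task is
#' appended by the engine after selection.
#'
#' @inheritParams enumerateNcvTasks
#' @return data.frame(kind, i, j, m, id) with i = NA throughout.
#' @examples
#' nrow(enumerateDachosTasks(4, 9))  # 36
#' @export
enumerateDachosTasks <- function(k, n) {
  if (k < 2 || n < 1) stop("invalid dimensions: need k >= 2, n >= 1")
  grid <- expand.grid(m = 0:(k - 1), j = 0:(n - 1),
                      KEEP.OUT.ATTRS = FALSE)[, c("j", "m")]
  out <- data.frame(kind = "cv", i = NA_integer_, grid, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$id <- mapply(taskId, out$kind, out$i, out$j, out$m)
  out
}

#' Deterministic per-task seed
#'
#' Mixes the global seed with the task indices so each task's randomness is
#' independent of execution order and worker assignment. Kept below 2^31.
#'
#' @param seed global integer seed.
#' @param i,j,m task indices (NA treated as -1).
#' @export
taskSeed <- function(seed, i, j, m) {
  i <- if (is.na(i)) -1L else as.integer(i)
  j <- if (is.na(j)) -1L else as.integer(j)
  m <- if (is.na(m)) -1L else as.integer(m)
  as.integer((as.numeric(seed) + 1000003 * (i + 2) + 10007 * (j + 2) +
                101 * (m + 2)) %% 2147483647)
}
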