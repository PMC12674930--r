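#' Build a confusion matrix
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels, same length.
#' @param classes the full class list (fixes the matrix dimensions even for
#'   classes absent from this evaluation).
#' @return integer matrix, true classes in rows, predicted in columns.
#' @export
confusionMatrix <- function(truth, predicted, classes) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("label mismatch: unknown class ", paste(bad, collapse = ", "))
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Classification accuracy of a confusion matrix
#'
#' The proportion of correct predictions: the matrix trace divided by the
#' total count (in the two-class case, (TP + TN) / (TP + TN + FP + FN)).
#'
#' @param cm a square confusion matrix (true x predicted).
#' @return accuracy in [0, 1].
#' @examples
#' cm <- matrix(c(3, 1, 2, 2), 2, 2,
#'              dimnames = list(c("neg", "pos"), c("neg", "pos")))
#' accuracy(cm)  # 5/8
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("empty evaluation")
  sum(diag(as.matrix(cm))) / total
}

#' Element-wise mean and SD of confusion matrices
#'
#' Averages a list of confusion matrices cell by cell, reporting the sample
#' standard deviation (n-1 denominator) alongside the mean — the form in
#' which cross-testing confusion matrices are reported across test folds.
#'
#' @param cms list of confusion matrices sharing one class list.
#' @return list with \code{mean} and \code{sd} matrices.
#' @export
averageConfusion <- function(cms) {
  if (!length(cms)) stop("empty evaluation")
  dn <- dimnames(cms[[1]])
  for (cm in cms)
    if (!identical(dimnames(cm)[[1]], dn[[1]]) ||
        !identical(dimnames(cm)[[2]], dn[[2]]))
      stop("class mismatch across confusion matrices")
  arr <- array(unlist(cms), dim = c(dim(cms[[1]]), length(cms)))
  mn <- apply(arr, c(1, 2), mean)
  sd_ <- if (length(cms) > 1L) apply(arr, c(1, 2), stats::sd) else
    matrix(0, nrow(mn), ncol(mn))
  dimnames(mn) <- dn
  dimnames(sd_) <- dn
  list(mean = mn, sd = sd_)
}

# Synthetic confusion matrix with a prescribed accuracy over `total` counts.
# Correct counts go on the diagonal (split as evenly as possible); errors
# cycle over off-diagonal cells of the first row/column block.
.syntheticConfusion <- function(acc, classes, total = 100L) {
  nc <- length(classes)
  correct <- round(acc * total)
  wrong <- total - correct
  m <- matrix(0L, nc, nc, dimnames = list(truth = classes,
                                          predicted = classes))
  base <- correct %/% nc
  extra <- correct %% nc
  diag(m) <- base + c(rep(1L, extra), rep(0L, nc - extra))
  if (wrong > 0L) {
    off <- which(row(m) != col(m))
    take <- rep(off, length.out = wrong)
    for (ix in take) m[ix] <- m[ix] + 1L
  }
  m
}
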