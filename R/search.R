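#' Declare a hyperparameter search space
#'
#' A search space is a named list of finite candidate sets, one per
#' hyperparameter dimension. [defaultSearchSpace()] returns the canonical
#' six-dimension space used throughout this package's worked examples:
#' batch size \{16, 32, 64, 128\}, learning rate \{0.01, 0.001, 0.0001\},
#' learning-rate decay \{0.01, 0.001, 0.0001\}, momentum \{0.5, 0.9, 0.99\},
#' Nesterov acceleration \{TRUE, FALSE\} and architecture \{ResNet50,
#' InceptionV3, Xception\}.
#'
#' @param ... named candidate vectors (each non-empty and finite).
#' @return a list of class \code{search_space}.
#' @examples
#' sp <- searchSpace(batch_size = c(16, 32), learning_rate = c(0.1, 0.01))
#' sampleConfigs(sp, n = 3, seed = 1)
#' @export
searchSpace <- function(...) {
  dims <- list(...)
  if (length(dims) == 1L && is.list(dims[[1]]) && is.null(names(dims)))
    dims <- dims[[1]]
  if (is.null(names(dims)) || any(names(dims) == ""))
    stop("invalid space: every dimension must be named")
  for (nm in names(dims))
    if (length(dims[[nm]]) == 0L)
      stop("invalid space: dimension '", nm, "' is empty")
  structure(dims, class = "search_space")
}

#' @rdname searchSpace
#' @export
defaultSearchSpace <- function() {
  searchSpace(
    architecture = c("ResNet50", "InceptionV3", "Xception"),
    batch_size = c(16, 32, 64, 128),
    learning_rate = c(0.01, 0.001, 0.0001),
    decay = c(0.01, 0.001, 0.0001),
    momentum = c(0.5, 0.9, 0.99),
    nesterov = c(TRUE, FALSE)
  )
}

#' Sample hyperparameter configurations by random search
#'
#' Draws \code{n} configurations, each dimension independently and uniformly
#' from its candidate set. Duplicates are permitted (random search does not
#' deduplicate) and are evaluated independently downstream. Configurations
#' are indexed 0..n-1 and the same list is reused across every test fold of
#' a study — sampling happens once per study, not per fold.
#'
#' @param space a [searchSpace()].
#' @param n number of configurations (>= 0).
#' @param seed integer seed; identical inputs give identical output.
#' @return data.frame of class \code{hyperparameter_configs} with column
#'   \code{index} plus one column per dimension.
#' @export
sampleConfigs <- function(space, n, seed = 0L) {
  if (!inherits(space, "search_space")) space <- searchSpace(space)
  if (n < 0) stop("invalid n")
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  cols <- lapply(unclass(space), function(cand)
    cand[sample.int(length(cand), n, replace = TRUE)])
  .restore_seed(old)
  out <- cbind(data.frame(index = seq_len(n) - 1L),
               as.data.frame(cols, stringsAsFactors = FALSE))
  if (n == 0L) out <- out[0, , drop = FALSE]
  class(out) <- c("hyperparameter_configs", "data.frame")
  out
}

#' Load a configuration list from CSV
#'
#' Reads an ordered configuration table (columns: \code{index} plus one per
#' dimension; \code{index} optional and re-derived from row order). When a
#' \code{space} is supplied every value is validated against its candidate
#' set; otherwise values are accepted verbatim. This is how a pinned,
#' externally tabulated configuration list (e.g. the nine worked-example
#' configurations bundled in \code{extdata/configs_default.csv}) enters a
#' run unchanged.
#'
#' Logical-like values for \code{nesterov} (\code{Enabled/Disabled},
#' \code{Yes/No}, \code{TRUE/FALSE}) are normalised to logical.
#'
#' @param path CSV file.
#' @param space optional [searchSpace()] to validate against.
#' @return a \code{hyperparameter_configs} data.frame.
#' @export
loadConfigs <- function(path, space = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    out <- data.frame(index = integer())
    class(out) <- c("hyperparameter_configs", "data.frame")
    return(out)
  }
  df$index <- seq_len(nrow(df)) - 1L
  if ("nesterov" %in% names(df) && !is.logical(df$nesterov)) {
    nv <- tolower(as.character(df$nesterov))
    map <- c(enabled = TRUE, disabled = FALSE, yes = TRUE, no = FALSE,
             "true" = TRUE, "false" = FALSE)
    if (any(!nv %in% names(map)))
      stop("parse error in row ", which(!nv %in% names(map))[1],
           ": unrecognised nesterov value")
    df$nesterov <- unname(map[nv])
  }
  if (!is.null(space)) {
    for (nm in intersect(names(space), names(df))) {
      bad <- !df[[nm]] %in% space[[nm]]
      if (any(bad))
        stop("parse error in row ", which(bad)[1], ": value '",
             df[[nm]][which(bad)[1]], "' not in candidate set for '", nm, "'")
    }
  }
  df <- df[c("index", setdiff(names(df), "index"))]
  class(df) <- c("hyperparameter_configs", "data.frame")
  df
}

#' @rdname loadConfigs
#' @param configs a \code{hyperparameter_configs} data.frame.
#' @export
writeConfigs <- function(configs, path) {
  utils::write.csv(as.data.frame(configs), path, row.names = FALSE)
  invisible(path)
}

#' The bundled worked-example configuration list (h0..h8)
#'
#' Nine configurations drawn by random search from [defaultSearchSpace()],
#' as tabulated in the chest X-ray / kidney OCT worked examples replayed by
#' [makeReplayTables()].
#'
#' @return a \code{hyperparameter_configs} data.frame with 9 rows.
#' @export
defaultConfigs <- function() {
  loadConfigs(system.file("extdata", "configs_default.csv",
                          package = "nachos"),
              space = defaultSearchSpace())
}
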