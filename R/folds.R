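#' Assign grouped folds at a hierarchy level
#'
#' Partitions a manifest into \code{k} folds \code{F0..Fk-1} with group
#' integrity at the declared hierarchy level: every record sharing a group
#' identifier at \code{level} lands in the same fold, preventing leakage of
#' (say) a patient's images across training and test sets. Groups are sorted
#' lexicographically by identifier, shuffled with \code{seed}, and dealt
#' round-robin so fold group-counts differ by at most one; when the number
#' of groups equals \code{k}, each fold is exactly one group. The assignment
#' therefore depends only on the set of group identifiers and the seed, not
#' on record order.
#'
#' Balancing is by group count, not image count: group integrity dominates,
#' and study designs typically balance image counts by construction.
#'
#' @param manifest a [DataManifest-class].
#' @param k number of folds (>= 2).
#' @param level hierarchy level at which integrity is enforced
#'   (\code{"image"} gives ungrouped random folds).
#' @param seed integer seed for the group shuffle.
#' @return a [FoldAssignment-class].
#' @examples
#' rec <- data.frame(image_id = as.character(1:8),
#'                   dataset = rep(c("d1", "d2", "d3", "d4"), each = 2),
#'                   label = rep(c("a", "b"), 4))
#' m <- dataManifest(rec, c("dataset", "image"))
#' fa <- assignFolds(m, k = 4, level = "dataset", seed = 1)
#' table(foldOf(fa), rec$dataset[match(names(foldOf(fa)), rec$image_id)])
#' @export
assignFolds <- function(manifest, k, level, seed = 0L) {
  if (length(k) != 1L || is.na(k) || k < 2)
    stop("invalid k: fold count must be an integer >= 2")
  k <- as.integer(k)
  if (!level %in% hierarchy(manifest))
    stop("unknown level: '", level, "'")
  gid <- groupIds(manifest, level)
  groups <- sort(unique(gid))
  if (length(groups) < k)
    stop("insufficient groups: ", length(groups), " groups at level '",
         level, "' for k = ", k)
  seed <- as.integer(seed)
  old <- .Random.seed_exists()
  set.seed(seed)
  shuffled <- sample(groups)
  .restore_seed(old)
  # round-robin deal: fold sizes in groups differ by at most 1
  fold_of_group <- stats::setNames((seq_along(shuffled) - 1L) %% k, shuffled)
  fold <- as.integer(fold_of_group[gid])
  names(fold) <- records(manifest)$image_id
  new("FoldAssignment", k = k, level = level, foldOf = fold, seed = seed)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @rdname FoldAssignment-class
#' @export
setMethod("foldOf", "FoldAssignment", function(x) x@foldOf)

#' @rdname FoldAssignment-class
#' @export
setMethod("foldCount", "FoldAssignment", function(x) x@k)

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: k = %d at level '%s' (seed %d)\n",
              object@k, object@level, object@seed))
  print(table(fold = object@foldOf))
})

#' Audit a fold assignment against a manifest
#'
#' Checks every fold-assignment invariant and reports violations instead of
#' raising: each manifest record assigned exactly one fold, fold indices in
#' range, no empty fold, no stray image_ids, and group integrity at the
#' assignment's level (no group split across folds).
#'
#' @param assignment a [FoldAssignment-class].
#' @param manifest the [DataManifest-class] it refers to.
#' @return a list with \code{pass} (logical) and \code{violations}
#'   (data.frame with columns rule, detail).
#' @export
auditAssignment <- function(assignment, manifest) {
  v <- list()
  add <- function(rule, detail) v[[length(v) + 1L]] <<- data.frame(
    rule = rule, detail = detail, stringsAsFactors = FALSE)
  ids <- records(manifest)$image_id
  f <- foldOf(assignment)
  unassigned <- setdiff(ids, names(f))
  for (id in unassigned) add("unassigned record", id)
  stray <- setdiff(names(f), ids)
  for (id in stray) add("unknown record", id)
  keep <- intersect(names(f), ids)
  fk <- f[keep]
  if (any(is.na(fk) | fk < 0L | fk >= assignment@k))
    add("fold index out of range",
        paste(names(fk)[is.na(fk) | fk < 0L | fk >= assignment@k],
              collapse = ","))
  present <- sort(unique(fk[!is.na(fk)]))
  empty <- setdiff(seq_len(assignment@k) - 1L, present)
  for (e in empty) add("empty fold", paste0("F", e))
  if (assignment@level %in% hierarchy(manifest) && length(keep)) {
    gid <- groupIds(manifest, assignment@level)
    names(gid) <- ids
    split_groups <- vapply(split(fk, gid[keep]),
                           function(x) length(unique(x)) > 1L, TRUE)
    for (g in names(split_groups)[split_groups])
      add("group split across folds", g)
  } else if (!assignment@level %in% hierarchy(manifest)) {
    add("unknown level", assignment@level)
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), detail = character(),
               stringsAsFactors = FALSE)
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Write a fold assignment as CSV (image_id, fold)
#' @param assignment a [FoldAssignment-class].
#' @param path output file.
#' @export
writeFoldAssignment <- function(assignment, path) {
  utils::write.csv(data.frame(image_id = names(foldOf(assignment)),
                              fold = unname(foldOf(assignment))),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a fold assignment from CSV
#' @param path CSV with columns image_id, fold.
#' @param k fold count; defaults to max(fold) + 1.
#' @param level level label to attach.
#' @param seed seed label to attach.
#' @export
readFoldAssignment <- function(path, k = NULL, level = "image", seed = 0L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  f <- as.integer(df$fold)
  names(f) <- as.character(df$image_id)
  if (is.null(k)) k <- max(f) + 1L
  new("FoldAssignment", k = as.integer(k), level = level, foldOf = f,
      seed = as.integer(seed))
}
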