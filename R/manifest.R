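#' Construct a data manifest
#'
#' @param records data.frame with columns \code{image_id}, one column per
#'   non-image hierarchy level, \code{label}, and optionally
#'   \code{payload_ref}, \code{height}, \code{width}.
#' @param hierarchy character vector of level names, coarsest to finest; the
#'   finest level must be (or is appended as) \code{"image"}.
#' @param classNames permitted class labels; defaults to the sorted labels
#'   present in \code{records}.
#' @param payloads optional named list of pixel matrices keyed by image_id.
#' @return a [DataManifest-class].
#' @examples
#' rec <- data.frame(image_id = c("a", "b"), patient = c("p1", "p1"),
#'                   label = c("healthy", "disease"))
#' m <- dataManifest(rec, hierarchy = c("patient", "image"))
#' @export
dataManifest <- function(records, hierarchy, classNames = NULL,
                         payloads = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (hierarchy[length(hierarchy)] != "image")
    hierarchy <- c(hierarchy, "image")
  if (is.null(classNames))
    classNames <- sort(unique(as.character(records$label)))
  for (col in c("image_id", "label", setdiff(hierarchy, "image")))
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  if (is.null(records$payload_ref)) records$payload_ref <- records$image_id
  if (is.null(records$height)) records$height <- NA_integer_
  if (is.null(records$width)) records$width <- NA_integer_
  new("DataManifest", records = records, hierarchy = hierarchy,
      classNames = classNames, payloads = payloads)
}

#' @rdname DataManifest-class
#' @export
setMethod("records", "DataManifest", function(x) x@records)

#' @rdname DataManifest-class
#' @export
setMethod("hierarchy", "DataManifest", function(x) x@hierarchy)

#' @rdname DataManifest-class
#' @export
setMethod("classNames", "DataManifest", function(x) x@classNames)

#' @rdname DataManifest-class
#' @export
setMethod("payloads", "DataManifest", function(x) x@payloads)

#' @rdname DataManifest-class
#' @export
setMethod("groupIds", "DataManifest", function(x, level) {
  if (!level %in% x@hierarchy)
    stop("unknown level: '", level, "'")
  if (level == "image") x@records$image_id else x@records[[level]]
})

#' @rdname DataManifest-class
#' @export
setMethod("length", "DataManifest", function(x) nrow(x@records))

setMethod("show", "DataManifest", function(object) {
  cat("DataManifest:", nrow(object@records), "records,",
      length(object@classNames), "classes\n")
  cat("  hierarchy:", paste(object@hierarchy, collapse = " > "), "\n")
  for (lv in setdiff(object@hierarchy, "image"))
    cat(sprintf("  %s: %d groups\n", lv,
                length(unique(object@records[[lv]]))))
  cat("  classes:", paste(object@classNames, collapse = ", "), "\n")
  cat("  payloads attached:", length(object@payloads), "\n")
})

#' Read / write a manifest as CSV
#'
#' The CSV carries one row per image with columns \code{image_id}, one column
#' per non-image hierarchy level, \code{label}, \code{payload_ref},
#' \code{height}, \code{width}. The hierarchy order is recovered from the
#' column order (columns between image_id and label).
#'
#' @param path file path.
#' @param classNames optional explicit class set.
#' @return [readManifest()] returns a [DataManifest-class];
#'   [writeManifest()] returns \code{path} invisibly.
#' @export
readManifest <- function(path, classNames = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  fixed <- c("image_id", "label", "payload_ref", "height", "width")
  lvls <- setdiff(names(df), fixed)
  df$height <- as.integer(df$height)
  df$width <- as.integer(df$width)
  dataManifest(df, hierarchy = c(lvls, "image"), classNames = classNames)
}

#' @rdname readManifest
#' @param manifest a [DataManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  lvls <- setdiff(hierarchy(manifest), "image")
  cols <- c("image_id", lvls, "label", "payload_ref", "height", "width")
  utils::write.csv(records(manifest)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write attached pixel payloads as PNG files
#'
#' Payload matrices are clipped to [0, 1] and written as 8-bit grayscale
#' PNGs named \code{<image_id>.png}.
#'
#' @param manifest a [DataManifest-class] with attached payloads.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writePayloads <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pl <- payloads(manifest)
  paths <- character(length(pl))
  for (i in seq_along(pl)) {
    img <- pmin(pmax(pl[[i]], 0), 1)
    paths[i] <- file.path(dir, paste0(names(pl)[i], ".png"))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
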