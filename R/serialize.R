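#' Read and write centerline trees as JSON
#'
#' Trees are stored as a root point plus one record per path (name, world
#' points, slice indices, flags) — the exchange format between the tracking,
#' rendering and grading stages.
#'
#' @param tree a [centerline_tree].
#' @param path output / input file.
#' @return `write_tree` returns `path` invisibly; `read_tree` returns a
#'   [centerline_tree].
#' @export
write_tree <- function(tree, path) {
  obj <- list(root = tree$root,
              paths = lapply(tree$paths, function(p) list(
                name = p$name, points = p$points, resampled = p$resampled,
                slices = p$slices, flagged = p$flagged)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  paths <- lapply(obj$paths, function(p)
    centerline_path(p$name, matrix(unlist(p$points), ncol = 3),
                    resampled = isTRUE(p$resampled),
                    slices = if (is.null(p$slices)) NULL else p$slices,
                    flagged = as.logical(p$flagged)))
  centerline_tree(as.numeric(obj$root), paths, root_tol = Inf)
}

#' Serialize phantom ground truth
#'
#' Writes lesion list, per-segment truth table and centerline polylines as
#' JSON (masks are omitted: they are derivable by regenerating the phantom).
#'
#' @param truth a `phantom_truth` from [generate_phantom].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(segments = truth$segments,
              lesions = lapply(truth$lesions, unclass),
              centerlines = list(
                root = truth$centerlines$root,
                paths = lapply(truth$centerlines$paths, function(p)
                  list(name = p$name, points = p$points, slices = p$slices))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Export a centerline tree as CSV polylines
#'
#' One row per point: `path`, `slice`, `x`, `y`, `z`, `flagged`.
#'
#' @param tree a [centerline_tree].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_csv <- function(tree, path) {
  rows <- do.call(rbind, lapply(tree$paths, function(p) {
    data.frame(path = p$name,
               slice = if (is.null(p$slices)) NA_integer_ else p$slices,
               x = p$points[, 1], y = p$points[, 2], z = p$points[, 3],
               flagged = p$flagged, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
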