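#' Centerline path and tree containers
#'
#' A `centerline_path` is an ordered polyline of world points (mm) from the
#' tree root towards an endpoint. When `resampled`, it carries exactly one
#' point per axial slice over its z extent (`slices` holds the 0-based slice
#' indices, strictly increasing by one), which is the form every renderer
#' consumes: one output row per slice.
#'
#' @param name endpoint (or branch) label.
#' @param points n x 3 matrix of world coordinates (mm).
#' @param resampled logical; one point per slice?
#' @param slices 0-based slice indices (required when `resampled`).
#' @param flagged optional logical vector marking points with no lumen
#'   cross-section (e.g. inside occlusions).
#' @return an object of class `centerline_path`.
#' @export
centerline_path <- function(name, points, resampled = FALSE, slices = NULL,
                            flagged = NULL) {
  points <- as_point_matrix(points)
  if (nrow(points) < 1 || any(!is.finite(points)))
    stop("centerline points must be finite")
  if (resampled) {
    if (is.null(slices) || length(slices) != nrow(points))
      stop("a resampled path needs one slice index per point")
    if (nrow(points) > 1 && any(diff(slices) != 1L))
      stop("resampled path slice indices must increase by exactly one")
  }
  if (is.null(flagged)) flagged <- rep(FALSE, nrow(points))
  structure(list(name = name, points = points, resampled = resampled,
                 slices = if (is.null(slices)) NULL else as.integer(slices),
                 flagged = flagged),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("<centerline_path> '%s': %d points%s, z %.1f..%.1f mm\n",
              x$name, nrow(x$points),
              if (x$resampled) " (one per slice)" else "",
              x$points[1, 3], x$points[nrow(x$points), 3]))
  invisible(x)
}

#' @param root world coordinates (mm) of the common root (infra-renal aorta).
#' @param paths list of [centerline_path], each starting at `root`.
#' @param root_tol tolerance (mm) for the shared-root check.
#' @rdname centerline_path
#' @export
centerline_tree <- function(root, paths, root_tol = 1e-6) {
  root <- as.numeric(root)
  if (length(root) != 3) stop("root must be a world point (x, y, z)")
  nms <- vapply(paths, function(p) p$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate endpoint name: ", nms[duplicated(nms)][1])
  for (p in paths) {
    if (sqrt(sum((p$points[1, ] - root)^2)) > root_tol)
      stop("path '", p$name, "' does not start at the tree root")
  }
  names(paths) <- nms
  structure(list(root = root, paths = paths), class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> root (%.1f, %.1f, %.1f) mm, %d paths: %s\n",
              x$root[1], x$root[2], x$root[3], length(x$paths),
              paste(names(x$paths), collapse = ", ")))
  invisible(x)
}

# Linear interpolation of a (near) z-monotone polyline at the given slice
# z coordinates. Local z reversals are monotonised by keeping the first
# crossing, with a warning. Returns NULL when fewer than two slices are
# covered.
resample_polyline <- function(points, zvals, slice0 = 0L, name = "path",
                              flagged = NULL, warn = TRUE) {
  z <- points[, 3]
  if (any(diff(z) <= 0)) {
    keep <- c(TRUE, z[-1] > utils::head(cummax(z), -1)) # first crossing only
    if (warn) warning("path '", name, "' locally reverses z; first crossing kept")
    points <- points[keep, , drop = FALSE]
    if (!is.null(flagged)) flagged <- flagged[keep]
    z <- points[, 3]
  }
  inside <- which(zvals >= z[1] - 1e-9 & zvals <= z[length(z)] + 1e-9)
  if (length(inside) < 2) return(NULL)
  zi <- zvals[inside]
  if (nrow(points) == 1) return(NULL)
  xs <- stats::approx(z, points[, 1], xout = zi, rule = 2)$y
  ys <- stats::approx(z, points[, 2], xout = zi, rule = 2)$y
  fl <- if (is.null(flagged)) NULL else
    as.logical(stats::approx(z, as.numeric(flagged), xout = zi,
                             method = "constant", rule = 2)$y)
  centerline_path(name, cbind(xs, ys, zi), resampled = TRUE,
                  slices = slice0 + inside - 1L, flagged = fl)
}

#' Resample a centerline path to one point per slice
#'
#' @param path a [centerline_path].
#' @param vol the [ct_volume] whose slice grid defines the target z values.
#' @return a resampled [centerline_path].
#' @export
resample_path <- function(path, vol) {
  out <- resample_polyline(path$points, slice_z(vol), slice0 = 0L,
                           name = path$name, flagged = path$flagged)
  if (is.null(out))
    stop("path '", path$name, "' covers fewer than two slices")
  out
}

# cumulative arclength (mm) along a path, starting at 0
path_arclength <- function(points) {
  if (nrow(points) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(points)^2))))
}
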