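#' Traversal-cost image from arterial enhancement
#'
#' The vessel-growth cost is minimal (the `floor`) for attenuation inside
#' the enhancement window and grows quadratically with the HU distance
#' outside it, capped so barriers stay finite and strictly positive
#' everywhere (no zero-cost shortcuts). The default window starts 150 HU
#' above soft tissue — the bolus-trigger enhancement target — and ends
#' below stent/bone attenuation.
#'
#' @param vol a [ct_volume].
#' @param enhancement_window length-2 HU `c(low, high)`, `low < high`.
#' @param floor cost inside the window (> 0).
#' @param hu_scale HU distance over which the penalty reaches `floor`
#'   (quadratic growth), default 50.
#' @param cap maximum cost multiple of `floor`, default 1000.
#' @return a `cost_image`: list with `cost` (3-D array), `spacing`, `origin`.
#' @export
cost_image <- function(vol, enhancement_window = c(190, 1200), floor = 1,
                       hu_scale = 50, cap = 1000) {
  w <- as.numeric(enhancement_window)
  if (length(w) != 2 || !(w[1] < w[2])) stop("enhancement window needs low < high")
  if (floor <= 0) stop("cost floor must be > 0")
  v <- vol$voxels
  dhu <- pmax(w[1] - v, v - w[2], 0)
  cost <- floor * (1 + pmin((dhu / hu_scale)^2, cap - 1))
  structure(list(cost = cost, spacing = vol$spacing, origin = vol$origin,
                 floor = floor),
            class = "cost_image")
}

nearest_voxel <- function(obj, p) {
  idx <- round(world_to_voxel(obj, p))
  d <- dim(if (!is.null(obj$cost)) obj$cost else obj$voxels)
  if (any(idx < 0) || any(idx >= matrix(d, nrow(idx), 3, byrow = TRUE)))
    stop("point (", paste(format(p), collapse = ", "), ") lies outside the grid")
  idx
}

#' Minimum-cost path between two points
#'
#' Dijkstra's algorithm on the 26-connected voxel grid; each edge costs the
#' mean of its endpoint costs times the physical step length, so the optimum
#' is the discrete line integral of the cost field. Ties in the settle order
#' are broken by the smaller lexicographic voxel index, making the result
#' deterministic.
#'
#' @param cost a `cost_image` from [cost_image].
#' @param a,b world points (mm) inside the grid.
#' @return a [centerline_path] (not yet resampled) with attribute
#'   `total_cost`.
#' @export
min_cost_path <- function(cost, a, b) {
  ia <- nearest_voxel(cost, a); ib <- nearest_voxel(cost, b)
  d <- dim(cost$cost)
  lin_a <- ia[1] + d[1] * ia[2] + d[1] * d[2] * ia[3]
  lin_b <- ib[1] + d[1] * ib[2] + d[1] * d[2] * ib[3]
  res <- dijkstra_grid_cpp(as.numeric(cost$cost), d, cost$spacing,
                           as.integer(lin_a), as.integer(lin_b))
  if (length(res) == 0)
    stop("tracking error: no traversable path; gap near (",
         paste(format(round(b, 1)), collapse = ", "), ") mm")
  k <- res %/% (d[1] * d[2])
  j <- (res %% (d[1] * d[2])) %/% d[1]
  i <- res %% d[1]
  pts <- voxel_to_world(cost, cbind(i, j, k))
  out <- centerline_path("path", pts, resampled = FALSE)
  attr(out, "total_cost") <- attr(res, "total_cost")
  out
}

# orthonormal in-plane basis perpendicular to a tangent vector
plane_basis <- function(tangent) {
  t <- tangent / sqrt(sum(tangent^2))
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(t[2] * ref[3] - t[3] * ref[2],
         t[3] * ref[1] - t[1] * ref[3],
         t[1] * ref[2] - t[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(t[2] * u[3] - t[3] * u[2],
         t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  list(u = u, v = v, t = t)
}

# centroid of the connected above-threshold region containing `p` in the
# plane orthogonal to `tangent`; NULL when the centre sample is below
# threshold (no lumen)
plane_centroid <- function(vol, p, tangent, lumen_threshold,
                           max_radius = 8, step = NULL) {
  if (is.null(step)) step <- min(vol$spacing[1:2]) / 2
  B <- plane_basis(tangent)
  s <- seq(-max_radius, max_radius, by = step)
  n <- length(s)
  gu <- rep(s, times = n); gv <- rep(s, each = n)
  pts <- cbind(p[1] + gu * B$u[1] + gv * B$v[1],
               p[2] + gu * B$u[2] + gv * B$v[2],
               p[3] + gu * B$u[3] + gv * B$v[3])
  hu <- sample_trilinear(vol, pts, clamp = TRUE)
  mask <- hu >= lumen_threshold
  ctr <- (n + 1) %/% 2
  ctr_idx <- (ctr - 1) * n + ctr
  if (!mask[ctr_idx]) return(NULL)
  lab <- label_components_cpp(mask, c(n, n, 1L), 26L)
  sel <- lab == lab[ctr_idx]
  cu <- mean(gu[sel]); cv <- mean(gv[sel])
  list(centroid = p + cu * B$u + cv * B$v,
       area = sum(sel) * step^2, n_sel = sum(sel))
}

path_tangents <- function(points, window = 3L) {
  n <- nrow(points)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  # central difference over +-window points: damps the tilt that a noisy
  # single-step difference would feed into the orthogonal-plane estimate
  lo <- pmax(seq_len(n) - window, 1L)
  hi <- pmin(seq_len(n) + window, n)
  tg <- points[hi, , drop = FALSE] - points[lo, , drop = FALSE]
  # degenerate (backtracking) tangents default to the slice axis
  bad <- rowSums(tg^2) < 1e-12
  if (any(bad)) tg[bad, ] <- matrix(c(0, 0, 1), sum(bad), 3, byrow = TRUE)
  tg
}

#' Recenter a path on the lumen
#'
#' Moves every path point to the centroid of the connected above-threshold
#' lumen region around it in the plane orthogonal to the local tangent,
#' iterating to convergence (at most `max_iter` passes, 0.05 mm tolerance).
#' Points with no lumen cross-section (e.g. inside an occlusion) are flagged
#' and left in place. The result is resampled to one point per slice.
#'
#' @param vol a [ct_volume].
#' @param path a [centerline_path].
#' @param lumen_threshold HU threshold separating lumen from background.
#' @param max_iter,tol iteration control (passes, mm).
#' @param max_radius search radius (mm) of the orthogonal plane.
#' @return a resampled [centerline_path] with `flagged` marking empty
#'   cross-sections.
#' @export
recenter <- function(vol, path, lumen_threshold, max_iter = 10, tol = 0.05,
                     max_radius = 8) {
  pts <- path$points
  flagged <- rep(FALSE, nrow(pts))
  for (it in seq_len(max_iter)) {
    tg <- path_tangents(pts)
    moved <- 0
    for (i in seq_len(nrow(pts))) {
      res <- plane_centroid(vol, pts[i, ], tg[i, ], lumen_threshold,
                            max_radius = max_radius)
      if (is.null(res)) { flagged[i] <- TRUE; next }
      flagged[i] <- FALSE
      # move in-plane only (keep z): stabilises against axial drift
      new <- res$centroid
      moved <- max(moved, sqrt(sum((new[1:2] - pts[i, 1:2])^2)))
      pts[i, 1:2] <- new[1:2]
    }
    if (moved <= tol) break
  }
  # flags must describe the final positions, not the pre-move ones
  tg <- path_tangents(pts)
  for (i in seq_len(nrow(pts)))
    flagged[i] <- is.null(plane_centroid(vol, pts[i, ], tg[i, ],
                                         lumen_threshold,
                                         max_radius = max_radius))
  rp <- resample_polyline(pts, slice_z(vol), name = path$name,
                          flagged = flagged, warn = FALSE)
  if (is.null(rp)) stop("recentered path '", path$name,
                        "' covers fewer than two slices")
  rp
}

#' Assemble a centerline tree from control points
#'
#' For each endpoint, concatenates minimum-cost paths between consecutive
#' control points (the first of which must be the common root), recenters on
#' the lumen and resamples to one point per slice. Occlusions are bridged by
#' supplying intermediate control points through the occluded extent.
#'
#' @param vol a [ct_volume].
#' @param control_points named list; each element an n x 3 matrix of world
#'   points ordered root -> endpoint (n >= 2).
#' @param enhancement_window,cost_floor passed to [cost_image].
#' @param lumen_threshold HU threshold for recentering.
#' @param recenter_paths logical; recenter after tracking (default `TRUE`).
#' @param max_radius recentering search radius (mm).
#' @return a [centerline_tree]; attribute `trunk_shared` gives, per path,
#'   the number of leading slices shared with the first path.
#' @export
build_tree <- function(vol, control_points, enhancement_window = c(190, 1200),
                       cost_floor = 1, lumen_threshold = 140,
                       recenter_paths = TRUE, max_radius = 8) {
  if (is.null(names(control_points)) || any(names(control_points) == ""))
    stop("control_points must be a named list (one entry per endpoint)")
  cim <- cost_image(vol, enhancement_window, floor = cost_floor)
  root <- as_point_matrix(control_points[[1]])[1, ]
  paths <- list()
  for (ep in names(control_points)) {
    cp <- as_point_matrix(control_points[[ep]])
    if (max(abs(cp[1, ] - root)) > 1e-9)
      stop("endpoint '", ep, "': control points must start at the common root")
    if (nrow(unique(cp)) < 2)
      stop("endpoint '", ep, "': need at least two distinct control points")
    pts <- NULL
    for (s in seq_len(nrow(cp) - 1)) {
      leg <- tryCatch(min_cost_path(cim, cp[s, ], cp[s + 1, ]),
                      error = function(e)
                        stop("endpoint '", ep, "': ", conditionMessage(e),
                             call. = FALSE))
      pts <- if (is.null(pts)) leg$points else
        rbind(pts, leg$points[-1, , drop = FALSE])
    }
    p <- centerline_path(ep, pts)
    paths[[ep]] <- if (recenter_paths)
      recenter(vol, p, lumen_threshold, max_radius = max_radius)
    else {
      rp <- resample_polyline(pts, slice_z(vol), name = ep, warn = FALSE)
      if (is.null(rp)) stop("endpoint '", ep, "' covers fewer than two slices")
      rp
    }
  }
  first <- paths[[1]]
  shared <- vapply(paths, function(p) {
    n <- min(nrow(p$points), nrow(first$points))
    off <- p$slices[1] - first$slices[1]
    if (off != 0 || n == 0) return(0L)
    dif <- sqrt(rowSums((p$points[seq_len(n), , drop = FALSE] -
                           first$points[seq_len(n), , drop = FALSE])^2))
    m <- which(dif > min(vol$spacing))
    if (length(m)) m[1] - 1L else n
  }, integer(1))
  tol <- max(vol$spacing) + 1e-6
  tree <- centerline_tree(first$points[1, ], paths, root_tol = max(tol, 2 * max(vol$spacing)))
  attr(tree, "trunk_shared") <- shared
  tree
}

#' Detect step formations along a resampled path
#'
#' A step formation is an abrupt in-plane jump between consecutive slices —
#' the footprint of the tracker switching between an artery and its
#' accompanying vein across an occlusion. Every slice transition whose
#' in-plane displacement exceeds `jump_threshold` is reported.
#'
#' @param path a resampled [centerline_path].
#' @param jump_threshold mm (default 3, the calibre of a typical
#'   artery-vein offset).
#' @return data frame with columns `slice` (0-based index of the latter
#'   slice) and `jump_mm`.
#' @export
detect_steps <- function(path, jump_threshold = 3) {
  if (!path$resampled) stop("detect_steps needs a resampled path")
  n <- nrow(path$points)
  if (n < 2) return(data.frame(slice = integer(0), jump_mm = numeric(0)))
  dxy <- sqrt(rowSums((path$points[-1, 1:2, drop = FALSE] -
                         path$points[-n, 1:2, drop = FALSE])^2))
  hit <- which(dxy > jump_threshold)
  data.frame(slice = path$slices[hit + 1], jump_mm = dxy[hit])
}
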