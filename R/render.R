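#' Rotation series viewing angles
#'
#' Inclusive arithmetic sequence of viewing angles from `-range_deg/2` to
#' `+range_deg/2`: the convention is -90 right-lateral, 0 anteroposterior,
#' +90 left-lateral. The clinical series spans 180 degrees in 9-degree
#' intervals, giving 21 views.
#'
#' @param range_deg total span (degrees).
#' @param step_deg increment (degrees); must divide `range_deg`.
#' @return numeric vector of length `range_deg / step_deg + 1`.
#' @export
rotation_angles <- function(range_deg = 180, step_deg = 9) {
  if (step_deg <= 0 || range_deg <= 0) stop("angles must be positive")
  k <- range_deg / step_deg
  if (abs(k - round(k)) > 1e-9) stop("step_deg must divide range_deg")
  seq(-range_deg / 2, range_deg / 2, by = step_deg)
}

# viewing geometry: d = ray direction, u = screen-horizontal axis, both
# in-plane unit vectors. angle 0 looks along +y (anteroposterior);
# +90 looks along +x (left-lateral).
view_axes <- function(angle) {
  th <- angle * pi / 180
  if (angle < -90 || angle > 90) stop("viewing angle must lie in [-90, +90]")
  list(d = c(sin(th), cos(th), 0), u = c(cos(th), -sin(th), 0))
}

new_reformat_image <- function(pixels, angle, attribution, row_spacing,
                               col_spacing, cols, sample_points = NULL,
                               mode = "cpr") {
  structure(list(pixels = pixels, angle = angle, attribution = attribution,
                 row_spacing = row_spacing, col_spacing = col_spacing,
                 cols = cols, sample_points = sample_points, mode = mode),
            class = "reformat_image")
}

#' @export
print.reformat_image <- function(x, ...) {
  cat(sprintf("<reformat_image> %s, %d slices x %d columns, angle %+.0f deg\n",
              x$mode, nrow(x$pixels), ncol(x$pixels), x$angle))
  invisible(x)
}

#' @export
dim.reformat_image <- function(x) dim(x$pixels)

#' Curved planar reformation of a single path
#'
#' For every axial slice, samples the volume along the in-plane line through
#' the path point at that slice, oriented perpendicular to the viewing
#' direction and centred on the path point, over `+-halfwidth`. Row index
#' equals slice index (full z resolution); attenuation is taken by trilinear
#' interpolation, never remapped. Slices not covered by the path render as
#' -1024 with no attribution.
#'
#' @param vol a [ct_volume].
#' @param path a resampled [centerline_path].
#' @param angle viewing angle in degrees, `[-90, +90]`.
#' @param halfwidth lateral extent each side of the path (mm).
#' @param col_spacing lateral sample spacing (mm); defaults to the smaller
#'   in-plane voxel spacing.
#' @return a `reformat_image`: `pixels` (rows = slices), `attribution`
#'   (path name or `NA`), `cols` (lateral offsets mm), `sample_points`
#'   (n x 3 matrix of the 3-D sampling position of every attributed pixel,
#'   row-major by image row).
#' @export
render_cpr <- function(vol, path, angle = 0, halfwidth = 10,
                       col_spacing = NULL) {
  if (!path$resampled) stop("render_cpr needs a resampled path")
  if (halfwidth <= 0) stop("halfwidth must be > 0")
  if (is.null(col_spacing)) col_spacing <- min(vol$spacing[1:2])
  ax <- view_axes(angle)
  nz <- dim(vol$voxels)[3]
  s <- seq(-halfwidth, halfwidth, by = col_spacing)
  nc <- length(s)
  px <- matrix(-1024, nz, nc)
  att <- matrix(NA_character_, nz, nc)
  rows <- path$slices + 1L
  bad <- rows < 1 | rows > nz
  if (any(bad))
    stop("render error: path outside volume at slices ",
         paste(path$slices[bad], collapse = ", "))
  npt <- length(rows)
  gx <- rep(path$points[, 1], each = nc) + rep(s, npt) * ax$u[1]
  gy <- rep(path$points[, 2], each = nc) + rep(s, npt) * ax$u[2]
  gz <- rep(path$points[, 3], each = nc)
  vals <- sample_trilinear(vol, cbind(gx, gy, gz))
  px[rows, ] <- matrix(vals, npt, nc, byrow = TRUE)
  att[rows, ] <- path$name
  # sample positions indexed like the pixel matrix (column-major linear index)
  spt <- matrix(NA_real_, nz * nc, 3)
  pix_lin <- rep((seq_len(nc) - 1L) * nz, each = npt) + rep(rows, nc)
  src_ord <- rep(seq_len(npt), nc) # gx is row-major (point-major) order
  spt[pix_lin, ] <- cbind(gx, gy, gz)[(src_ord - 1L) * nc +
                                        rep(seq_len(nc), each = npt), ]
  new_reformat_image(px, angle, att, row_spacing = vol$spacing[3],
                     col_spacing = col_spacing, cols = s,
                     sample_points = spt, mode = "cpr")
}

#' Multipath curved planar reformation
#'
#' Composites the whole arterial tree into one image. Per slice, every image
#' column at screen abscissa `x` is attributed to the path whose projected
#' centerline abscissa is nearest (ties to the leftmost path on screen);
#' columns within `halfwidth` of the winning path are trilinear samples of
#' the volume on the line through that path point perpendicular to the view
#' — so vessels appear at their projected screen position and left/right
#' anatomical ordering follows the projection. Columns farther than
#' `halfwidth` from every path show context: nothing (-1024) or a thin-slab
#' maximum intensity projection around the tree's depth.
#'
#' @param vol a [ct_volume].
#' @param tree a [centerline_tree] of resampled paths.
#' @param angle viewing angle in degrees.
#' @param halfwidth per-path lateral extent (mm).
#' @param context `"slab_mip"` (default) or `"none"`.
#' @param slab thin-slab thickness (mm) for the context MIP.
#' @param col_spacing lateral sample spacing (mm).
#' @return a `reformat_image` with per-pixel `attribution` (path name,
#'   `"context"`, or `NA`).
#' @export
render_mpcpr <- function(vol, tree, angle = 0, halfwidth = 10,
                         context = c("slab_mip", "none"), slab = 20,
                         col_spacing = NULL) {
  context <- match.arg(context)
  if (is.null(col_spacing)) col_spacing <- min(vol$spacing[1:2])
  ax <- view_axes(angle)
  nz <- dim(vol$voxels)[3]
  paths <- tree$paths
  np <- length(paths)
  # projected abscissa (screen x) and depth of every path at every slice
  A <- matrix(NA_real_, nz, np)
  D <- matrix(NA_real_, nz, np)
  for (ip in seq_len(np)) {
    p <- paths[[ip]]
    if (!p$resampled) stop("all tree paths must be resampled")
    r <- p$slices + 1L
    A[r, ip] <- p$points[, 1] * ax$u[1] + p$points[, 2] * ax$u[2]
    D[r, ip] <- p$points[, 1] * ax$d[1] + p$points[, 2] * ax$d[2]
  }
  if (np >= 2) {
    same <- 0
    for (ip in 2:np)
      same <- max(same, sum(abs(A[, 1] - A[, ip]) < col_spacing / 2, na.rm = TRUE))
    if (same > 0.5 * nz)
      warning("paths share projected abscissa over >50% of slices ",
              "(expected near lateral views)")
  }
  rngA <- range(A, na.rm = TRUE)
  cols <- seq(rngA[1] - halfwidth, rngA[2] + halfwidth, by = col_spacing)
  nc <- length(cols)
  px <- matrix(-1024, nz, nc)
  att <- matrix(NA_character_, nz, nc)
  spt <- matrix(NA_real_, nz * nc, 3)
  pnames <- names(paths)
  for (z in seq_len(nz)) {
    act <- which(!is.na(A[z, ]))
    if (!length(act)) next
    a <- A[z, act]
    # nearest projected abscissa; ties -> leftmost on screen (smaller a)
    dmat <- abs(outer(cols, a, "-"))
    ord <- order(a)
    dmat <- dmat[, ord, drop = FALSE]
    win <- max.col(-dmat, ties.method = "first")
    wdist <- dmat[cbind(seq_len(nc), win)]
    winp <- act[ord][win]
    inside <- wdist <= halfwidth
    if (any(inside)) {
      pidx <- winp[inside]
      aw <- A[z, ][pidx]
      off <- cols[inside] - aw
      p3 <- do.call(rbind, lapply(seq_along(pidx), function(q) {
        pp <- paths[[pidx[q]]]
        pp$points[match(z - 1L, pp$slices), ]
      }))
      gpt <- cbind(p3[, 1] + off * ax$u[1], p3[, 2] + off * ax$u[2], p3[, 3])
      px[z, inside] <- sample_trilinear(vol, gpt)
      att[z, inside] <- pnames[pidx]
      spt[(which(inside) - 1L) * nz + z, ] <- gpt
    }
    if (context == "slab_mip" && any(!inside)) {
      dc <- mean(D[z, act])
      ts <- seq(dc - slab / 2, dc + slab / 2, by = col_spacing)
      cc <- cols[!inside]
      gx <- rep(cc, each = length(ts)) * ax$u[1] + rep(ts, length(cc)) * ax$d[1]
      gy <- rep(cc, each = length(ts)) * ax$u[2] + rep(ts, length(cc)) * ax$d[2]
      zz <- vol$origin[3] + (z - 1) * vol$spacing[3]
      vv <- sample_trilinear(vol, cbind(gx, gy, zz))
      px[z, !inside] <- apply(matrix(vv, length(ts), length(cc)), 2, max)
      att[z, !inside] <- "context"
    }
  }
  new_reformat_image(px, angle, att, row_spacing = vol$spacing[3],
                     col_spacing = col_spacing, cols = cols,
                     sample_points = spt, mode = "mpcpr")
}

#' Bone segmentation mask
#'
#' Thresholds the volume, keeps connected components (26-connectivity) of at
#' least `min_component_voxels`, and closes the mask morphologically
#' (3x3x3 box, `closing_iter` passes). The size filter is what keeps small
#' high-attenuation structures — stent shells, focal calcifications — out of
#' the bone mask.
#'
#' @param vol a [ct_volume].
#' @param hu_threshold HU threshold (default 700).
#' @param min_component_voxels smallest component kept (default 2000).
#' @param closing_iter morphological closing passes (default 1; 0 disables).
#' @return logical 3-D array, `TRUE` = bone.
#' @export
segment_bones <- function(vol, hu_threshold = 700, min_component_voxels = 2000,
                          closing_iter = 1) {
  d <- dim(vol$voxels)
  mask <- vol$voxels >= hu_threshold
  if (!any(mask)) return(array(FALSE, d))
  lab <- label_components_cpp(mask, d, 26L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_component_voxels)
  mask <- array(lab %in% keep, d)
  for (i in seq_len(closing_iter)) {
    mask <- array(morph3_cpp(mask, d, 1L), d)
    mask <- array(morph3_cpp(mask, d, 0L), d)
  }
  mask
}

#' Maximum intensity projection with bone suppression
#'
#' Per slice and per screen column, the maximum attenuation along the
#' viewing ray, with bone-mask voxels excluded (treated as air). Rays are
#' sampled trilinearly at the in-plane voxel pitch; at axis-aligned angles
#' (0, +-90) the samples coincide with voxel centres and the projection is
#' exact.
#'
#' @param vol a [ct_volume].
#' @param mask logical array of [segment_bones] shape, or `NULL`.
#' @param angle viewing angle in degrees.
#' @param col_spacing screen column pitch (mm); defaults to the smaller
#'   in-plane spacing.
#' @return a `reformat_image` (attribution `"mip"` everywhere).
#' @export
render_mip <- function(vol, mask = NULL, angle = 0, col_spacing = NULL) {
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(vol$voxels)))
      stop("mask shape must equal volume shape")
    v2 <- vol$voxels
    v2[mask] <- -1024
    vol <- ct_volume(v2, vol$spacing, vol$origin)
  }
  if (is.null(col_spacing)) col_spacing <- min(vol$spacing[1:2])
  ax <- view_axes(angle)
  d <- dim(vol$voxels)
  xs <- vol$origin[1] + c(0, d[1] - 1) * vol$spacing[1]
  ys <- vol$origin[2] + c(0, d[2] - 1) * vol$spacing[2]
  corners <- as.matrix(expand.grid(xs, ys))
  su <- corners %*% ax$u[1:2]
  sd <- corners %*% ax$d[1:2]
  cols <- seq(min(su), max(su), by = col_spacing)
  ts <- seq(min(sd), max(sd), by = col_spacing)
  nc <- length(cols); nt <- length(ts); nz <- d[3]
  gx <- rep(cols, each = nt) * ax$u[1] + rep(ts, nc) * ax$d[1]
  gy <- rep(cols, each = nt) * ax$u[2] + rep(ts, nc) * ax$d[2]
  px <- matrix(-1024, nz, nc)
  for (z in seq_len(nz)) {
    zz <- vol$origin[3] + (z - 1) * vol$spacing[3]
    vv <- sample_trilinear(vol, cbind(gx, gy, zz))
    px[z, ] <- apply(matrix(vv, nt, nc), 2, max)
  }
  att <- matrix("mip", nz, nc)
  new_reformat_image(px, angle, att, row_spacing = vol$spacing[3],
                     col_spacing = col_spacing, cols = cols, mode = "mip")
}

#' Render the 21-view rotation series
#'
#' One image per angle of `rotation_angles(180, 9)` — right-lateral (-90)
#' through anteroposterior (0) to left-lateral (+90) in 9-degree steps —
#' fully automatic, each stamped with its viewing angle.
#'
#' @param vol a [ct_volume].
#' @param tree a [centerline_tree] (required for modes `"mpcpr"`/`"cpr"`).
#' @param mode `"mpcpr"` or `"mip"`.
#' @param mask bone mask for `"mip"` (`NULL` = no suppression).
#' @param range_deg,step_deg series geometry (defaults 180 and 9).
#' @param ... passed to the per-angle renderer.
#' @return list of `reformat_image`, one per angle.
#' @export
render_series <- function(vol, tree = NULL, mode = c("mpcpr", "mip"),
                          mask = NULL, range_deg = 180, step_deg = 9, ...) {
  mode <- match.arg(mode)
  angles <- rotation_angles(range_deg, step_deg)
  lapply(angles, function(a) {
    if (mode == "mpcpr") {
      if (is.null(tree)) stop("mpcpr series needs a centerline tree")
      render_mpcpr(vol, tree, angle = a, ...)
    } else {
      render_mip(vol, mask = mask, angle = a, ...)
    }
  })
}
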