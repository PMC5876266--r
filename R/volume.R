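#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of attenuation values in Hounsfield units
#' together with its physical geometry. Axis 1 and 2 are the in-plane (x, y)
#' axes; axis 3 is the slice (z, cranio-caudal) axis, so every reformation
#' produces one output row per slice. Geometry is axis-aligned:
#' `world = origin + index * spacing` with 0-based voxel indices. Oblique
#' direction cosines are not modelled; inputs that need them are rejected at
#' read time.
#'
#' @param voxels 3-D numeric array of attenuation values (HU).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0, 0, 0).
#' @param clamp clamp voxel values into the valid CT range
#'   \eqn{[-1024, 4000]} HU (default `TRUE`); with `clamp = FALSE`,
#'   out-of-range values are an error.
#' @return An object of class `ct_volume`: a list with elements `voxels`,
#'   `spacing`, `origin`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), clamp = TRUE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  storage.mode(voxels) <- "double"
  rng <- range(voxels, finite = TRUE)
  if (rng[1] < -1024 || rng[2] > 4000) {
    if (clamp) {
      voxels[voxels < -1024] <- -1024
      voxels[voxels > 4000] <- 4000
    } else {
      stop("attenuation values must lie in [-1024, 4000] HU")
    }
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm, HU range [%.1f, %.1f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

as_point_matrix <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop("points must have three columns (x, y, z)")
  storage.mode(pts) <- "double"
  pts
}

#' Convert between world coordinates and voxel indices
#'
#' Voxel indices are 0-based and fractional; `world = origin + index * spacing`.
#'
#' @param vol a [ct_volume] (or any list with `spacing` and `origin`).
#' @param pts numeric matrix (n x 3) or length-3 vector of world points (mm)
#'   for `world_to_voxel`, or of 0-based voxel indices for `voxel_to_world`.
#' @return n x 3 matrix of 0-based fractional voxel indices, resp. world mm.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- as_point_matrix(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, pts) {
  pts <- as_point_matrix(pts)
  sweep(sweep(pts, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Trilinear sampling of a volume at world positions
#'
#' Samples lying outside the voxel-centre bounding box return `outside`
#' (default -1024 HU, the air floor), which defines the renderers' boundary
#' behaviour.
#'
#' @param vol a [ct_volume].
#' @param pts n x 3 matrix of world points (mm).
#' @param outside value returned for out-of-volume samples.
#' @param clamp if `TRUE`, out-of-volume positions are clamped to the
#'   voxel-centre bounding box (replicate-boundary sampling) instead of
#'   returning `outside`; used by measurements that must not see an
#'   artificial air border at the first and last slice.
#' @return numeric vector of length n.
#' @export
sample_trilinear <- function(vol, pts, outside = -1024, clamp = FALSE) {
  idx <- world_to_voxel(vol, pts)
  d <- dim(vol$voxels)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  if (clamp) {
    x <- pmin(pmax(x, 0), d[1] - 1)
    y <- pmin(pmax(y, 0), d[2] - 1)
    z <- pmin(pmax(z, 0), d[3] - 1)
  }
  inside <- is.finite(x) & is.finite(y) & is.finite(z) &
    x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  out <- rep(outside, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 2L); y0 <- pmin(floor(y), d[2] - 2L)
  z0 <- pmin(floor(z), d[3] - 2L)
  # degenerate axes (single-voxel extent): pin to index 0 with zero fraction
  if (d[1] < 2) x0 <- rep(0, length(x))
  if (d[2] < 2) y0 <- rep(0, length(y))
  if (d[3] < 2) z0 <- rep(0, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  nx <- d[1]; nxy <- d[1] * d[2]
  sx <- if (d[1] < 2) 0L else 1L
  sy <- if (d[2] < 2) 0L else 1L
  sz <- if (d[3] < 2) 0L else 1L
  base <- x0 + nx * y0 + nxy * z0 + 1
  v <- vol$voxels
  c000 <- v[base]
  c100 <- v[base + sx]
  c010 <- v[base + sy * nx]
  c110 <- v[base + sx + sy * nx]
  c001 <- v[base + sz * nxy]
  c101 <- v[base + sx + sz * nxy]
  c011 <- v[base + sy * nx + sz * nxy]
  c111 <- v[base + sx + sy * nx + sz * nxy]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' World z coordinate of every slice centre
#' @param vol a [ct_volume].
#' @return numeric vector of length `dim(vol)[3]`.
#' @export
slice_z <- function(vol) {
  vol$origin[3] + (seq_len(dim(vol$voxels)[3]) - 1) * vol$spacing[3]
}
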