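#' Lumen caliber profile along a centerline
#'
#' For every slice of a resampled path, measures the cross-sectional lumen
#' area in the plane orthogonal to the local tangent: trilinear samples on a
#' sub-voxel plane grid are thresholded and the connected region containing
#' the centerline point is counted (area = cells x cell area). Slices whose
#' centerline sample falls below the threshold — occlusions, contrast
#' gaps — are marked unassessable with area 0. The effective diameter is
#' the diameter of the circle of equal area, `2 * sqrt(area / pi)`.
#'
#' @param vol a [ct_volume].
#' @param path a resampled [centerline_path].
#' @param lumen_threshold HU threshold; the package default is background
#'   + 100 HU, below the 150-HU enhancement floor so moderate noise does
#'   not break up the lumen.
#' @param max_radius plane half-extent (mm), default 8.
#' @param plane_step plane sampling pitch (mm); default one quarter of the
#'   in-plane voxel spacing for sub-voxel area resolution.
#' @return a `lumen_profile` data frame: `slice` (0-based), `arclength`
#'   (mm), `area` (mm^2), `diameter` (mm), `assessable`.
#' @export
lumen_profile <- function(vol, path, lumen_threshold = 140, max_radius = 8,
                          plane_step = NULL) {
  if (!path$resampled) stop("lumen_profile needs a resampled path")
  if (is.null(plane_step)) plane_step <- min(vol$spacing[1:2]) / 4
  n <- nrow(path$points)
  tg <- path_tangents(path$points)
  arc <- path_arclength(path$points)
  area <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    res <- plane_centroid(vol, path$points[i, ], tg[i, ], lumen_threshold,
                          max_radius = max_radius, step = plane_step)
    if (is.null(res)) { area[i] <- 0; ok[i] <- FALSE }
    else { area[i] <- res$area; ok[i] <- TRUE }
  }
  out <- data.frame(slice = path$slices, arclength = arc, area = area,
                    diameter = 2 * sqrt(area / pi), assessable = ok)
  class(out) <- c("lumen_profile", class(out))
  out
}

#' Grade the worst stenosis in a segment
#'
#' Implements the hemodynamic-significance rule: the worst diameter
#' stenosis of the segment, `100 * (1 - d_min / d_ref)` percent, is
#' significant strictly above 70 percent. The reference diameter is the
#' median effective diameter over the segment's assessable slices after
#' excluding the narrowest `trim` fraction (default 20 percent), so the
#' lesion itself does not drag the reference down. Occluded slices (area 0)
#' grade the segment 100 percent; a fully unassessable extent returns the
#' non-assessable verdict `na_low_contrast` (callers may override the
#' category when the cause is known, e.g. calcification or stent artifact).
#'
#' @param profile a [lumen_profile].
#' @param extent half-open arclength interval `c(start, end)` (mm) within
#'   the profile.
#' @param trim fraction of narrowest slices excluded from the reference
#'   (default 0.2).
#' @return one-row data frame: `worst_percent`, `verdict`
#'   (`"significant"`, `"non_significant"` or an `na_*` category), `d_min`,
#'   `d_ref`, `n_slices`.
#' @export
grade_segment <- function(profile, extent, trim = 0.2) {
  if (length(extent) != 2 || !(extent[1] < extent[2]))
    stop("extent must be c(start, end) with start < end")
  sel <- profile$arclength >= extent[1] & profile$arclength < extent[2]
  if (!any(sel)) stop("extent lies outside the profile")
  sub <- profile[sel, ]
  if (!any(sub$assessable)) {
    return(data.frame(worst_percent = NA_real_, verdict = "na_low_contrast",
                      d_min = NA_real_, d_ref = NA_real_,
                      n_slices = nrow(sub), stringsAsFactors = FALSE))
  }
  dia <- sub$diameter[sub$assessable]
  dref <- stats::median(dia[dia >= stats::quantile(dia, trim, names = FALSE)])
  dmin <- if (all(sub$assessable)) min(dia) else 0 # occluded slices inside
  worst <- 100 * (1 - dmin / dref)
  worst <- min(max(worst, 0), 100)
  data.frame(worst_percent = worst,
             verdict = if (worst > 70) "significant" else "non_significant",
             d_min = dmin, d_ref = dref, n_slices = nrow(sub),
             stringsAsFactors = FALSE)
}

#' Map model segments onto tree paths
#'
#' Assigns each anatomical segment of the leg model to one path of the
#' tracked tree and a half-open arclength interval on it. A segment is
#' carried by the first path (in tree order) whose root-to-endpoint branch
#' chain contains it; the interval is delimited by the segment's z extent
#' in the model, so consecutive segments partition their parent artery
#' exactly. Proximal/middle/distal thirds are separate model branches of
#' equal design length, which realises the equal-arclength split.
#'
#' @param tree a [centerline_tree] whose path names are terminal branch
#'   names of the model.
#' @param model named list of [vessel_branch] (e.g. [default_tree] or
#'   [default_leg_tree]).
#' @return data frame: `segment`, `side`, `group`, `path`, `z_start`,
#'   `z_end`, `start_mm`, `end_mm` (arclength on the carrying path).
#' @export
map_segments <- function(tree, model) {
  terms <- names(tree$paths)
  missing <- setdiff(terms, names(model))
  if (length(missing))
    stop("mapping error: tree endpoint '", missing[1],
         "' is not a branch of the model")
  chains <- lapply(terms, function(tb) branch_chain(model, tb))
  names(chains) <- terms
  rated <- names(model)[!vapply(model, function(b) is.na(b$group), logical(1))]
  rows <- list()
  for (sg in rated) {
    carrier <- NULL
    for (tb in terms) if (sg %in% chains[[tb]]) { carrier <- tb; break }
    if (is.null(carrier)) {
      art <- sub("-(prox|mid|dist)$", "", sg)
      stop("mapping error: no tree endpoint reaches the ", art, " artery ('",
           sg, "')")
    }
    b <- model[[sg]]
    zr <- range(b$points[, 3])
    p <- tree$paths[[carrier]]
    arc <- path_arclength(p$points)
    z <- p$points[, 3]
    inz <- which(z >= zr[1] - 1e-9 & z < zr[2] - 1e-9)
    if (!length(inz))
      stop("mapping error: path '", carrier, "' does not cover segment '",
           sg, "'")
    i0 <- inz[1]; i1 <- inz[length(inz)]
    start_mm <- arc[i0]
    end_mm <- if (i1 < length(arc)) arc[i1 + 1] else arc[i1] + 1e-9
    rows[[sg]] <- data.frame(segment = sg, side = b$side, group = b$group,
                             path = carrier, z_start = zr[1], z_end = zr[2],
                             start_mm = start_mm, end_mm = end_mm,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grade every mapped segment of a tree
#'
#' Convenience wrapper: computes one lumen profile per tree path and grades
#' each mapped segment, emitting the per-segment rating table used by the
#' diagnostic-performance module.
#'
#' @param vol a [ct_volume].
#' @param tree a [centerline_tree].
#' @param model branch model for [map_segments].
#' @param lumen_threshold,max_radius,plane_step passed to [lumen_profile].
#' @param trim passed to [grade_segment].
#' @return data frame: `segment`, `side`, `group`, `verdict`,
#'   `worst_percent`, `d_min`, `d_ref`.
#' @export
grade_tree <- function(vol, tree, model, lumen_threshold = 140,
                       max_radius = 8, plane_step = NULL, trim = 0.2) {
  mp <- map_segments(tree, model)
  profiles <- lapply(tree$paths, lumen_profile, vol = vol,
                     lumen_threshold = lumen_threshold,
                     max_radius = max_radius, plane_step = plane_step)
  res <- lapply(seq_len(nrow(mp)), function(i) {
    g <- grade_segment(profiles[[mp$path[i]]],
                       c(mp$start_mm[i], mp$end_mm[i]), trim = trim)
    cbind(mp[i, c("segment", "side", "group")], g)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
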