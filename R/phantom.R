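#' Vessel branch description
#'
#' A branch is one named arterial segment of the leg model: a world-space
#' axis polyline (monotone in z, the cranio-caudal axis) with a lumen radius
#' in mm. Branches chain via `parent` to form the arterial tree.
#'
#' @param name segment label from the 21-segment leg model (e.g. `"SFA-mid"`).
#' @param points axis polyline, n x 3 world mm, z strictly increasing.
#' @param radius lumen radius in mm (> 0).
#' @param parent name of the parent branch (`NA` for a root branch).
#' @param group anatomical group: `"iliac"`, `"femoro-popliteal"` or
#'   `"infra-popliteal"`.
#' @param side `"left"`, `"right"` or `NA` for midline vessels.
#' @return an object of class `vessel_branch`.
#' @export
vessel_branch <- function(name, points, radius, parent = NA_character_,
                          group = NA_character_, side = NA_character_) {
  points <- as_point_matrix(points)
  if (nrow(points) < 2) stop("a branch needs at least two axis points")
  if (any(diff(points[, 3]) <= 0)) stop("branch '", name, "' axis must be monotone in z")
  if (!is.finite(radius) || radius <= 0) stop("branch radius must be > 0")
  structure(list(name = name, points = points, radius = radius,
                 parent = parent, group = group, side = side),
            class = "vessel_branch")
}

#' Lesion description
#'
#' @param kind `"stenosis"`, `"occlusion"`, `"calcification"` or `"stent"`.
#' @param segment name of the branch carrying the lesion.
#' @param start arclength (mm) of the lesion start within that branch.
#' @param length lesion length (mm).
#' @param severity diameter-reduction fraction `1 - d_min/d_ref`: in (0, 1)
#'   for stenosis, 1 for occlusion; for calcification/stent an optional
#'   concomitant narrowing (default 0).
#' @return an object of class `vessel_lesion`.
#' @export
lesion <- function(kind = c("stenosis", "occlusion", "calcification", "stent"),
                   segment, start, length, severity = NULL) {
  kind <- match.arg(kind)
  if (is.null(severity))
    severity <- switch(kind, stenosis = stop("stenosis needs a severity"),
                       occlusion = 1, 0)
  if (kind == "stenosis" && (severity <= 0 || severity >= 1))
    stop("stenosis severity must lie in (0, 1)")
  if (kind == "occlusion" && severity != 1)
    stop("occlusion severity is 1 by definition")
  if (start < 0 || length <= 0) stop("lesion extent must be positive")
  structure(list(kind = kind, segment = segment, start = start,
                 length = length, severity = severity),
            class = "vessel_lesion")
}

#' Synthetic peripheral-CTA phantom specification
#'
#' Describes a synthetic contrast-enhanced CTA volume: an arterial tree of
#' [vessel_branch] tubes at `lumen_hu` over a `background_hu` soft-tissue
#' bed, optional bone cylinders, lesions, and an early-enhancing accompanying
#' vein parallel to a named artery. The arterial enhancement must be at
#' least 150 HU over background, mirroring the bolus-trigger target of
#' clinical run-off CTA. Default HU palette (all overridable): soft tissue
#' 40, lumen 400, bone 1000, calcification 800, stent 2000, vein 300 —
#' plausible 80-kV values.
#'
#' @param shape grid dimensions, length 3 (nx, ny, nz).
#' @param spacing voxel size mm, length 3.
#' @param origin world position of voxel (0,0,0), mm.
#' @param tree list of [vessel_branch].
#' @param lesions list of [lesion].
#' @param bones list of tubes, each `list(points =, radius =)`, rendered at
#'   `bone_hu`.
#' @param background_hu,lumen_hu,bone_hu,calcification_hu,stent_hu,vein_hu
#'   tissue attenuation levels (HU).
#' @param noise_sd Gaussian noise standard deviation (HU), >= 0.
#' @param vein_overlay `NULL`, or `list(artery = <branch names>, offset =
#'   <mm, scalar x-offset or 3-vector>, radius = <mm or NULL>)` adding an
#'   enhancing vein parallel to the named arteries (default offset 3 mm).
#' @param seed integer seed making the noise reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         tree, lesions = list(), bones = list(),
                         background_hu = 40, lumen_hu = 400, bone_hu = 1000,
                         calcification_hu = 800, stent_hu = 2000,
                         vein_hu = 300, noise_sd = 0, vein_overlay = NULL,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 2)) stop("shape must be three sizes >= 2")
  if (lumen_hu - background_hu < 150)
    stop("arterial enhancement must be >= 150 HU over background")
  hu <- c(background_hu, lumen_hu, bone_hu, calcification_hu, stent_hu, vein_hu)
  if (any(hu < -1024 | hu > 4000)) stop("HU levels must lie in [-1024, 4000]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!length(tree)) stop("the tree needs at least one branch")
  ids <- vapply(tree, function(b) b$name, character(1))
  if (anyDuplicated(ids)) stop("duplicate branch name: ", ids[duplicated(ids)][1])
  for (l in lesions) {
    if (!l$segment %in% ids)
      stop("lesion references unknown segment '", l$segment, "'")
    blen <- max(path_arclength(tree[[which(ids == l$segment)]]$points))
    if (l$start + l$length > blen + 1e-6)
      stop("lesion extent exceeds segment '", l$segment, "' length")
  }
  if (!is.null(vein_overlay)) {
    if (is.null(vein_overlay$offset)) vein_overlay$offset <- 3
    if (length(vein_overlay$offset) == 1)
      vein_overlay$offset <- c(vein_overlay$offset, 0, 0)
    if (!all(vein_overlay$artery %in% ids))
      stop("vein_overlay references unknown segment")
  }
  names(tree) <- ids
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), tree = tree, lesions = lesions,
                 bones = bones, background_hu = background_hu,
                 lumen_hu = lumen_hu, bone_hu = bone_hu,
                 calcification_hu = calcification_hu, stent_hu = stent_hu,
                 vein_hu = vein_hu, noise_sd = noise_sd,
                 vein_overlay = vein_overlay, seed = as.integer(seed)),
            class = "phantom_spec")
}

# raised-cosine radius profile of a stenosis over [start, start + length):
# factor 1 at the edges, 1 - severity at the lesion centre
stenosis_factor <- function(t, start, length, severity) {
  u <- (t - (start + length / 2)) / length # in [-1/2, 1/2] inside the lesion
  f <- rep(1, length(t))
  inl <- u >= -0.5 & u <= 0.5
  f[inl] <- 1 - severity * 0.5 * (1 + cos(2 * pi * u[inl]))
  f
}

# local radius along a branch after applying its stenosis-type lesions
branch_radius_at <- function(branch, lesions, t) {
  r <- rep(branch$radius, length(t))
  for (l in lesions) {
    if (l$segment != branch$name) next
    if (l$kind %in% c("stenosis", "calcification", "stent") && l$severity > 0)
      r <- r * stenosis_factor(t, l$start, l$length, l$severity)
  }
  r
}

# For every voxel of the sub-grid around a polyline: distance to the
# polyline (exact point-to-segment minimum), the arclength of the nearest
# axis point, and the in-plane x offset from it (for calcific crescents).
polyline_distance_field <- function(spec, points, max_r) {
  d <- spec$shape
  xs <- spec$origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
  ys <- spec$origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
  zs <- spec$origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  pad <- max_r + 2 * max(spec$spacing)
  rng <- apply(points, 2, range)
  ix <- which(xs >= rng[1, 1] - pad & xs <= rng[2, 1] + pad)
  iy <- which(ys >= rng[1, 2] - pad & ys <= rng[2, 2] + pad)
  iz <- which(zs >= rng[1, 3] - pad & zs <= rng[2, 3] + pad)
  if (!length(ix) || !length(iy) || !length(iz)) return(NULL)
  G <- as.matrix(expand.grid(x = xs[ix], y = ys[iy], z = zs[iz],
                             KEEP.OUT.ATTRS = FALSE))
  arc <- path_arclength(points)
  best_d2 <- rep(Inf, nrow(G)); best_t <- numeric(nrow(G))
  best_dx <- numeric(nrow(G))
  for (s in seq_len(nrow(points) - 1)) {
    p0 <- points[s, ]; p1 <- points[s + 1, ]
    v <- p1 - p0; L2 <- sum(v^2)
    tt <- ((G[, 1] - p0[1]) * v[1] + (G[, 2] - p0[2]) * v[2] +
             (G[, 3] - p0[3]) * v[3]) / L2
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    ex <- G[, 1] - (p0[1] + tt * v[1])
    ey <- G[, 2] - (p0[2] + tt * v[2])
    ez <- G[, 3] - (p0[3] + tt * v[3])
    d2 <- ex * ex + ey * ey + ez * ez
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_t[upd] <- arc[s] + tt[upd] * sqrt(L2)
    best_dx[upd] <- ex[upd]
  }
  list(ix = ix, iy = iy, iz = iz, dist = sqrt(best_d2), t = best_t,
       dx = best_dx, nvox = nrow(G))
}

# accumulate max-composited coverage into a full-grid array
accumulate_cov <- function(cov_arr, fld, cov) {
  sub <- cov_arr[fld$ix, fld$iy, fld$iz]
  cov_arr[fld$ix, fld$iy, fld$iz] <- pmax(sub, cov)
  cov_arr
}

#' Generate a synthetic CTA phantom
#'
#' Rasterizes the specified arterial tree into a [ct_volume] with sub-voxel
#' edge antialiasing (coverage ramp one in-plane voxel wide, so fractional
#' stenosis severities are representable), applies lesions, bones, the vein
#' overlay and Gaussian noise, and returns the ground truth: the centerline
#' tree resampled to the volume's slices, per-segment worst stenosis
#' fraction and >70 percent significance flags, and binary lumen/bone/vein
#' masks before noise.
#'
#' @param spec a [phantom_spec].
#' @return `list(volume = <ct_volume>, truth = <phantom_truth>)`; the truth
#'   carries `centerlines`, `segments` (data frame), `lesions`, `masks`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  vox <- array(spec$background_hu, d)
  lumen_cov <- array(0, d)   # enhancing arterial lumen
  vein_cov <- array(0, d)
  bone_cov <- array(0, d)
  hard <- array(0, d)        # calcification/stent override HU (0 = none)
  aa <- mean(spec$spacing[1:2]) # antialiasing ramp width (mm)

  for (b in spec$tree) {
    fld <- polyline_distance_field(spec, b$points, b$radius + 4)
    if (is.null(fld)) next
    r_loc <- branch_radius_at(b, spec$lesions, fld$t)
    cov <- pmin(pmax((r_loc - fld$dist) / aa + 0.5, 0), 1)
    # occlusions suppress enhancement over their extent
    for (l in spec$lesions) {
      if (l$kind == "occlusion" && l$segment == b$name) {
        occ <- fld$t >= l$start & fld$t < l$start + l$length
        cov[occ] <- 0
      }
    }
    lumen_cov <- accumulate_cov(lumen_cov, fld, cov)
    # wall structures
    for (l in spec$lesions) {
      if (l$segment != b$name) next
      inl <- fld$t >= l$start & fld$t < l$start + l$length
      if (l$kind == "calcification") {
        wall <- pmin(pmax((fld$dist - r_loc) / aa + 0.5, 0), 1) *
          pmin(pmax((r_loc + 1.5 - fld$dist) / aa + 0.5, 0), 1)
        cc <- ifelse(inl & fld$dx >= 0, wall, 0) # crescent on the +x wall
        hard <- accumulate_cov(hard, fld, cc * spec$calcification_hu)
      } else if (l$kind == "stent") {
        shell <- pmin(pmax((fld$dist - b$radius) / aa + 0.5, 0), 1) *
          pmin(pmax((b$radius + 1 - fld$dist) / aa + 0.5, 0), 1)
        hard <- accumulate_cov(hard, fld, ifelse(inl, shell, 0) * spec$stent_hu)
      }
    }
  }

  if (!is.null(spec$vein_overlay)) {
    vo <- spec$vein_overlay
    for (an in vo$artery) {
      b <- spec$tree[[an]]
      vp <- sweep(b$points, 2, vo$offset, "+")
      vr <- if (is.null(vo$radius)) b$radius else vo$radius
      fld <- polyline_distance_field(spec, vp, vr + 4)
      if (is.null(fld)) next
      cov <- pmin(pmax((vr - fld$dist) / aa + 0.5, 0), 1)
      vein_cov <- accumulate_cov(vein_cov, fld, cov)
    }
  }

  for (bn in spec$bones) {
    fld <- polyline_distance_field(spec, as_point_matrix(bn$points),
                                   bn$radius + 4)
    if (is.null(fld)) next
    cov <- pmin(pmax((bn$radius - fld$dist) / aa + 0.5, 0), 1)
    bone_cov <- accumulate_cov(bone_cov, fld, cov)
  }

  # composite: soft tissue -> bone -> vein -> arterial lumen -> wall overrides
  vox <- vox * (1 - bone_cov) + spec$bone_hu * bone_cov
  vox <- vox * (1 - vein_cov) + spec$vein_hu * vein_cov
  vox <- vox * (1 - lumen_cov) + spec$lumen_hu * lumen_cov
  ov <- hard > 0
  vox[ov] <- pmax(vox[ov], hard[ov])

  masks <- list(lumen = lumen_cov > 0.5, vein = vein_cov > 0.5,
                bone = bone_cov > 0.5)

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vox <- vox + stats::rnorm(length(vox), 0, spec$noise_sd)
  }
  vol <- ct_volume(array(vox, d), spec$spacing, spec$origin)

  truth <- phantom_truth(spec, vol, masks)
  list(volume = vol, truth = truth)
}

# walk parent links from a terminal branch back to the root
branch_chain <- function(tree, terminal) {
  chain <- terminal
  b <- tree[[terminal]]
  while (!is.na(b$parent)) {
    if (!b$parent %in% names(tree))
      stop("branch '", b$name, "' references unknown parent '", b$parent, "'")
    chain <- c(b$parent, chain)
    b <- tree[[b$parent]]
  }
  chain
}

terminal_branches <- function(tree) {
  parents <- stats::na.omit(vapply(tree, function(b) b$parent, character(1)))
  setdiff(names(tree), parents)
}

phantom_truth <- function(spec, vol, masks) {
  tree <- spec$tree
  terms <- terminal_branches(tree)
  root <- tree[[branch_chain(tree, terms[1])[1]]]$points[1, ]
  zs <- slice_z(vol)
  paths <- list()
  for (tb in terms) {
    chain <- branch_chain(tree, tb)
    pts <- do.call(rbind, lapply(seq_along(chain), function(i) {
      p <- tree[[chain[i]]]$points
      if (i > 1) p[-1, , drop = FALSE] else p # drop duplicated joints
    }))
    rp <- resample_polyline(pts, zs, name = tb, warn = FALSE)
    if (!is.null(rp)) paths[[tb]] <- rp
  }
  nroots <- sum(vapply(tree, function(b) is.na(b$parent), logical(1)))
  # a multi-root spec (disjoint tubes) yields a forest: skip the root check
  tol <- if (nroots > 1) Inf else max(spec$spacing) + 1e-6
  tree_obj <- centerline_tree(paths[[1]]$points[1, ], paths, root_tol = tol)

  worst <- stats::setNames(rep(0, length(tree)), names(tree))
  for (l in spec$lesions) {
    frac <- switch(l$kind, stenosis = l$severity, occlusion = 1, l$severity)
    worst[l$segment] <- max(worst[l$segment], frac)
  }
  seg <- data.frame(
    segment = names(tree),
    side = vapply(tree, function(b) b$side, character(1)),
    group = vapply(tree, function(b) b$group, character(1)),
    worst_fraction = as.numeric(worst),
    significant = as.numeric(worst) > 0.70,
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(centerlines = tree_obj, segments = seg,
                 lesions = spec$lesions, masks = masks),
            class = "phantom_truth")
}

#' Default 21-segment leg arterial tree
#'
#' The per-leg segment model of peripheral run-off CTA: CIA, EIA, IIA, CFA,
#' DFA, SFA (proximal/middle/distal), POP (x3), ATA (x3), TPT, PA (x3),
#' PTA (x3) — 21 named segments grouped into iliac, femoro-popliteal and
#' infra-popliteal arteries. Geometry is a stylised straight-segment layout
#' at realistic lengths and radii; the left and right trees are mirror
#' images in x.
#'
#' @param side `"left"` or `"right"`.
#' @param scale multiplies all coordinates (not radii); use < 1 for compact
#'   test volumes.
#' @param suffix appended to every branch name (e.g. `"-L"`); default none.
#' @return named list of 21 [vessel_branch] objects; the common iliac artery
#'   has `parent = NA` and starts at the aortic bifurcation `(0, 0, 40*scale)`.
#' @export
default_leg_tree <- function(side = c("left", "right"), scale = 1,
                             suffix = "") {
  side <- match.arg(side)
  sx <- if (side == "left") 1 else -1
  seg <- function(name, x0, x1, group, r, parent) {
    vessel_branch(paste0(name, suffix),
                  rbind(c(sx * x0[1], x0[2], x0[3]),
                        c(sx * x1[1], x1[2], x1[3])) * scale,
                  radius = r,
                  parent = if (is.na(parent)) NA_character_
                           else paste0(parent, suffix),
                  group = group, side = side)
  }
  il <- "iliac"; fp <- "femoro-popliteal"; ip <- "infra-popliteal"
  b <- list(
    seg("CIA", c(0, 0, 40), c(20, 0, 100), il, 4.5, NA),
    seg("EIA", c(20, 0, 100), c(32, 4, 170), il, 4.0, "CIA"),
    seg("IIA", c(20, 0, 100), c(34, 10, 145), il, 3.0, "CIA"),
    seg("CFA", c(32, 4, 170), c(32, 0, 210), fp, 4.0, "EIA"),
    seg("DFA", c(32, 0, 210), c(40, 8, 265), fp, 2.5, "CFA"),
    seg("SFA-prox", c(32, 0, 210), c(30, 0, 290), fp, 3.5, "CFA"),
    seg("SFA-mid", c(30, 0, 290), c(28, 2, 370), fp, 3.5, "SFA-prox"),
    seg("SFA-dist", c(28, 2, 370), c(26, 6, 450), fp, 3.3, "SFA-mid"),
    seg("POP-prox", c(26, 6, 450), c(26, 8, 490), fp, 3.0, "SFA-dist"),
    seg("POP-mid", c(26, 8, 490), c(26, 8, 530), fp, 3.0, "POP-prox"),
    seg("POP-dist", c(26, 8, 530), c(26, 6, 570), fp, 2.8, "POP-mid"),
    seg("ATA-prox", c(26, 6, 570), c(34, -4, 660), ip, 1.6, "POP-dist"),
    seg("ATA-mid", c(34, -4, 660), c(36, -6, 750), ip, 1.5, "ATA-prox"),
    seg("ATA-dist", c(36, -6, 750), c(36, -6, 840), ip, 1.4, "ATA-mid"),
    seg("TPT", c(26, 6, 570), c(24, 8, 600), ip, 2.0, "POP-dist"),
    seg("PA-prox", c(24, 8, 600), c(28, 6, 670), ip, 1.6, "TPT"),
    seg("PA-mid", c(28, 6, 670), c(28, 6, 740), ip, 1.5, "PA-prox"),
    seg("PA-dist", c(28, 6, 740), c(28, 6, 810), ip, 1.4, "PA-mid"),
    seg("PTA-prox", c(24, 8, 600), c(18, 10, 680), ip, 1.6, "TPT"),
    seg("PTA-mid", c(18, 10, 680), c(16, 10, 760), ip, 1.5, "PTA-prox"),
    seg("PTA-dist", c(16, 10, 760), c(14, 10, 840), ip, 1.4, "PTA-mid"))
  stats::setNames(b, vapply(b, function(x) x$name, character(1)))
}

#' Default two-leg arterial tree with aortic trunk
#'
#' Both legs of [default_leg_tree] (suffixed `-L` / `-R`) hanging off a
#' short infra-renal aortic trunk `AO` from `(0, 0, 0)`.
#'
#' @inheritParams default_leg_tree
#' @return named list of 43 [vessel_branch] objects (1 aorta + 2 x 21).
#' @export
default_tree <- function(scale = 1) {
  ao <- vessel_branch("AO", rbind(c(0, 0, 0), c(0, 0, 40 * scale)),
                      radius = 8, group = NA_character_)
  left <- default_leg_tree("left", scale, suffix = "-L")
  right <- default_leg_tree("right", scale, suffix = "-R")
  left[["CIA-L"]]$parent <- "AO"
  right[["CIA-R"]]$parent <- "AO"
  c(list(AO = ao), left, right)
}
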