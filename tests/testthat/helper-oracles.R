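# Independent oracles and fixture builders. Every oracle here is written
# against the definitions (scalar loops, enumeration), not against the
# package's vectorised/compiled implementations.

# scalar trilinear interpolation, written independently: explicit corner loop
oracle_trilinear <- function(vol, p) {
  idx <- (p - vol$origin) / vol$spacing
  d <- dim(vol$voxels)
  if (any(idx < 0) || any(idx > d - 1)) return(-1024)
  i0 <- pmin(floor(idx), d - 2); f <- idx - i0
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
      (if (cy) f[2] else 1 - f[2]) *
      (if (cz) f[3] else 1 - f[3])
    acc <- acc + w * vol$voxels[i0[1] + cx + 1, i0[2] + cy + 1, i0[3] + cz + 1]
  }
  acc
}

# brute-force projected CPR: per-pixel loop over slices and lateral offsets
oracle_cpr <- function(vol, path, angle, halfwidth, col_spacing) {
  th <- angle * pi / 180
  u <- c(cos(th), -sin(th), 0)
  s <- seq(-halfwidth, halfwidth, by = col_spacing)
  nz <- dim(vol$voxels)[3]
  out <- matrix(-1024, nz, length(s))
  for (q in seq_len(nrow(path$points))) {
    z <- path$slices[q] + 1
    for (c in seq_along(s))
      out[z, c] <- oracle_trilinear(vol, path$points[q, ] + s[c] * u)
  }
  out
}

# brute-force axis-aligned MIP at angle 0: per slice, per x, max over y
oracle_mip_ap <- function(vol, mask = NULL) {
  v <- vol$voxels
  if (!is.null(mask)) v[mask] <- -1024
  t(apply(v, c(1, 3), max)) # rows = slices, cols = x
}

# --- shortest-path oracles -------------------------------------------------

grid_neighbors <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  list(offs = offs, nx = nx, ny = ny, nz = nz)
}

edge_cost <- function(cost, spacing, a, b) {
  len <- sqrt(sum(((a - b) * spacing)^2))
  0.5 * (cost[a[1] + 1, a[2] + 1, a[3] + 1] +
           cost[b[1] + 1, b[2] + 1, b[3] + 1]) * len
}

# full enumeration of every simple path (tiny grids only)
oracle_enum_cost <- function(cost, spacing, a, b) {
  dims <- dim(cost)
  nb <- grid_neighbors(dims)
  best <- Inf
  visited <- array(FALSE, dims)
  rec <- function(v, acc) {
    if (all(v == b)) { best <<- min(best, acc); return(invisible()) }
    if (acc >= best) return(invisible())
    for (r in seq_len(nrow(nb$offs))) {
      w <- v + nb$offs[r, ]
      if (any(w < 0) || any(w >= dims)) next
      if (visited[w[1] + 1, w[2] + 1, w[3] + 1]) next
      visited[w[1] + 1, w[2] + 1, w[3] + 1] <<- TRUE
      rec(w, acc + edge_cost(cost, spacing, v, w))
      visited[w[1] + 1, w[2] + 1, w[3] + 1] <<- FALSE
    }
  }
  visited[a[1] + 1, a[2] + 1, a[3] + 1] <- TRUE
  rec(a, 0)
  best
}

# provably exact branch-and-bound: prunes with the admissible lower bound
# (remaining Euclidean distance x minimum voxel cost); exact because the
# bound never overestimates
oracle_bnb_cost <- function(cost, spacing, a, b) {
  dims <- dim(cost)
  nb <- grid_neighbors(dims)
  cmin <- min(cost)
  bw <- b * spacing
  lower <- function(v) cmin * sqrt(sum((v * spacing - bw)^2))
  # seed the incumbent with a greedy diagonal walk
  best <- {
    v <- a; acc <- 0
    while (!all(v == b)) {
      w <- v + sign(b - v)
      acc <- acc + edge_cost(cost, spacing, v, w)
      v <- w
    }
    acc
  }
  visited <- array(FALSE, dims)
  rec <- function(v, acc) {
    if (all(v == b)) { best <<- min(best, acc); return(invisible()) }
    if (acc + lower(v) >= best) return(invisible())
    for (r in seq_len(nrow(nb$offs))) {
      w <- v + nb$offs[r, ]
      if (any(w < 0) || any(w >= dims)) next
      if (visited[w[1] + 1, w[2] + 1, w[3] + 1]) next
      visited[w[1] + 1, w[2] + 1, w[3] + 1] <<- TRUE
      rec(w, acc + edge_cost(cost, spacing, v, w))
      visited[w[1] + 1, w[2] + 1, w[3] + 1] <<- FALSE
    }
  }
  visited[a[1] + 1, a[2] + 1, a[3] + 1] <- TRUE
  rec(a, 0)
  best
}

# independent library oracle (igraph Dijkstra) for mid-size grids
oracle_igraph_cost <- function(cost, spacing, a, b) {
  dims <- dim(cost)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  lin <- function(v) v[1] + nx * v[2] + nx * ny * v[3] + 1
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- grid_neighbors(dims)$offs
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE] # undirected: half
  for (k in 0:(nz - 1)) for (j in 0:(ny - 1)) for (i in 0:(nx - 1)) {
    v <- c(i, j, k)
    for (r in seq_len(nrow(offs))) {
      u <- v + offs[r, ]
      if (any(u < 0) || u[1] >= nx || u[2] >= ny || u[3] >= nz) next
      from <- c(from, lin(v)); to <- c(to, lin(u))
      w <- c(w, edge_cost(cost, spacing, v, u))
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = nx * ny * nz, directed = FALSE)
  as.numeric(igraph::distances(g, v = lin(a), to = lin(b), weights = w,
                               algorithm = "dijkstra"))
}

# --- fixture builders ------------------------------------------------------

# straight z-aligned tube phantom
tube_phantom <- function(radius = 4, shape = c(32, 32, 32), center = NULL,
                         spacing = c(1, 1, 1), lesions = list(),
                         noise_sd = 0, seed = 1, ...) {
  if (is.null(center)) center <- (shape[1:2] - 1) / 2 * spacing[1:2]
  br <- vessel_branch("T",
                      rbind(c(center, 0),
                            c(center, (shape[3] - 1) * spacing[3])),
                      radius = radius)
  generate_phantom(phantom_spec(shape = shape, spacing = spacing,
                                tree = list(br), lesions = lesions,
                                noise_sd = noise_sd, seed = seed, ...))
}

# smooth radial-profile cylinder: isolates renderer anisotropy from
# voxelisation error in rotation-invariance checks
smooth_cylinder <- function(n = 128, nz = 160, sigma = 16, amp = 360,
                            bg = 40) {
  xs <- (0:(n - 1)) - (n - 1) / 2
  prof <- bg + amp * exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  ct_volume(array(rep(prof, nz), c(n, n, nz)), c(1, 1, 1),
            c(-(n - 1) / 2, -(n - 1) / 2, 0))
}

axis_path <- function(nz, x = 0, y = 0) {
  centerline_path("axis", cbind(x, y, 0:(nz - 1)), resampled = TRUE,
                  slices = 0:(nz - 1))
}

# occluded artery with separated accompanying vein (the venous-overlay
# failure scenario): 1.6 mm artery, 10 mm occlusion, vein 6 mm lateral
vein_overlay_phantom <- function(seed = 2) {
  art <- vessel_branch("PTA", rbind(c(12, 12, 0), c(12, 12, 47)), radius = 1.6)
  generate_phantom(phantom_spec(
    shape = c(28, 24, 48), tree = list(art),
    lesions = list(lesion("occlusion", "PTA", 18, 10)),
    vein_overlay = list(artery = "PTA", offset = 6, radius = 1.6),
    seed = seed))
}

read_fixture <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "mpcpr"),
                  stringsAsFactors = FALSE)
}
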