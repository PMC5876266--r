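test_that("cost image has a flat floor in the window and steep cost outside", {
  vol <- ct_volume(array(c(400, 40, 1500, 190, 1200), c(5, 1, 1)),
                   c(1, 1, 1))
  ci <- cost_image(vol, c(190, 1200), floor = 1)
  expect_equal(ci$cost[1, 1, 1], 1)        # lumen: the floor
  expect_equal(ci$cost[4, 1, 1], 1)        # window edges are inside
  expect_equal(ci$cost[5, 1, 1], 1)
  expect_gte(ci$cost[2, 1, 1], 10)         # soft tissue: >= 10x floor
  expect_true(all(ci$cost > 0))
  expect_error(cost_image(vol, c(500, 100)), "low < high")
})

test_that("per-slice argmin of the cost lies inside the true lumen", {
  ph <- tube_phantom(radius = 4, shape = c(24, 24, 16))
  ci <- cost_image(ph$volume, c(190, 1200))
  for (k in seq_len(16)) {
    sl <- ci$cost[, , k]
    amin <- which(sl == min(sl), arr.ind = TRUE)
    for (r in seq_len(nrow(amin)))
      expect_true(ph$truth$masks$lumen[amin[r, 1], amin[r, 2], k])
  }
})

test_that("uniform cost yields the 26-connected digital straight segment", {
  cost <- array(1, c(8, 8, 8))
  ci <- structure(list(cost = cost, spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                  class = "cost_image")
  p <- min_cost_path(ci, c(0, 0, 0), c(7, 7, 7))
  expect_equal(nrow(p$points), 8) # pure space diagonal
  expect_equal(p$points, cbind(0:7, 0:7, 0:7), ignore_attr = TRUE)
  p2 <- min_cost_path(ci, c(0, 0, 0), c(7, 3, 0))
  expect_equal(nrow(p2$points), 8) # one hop per x step, y folded in
  expect_equal(diff(p2$points[, 1]), rep(1, 7))
  expect_true(all(diff(p2$points[, 2]) %in% c(0, 1)))
})

test_that("minimum-cost paths match exhaustive enumeration on tiny grids", {
  set.seed(101)
  for (dims in list(c(2, 2, 2), c(3, 3, 1), c(4, 2, 1))) {
    for (rep in 1:3) {
      cost <- array(runif(prod(dims), 0.5, 3), dims)
      sp <- runif(3, 0.5, 2)
      ci <- structure(list(cost = cost, spacing = sp, origin = c(0, 0, 0)),
                      class = "cost_image")
      b <- dims - 1
      p <- min_cost_path(ci, c(0, 0, 0) * sp, b * sp)
      expect_equal(attr(p, "total_cost"),
                   oracle_enum_cost(cost, sp, c(0, 0, 0), b),
                   tolerance = 1e-10)
    }
  }
})

test_that("minimum-cost paths match branch-and-bound and igraph oracles", {
  set.seed(202)
  for (dims in list(c(3, 3, 3), c(4, 3, 2))) {
    cost <- array(runif(prod(dims), 0.5, 3), dims)
    ci <- structure(list(cost = cost, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)), class = "cost_image")
    b <- dims - 1
    p <- min_cost_path(ci, c(0, 0, 0), b)
    expect_equal(attr(p, "total_cost"),
                 oracle_bnb_cost(cost, c(1, 1, 1), c(0, 0, 0), b),
                 tolerance = 1e-10)
  }
  dims <- c(5, 4, 4)
  cost <- array(runif(prod(dims), 0.5, 3), dims)
  ci <- structure(list(cost = cost, spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                  class = "cost_image")
  p <- min_cost_path(ci, c(0, 0, 0), dims - 1)
  expect_equal(attr(p, "total_cost"),
               oracle_igraph_cost(cost, c(1, 1, 1), c(0, 0, 0), dims - 1),
               tolerance = 1e-10)
})

test_that("path cost is symmetric in its endpoints", {
  set.seed(33)
  cost <- array(runif(6 * 6 * 6, 0.5, 5), c(6, 6, 6))
  ci <- structure(list(cost = cost, spacing = c(0.7, 0.7, 1.5),
                       origin = c(0, 0, 0)), class = "cost_image")
  a <- c(0, 0, 0); b <- c(0.7 * 5, 0.7 * 4, 1.5 * 5)
  expect_equal(attr(min_cost_path(ci, a, b), "total_cost"),
               attr(min_cost_path(ci, b, a), "total_cost"))
})

test_that("an impassable barrier raises a tracking error naming the gap", {
  cost <- array(1, c(5, 5, 5))
  cost[, , 3] <- Inf
  ci <- structure(list(cost = cost, spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                  class = "cost_image")
  expect_error(min_cost_path(ci, c(0, 0, 0), c(4, 4, 4)), "tracking error")
})

test_that("recentering recovers the axis of an offset seed path", {
  ph <- tube_phantom(radius = 4, shape = c(32, 32, 24))
  seed <- centerline_path("T", cbind(17.5, 16.5, 0:23)) # 2 mm off-axis
  rc <- recenter(ph$volume, seed, 140)
  expect_lt(max(abs(rc$points[, 1] - 15.5)), 0.5)
  expect_lt(max(abs(rc$points[, 2] - 15.5)), 0.5)
  # a path already on the axis is a fixed point
  on_axis <- centerline_path("T", cbind(15.5, 15.5, 0:23))
  rc2 <- recenter(ph$volume, on_axis, 140)
  expect_lt(max(abs(rc2$points[, 1:2] - 15.5)), 0.05)
})

test_that("recentering never worsens the distance to the true axis", {
  ph <- tube_phantom(radius = 4, shape = c(32, 32, 24))
  for (off in list(c(1, 0), c(-1.5, 1), c(0.5, -2))) {
    seed <- centerline_path("T", cbind(15.5 + off[1], 15.5 + off[2], 0:23))
    before <- sqrt(mean((seed$points[, 1] - 15.5)^2 +
                          (seed$points[, 2] - 15.5)^2))
    rc <- recenter(ph$volume, seed, 140)
    after <- sqrt(mean((rc$points[, 1] - 15.5)^2 +
                         (rc$points[, 2] - 15.5)^2))
    expect_lte(after, before)
  }
})

test_that("occluded extents are flagged point-for-slice", {
  ph <- tube_phantom(radius = 3, shape = c(24, 24, 40),
                     lesions = list(lesion("occlusion", "T", 15, 10)))
  path <- ph$truth$centerlines$paths$T
  rc <- recenter(ph$volume, path, 140)
  expect_true(abs(sum(rc$flagged) - 10) <= 1) # 10 mm / 1 mm slices
  expect_true(all(rc$points[rc$flagged, 1] == path$points[rc$flagged, 1]))
})

test_that("build_tree recovers ground truth on a lesion-free two-leg phantom", {
  model <- default_tree()
  sp <- phantom_spec(shape = c(68, 20, 284), spacing = c(1.5, 1.5, 3),
                     origin = c(-50, -9, 0), tree = model, seed = 5)
  ph <- generate_phantom(sp)
  truth <- ph$truth$centerlines
  eps <- c("ATA-dist-L", "PTA-dist-L", "ATA-dist-R")
  cps <- lapply(eps, function(e) {
    p <- truth$paths[[e]]$points
    rbind(c(0, 0, 0), p[nrow(p), ])
  })
  names(cps) <- eps
  tr <- build_tree(ph$volume, cps, max_radius = 6)
  for (e in eps) {
    tp <- tr$paths[[e]]; gp <- truth$paths[[e]]
    m <- match(tp$slices, gp$slices)
    ok <- !is.na(m)
    rms <- sqrt(mean(rowSums((tp$points[ok, 1:2] -
                                gp$points[m[ok], 1:2])^2)))
    expect_lt(rms, 1.5) # within one in-plane voxel RMS
  }
  expect_true(all(attr(tr, "trunk_shared") > 0))
})

test_that("bridged occlusions track through; degenerate input errors", {
  ph <- vein_overlay_phantom()
  tr <- build_tree(ph$volume,
                   list(PTA = rbind(c(12, 12, 0), c(12, 12, 23),
                                    c(12, 12, 47))))
  expect_lt(max(abs(tr$paths$PTA$points[, 1] - 12)), 1)
  expect_error(build_tree(ph$volume,
                          list(PTA = rbind(c(12, 12, 0), c(12, 12, 0)))),
               "two distinct control points")
})

test_that("step detection flags constructed and tracked artery-vein jumps", {
  straight <- axis_path(30, x = 5, y = 5)
  expect_equal(nrow(detect_steps(straight, 3)), 0)
  pts <- cbind(c(rep(5, 15), rep(11, 15)), 5, 0:29) # one 6 mm lateral jump
  jump <- centerline_path("J", pts, resampled = TRUE, slices = 0:29)
  st <- detect_steps(jump, 3)
  expect_equal(nrow(st), 1)
  expect_equal(st$slice, 15)
  expect_equal(st$jump_mm, 6)
  # venous overlay without a bridging control point: the tracker switches
  # into the vein and the switch shows up as a step inside the occlusion
  ph <- vein_overlay_phantom()
  tr <- build_tree(ph$volume, list(PTA = rbind(c(12, 12, 0), c(12, 12, 47))))
  st2 <- detect_steps(tr$paths$PTA, 3)
  expect_gte(sum(st2$slice >= 16 & st2$slice <= 30), 1)
  # the detour really runs through the vein tube
  mid <- tr$paths$PTA$points[tr$paths$PTA$slices %in% 20:26, ]
  expect_true(all(abs(mid[, 1] - 18) < 2))
})
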