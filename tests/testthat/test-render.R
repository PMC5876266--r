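test_that("rotation angle series is inclusive, symmetric and validated", {
  a <- rotation_angles(180, 9)
  expect_length(a, 21)
  expect_equal(a[1], -90)
  expect_equal(a[21], 90)
  expect_equal(unique(diff(a)), 9)
  expect_equal(rotation_angles(180, 90), c(-90, 0, 90))
  expect_error(rotation_angles(180, 7), "divide")
})

test_that("straight-tube CPR at angle 0 equals the coronal reslice", {
  ph <- tube_phantom(radius = 4, shape = c(32, 32, 20), center = c(16, 16))
  path <- axis_path(20, 16, 16)
  img <- render_cpr(ph$volume, path, 0, halfwidth = 8)
  resl <- t(ph$volume$voxels[9:25, 17, ]) # x = 8..24 (0-based) at y = 16
  expect_equal(img$pixels, resl, ignore_attr = TRUE)
})

test_that("CPR pixels match the brute-force sampler pixel for pixel", {
  set.seed(5)
  vol <- ct_volume(array(runif(8 * 8 * 8, -500, 2000), c(8, 8, 8)),
                   c(0.9, 1.1, 1.4), c(-2, 1, 0))
  path <- centerline_path("p", cbind(runif(8, 0, 5), runif(8, 2, 7),
                                     seq(0, 9.8, by = 1.4)),
                          resampled = TRUE, slices = 0:7)
  for (ang in c(-90, -45, 0, 33, 90)) {
    img <- render_cpr(vol, path, ang, halfwidth = 4, col_spacing = 0.9)
    expect_equal(img$pixels, oracle_cpr(vol, path, ang, 4, 0.9),
                 tolerance = 1e-12)
  }
})

test_that("attributed pixels are trilinear samples at their recorded position", {
  ph <- tube_phantom(radius = 4, shape = c(24, 24, 12))
  path <- axis_path(12, 11.5, 11.5)
  tree <- centerline_tree(path$points[1, ], list(T = path))
  for (img in list(render_cpr(ph$volume, path, 21, halfwidth = 6),
                   render_mpcpr(ph$volume, tree, 21, halfwidth = 6))) {
    att <- which(!is.na(img$attribution) & img$attribution != "context")
    expect_gt(length(att), 0)
    for (q in att[seq(1, length(att), by = 7)]) {
      p <- img$sample_points[q, ]
      expect_equal(img$pixels[q], oracle_trilinear(ph$volume, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("21 CPR views of a smooth cylinder agree to within 0.5 HU", {
  vol <- smooth_cylinder(n = 64, nz = 24, sigma = 16)
  path <- axis_path(24)
  imgs <- lapply(rotation_angles(180, 9),
                 function(a) render_cpr(vol, path, a, halfwidth = 20)$pixels)
  ref <- imgs[[11]] # anteroposterior
  dev <- vapply(imgs, function(m) max(abs(m - ref)), numeric(1))
  expect_lt(max(dev), 0.5)
})

test_that("mpCPR of a single straight path reduces to the CPR", {
  ph <- tube_phantom(radius = 4, shape = c(32, 32, 20))
  path <- axis_path(20, 15.5, 15.5)
  tree <- centerline_tree(path$points[1, ], list(T = path))
  cpr <- render_cpr(ph$volume, path, 0, halfwidth = 8)
  mp <- render_mpcpr(ph$volume, tree, 0, halfwidth = 8, context = "none")
  expect_equal(mp$pixels, cpr$pixels)
  expect_equal(dim(mp$pixels), dim(cpr$pixels))
})

test_that("two parallel tubes split the mpCPR at the midline, each at its CPR", {
  t1 <- vessel_branch("A", rbind(c(20, 14, 0), c(20, 14, 29)), radius = 4)
  t2 <- vessel_branch("B", rbind(c(40, 14, 0), c(40, 14, 29)), radius = 4)
  ph <- generate_phantom(phantom_spec(c(60, 28, 30), tree = list(t1, t2),
                                      seed = 1))
  tr <- ph$truth$centerlines
  mp <- render_mpcpr(ph$volume, tr, 0, halfwidth = 8, context = "none")
  att <- mp$attribution[15, ]
  expect_true(all(att[mp$cols < 29] == "A", na.rm = TRUE))
  expect_true(all(att[mp$cols > 31] == "B", na.rm = TRUE))
  expect_true(all(is.na(att[abs(mp$cols - 30) < 1.5])))
  for (nm in c("A", "B")) {
    x0 <- if (nm == "A") 20 else 40
    cpr <- render_cpr(ph$volume, tr$paths[[nm]], 0, halfwidth = 8)
    hit <- which(abs(outer(mp$cols, x0 + cpr$cols, "-")) < 1e-9,
                 arr.ind = TRUE)
    expect_equal(mp$pixels[, hit[, 1]], cpr$pixels[, hit[, 2]])
  }
})

test_that("every renderer yields one row per axial slice at any angle", {
  ph <- tube_phantom(radius = 3, shape = c(20, 20, 17))
  path <- axis_path(17, 9.5, 9.5)
  tree <- centerline_tree(path$points[1, ], list(T = path))
  for (ang in c(-90, -18, 0, 63)) {
    expect_equal(nrow(render_cpr(ph$volume, path, ang, 6)$pixels), 17)
    expect_equal(nrow(render_mpcpr(ph$volume, tree, ang, 6)$pixels), 17)
    expect_equal(nrow(render_mip(ph$volume, NULL, ang)$pixels), 17)
  }
})

test_that("bone segmentation keeps bone, drops small bright components", {
  art <- vessel_branch("SFA", rbind(c(20, 12, 0), c(20, 12, 39)), radius = 3)
  ph <- generate_phantom(phantom_spec(
    c(40, 28, 40), tree = list(art),
    lesions = list(lesion("stent", "SFA", 14, 6)),
    bones = list(list(points = rbind(c(8, 14, 0), c(8, 14, 39)), radius = 5)),
    seed = 3))
  bm <- segment_bones(ph$volume, 700, min_component_voxels = 500)
  expect_gte(mean(bm[ph$truth$masks$bone]), 0.95)
  expect_lt(mean(bm[ph$truth$masks$lumen]), 0.01)
  # the stent shell is brighter than bone but too small for the size filter
  bm2 <- segment_bones(ph$volume, 1500, min_component_voxels = 5000)
  expect_false(any(bm2))
  # threshold above the maximum attenuation: empty mask
  expect_false(any(segment_bones(ph$volume, 3999, 1)))
})

test_that("MIP matches the brute-force ray maximum and handles masks", {
  vc <- ct_volume(array(40, c(8, 8, 8)), c(1, 1, 1))
  expect_true(all(render_mip(vc, NULL, 0)$pixels == 40))
  set.seed(6)
  vol <- ct_volume(array(runif(8 * 8 * 8, -500, 2000), c(8, 8, 8)),
                   c(1, 1, 1))
  expect_equal(render_mip(vol, NULL, 0)$pixels, oracle_mip_ap(vol),
               ignore_attr = TRUE)
  mask <- vol$voxels > 1500
  expect_equal(render_mip(vol, mask, 0)$pixels, oracle_mip_ap(vol, mask),
               ignore_attr = TRUE)
  expect_error(render_mip(vol, array(TRUE, c(4, 4, 4)), 0), "shape")
})

test_that("MIP is blinded by calcification where mpCPR still shows lumen", {
  art <- vessel_branch("SFA", rbind(c(20, 12, 0), c(20, 12, 39)), radius = 3)
  ph <- generate_phantom(phantom_spec(
    c(40, 28, 40), tree = list(art),
    lesions = list(lesion("calcification", "SFA", 14, 8, severity = 0.5)),
    seed = 3))
  mip <- render_mip(ph$volume, NULL, 0)
  mp <- render_mpcpr(ph$volume, ph$truth$centerlines, 0, halfwidth = 8,
                     context = "none")
  z <- 19 # inside the lesion
  cmip <- which.min(abs(mip$cols - 20))
  cmp <- which.min(abs(mp$cols - 20))
  expect_gte(mip$pixels[z, cmip], 700)  # calcification dominates the ray
  expect_lt(mp$pixels[z, cmp], 500)     # centerline sample stays luminal
})

test_that("the rotation series has 21 stamped views and empty-mask identity", {
  ph <- tube_phantom(radius = 3, shape = c(20, 20, 10))
  path <- axis_path(10, 9.5, 9.5)
  tree <- centerline_tree(path$points[1, ], list(T = path))
  ser <- render_series(ph$volume, tree, "mpcpr", halfwidth = 6,
                       context = "none")
  expect_length(ser, 21)
  expect_equal(vapply(ser, function(im) im$angle, numeric(1)),
               seq(-90, 90, by = 9))
  m1 <- render_series(ph$volume, mode = "mip")
  m2 <- render_series(ph$volume, mode = "mip",
                      mask = array(FALSE, dim(ph$volume$voxels)))
  for (i in c(1, 11, 21)) expect_equal(m1[[i]]$pixels, m2[[i]]$pixels)
})

test_that("mirrored scenes render mirrored images at the opposite angle", {
  set.seed(12)
  n <- 32
  vox <- array(runif(n * n * 6, -100, 800), c(n, n, 6))
  vol <- ct_volume(vox, c(1, 1, 1), c(-(n - 1) / 2, -(n - 1) / 2, 0))
  mvol <- ct_volume(vox[n:1, , ], c(1, 1, 1), c(-(n - 1) / 2, -(n - 1) / 2, 0))
  path <- centerline_path("p", cbind(0.3, -0.2, 0:5), resampled = TRUE,
                          slices = 0:5)
  mpath <- centerline_path("p", cbind(-0.3, -0.2, 0:5), resampled = TRUE,
                           slices = 0:5)
  i1 <- render_cpr(vol, path, 27, halfwidth = 10)$pixels
  i2 <- render_cpr(mvol, mpath, -27, halfwidth = 10)$pixels
  expect_equal(i2, i1[, ncol(i1):1], tolerance = 1e-9)
})
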