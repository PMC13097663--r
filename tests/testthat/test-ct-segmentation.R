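ball_mask <- function(shape, center, radius) {
  d <- shape
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  m <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <= radius^2
  binary_volume(array(m, d))
}

test_that("erode_binary matches a brute-force distance computation", {
  b <- ball_mask(c(25, 25, 25), c(13, 13, 13), 10)
  expect_identical(erode_binary(b, 0)$voxels, b$voxels)
  # single voxel, radius 1 -> empty
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(sum(erode_binary(binary_volume(single), 1)$voxels), 0L)
  # ball of radius 10 eroded by 3: every surviving voxel is > 3 from background
  er <- erode_binary(b, 3)
  g <- expand.grid(x = 1:25, y = 1:25, z = 1:25)
  bg <- as.matrix(g[!b$voxels, ])
  fg <- which(er$voxels)
  # brute-force check on a sample of surviving and removed voxels
  set.seed(1)
  for (i in sample(fg, 20)) {
    p <- as.numeric(g[i, ])
    dmin <- sqrt(min(colSums((t(bg) - p)^2)))
    expect_gt(dmin, 3)
  }
  removed <- which(b$voxels & !er$voxels)
  for (i in sample(removed, 20)) {
    p <- as.numeric(g[i, ])
    dmin <- sqrt(min(colSums((t(bg) - p)^2)))
    expect_lte(dmin, 3)
  }
  # voxel count shrinks roughly like a radius-7 ball
  expect_lt(sum(er$voxels), sum(b$voxels))
  expect_equal(sum(er$voxels), sum(ball_mask(c(25, 25, 25), c(13, 13, 13), 7)$voxels),
               tolerance = 0.15)
})

test_that("half-maximum threshold is exact on constant seeds and ordered means", {
  vox <- array(100, c(12, 12, 12))
  vox[4:9, 4:9, 4:9] <- 200
  vol <- grey_volume(vox)
  bone <- binary_volume(vox == 200)
  bg <- binary_volume(vox == 100)
  res <- global_halfmax_threshold(vol, bone, bg, shrink_bone = 1, shrink_background = 1)
  expect_equal(res$threshold_spec$threshold, 150)
  expect_equal(res$threshold_spec$mean_bone, 200)
  expect_equal(res$threshold_spec$mean_background, 100)
  expect_identical(res$segmentation$voxels, bone$voxels)
  # reversed intensities violate the threshold invariant
  expect_error(global_halfmax_threshold(vol, bg, bone, 1, 1), "exceed")
  # over-shrunk seed errors with advice
  expect_error(global_halfmax_threshold(vol, bone, bg, shrink_bone = 10,
                                        shrink_background = 1), "shrink")
})

test_that("phantom half-max threshold lands near the midpoint with accurate segmentation", {
  sim <- simulate_phantom(phantom_params(shape = c(48, 48, 48), seed = 4))
  res <- global_halfmax_threshold(sim$volume, sim$truth,
                                  binary_volume(!sim$truth$voxels),
                                  shrink_bone = 3, shrink_background = 3)
  expect_lt(abs(res$threshold_spec$threshold - 120), 2)
  expect_gte(mean(res$segmentation$voxels == sim$truth$voxels), 0.99)
})

test_that("local Otsu equals global Otsu on a clean two-level step image", {
  # narrow image: every bone-side neighborhood spans the two-level step
  vox <- array(60, c(13, 24, 3))
  vox[9:13, , ] <- 180
  seg <- local_otsu(grey_volume(vox), radius = 5)
  expect_identical(seg$voxels, vox > 120)
  # independent oracle: EBImage global Otsu on the slice, rescaled to [0,1]
  if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- (vox[, , 1] - min(vox)) / diff(range(vox))
    thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    expect_identical(seg$voxels[, , 1], img > thr)
  }
  # constant volume: everything background
  expect_equal(sum(local_otsu(grey_volume(array(7, c(10, 10, 2))), 5)$voxels), 0L)
})

test_that("local Otsu with voting segments a noisy phantom accurately", {
  sim <- simulate_phantom(phantom_params(shape = c(48, 48, 48), seed = 5))
  seg1 <- local_otsu(sim$volume, 5)
  expect_gte(mean(seg1$voxels == sim$truth$voxels), 0.98)
  segv <- otsu_vote_segment(sim$volume, 5)
  expect_gte(mean(segv$voxels == sim$truth$voxels), 0.98)
})

test_that("reslicing permutes axes as documented and is involutive", {
  vox <- array(seq_len(24), c(2, 3, 4))
  v <- grey_volume(vox, spacing = c(0.1, 0.2, 0.3))
  expect_identical(reslice(v, "original")$voxels, vox)
  tb <- reslice(v, "top_bottom")
  expect_equal(dim(tb$voxels), c(2L, 4L, 3L))
  expect_equal(tb$spacing, c(0.1, 0.3, 0.2))
  expect_equal(tb$voxels[2, 4, 1], vox[2, 1, 4])
  expect_equal(tb$voxels[1, 2, 3], vox[1, 3, 2])
  expect_identical(reslice(tb, "top_bottom")$voxels, vox)
  lr <- reslice(v, "left_right")
  expect_equal(dim(lr$voxels), c(4L, 3L, 2L))
  expect_equal(lr$voxels[4, 2, 1], vox[1, 2, 4])
  expect_identical(reslice(lr, "left_right")$voxels, vox)
  expect_error(reslice(v, "diagonal"), "arg")
})

test_that("2-of-3 voting matches the exhaustive truth table and brute force", {
  for (bits in 0:7) {
    b <- as.logical(intToBits(bits)[1:3])
    m <- lapply(b, function(x) binary_volume(array(x, c(1, 1, 1))))
    out <- vote_combine(m[[1]], m[[2]], m[[3]])$voxels[1, 1, 1]
    expect_identical(out, sum(b) >= 2)
  }
  set.seed(6)
  d <- c(40, 50, 50) # 1e5 voxels
  ms <- lapply(1:3, function(i) binary_volume(array(runif(prod(d)) > 0.5, d)))
  out <- vote_combine(ms[[1]], ms[[2]], ms[[3]])$voxels
  brute <- (ms[[1]]$voxels + ms[[2]]$voxels + ms[[3]]$voxels) >= 2
  expect_identical(out, brute)
  # permutation invariance
  expect_identical(vote_combine(ms[[3]], ms[[1]], ms[[2]])$voxels, out)
  expect_identical(vote_combine(ms[[1]], ms[[1]], ms[[1]])$voxels, ms[[1]]$voxels)
  expect_error(vote_combine(ms[[1]], ms[[2]],
                            binary_volume(array(TRUE, c(2, 2, 2)))), "mismatch")
})

test_that("segmentation comparison reports disagreement, Dice and boundary distance", {
  a <- ball_mask(c(30, 30, 30), c(15, 15, 15), 8)
  expect_equal(segmentation_compare(a, a),
               list(n_disagree = 0L, dice = 1, max_boundary_distance = 0,
                    dist_a_to_b = 0, dist_b_to_a = 0))
  # dilation by 1 voxel (6-connectivity ball): shell disagreement, distance 1
  dil <- a$voxels
  d <- dim(dil)
  idx <- which(a$voxels, arr.ind = TRUE)
  for (shift in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
    moved <- sweep(idx, 2, shift, `+`)
    keep <- moved[, 1] >= 1 & moved[, 1] <= d[1] & moved[, 2] >= 1 &
      moved[, 2] <= d[2] & moved[, 3] >= 1 & moved[, 3] <= d[3]
    dil[moved[keep, , drop = FALSE]] <- TRUE
  }
  b <- binary_volume(dil)
  cmp <- segmentation_compare(a, b)
  shell <- sum(dil) - sum(a$voxels)
  expect_equal(cmp$n_disagree, shell)
  expect_equal(cmp$max_boundary_distance, 1)
  expect_lt(cmp$dice, 1)
  # disjoint masks: Dice 0
  c1 <- array(FALSE, c(10, 10, 10)); c1[1:2, , ] <- TRUE
  c2 <- array(FALSE, c(10, 10, 10)); c2[8:10, , ] <- TRUE
  expect_equal(segmentation_compare(binary_volume(c1), binary_volume(c2))$dice, 0)
})

test_that("thresholding is monotone: raising the threshold never adds bone", {
  sim <- simulate_phantom(phantom_params(shape = c(24, 24, 24), seed = 7))
  v <- sim$volume$voxels
  thr <- sort(runif(5, 60, 180))
  counts <- vapply(thr, function(t) sum(v >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("volumes round-trip through NRRD and TIFF", {
  sim <- simulate_phantom(phantom_params(shape = c(12, 14, 9), seed = 8))
  p1 <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(sim$volume, p1)
  back <- read_volume(p1)
  expect_equal(back$voxels, sim$volume$voxels, tolerance = 1e-12)
  expect_equal(back$spacing, sim$volume$spacing)
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_volume(sim$volume, p2)
  back2 <- read_volume(p2)
  expect_equal(back2$voxels, sim$volume$voxels, tolerance = 1e-4)
})
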