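# Independent dense-system TPS oracle: same mathematical definition, coded
# separately (explicit loops, no shared helpers) for the bent-grid check.
tps_oracle_eval <- function(source, target, points) {
  m <- nrow(source); D <- ncol(source)
  U <- function(r) if (D == 3) r else ifelse(r > 0, r^2 * log(r), 0)
  K <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m)
    K[i, j] <- U(sqrt(sum((source[i, ] - source[j, ])^2)))
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, D + 1, D + 1)))
  coefs <- solve(L, rbind(target, matrix(0, D + 1, D)))
  out <- matrix(0, nrow(points), D)
  for (q in seq_len(nrow(points))) {
    u <- vapply(1:m, function(j) U(sqrt(sum((points[q, ] - source[j, ])^2))),
                numeric(1))
    out[q, ] <- c(1, points[q, ]) %*% coefs[m + 1:(D + 1), ] +
      u %*% coefs[1:m, ]
  }
  out
}

test_that("TPS reproduces control points exactly and zero/translation warps", {
  set.seed(1)
  src <- matrix(runif(30, -1, 1), 10, 3)
  # identity warp
  map0 <- tps_fit(src, src)
  expect_lt(max(abs(map0$weights)), 1e-8)
  expect_equal(map0$affine, rbind(0, diag(3)), tolerance = 1e-8, ignore_attr = TRUE)
  # translation reproduced everywhere
  t_vec <- c(0.3, -1.2, 0.7)
  mapt <- tps_fit(src, sweep(src, 2, t_vec, `+`))
  pts <- matrix(runif(150, -2, 2), 50, 3)
  expect_equal(tps_apply(mapt, pts), sweep(pts, 2, t_vec, `+`), tolerance = 1e-8)
  # exact interpolation at control points for a nonlinear warp
  tgt <- src + 0.2 * sin(src[, c(2, 3, 1)])
  map <- tps_fit(src, tgt)
  expect_equal(tps_apply(map, src), tgt, tolerance = 1e-8)
  # side conditions on the weights
  expect_lt(max(abs(colSums(map$weights))), 1e-8)
  expect_lt(max(abs(t(map$weights) %*% src)), 1e-8)
})

test_that("2D bent-grid TPS matches an independently coded dense solve", {
  set.seed(2)
  gx <- expand.grid(x = seq(0, 1, length.out = 4), y = seq(0, 1, length.out = 4))
  src <- as.matrix(gx)
  tgt <- src + cbind(0.1 * sin(pi * src[, 2]), 0.1 * src[, 1]^2)
  map <- tps_fit(src, tgt)
  pts <- matrix(runif(40, 0.05, 0.95), 20, 2)
  expect_equal(unname(tps_apply(map, pts)), tps_oracle_eval(src, tgt, pts),
               tolerance = 1e-9)
})

test_that("affine-only mappings are applied exactly", {
  set.seed(3)
  src <- matrix(runif(24, -1, 1), 8, 3)
  A <- matrix(c(1.2, 0.1, 0, -0.2, 0.9, 0.05, 0, 0.1, 1.1), 3, 3)
  b <- c(0.5, -0.3, 0.2)
  tgt <- sweep(src %*% A, 2, b, `+`)
  map <- tps_fit(src, tgt)
  pts <- matrix(runif(30, -1.5, 1.5), 10, 3)
  expect_equal(tps_apply(map, pts), sweep(pts %*% A, 2, b, `+`), tolerance = 1e-6)
  expect_lt(max(abs(map$weights)), 1e-6)
})

test_that("degenerate sources and undersized control sets are rejected", {
  flat <- cbind(seq_len(6), seq_len(6) * 2, 0 * seq_len(6)) # coplanar
  expect_error(tps_fit(flat, flat + 1), "degenerate|singular")
  expect_error(tps_fit(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3)),
               "control points")
})

mask_landmarks <- function(dataset, specimen, lms) {
  cfgs <- dataset$configurations
  cf <- cfgs[[specimen]]
  cf$missing[lms] <- TRUE
  cf$coords[lms, ] <- NA_real_
  cfgs[[specimen]] <- landmark_config(cf$coords, labels = cf$labels,
                                      specimen_id = cf$specimen_id,
                                      missing = cf$missing)
  assemble_dataset(cfgs, dataset$metadata, dataset$pairing,
                   template = dataset$labels)
}

test_that("a masked landmark on a reference-identical specimen is recovered exactly", {
  sim <- small_landmark_sim(seed = 5, n = 4, noise_sd = 0, asymmetry_sd = 0,
                            sex_effect = 0, allometry = 0, size_sdlog = 0)
  # all specimens share one shape; mask one landmark of specimen 2
  ds <- mask_landmarks(sim$dataset, 2L, 7L)
  truth <- sim$dataset$configurations[[2]]$coords[7, ]
  est <- estimate_missing(ds, group_by = "species")
  expect_equal(est$configurations[[2]]$coords[7, ], truth, tolerance = 1e-8)
  expect_equal(attr(est, "estimation_log")$n_estimated, 1L)
})

test_that("an affine deformation of the reference is recovered within 1e-6", {
  sim <- small_landmark_sim(seed = 6, n = 6, noise_sd = 0, asymmetry_sd = 0,
                            sex_effect = 0, allometry = 0, size_sdlog = 0)
  ds <- sim$dataset
  cfgs <- ds$configurations
  # make specimen 3 an affine transform of the common shape, mask 3 landmarks
  A <- diag(3) + matrix(c(0.08, 0.02, 0, -0.03, 0.05, 0.01, 0, 0.02, -0.06), 3, 3)
  base <- cfgs[[1]]$coords
  cfgs[[3]] <- landmark_config(base %*% A, labels = ds$labels,
                               specimen_id = cfgs[[3]]$specimen_id)
  ds <- assemble_dataset(cfgs, ds$metadata, ds$pairing, template = ds$labels)
  truth <- ds$configurations[[3]]$coords[c(2, 9, 17), ]
  ds <- mask_landmarks(ds, 3L, c(2, 9, 17))
  est <- estimate_missing(ds, group_by = "species")
  expect_equal(est$configurations[[3]]$coords[c(2, 9, 17), ], truth,
               tolerance = 1e-6)
})

test_that("estimate_missing logs counts, is idempotent, and guards its preconditions", {
  sim <- small_landmark_sim(seed = 7, n = 6)
  # complete dataset: unchanged
  est0 <- estimate_missing(sim$dataset)
  expect_equal(dataset_array(est0), dataset_array(sim$dataset))

  # 14 masked coordinates -> 14 estimated, none remaining
  ds <- sim$dataset
  set.seed(21)
  left <- 14L
  spec <- 2L
  while (left > 0L) {
    take <- min(left, 3L)
    ds <- mask_landmarks(ds, spec, sample(20L, take))
    left <- left - take
    spec <- spec + 1L
  }
  n_masked <- sum(ds$missing_report$n_missing)
  expect_equal(n_masked, 14L)
  est <- estimate_missing(ds)
  expect_equal(sum(est$missing_report$n_missing), 0L)
  expect_equal(sum(attr(est, "estimation_log")$n_estimated), 14L)

  # a group with no complete specimen is an error naming the group
  sim_b <- small_landmark_sim(seed = 8, n = 2)
  ds_b <- sim_b$dataset
  for (i in seq_len(n_specimens(ds_b)))
    if (ds_b$metadata$species[i] == "B") ds_b <- mask_landmarks(ds_b, i, 1L)
  expect_error(estimate_missing(ds_b), "'B'")
})

test_that("recovery error stays below 3 sigma for small digitisation noise", {
  # specimens = reference + smooth deformation + coordinate noise sigma;
  # sigma = 0.5% of centroid size (unit CS template)
  sigma <- 0.005
  sim <- small_landmark_sim(seed = 9, n = 20, noise_sd = sigma)
  ds <- sim$dataset
  errs <- numeric(0)
  set.seed(33)
  for (r in 1:20) {
    spec <- sample(2:20, 1)
    lm <- sample(20L, 1)
    truth <- ds$configurations[[spec]]$coords[lm, ]
    cs <- centroid_size(ds$configurations[[spec]]$coords)
    masked <- mask_landmarks(ds, spec, lm)
    est <- estimate_missing(masked)
    errs <- c(errs, abs(est$configurations[[spec]]$coords[lm, ] - truth) / cs)
  }
  expect_lt(mean(errs), 3 * sigma)
  expect_lt(stats::quantile(errs, 0.9), 3 * sigma)
})
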