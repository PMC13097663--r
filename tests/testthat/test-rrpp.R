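one_way_data <- function(n_per = 5, k = 3, seed = 1, delta = 1) {
  set.seed(seed)
  data.frame(g = factor(rep(LETTERS[1:k], each = n_per)),
             y = rnorm(n_per * k) + rep(seq_len(k) * delta, each = n_per))
}

test_that("univariate single-factor F equals the classical ANOVA F exactly", {
  d <- one_way_data(n_per = 5, k = 3, seed = 2)
  fit <- fit_rrpp(d$y, "g", d, iter = 9, seed = 1)
  oracle <- anova(lm(y ~ g, data = d))
  expect_equal(fit$F[["g"]], oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(fit$SS[["g"]], oracle$`Sum Sq`[1], tolerance = 1e-12)
  expect_equal(unname(fit$df), oracle$Df[1])
  expect_equal(fit$SS_residual, oracle$`Sum Sq`[2], tolerance = 1e-12)
})

test_that("exhaustive residual permutation reproduces the brute-force p-value", {
  # two groups of 3: the reduced model is the intercept, so permuting its
  # residuals is equivalent to permuting y; enumerate all 6! arrangements
  set.seed(3)
  d <- data.frame(g = factor(rep(c("a", "b"), each = 3)),
                  y = c(1.2, 0.4, 0.9, 2.6, 2.1, 3.0))
  perms_list <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms_list <- perms_list[apply(perms_list, 1, function(r) !anyDuplicated(r)), ]
  perms <- t(perms_list)
  id <- which(apply(perms, 2, function(p) all(p == 1:6)))
  perms <- cbind(perms[, id], perms[, -id])
  fit <- fit_rrpp(d$y, "g", d, perms = perms)
  # independent brute force: classical F for every permutation of y
  f_stat <- function(y, g) anova(lm(y ~ g))$`F value`[1]
  f_obs <- f_stat(d$y, d$g)
  f_all <- apply(perms, 2, function(p) f_stat(d$y[p], d$g))
  expect_equal(fit$p[["g"]], mean(f_all >= f_obs - 1e-12))
  expect_equal(fit$n_permutations, 719L)
  expect_gte(fit$p[["g"]], 1 / 720)
})

test_that("SS partition and R2 identities hold for multi-term multivariate fits", {
  set.seed(4)
  n <- 40
  d <- data.frame(x = rnorm(n),
                  sex = factor(sample(c("M", "F"), n, TRUE)),
                  g = factor(sample(c("p", "q", "r"), n, TRUE)))
  Y <- matrix(rnorm(n * 6), n, 6) + model.matrix(~g, d)[, 2:3] %*%
    matrix(rnorm(12), 2, 6)
  fit <- fit_rrpp(Y, c("x", "sex", "g", "sex:g"), d, iter = 99, seed = 5)
  expect_equal(sum(fit$SS) + fit$SS_residual, fit$SS_total, tolerance = 1e-8)
  tab <- anova_table(fit)
  expect_equal(sum(tab$Rsq[1:5]), 1, tolerance = 1e-8)
  expect_equal(tab$Rsq[1:4], unname(fit$SS / fit$SS_total), tolerance = 1e-12)
  expect_true(all(fit$p >= 1 / 100 & fit$p <= 1))
})

test_that("permutation p-values are bit-reproducible given (seed, iter)", {
  d <- one_way_data(n_per = 6, k = 3, seed = 6, delta = 0.3)
  f1 <- fit_rrpp(d$y, "g", d, iter = 199, seed = 42)
  f2 <- fit_rrpp(d$y, "g", d, iter = 199, seed = 42)
  expect_identical(f1$p, f2$p)
  expect_identical(f1$permutation_F, f2$permutation_F)
  f3 <- fit_rrpp(d$y, "g", d, iter = 199, seed = 43)
  expect_false(identical(f1$permutation_F, f3$permutation_F))
})

test_that("nested island-within-region terms get the nested degrees of freedom", {
  set.seed(7)
  d <- expand.grid(rep = 1:4, island = paste0("is", 1:6))
  d$region <- factor(ifelse(d$island %in% paste0("is", 1:3), "N", "S"))
  d$island <- factor(d$island)
  d$y <- rnorm(nrow(d))
  fit <- fit_rrpp(d$y, c("region", "region:island"), d, iter = 9, seed = 1)
  expect_equal(unname(fit$df), c(1L, 4L)) # 6 islands - 2 regions
  # a duplicated term is fully aliased -> error naming it
  expect_error(fit_rrpp(d$y, c("region", "region"), d, iter = 9, seed = 1),
               "rank-deficient")
})

test_that("effect_size matches hand computation and guards degenerate input", {
  expect_equal(effect_size(3, c(1, 2, 3), "identity"), 1.0)
  expect_equal(effect_size(2, c(1, 2, 3), "identity"), 0)
  expect_warning(z <- effect_size(5, c(2, 2, 2), "identity"), "degenerate")
  expect_equal(z, 0)
  # log transform: floor protects zero statistics
  expect_silent(effect_size(1, c(0, 1, 2), "log"))
})

test_that("observed pairwise distance equals independently computed LS-mean distance", {
  set.seed(8)
  n <- 36
  d <- data.frame(x = rnorm(n),
                  sex = factor(rep(c("M", "F"), n / 2)),
                  g = factor(rep(c("p", "q", "r"), each = n / 3)))
  Y <- matrix(rnorm(n * 4), n, 4)
  Y[d$g == "q", ] <- Y[d$g == "q", ] + 1.5
  full <- fit_rrpp(Y, c("x", "sex", "g"), d, iter = 99, seed = 9)
  null <- fit_rrpp(Y, c("x", "sex"), d, iter = 99, seed = 9)
  pw <- pairwise_groups(full, null, "g", iter = 99, seed = 9)
  # oracle: column-wise lm predictions on the factor grid at mean covariate
  grid <- expand.grid(sex = levels(d$sex), g = levels(d$g))
  grid$x <- mean(d$x)
  pred <- sapply(seq_len(ncol(Y)), function(j) {
    m <- lm(Y[, j] ~ x + sex + g, data = d)
    predict(m, newdata = grid)
  })
  lsm <- apply(pred, 2, function(cl) tapply(cl, grid$g, mean))
  d_pq <- sqrt(sum((lsm["p", ] - lsm["q", ])^2))
  expect_equal(pw$d[pw$pair == "p:q"], d_pq, tolerance = 1e-10)
  expect_true(all(pw$d >= 0))
  expect_true(all(pw$UCL95 >= apply(attr(pw, "ls_means"), 1, function(x) 0)))
  # strong separation of q shows up, matched pair orders
  expect_lt(pw$p[pw$pair == "p:q"], 0.05)
})

test_that("pairwise test is calibrated under the null", {
  # identical generating means: p should exceed 0.05 in at least ~90% of runs
  set.seed(10)
  hits <- 0L
  for (r in 1:100) {
    n <- 20
    d <- data.frame(g = factor(rep(c("a", "b"), each = n / 2)), x = rnorm(n))
    Y <- matrix(rnorm(n * 2), n, 2)
    full <- fit_rrpp(Y, c("x", "g"), d, iter = 99, seed = r)
    null <- fit_rrpp(Y, "x", d, iter = 99, seed = r)
    pw <- pairwise_groups(full, null, "g", iter = 99, seed = r)
    if (pw$p[1] > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("rejection power increases with simulated effect size", {
  set.seed(11)
  power_at <- function(delta) {
    rej <- 0L
    for (r in 1:100) {
      d <- data.frame(g = factor(rep(c("a", "b"), each = 12)))
      y <- rnorm(24) + (d$g == "b") * delta
      fit <- fit_rrpp(y, "g", d, iter = 99, seed = 1000 + r)
      if (fit$p[["g"]] <= 0.05) rej <- rej + 1L
    }
    rej / 100
  }
  pw <- vapply(c(0, 0.6, 1.5), power_at, numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_lt(pw[1], 0.12)
  expect_gt(pw[3], 0.9)
})

test_that("anova_table formats one row per term plus residual and total", {
  d <- one_way_data(n_per = 5, k = 2, seed = 12)
  fit <- fit_rrpp(d$y, "g", d, iter = 99, seed = 1)
  tab <- anova_table(fit)
  expect_equal(rownames(tab), c("g", "Residuals", "Total"))
  expect_equal(tab$Rsq[1], fit$SS[["g"]] / fit$SS_total)
  expect_equal(tab$Df[3], nrow(d) - 1L)
})
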