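test_that("design construction enforces rank and contrast length", {
  X <- data.frame(intercept = 1, group = rep(0:1, 5), age = rnorm(10))
  d <- vbm_design(X, c(0, 1, 0))
  expect_s3_class(d, "vbm_design")
  expect_error(vbm_design(X, c(0, 1)), "length")
  X$dup <- X$group
  expect_error(vbm_design(X, c(0, 1, 0, 0)), "dup")
  # a constant predictor is collinear with the intercept
  X2 <- data.frame(intercept = 1, pred = rep(2, 10))
  expect_error(vbm_design(X2, c(0, 1)), "collinear")
  # single column name contrast
  d2 <- vbm_design(data.frame(intercept = 1, g = rep(0:1, 5)), "g")
  expect_equal(d2$contrast, c(0, 1))
})

test_that("GLM t-map equals classical closed forms per voxel", {
  dim3 <- c(5, 5, 4)
  n <- 9
  Y <- noise_data(2 * n, dim3, seed = 101)
  g <- rep(0:1, each = n)
  des <- two_group_design(n)
  tm <- fit_glm_tmap(Y, des)
  # oracle: two-sample pooled-variance t at every voxel
  t_oracle <- apply(Y, 2, function(y)
    t.test(y[g == 1], y[g == 0], var.equal = TRUE)$statistic)
  expect_equal(as.numeric(tm$t), as.numeric(t_oracle), tolerance = 1e-10)
  expect_equal(tm$df, 2 * n - 2)
  # simple regression slope t with a covariate design
  x <- rnorm(2 * n)
  des2 <- vbm_design(data.frame(intercept = 1, x = x), "x")
  tm2 <- fit_glm_tmap(Y, des2)
  t_lm <- apply(Y, 2, function(y)
    summary(lm(y ~ x))$coefficients["x", "t value"])
  expect_equal(as.numeric(tm2$t), as.numeric(t_lm), tolerance = 1e-10)
  # zero contrast gives a zero map
  des0 <- vbm_design(data.frame(intercept = 1, g = g), c(0, 0))
  expect_true(all(fit_glm_tmap(Y, des0)$t == 0))
})

test_that("nuisance covariate adjustment removes a planted age effect", {
  dim3 <- c(6, 6, 6)
  n <- 40
  set.seed(55)
  g <- rep(0:1, each = n / 2)
  age <- 55 + 8 * g + rnorm(n, 0, 4) # groups differ in age
  Y <- matrix(rnorm(n * prod(dim3), sd = 0.5), n) +
    outer(0.05 * age, rep(1, prod(dim3))) # density depends on age only
  attr(Y, "dim3") <- dim3
  with_age <- vbm_design(data.frame(intercept = 1, group = g, age = age),
                         c(0, 1, 0))
  without_age <- vbm_design(data.frame(intercept = 1, group = g), c(0, 1))
  t_adj <- fit_glm_tmap(Y, with_age)$t
  t_raw <- fit_glm_tmap(Y, without_age)$t
  # adjusting for age leaves a null-like group map; omitting it inflates t
  expect_lt(abs(mean(t_adj)), 0.35)
  expect_gt(mean(t_raw), mean(t_adj) + 0.5)
  expect_gt(mean(abs(t_raw) > 2), mean(abs(t_adj) > 2))
})

test_that("TFCE matches the single-voxel closed form and the brute-force
           reference", {
  # single suprathreshold voxel: integral of h^H dh = h^{H+1}/(H+1)
  m <- array(0, c(8, 8, 8))
  m[4, 4, 4] <- 3
  v <- tfce_transform(m, params = tfce_params(H = 2, E = 0.5, dh = 0.01))
  expect_equal(v[4, 4, 4], 9, tolerance = 0.05 / 9)
  expect_equal(sum(v > 0), 1)
  # all-zero map
  expect_true(all(tfce_transform(array(0, c(8, 8, 8))) == 0))
  # plateau voxels dominate an isolated voxel of the same height
  p <- array(0, c(5, 5, 5))
  p[2, 2, 2] <- 2; p[3, 2, 2] <- 2; p[5, 5, 5] <- 2
  vp <- tfce_transform(p, params = tfce_params(dh = 0.01))
  expect_gte(vp[2, 2, 2], vp[5, 5, 5])
  expect_equal(vp[2, 2, 2], sqrt(2) * vp[5, 5, 5], tolerance = 1e-6)
  # brute-force reference with dh/10 on random smooth maps
  nbrs <- neighbour_list(c(8, 8, 8), 26)
  for (seed in 1:6) {
    mm <- random_stat_map(c(8, 8, 8), seed = seed)
    dh <- max(mm) / 100
    impl <- tfce_transform(mm, params = tfce_params(dh = dh))
    ref <- tfce_reference(mm, dh = dh / 10, nbrs = nbrs)
    scale <- max(ref)
    expect_lt(max(abs(impl - ref)) / scale, 0.01)
  }
})

test_that("TFCE respects connectivity and dh refinement is stable", {
  # two diagonal voxels: one component under 26-connectivity, two under 6
  m <- array(0, c(5, 5, 5))
  m[2, 2, 2] <- 1; m[3, 3, 3] <- 1
  v26 <- tfce_transform(m, params = tfce_params(dh = 0.005, connectivity = 26))
  v6 <- tfce_transform(m, params = tfce_params(dh = 0.005, connectivity = 6))
  expect_equal(v26[2, 2, 2], sqrt(2) * v6[2, 2, 2], tolerance = 1e-6)
  # halving dh changes values by < 0.5%
  mm <- random_stat_map(c(8, 8, 8), seed = 31)
  dh <- max(mm) / 100
  a <- tfce_transform(mm, params = tfce_params(dh = dh))
  b <- tfce_transform(mm, params = tfce_params(dh = dh / 2))
  expect_lt(max(abs(a - b)) / max(b), 0.005)
})

test_that("connected component labelling matches the flood-fill oracle", {
  set.seed(77)
  for (conn in c(6L, 18L, 26L)) {
    mask <- array(runif(6^3) < 0.25, c(6, 6, 6))
    lab <- label_components(mask, conn)
    nbrs <- neighbour_list(c(6, 6, 6), conn)
    oracle <- array(flood_label(which(mask), nbrs, length(mask)), dim(mask))
    # same partition: component memberships agree up to label naming
    expect_equal(lab > 0, mask)
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      expect_equal(length(unique(oracle[vox])), 1L)
      expect_equal(sum(oracle %in% oracle[vox[1]]), length(vox))
    }
  }
})

test_that("permutation FWE is deterministic, bounded below, and absorbs
           intercept shifts", {
  dim3 <- c(8, 8, 8)
  Y <- noise_data(20, dim3, seed = 202)
  des <- two_group_design(10)
  r1 <- permutation_fwe(Y, des, n_perm = 199, seed = 5)
  r2 <- permutation_fwe(Y, des, n_perm = 199, seed = 5)
  expect_identical(r1$fwe_p_map, r2$fwe_p_map)
  expect_true(all(r1$fwe_p_map >= 1 / 200))
  # adding a constant to every subject volume leaves fwe_p unchanged
  Yc <- Y + 5
  attr(Yc, "dim3") <- dim3
  r3 <- permutation_fwe(Yc, des, n_perm = 199, seed = 5)
  expect_equal(r1$fwe_p_map, r3$fwe_p_map, tolerance = 1e-12)
  # TFCE map is zero where t <= 0 (one-sided)
  expect_true(all(r1$tfce_map[r1$t_map <= 0] == 0))
  # insufficient permutation resolution warns
  expect_warning(permutation_fwe(Y, des, n_perm = 199, seed = 1,
                                 alpha = 0.001),
                 "cannot resolve")
})

test_that("a planted group effect is detected and localised", {
  dim3 <- c(10, 10, 10)
  n <- 14
  set.seed(404)
  effect <- box_mask(dim3, 3:5, 3:5, 3:5)
  Y <- matrix(rnorm(2 * n * prod(dim3), sd = 0.3), 2 * n)
  g <- rep(0:1, each = n)
  Y[, which(effect)] <- Y[, which(effect)] - outer(g, rep(0.8, sum(effect)))
  attr(Y, "dim3") <- dim3
  des <- two_group_design(n, direction = -1) # test for decreases in group 1
  r <- permutation_fwe(Y, des, n_perm = 299, seed = 6)
  cl <- extract_clusters(r, alpha = 0.05)
  expect_gte(nrow(cl), 1)
  sig <- r$fwe_p_map < 0.05
  expect_gt(sum(sig & effect) / sum(effect), 0.5)
})

test_that("masked regression recovers a planted descriptor association", {
  dim3 <- c(10, 10, 10)
  n <- 30
  set.seed(505)
  cfl <- exp(rnorm(n, 0, 0.5))
  region <- box_mask(dim3, 6:8, 6:8, 6:8)
  Y <- matrix(rnorm(n * prod(dim3), sd = 0.3), n)
  # density falls with log(cfl) inside the region
  Y[, which(region)] <- Y[, which(region)] -
    outer(log(cfl), rep(0.8, sum(region)))
  attr(Y, "dim3") <- dim3
  mask <- array(TRUE, dim3)
  r <- masked_regression(Y, log(cfl), covariates = NULL,
                         restrict_mask = mask, n_perm = 299, seed = 7)
  sig <- r$fwe_p_map < 0.025
  expect_gt(sum(sig & region) / sum(region), 0.5)
  # restriction to a single voxel defines the result on exactly that voxel
  one <- array(FALSE, dim3); one[2, 2, 2] <- TRUE
  r1 <- masked_regression(Y, log(cfl), covariates = NULL,
                          restrict_mask = one, n_perm = 199, seed = 8)
  expect_equal(sum(r1$t_map != 0), 1)
  # a constant predictor is a design error
  expect_error(masked_regression(Y, rep(1, n), covariates = NULL,
                                 restrict_mask = mask, n_perm = 199),
               "collinear")
  expect_error(masked_regression(Y, log(cfl), covariates = NULL,
                                 restrict_mask = array(FALSE, dim3)),
               "empty")
})

test_that("Bonferroni threshold and cluster tables behave as defined", {
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_error(bonferroni_threshold(1.2, 2), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")

  # two disjoint planted regions -> exactly two clusters, sorted by size
  dim3 <- c(12, 12, 12)
  n <- 12
  set.seed(66)
  r1m <- box_mask(dim3, 2:5, 2:5, 2:5)     # 64 voxels
  r2m <- box_mask(dim3, 9:11, 9:11, 9:11)  # 27 voxels
  Y <- matrix(rnorm(2 * n * prod(dim3), sd = 0.2), 2 * n)
  g <- rep(0:1, each = n)
  for (m in list(r1m, r2m))
    Y[, which(m)] <- Y[, which(m)] - outer(g, rep(1, sum(m)))
  attr(Y, "dim3") <- dim3
  res <- permutation_fwe(Y, two_group_design(n, -1), n_perm = 299, seed = 9)
  cl <- extract_clusters(res, alpha = 0.05)
  expect_equal(nrow(cl), 2)
  expect_true(all(diff(cl$n_voxels) <= 0))
  # no significant voxels -> empty table
  null_res <- permutation_fwe(noise_data(20, c(6, 6, 6), seed = 1),
                              two_group_design(10), n_perm = 199, seed = 2)
  expect_equal(nrow(extract_clusters(null_res, alpha = 1 / 200)), 0)
})
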