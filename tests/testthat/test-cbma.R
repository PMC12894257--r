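# Coordinate-based meta-analysis: kernel reconstruction, random-effects
# pooling against closed-form and metafor oracles, clustering rules, and
# the robustness diagnostics.

test_that("kernel reconstruction honors the FWHM definition and signed
          maximum-magnitude overlap", {
  # 5 mm lattice: peak and probes sit exactly on voxel centers
  g <- test_grid(5)
  study <- list(id = "S1", n_patients = 24, n_controls = 26,
                peaks = data.frame(x = 0, y = -26, z = 3, t = 3))
  rec <- reconstruct_effect_map(study, g, fwhm = 20)
  mask_idx <- which(g$mask)
  d_expect <- peak_d(3, 24, 26)
  at <- function(xyz) rec$d[match(nearest_voxel(g, matrix(xyz, 1)),
                                  mask_idx)]
  # value 1 at distance 0
  expect_equal(at(c(0, -26, 3)), d_expect, tolerance = 1e-12)
  # half maximum at FWHM/2 by definition
  expect_equal(at(c(0, -16, 3)), d_expect / 2, tolerance = 1e-12)
  # zero beyond the 2*FWHM truncation
  expect_equal(at(c(0, -26 + 45, 3)), 0)
  # variance formula applied voxelwise
  expect_equal(rec$v, d_variance(rec$d, 24, 26), tolerance = 1e-14)

  # two same-sign peaks 5 mm apart: midpoint carries the larger-magnitude
  # kernel contribution, verified by brute-force kernel evaluation
  study2 <- list(id = "S2", n_patients = 24, n_controls = 26,
                 peaks = data.frame(x = c(0, 0), y = c(-26, -21), z = 3,
                                    t = c(3, 2)))
  rec2 <- reconstruct_effect_map(study2, g, fwhm = 20)
  sigma <- 20 / (2 * sqrt(2 * log(2)))
  probe <- c(0, -21, 3)
  vox <- voxel_to_world(g, arrayInd(nearest_voxel(g, matrix(probe, 1)),
                                    g$dims) - 1L)
  contrib <- vapply(1:2, function(i) {
    pk_vox <- voxel_to_world(
      g, arrayInd(nearest_voxel(
        g, as.matrix(study2$peaks[i, c("x", "y", "z")])), g$dims) - 1L)
    peak_d(study2$peaks$t[i], 24, 26) *
      exp(-sum((vox - pk_vox)^2) / (2 * sigma^2))
  }, numeric(1))
  expect_equal(rec2$d[match(nearest_voxel(g, matrix(probe, 1)), mask_idx)],
               contrib[which.max(abs(contrib))], tolerance = 1e-12)

  # zero peaks: flat zero map is valid and logged
  expect_message(
    rec0 <- reconstruct_effect_map(
      list(id = "S0", n_patients = 20, n_controls = 20,
           peaks = data.frame(x = numeric(0), y = numeric(0),
                              z = numeric(0), t = numeric(0))), g),
    "flat zero")
  expect_true(all(rec0$d == 0))
})

test_that("DerSimonian-Laird pooling matches the closed-form and metafor
          oracles", {
  d <- c(0.9, 0.1, 0.5)
  v <- c(0.1, 0.2, 0.4)
  pool <- pool_random_effects(matrix(d, 3), matrix(v, 3))
  # frozen from the DL closed form; cross-checked against metafor below
  expect_equal(pool$mean, 0.601198138430, tolerance = 1e-10)
  expect_equal(pool$se, 0.253680418970, tolerance = 1e-10)
  expect_equal(pool$tau2, 0.017142857143, tolerance = 1e-10)
  skip_if_not_installed("metafor")
  f <- metafor::rma(yi = d, vi = v, method = "DL")
  expect_equal(pool$mean, as.numeric(f$b), tolerance = 1e-10)
  expect_equal(pool$se, f$se, tolerance = 1e-10)
  expect_equal(pool$tau2, f$tau2, tolerance = 1e-10)
})

test_that("pooling degenerate cases: identical maps, symmetry, reordering
          and sign flip", {
  set.seed(8)
  k <- 5; nv <- 40
  d1 <- matrix(rnorm(nv), k, nv, byrow = TRUE)
  v1 <- matrix(0.2, k, nv)
  p <- pool_random_effects(d1, v1)
  expect_equal(p$mean, d1[1, ], tolerance = 1e-12)
  expect_true(all(p$tau2 == 0))

  p2 <- pool_random_effects(matrix(c(1, -1), 2, nv), matrix(0.2, 2, nv))
  expect_equal(p2$mean, rep(0, nv), tolerance = 1e-12)

  dm <- matrix(rnorm(k * nv), k, nv)
  vm <- matrix(runif(k * nv, 0.1, 0.5), k, nv)
  ord <- sample(k)
  expect_equal(pool_random_effects(dm[ord, ], vm[ord, ])$z,
               pool_random_effects(dm, vm)$z, tolerance = 1e-12)
  expect_equal(pool_random_effects(-dm, vm)$z,
               -pool_random_effects(dm, vm)$z, tolerance = 1e-12)
  expect_true(all(pool_random_effects(dm, vm)$tau2 >= 0))
  expect_warning(pool_random_effects(dm[1, , drop = FALSE],
                                     vm[1, , drop = FALSE]), "single")
})

test_that("cluster extraction applies extent and peak-height rules", {
  g <- test_grid(6)
  mask_idx <- which(g$mask)
  z <- rep(0, length(mask_idx))
  # a compact blob of 49 suprathreshold voxels and one of 60
  ctr49 <- nearest_voxel(g, matrix(c(20, -20, 0), 1))
  ctr60 <- nearest_voxel(g, matrix(c(-30, 20, 10), 1))
  xyz <- voxel_to_world(g, arrayInd(mask_idx, g$dims) - 1L)
  d49 <- sqrt(rowSums(sweep(xyz, 2, c(20, -20, 0))^2))
  d60 <- sqrt(rowSums(sweep(xyz, 2, c(-30, 20, 10))^2))
  z[order(d49)[1:49]] <- 5
  z[order(d60)[1:60]] <- -5
  null_abs_z <- abs(rnorm(20000))
  cl <- threshold_and_cluster(z, g, null_abs_z, voxel_p = 0.005,
                              peak_z = 1, extent = 50)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$sign, -1)
  expect_identical(cl$extent, 60L)
  # the same blob survives when the extent rule allows it
  cl2 <- threshold_and_cluster(z, g, null_abs_z, extent = 40)
  expect_identical(nrow(cl2), 2L)
  # peak-height filter: a suprathreshold cluster whose null-calibrated z
  # stays below peak_z is discarded
  cl3 <- threshold_and_cluster(z, g, null_abs_z, peak_z = 10,
                               extent = 40)
  expect_identical(nrow(cl3), 0L)
  expect_error(threshold_and_cluster(z, g, numeric(0)), "null")
})

test_that("heterogeneity Q matches hand-computed values and flags planted
          disagreement", {
  # Q for d = (1, 1, 3), v = (1, 1, 1): fixed mean 5/3, Q = 8/3
  g1 <- point_grid()
  het_in <- list(d = matrix(c(1, 1, 3), 3), v = matrix(1, 3, 1))
  q <- attr(heterogeneity_map(het_in$d, het_in$v, g1), "q")
  expect_equal(q, 8 / 3, tolerance = 1e-10)

  # homogeneous studies: Q = 0 everywhere, no clusters
  g <- test_grid(6)
  nv <- sum(g$mask)
  d_same <- matrix(rep(rnorm(nv), 4), 4, nv, byrow = TRUE)
  het0 <- heterogeneity_map(d_same, matrix(0.2, 4, nv), g)
  expect_identical(nrow(het0), 0L)
  expect_true(all(abs(attr(het0, "q")) < 1e-18))

  # planted disagreement at one locus produces a heterogeneity cluster
  tr <- ground_truth(seed = 71,
                     effect_loci = data.frame(x = 0, y = -20, z = 0,
                                              d = 1))
  studies <- lapply(1:6, function(i) {
    list(id = paste0("S", i), n_patients = 30, n_controls = 30,
         peaks = data.frame(x = 0, y = -20, z = 0,
                            t = if (i <= 3) 4 else -4))
  })
  fp <- gmtx:::kernel_footprint(g, 20)
  recs <- lapply(studies, reconstruct_effect_map, grid = g, fwhm = 20,
                 footprint = fp)
  dmat <- do.call(rbind, lapply(recs, `[[`, "d"))
  vmat <- do.call(rbind, lapply(recs, `[[`, "v"))
  het <- heterogeneity_map(dmat, vmat, g, extent = 10)
  expect_gt(nrow(het), 0)
  pk <- which.max(het$peak_z)
  expect_lt(sqrt(het$x[pk]^2 + (het$y[pk] + 20)^2 + het$z[pk]^2), 12)
})

test_that("Egger regression matches a closed-form OLS oracle and detects
          planted small-study bias", {
  g1 <- point_grid()
  set.seed(12)
  se <- seq(0.1, 0.55, length.out = 10)
  eff <- rnorm(10, 0.4, 0.05)
  res <- egger_and_funnel(c(0, 0, 0), matrix(eff, 10),
                          matrix(se^2, 10), g1)
  # independent OLS oracle: regression of eff/se on 1/se via the normal
  # equations, intercept t-test
  x <- cbind(1, 1 / se)
  y <- eff / se
  beta <- solve(t(x) %*% x, t(x) %*% y)
  resid <- y - x %*% beta
  s2 <- sum(resid^2) / (10 - 2)
  se_b <- sqrt(s2 * solve(t(x) %*% x)[1, 1])
  p_oracle <- 2 * pt(abs(beta[1] / se_b), df = 8, lower.tail = FALSE)
  expect_equal(res$egger_intercept, beta[1], tolerance = 1e-10)
  expect_equal(res$egger_p, p_oracle, tolerance = 1e-10)
  expect_identical(nrow(res$funnel), 10L)

  # effects proportional to SE (planted bias): intercept detected
  eff_bias <- 2.5 * se + rnorm(10, 0, 0.01)
  res_b <- egger_and_funnel(c(0, 0, 0), matrix(eff_bias, 10),
                            matrix(se^2, 10), g1)
  expect_lt(res_b$egger_p, 0.05)

  # fewer than 3 contributing studies is reported as missing
  res_m <- egger_and_funnel(c(0, 0, 0), matrix(c(0.5, 0.4, 0, 0), 4),
                            matrix(0.04, 4, 1), g1)
  expect_true(is.na(res_m$egger_p))
})

test_that("jackknife survival reflects how many studies carry the effect", {
  g <- test_grid(6)
  tr <- ground_truth(seed = 81,
                     effect_loci = data.frame(x = 0, y = -20, z = 0,
                                              d = 1.2))
  ss <- simulate_study_set(tr, n_studies = 6, miss_rate = 0,
                           peak_noise_sd = 4, n_range = c(25, 45))
  nz <- build_null_ensemble(ss, g, n_null = 40, seed = 2)
  fit <- gmtx:::pool_study_set(ss, g, 20)
  cl <- threshold_and_cluster(fit$pool$z, g, nz)
  expect_gt(nrow(cl), 0)
  jk <- jackknife(ss, g, cl, nz)
  # the effect is carried equally by all studies: full survival
  expect_identical(jk$jackknife[1], "6/6")

  # effect present in a single study dies with its carrier
  df1 <- do.call(rbind, lapply(1:6, function(i) {
    peak_df(paste0("S", i), n1 = 30, n2 = 30,
            x = if (i == 1) 0 else 60 * (-1)^i, y = if (i == 1) -20 else
              (if (i %% 2) -80 else 30), z = 0,
            stat = if (i == 1) 6 else 0.2)
  }))
  ss1 <- study_set_from_df(df1)
  nz1 <- build_null_ensemble(ss1, g, n_null = 40, seed = 3)
  fit1 <- gmtx:::pool_study_set(ss1, g, 20)
  cl1 <- threshold_and_cluster(fit1$pool$z, g, nz1)
  if (nrow(cl1)) {
    jk1 <- jackknife(ss1, g, cl1, nz1)
    expect_lte(jk1$jk_survived[1], 1)
  }
})

test_that("the full CBMA recovers planted loci with robust diagnostics", {
  g <- test_grid(6)
  tr <- ground_truth(seed = 91)
  ss <- simulate_study_set(tr)
  res <- run_cbma(ss, g, n_null = 60, seed = 4)
  expect_gte(nrow(res$clusters), 2)
  for (i in seq_len(nrow(tr$effect_loci))) {
    dist <- sqrt((res$clusters$x - tr$effect_loci$x[i])^2 +
                 (res$clusters$y - tr$effect_loci$y[i])^2 +
                 (res$clusters$z - tr$effect_loci$z[i])^2)
    hit <- dist <= 10 &
      sign(res$clusters$peak_z) == sign(tr$effect_loci$d[i])
    expect_true(any(hit))
  }
  expect_true(all(res$clusters$jk_survived >= 0 &
                    res$clusters$jk_survived <= length(ss$studies)))
  expect_true(all(is.finite(res$clusters$egger_p)))
})
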