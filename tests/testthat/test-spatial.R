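# Sphere sampling, gene scores, variogram-matched surrogates and
# ensemble-based category enrichment.

test_that("sphere sampling averages exactly the in-reach voxels", {
  g <- test_grid(6)
  mask_idx <- which(g$mask)
  # constant map: every sphere mean equals the constant
  mc <- stat_map(g, rep(4.2, sum(g$mask)))
  # on-lattice coordinates so every 3 mm sphere reaches a voxel center
  samples <- data.frame(x = c(0, 12, -18), y = c(-24, 0, 6),
                        z = c(0, 6, -12))
  sv <- sphere_sample(mc, samples, radius = 3)
  expect_equal(sv$values, rep(4.2, 3), tolerance = 1e-12)

  # lone nonzero voxel, radius below the inter-voxel distance
  v <- rep(0, sum(g$mask))
  target <- nearest_voxel(g, matrix(c(0, -24, 0), 1))
  v[match(target, mask_idx)] <- 7
  m1 <- stat_map(g, v)
  s1 <- sphere_sample(m1, data.frame(x = 0, y = -24, z = 0), radius = 2.5)
  expect_equal(s1$values, 7, tolerance = 1e-12)

  # linear-gradient map, fully interior sphere: mean equals the value at
  # the sphere center (symmetry), brute-force voxel enumeration
  xyz <- voxel_to_world(g, arrayInd(mask_idx, g$dims) - 1L)
  grad <- 0.05 * xyz[, 2]
  mg <- stat_map(g, grad)
  ctr <- c(0, -24, 6)
  sg <- sphere_sample(mg, data.frame(x = ctr[1], y = ctr[2], z = ctr[3]),
                      radius = 7)
  in_sphere <- sqrt(rowSums(sweep(xyz, 2, ctr)^2)) <= 7
  expect_equal(sg$values, mean(grad[in_sphere]), tolerance = 1e-12)
  expect_equal(sg$values, 0.05 * ctr[2], tolerance = 1e-9)

  # samples beyond any in-mask voxel are dropped, all-out is an error
  far <- data.frame(x = c(0, 300), y = c(-20, 300), z = c(0, 300))
  expect_message(sf <- sphere_sample(mc, far, radius = 3), "dropped")
  expect_identical(sf$kept, c(TRUE, FALSE))
  expect_error(sphere_sample(mc, far[2, ], radius = 3), "no sample")
})

test_that("gene scores are exact for planted copies and aligned inputs", {
  set.seed(7)
  sv <- rnorm(40)
  expr <- cbind(copy = sv, neg = -sv, noise = rnorm(40),
                const = rep(1, 40))
  expect_warning(sc <- gene_scores(expr, sv), "constant")
  expect_equal(unname(sc["copy"]), 1, tolerance = 1e-12)
  expect_equal(unname(sc["neg"]), -1, tolerance = 1e-12)
  expect_identical(unname(sc["const"]), 0)
  expect_true(all(abs(sc) <= 1))
  expect_error(gene_scores(expr[1:10, ], sv), "aligned")
  expect_error(gene_scores(expr[1:2, ], sv[1:2]), "3 samples")
})

test_that("surrogates preserve the variogram of smooth maps and are
          deterministic", {
  g <- test_grid(6)
  tr <- ground_truth(seed = 23)
  v <- mask_values(true_effect_map(tr, g))
  ens <- make_surrogates(v, n = 60, seed = 5, grid = g)
  # value distribution preserved exactly under rank remapping
  expect_equal(sort(ens$maps[, 1]), sort(v), tolerance = 1e-12)
  # empirical variogram reproduced within 15% per bin on average
  gs <- vapply(seq_len(60), function(j) {
    gmtx:::pair_variogram(ens$maps[, j], ens$pairs)
  }, numeric(length(ens$gamma)))
  rel_dev <- mean(abs(rowMeans(gs) - ens$gamma) / ens$gamma)
  expect_lt(rel_dev, 0.15)
  ens2 <- make_surrogates(v, n = 60, seed = 5, grid = g)
  expect_identical(ens$maps, ens2$maps)

  # white-noise input degenerates to permutation-like surrogates
  set.seed(6)
  w <- rnorm(length(v))
  ensw <- make_surrogates(w, n = 30, seed = 7, grid = g)
  expect_lt(mean(abs(cor(ensw$maps, w))), 0.05)

  # scattered-coordinate (knn) path agrees on determinism and values
  sub <- sort(sample(length(v), 400))
  coords <- voxel_centers(g)[which(g$mask), ][sub, ]
  enk <- make_surrogates(v[sub], coords, n = 10, seed = 8)
  expect_identical(enk$maps,
                   make_surrogates(v[sub], coords, n = 10, seed = 8)$maps)
  expect_error(make_surrogates(v[1:200], matrix(0, 200, 3), n = 5),
               "coincide")
})

test_that("category filtering and GCEA honor size limits, determinism and
          the add-one convention", {
  g <- test_grid(8)
  tr <- ground_truth(seed = 33, n_genes = 200, n_signal = 20,
                     n_categories = 30, n_enriched = 2)
  eff <- true_effect_map(tr, g)
  b <- simulate_expression_atlas(tr, g, n_samples_per_donor = 60)
  prep <- suppressMessages(preprocess_atlas(b, g, n_regions = 10))
  op <- suppressMessages(sphere_operator(g, prep$samples, radius = 3))
  expr <- prep$expr[op$kept, , drop = FALSE]
  sc <- gene_scores(expr, as.numeric(op$A %*% mask_values(eff)))

  sets <- simulate_category_sets(tr, size_range = c(20, 60),
                                 n_undersized = 3)
  sets_f <- suppressMessages(filter_categories(sets, colnames(expr)))
  expect_true(all(lengths(sets_f) >= 10 & lengths(sets_f) <= 200))
  expect_false(any(startsWith(names(sets_f), "SMALL")))

  ens <- make_surrogates(mask_values(eff), n = 120, seed = 3, grid = g)
  # an exact duplicate category must get an identical p
  sets_f$DUP <- sets_f[[1]]
  res <- gcea(sc, sets_f, expr, op$A, ens)
  expect_equal(res$p[res$id == "DUP"], res$p[1])
  expect_equal(res$score[res$id == "DUP"], res$score[1])
  # category score equals the mean of member gene scores
  for (i in c(1, 5)) {
    expect_equal(res$score[i], mean(sc[sets_f[[res$id[i]]]]),
                 tolerance = 1e-12)
  }
  # p bounded below by 1/(N+1), never zero
  expect_true(all(res$p >= 1 / 121))
  expect_true(all(res$p <= 1))
  # planted enriched categories surface with positive direction
  planted <- res[res$id %in% tr$enriched_categories, ]
  expect_true(all(planted$significant & planted$direction == "above"))
  expect_error(gcea(sc, sets_f, expr, op$A,
                    structure(list(maps = ens$maps[, 1:10]),
                              class = "surrogate_ensemble")),
               "minimum")
})

test_that("the category null is specific to member co-expression", {
  # two categories of equal size: one of near-duplicate genes, one of
  # independent genes; the coherent category must get the wider null
  g <- test_grid(8)
  set.seed(9)
  nvox <- sum(g$mask)
  ns <- 120
  mask_idx <- which(g$mask)
  samples <- as.data.frame(voxel_to_world(
    g, arrayInd(sample(mask_idx, ns), g$dims) - 1L))
  names(samples) <- c("x", "y", "z")
  op <- sphere_operator(g, samples, radius = 3)
  ns_k <- sum(op$kept)
  shared <- rnorm(ns_k)
  coherent <- vapply(1:12, function(i) shared + rnorm(ns_k, sd = 0.05),
                     numeric(ns_k))
  indep <- matrix(rnorm(ns_k * 12), ns_k)
  expr <- cbind(coherent, indep)
  colnames(expr) <- c(sprintf("C%02d", 1:12), sprintf("I%02d", 1:12))
  v <- mask_values(smooth_field(g, 15, seed = 10))
  sc <- gene_scores(expr, as.numeric(op$A %*% v))
  ens <- make_surrogates(v, n = 150, seed = 11, grid = g)
  sets <- list(coherent = colnames(expr)[1:12],
               independent = colnames(expr)[13:24])
  res <- gcea(sc, sets, expr, op$A, ens, min_ensemble = 100)
  expect_gt(res$null_sd[res$id == "coherent"],
            2 * res$null_sd[res$id == "independent"])
})
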