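# Expression-atlas preprocessing: intensity filter, RNA-seq-guided probe
# selection, scaled robust sigmoid normalization, differential stability
# and mask restriction.

make_bundle <- function(expr, above = NULL, annotation = NULL,
                        rnaseq = NULL, samples = NULL) {
  if (is.null(above)) above <- matrix(TRUE, nrow(expr), ncol(expr),
                                      dimnames = dimnames(expr))
  structure(list(expr = expr, above_background = above,
                 annotation = annotation, rnaseq = rnaseq,
                 samples = samples), class = "atlas_bundle")
}

test_that("intensity filter applies the 50% above-background rule", {
  expr <- matrix(rnorm(300), 3, 100,
                 dimnames = list(c("P1", "P2", "P3"), NULL))
  above <- rbind(P1 = rep(c(TRUE, FALSE), c(49, 51)),
                 P2 = rep(c(TRUE, FALSE), c(50, 50)),
                 P3 = rep(TRUE, 100))
  ann <- data.frame(probe_id = c("P1", "P2", "P3"),
                    gene = c("G1", "G1", "G2"))
  b <- make_bundle(expr, above, ann)
  f <- suppressMessages(filter_probes_by_intensity(b))
  expect_identical(rownames(f$expr), c("P2", "P3"))  # 49% removed
  f0 <- suppressMessages(filter_probes_by_intensity(b, min_fraction = 0))
  expect_identical(nrow(f0$expr), 3L)
})

test_that("probe selection keeps the max-r probe and drops r < 0.2", {
  set.seed(4)
  n <- 60
  ref <- rnorm(n)
  mix <- function(r) r * ref + sqrt(1 - r^2) * rnorm(n)
  expr <- rbind(PA1 = mix(0.1), PA2 = mix(0.6), PA3 = mix(0.9),
                PB1 = 0.19 * ref + sqrt(1 - 0.19^2) * rnorm(n),
                PC1 = ref)
  colnames(expr) <- paste0("S", 1:n)
  ann <- data.frame(probe_id = rownames(expr),
                    gene = c("GA", "GA", "GA", "GB", "GC"))
  rna <- rbind(GA = ref, GB = ref, GC = ref)
  colnames(rna) <- colnames(expr)
  # force the low-r probe below threshold regardless of sampling noise
  expr["PB1", ] <- 0.1 * ref + rnorm(n, sd = 2)
  b <- make_bundle(expr, annotation = ann, rnaseq = rna)
  sel <- suppressMessages(select_probe_per_gene(b))
  expect_identical(sel$probe_map$probe_id[sel$probe_map$gene == "GA"],
                   "PA3")
  expect_false("GB" %in% sel$probe_map$gene)
  expect_equal(sel$probe_map$r[sel$probe_map$gene == "GC"], 1)
  # without RNA-seq the fallback is loud
  b2 <- make_bundle(expr, annotation = ann)
  b2$rnaseq <- NULL
  expect_warning(sel2 <- suppressMessages(select_probe_per_gene(b2)),
                 "RNA-seq")
  expect_identical(sort(unique(sel2$probe_map$gene)),
                   c("GA", "GB", "GC"))
})

test_that("scaled robust sigmoid is rank-preserving, bounded and matches
          the direct formula", {
  # direct arithmetic oracle for an outlier-bearing vector
  x <- c(0, 1, 2, 3, 100)
  iqr <- IQR(x)
  y <- 1 / (1 + exp(-(x - median(x)) / (iqr / 1.35)))
  expected <- (y - min(y)) / (max(y) - min(y))
  expect_equal(srs(x), expected, tolerance = 1e-14)
  expect_true(all(srs(x) >= 0 & srs(x) <= 1))
  # outlier does not saturate the neighbors' spacing
  expect_gt(min(diff(srs(x)[1:4])), 0.01)

  # symmetric input maps symmetrically around 0.5 before rescale
  xs <- c(-2, -1, 0, 1, 2)
  ys <- srs(xs)
  expect_equal(ys + rev(ys), rep(1, 5), tolerance = 1e-12)

  # any monotone transform with the same ranks gives the same ranks out
  set.seed(5)
  a <- rnorm(50)
  expect_identical(rank(srs(a)), rank(srs(exp(a))))
  expect_identical(rank(srs(a)), rank(a))

  expect_message(y0 <- srs(rep(3, 10)), "IQR")
  expect_equal(y0, rep(0.5, 10))

  m <- matrix(rnorm(200), 10, 20)
  nm <- srs_normalize(m)
  expect_true(all(nm >= 0 & nm <= 1))
  expect_false(anyNA(nm))
})

test_that("differential stability orders stable genes above noise and
          retains the exact top fraction", {
  set.seed(6)
  donors <- rep(paste0("D", 1:6), each = 30)
  regions <- rep(1:30, times = 6)
  profile <- rnorm(30)
  stable <- profile[regions] # identical regional profile in all donors
  noisy <- rnorm(180)
  expr <- cbind(G_stable = stable, G_noise = noisy)
  ds <- differential_stability(expr, donors, regions)
  expect_equal(unname(ds["G_stable"]), 1, tolerance = 1e-12)
  expect_lt(abs(ds["G_noise"]), 0.4)
  expect_gt(ds["G_stable"], ds["G_noise"])
  # Spearman flavor: invariant to per-donor monotone transforms
  expr_t <- expr
  expr_t[donors == "D1", ] <- exp(expr_t[donors == "D1", ])
  expect_equal(differential_stability(expr_t, donors, regions), ds,
               tolerance = 1e-12)

  # top-50% of a 5,013-gene vector retains exactly ceiling(G/2)
  dsv <- stats::setNames(runif(5013), sprintf("g%04d", 1:5013))
  expect_length(filter_top_fraction(dsv, 0.5), 2507)
  expect_length(filter_top_fraction(dsv, 0.4), ceiling(0.4 * 5013))
  expect_length(filter_top_fraction(dsv, 0.6), ceiling(0.6 * 5013))
})

test_that("mask restriction drops exactly the planted outside samples", {
  g <- test_grid(8)
  tr <- ground_truth(seed = 14, n_genes = 40, n_signal = 4)
  b <- simulate_expression_atlas(tr, g, n_samples_per_donor = 30,
                                 frac_outside = 0.3)
  expr <- t(b$expr)
  res <- suppressMessages(restrict_to_mask(expr, b$samples, g))
  expect_identical(nrow(res$expr), sum(b$in_mask_truth))
  expect_identical(res$samples$sample_id,
                   b$samples$sample_id[b$in_mask_truth])
  # mask = everything keeps every in-grid sample
  b_in <- simulate_expression_atlas(tr, g, n_samples_per_donor = 30)
  g_all <- make_grid(8)
  res2 <- suppressMessages(restrict_to_mask(t(b_in$expr), b_in$samples,
                                            g_all))
  expect_identical(nrow(res2$expr), nrow(b_in$samples))
  # all samples outside is an error
  g_far <- set_mask(g, array(
    seq_len(prod(g$dims)) == which(g$mask)[1], g$dims))
  far_samples <- b$samples
  far_samples$x <- far_samples$x + 500
  expect_error(restrict_to_mask(expr, far_samples, g_far), "outside")
})

test_that("the preprocessing chain is reproducible and bounded", {
  g <- test_grid(8)
  tr <- ground_truth(seed = 15, n_genes = 80, n_signal = 8)
  b <- simulate_expression_atlas(tr, g, n_samples_per_donor = 40)
  p1 <- suppressMessages(preprocess_atlas(b, g, n_regions = 10))
  p2 <- suppressMessages(preprocess_atlas(b, g, n_regions = 10))
  expect_identical(p1$expr, p2$expr)
  expect_false(anyNA(p1$expr))
  expect_true(all(p1$expr >= 0 & p1$expr <= 1))
  expect_length(p1$ds, ceiling(0.5 * nrow(p1$probe_map)))
  # atlas bundle round-trips through its TSV representation
  dir <- tempfile()
  write_atlas_bundle(b, dir)
  b2 <- read_atlas_bundle(dir)
  expect_equal(b2$expr, b$expr, tolerance = 1e-12)
  expect_identical(b2$above_background, b$above_background)
  expect_equal(b2$rnaseq, b$rnaseq, tolerance = 1e-12)
  # left-hemisphere restriction drops x > 0 samples first
  p3 <- suppressMessages(preprocess_atlas(b, g, n_regions = 10,
                                          left_only = TRUE))
  expect_true(all(p3$samples$x <= 0))
})
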