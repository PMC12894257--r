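# Linking the meta-analytic map to gene expression: sphere sampling at
# tissue-sample locations, per-gene spatial correlation "gene scores",
# variogram-matched surrogate maps, and ensemble-based gene-category
# enrichment (GCEA) against spatially constrained nulls.

#' Sphere-sampling operator for tissue-sample locations
#'
#' For each sample, the in-mask voxels whose centers lie within `radius`
#' of the sample's MNI coordinates. Returned as a sparse row-normalized
#' averaging matrix so an ensemble of maps can be sampled by one product.
#' Samples with no in-mask voxel in reach are dropped (logged).
#'
#' @param grid a `volume_grid`.
#' @param samples data.frame with x, y, z (MNI mm).
#' @param radius sphere radius in mm (default 3).
#' @return list: `A` (kept-samples x in-mask-voxels sparse matrix),
#'   `kept` (logical per input sample).
#' @export
sphere_operator <- function(grid, samples, radius = 3) {
  stopifnot(radius > 0)
  mask_idx <- which(grid$mask)
  sxyz <- as.matrix(samples[, c("x", "y", "z")])
  # candidate voxel offsets within the sphere around the containing voxel
  noff <- ceiling(radius / grid$voxel_size) + 1L
  off <- as.matrix(expand.grid(-noff[1]:noff[1], -noff[2]:noff[2],
                               -noff[3]:noff[3]))
  d1 <- grid$dims[1]; d2 <- grid$dims[2]; d3 <- grid$dims[3]
  base_ijk <- round(world_to_voxel(grid, sxyz))
  rows <- list(); cols <- list()
  for (s in seq_len(nrow(sxyz))) {
    i <- off[, 1] + base_ijk[s, 1]
    j <- off[, 2] + base_ijk[s, 2]
    k <- off[, 3] + base_ijk[s, 3]
    ok <- i >= 0 & i < d1 & j >= 0 & j < d2 & k >= 0 & k < d3
    cand <- cbind(i[ok], j[ok], k[ok])
    ctr <- voxel_to_world(grid, cand)
    within <- sqrt(rowSums(sweep(ctr, 2L, sxyz[s, ])^2)) <= radius
    lin <- 1L + cand[within, 1] + d1 * (cand[within, 2] +
                                          d2 * cand[within, 3])
    lin <- lin[grid$mask[lin]]
    if (length(lin)) {
      rows[[s]] <- rep.int(s, length(lin))
      cols[[s]] <- match(lin, mask_idx)
    }
  }
  kept_rows <- which(lengths(rows) > 0)
  if (!length(kept_rows)) stop("no sample has in-mask voxels within radius")
  if (length(kept_rows) < nrow(sxyz)) {
    message(sprintf("sphere sampling: dropped %d/%d samples with no in-mask voxel in reach",
                    nrow(sxyz) - length(kept_rows), nrow(sxyz)))
  }
  ri <- unlist(rows[kept_rows])
  ri <- match(ri, kept_rows)
  A <- Matrix::sparseMatrix(i = ri, j = unlist(cols[kept_rows]),
                            x = 1, dims = c(length(kept_rows),
                                            length(mask_idx)))
  A <- A / Matrix::rowSums(A)
  kept <- seq_len(nrow(sxyz)) %in% kept_rows
  list(A = A, kept = kept)
}

#' Mean map value in spheres around tissue samples
#'
#' @param map a `stat_map`.
#' @param samples data.frame with x, y, z.
#' @param radius sphere radius in mm (default 3).
#' @return list: `values` (mean in-sphere map value per kept sample),
#'   `kept` (logical per input sample).
#' @export
sphere_sample <- function(map, samples, radius = 3) {
  op <- sphere_operator(map$grid, samples, radius)
  list(values = as.numeric(op$A %*% mask_values(map)), kept = op$kept)
}

#' Per-gene spatial correlation scores
#'
#' Pearson correlation between each gene's expression profile across
#' tissue samples and the sphere-sampled map values at those samples.
#' Constant-expression genes score 0 with a warning.
#'
#' @param expr sample x gene matrix (rows aligned with `sphere_values`).
#' @param sphere_values numeric vector, one value per sample row.
#' @return named numeric vector of gene scores in [-1, 1].
#' @export
gene_scores <- function(expr, sphere_values) {
  if (nrow(expr) != length(sphere_values)) {
    stop("expression rows and sphere values are not aligned")
  }
  if (nrow(expr) < 3L) stop("need at least 3 samples for gene scores")
  sds <- apply(expr, 2L, stats::sd)
  r <- suppressWarnings(as.numeric(stats::cor(expr, sphere_values)))
  if (any(sds == 0)) {
    warning(sprintf("%d constant-expression gene(s) scored 0",
                    sum(sds == 0)))
    r[sds == 0] <- 0
  }
  names(r) <- colnames(expr)
  r
}

# Empirical variogram over a fixed set of voxel pairs.
# pairs: list(i, j, bin, nbins); returns mean semivariance per bin.
pair_variogram <- function(values, pairs) {
  sv <- 0.5 * (values[pairs$i] - values[pairs$j])^2
  sums <- numeric(pairs$nbins)
  agg <- rowsum(sv, pairs$bin)
  sums[as.integer(rownames(agg))] <- agg
  sums / tabulate(pairs$bin, pairs$nbins)
}

# Separable 3D Gaussian smoothing: one small dense kernel matrix per axis.
gauss_kernels <- function(grid, scale_mm) {
  lapply(1:3, function(ax) {
    n <- grid$dims[ax]
    x <- (seq_len(n) - 1) * grid$voxel_size[ax]
    exp(-outer(x, x, `-`)^2 / (2 * scale_mm^2))
  })
}

smooth3d <- function(arr, kerns) {
  d <- dim(arr)
  arr <- array(kerns[[1]] %*% matrix(arr, d[1], d[2] * d[3]), d)
  ap <- aperm(arr, c(2, 1, 3))
  ap <- array(kerns[[2]] %*% matrix(ap, d[2], d[1] * d[3]),
              c(d[2], d[1], d[3]))
  arr <- aperm(ap, c(2, 1, 3))
  ap <- aperm(arr, c(3, 1, 2))
  ap <- array(kerns[[3]] %*% matrix(ap, d[3], d[1] * d[2]),
              c(d[3], d[1], d[2]))
  aperm(ap, c(2, 3, 1))
}

# Mask-normalized smoothing operator factory: returns a function mapping
# in-mask values to in-mask smoothed values at the given scale.
masked_smoother <- function(grid, scale_mm) {
  kerns <- gauss_kernels(grid, scale_mm)
  mask_arr <- array(0, dim = grid$dims)
  mask_arr[grid$mask] <- 1
  denom <- smooth3d(mask_arr, kerns)[grid$mask]
  template <- array(0, dim = grid$dims)
  function(v) {
    template[grid$mask] <- v
    smooth3d(template, kerns)[grid$mask] / denom
  }
}

#' Variogram-matched surrogate maps
#'
#' Generates maps that randomize the input's topography while preserving
#' its value distribution and spatial autocorrelation, in the spirit of
#' spatial-lag surrogate generators. Each surrogate is a nonnegative
#' mixture of independent permutations of the map smoothed at several
#' candidate length scales plus a white-noise nugget; because the
#' components are independent their variograms add, so the mixture
#' weights are fit by nonnegative least squares against the empirical
#' variogram over distance bins, matching multi-scale autocorrelation
#' that no single smoothing scale can reproduce. The surrogate is then
#' (optionally) rank-remapped to the original value distribution.
#'
#' @param values numeric vector of in-mask map values.
#' @param coords matching n x 3 matrix of voxel-center coordinates (mm);
#'   ignored when `grid` is given.
#' @param n number of surrogate maps.
#' @param seed RNG seed; the ensemble is deterministic per (seed, index).
#' @param nbins variogram distance bins (default 25, equal-count).
#' @param knn neighbors used for kernel smoothing when no grid is
#'   available (default 50).
#' @param n_scales candidate smoothing length scales (default 8).
#' @param n_vario_sub voxels subsampled for the variogram (default 300).
#' @param resample rank-remap surrogates to the original values (default
#'   TRUE).
#' @param grid optional `volume_grid` the values live on; enables fast
#'   separable lattice smoothing (preferred for voxel maps).
#' @return a `surrogate_ensemble`: `maps` (n_voxels x n matrix), the
#'   empirical variogram (`bins`, `gamma`), and the generator parameters.
#' @export
make_surrogates <- function(values, coords = NULL, n = 1000, seed = 1,
                            nbins = 25, knn = 50, n_scales = 8,
                            n_vario_sub = 300, resample = TRUE,
                            grid = NULL) {
  nv <- length(values)
  if (!is.null(grid)) {
    stopifnot(sum(grid$mask) == nv)
    coords <- voxel_centers(grid)[which(grid$mask), , drop = FALSE]
  }
  stopifnot(nv >= 100, nrow(coords) == nv)
  set.seed(seed)

  if (is.null(grid)) {
    # k-nearest-neighbor table, chunked to bound memory
    knn <- min(knn, nv - 1L)
    nn_idx <- matrix(0L, nv, knn)
    nn_dist <- matrix(0, nv, knn)
    chunk <- max(1L, floor(2e7 / nv))
    sq <- rowSums(coords^2)
    for (start in seq(1L, nv, by = chunk)) {
      idx <- start:min(nv, start + chunk - 1L)
      d2 <- outer(sq[idx], sq, `+`) - 2 * coords[idx, , drop = FALSE] %*%
        t(coords)
      for (r in seq_along(idx)) {
        d2[r, idx[r]] <- Inf
        o <- order(d2[r, ])[seq_len(knn)]
        nn_idx[idx[r], ] <- o
        nn_dist[idx[r], ] <- sqrt(pmax(d2[r, o], 0))
      }
    }
    if (max(nn_dist) <= 0) {
      stop("degenerate coordinates: all points coincide")
    }
    scales <- exp(seq(log(stats::median(nn_dist[, 1])),
                      log(max(nn_dist) * 2), length.out = n_scales))
    smoothers <- lapply(scales, function(s) {
      w <- exp(-nn_dist / s)
      w <- w / rowSums(w)
      sm <- Matrix::sparseMatrix(i = rep(seq_len(nv), knn),
                                 j = as.vector(nn_idx),
                                 x = as.vector(w), dims = c(nv, nv))
      function(v) as.numeric(sm %*% v)
    })
  } else {
    # lattice smoothing: candidate scales span voxel size to a quarter of
    # the mask extent
    extent <- max(apply(coords, 2L, function(x) diff(range(x))))
    scales <- exp(seq(log(min(grid$voxel_size) / 2), log(extent / 4),
                      length.out = n_scales))
    smoothers <- lapply(scales, function(s) masked_smoother(grid, s))
  }

  # fixed voxel-pair subsample for all variogram evaluations
  sub <- sort(sample(nv, min(n_vario_sub, nv)))
  pr <- t(utils::combn(sub, 2L))
  pd <- sqrt(rowSums((coords[pr[, 1], ] - coords[pr[, 2], ])^2))
  dmax <- stats::quantile(pd, 0.5, names = FALSE)
  keep <- pd <= dmax
  pr <- pr[keep, , drop = FALSE]
  pd <- pd[keep]
  # equal-count distance bins so no bin is empty
  brks <- unique(stats::quantile(pd, seq(0, 1, length.out = nbins + 1L),
                                 names = FALSE))
  nbins <- length(brks) - 1L
  bin <- pmax(1L, pmin(nbins, findInterval(pd, brks,
                                           rightmost.closed = TRUE)))
  pairs <- list(i = pr[, 1], j = pr[, 2], bin = bin, nbins = nbins)
  gamma_emp <- pair_variogram(values, pairs)

  maps <- matrix(0, nv, n)
  sorted_vals <- sort(values)
  mu <- mean(values)
  sdv <- stats::sd(values)
  n_comp <- length(smoothers) + 1L
  for (b in seq_len(n)) {
    comps <- matrix(0, nv, n_comp)
    gmat <- matrix(0, length(gamma_emp), n_comp)
    for (si in seq_along(smoothers)) {
      sm <- smoothers[[si]](sample(values))
      s <- stats::sd(sm)
      if (s > 0) sm <- sm / s
      comps[, si] <- sm
      gmat[, si] <- pair_variogram(sm, pairs)
    }
    comps[, n_comp] <- stats::rnorm(nv)
    gmat[, n_comp] <- pair_variogram(comps[, n_comp], pairs)
    w <- pracma::lsqnonneg(gmat, gamma_emp)$x
    surr <- as.numeric(comps %*% sqrt(w))
    if (resample) {
      surr <- sorted_vals[rank(surr, ties.method = "first")]
    } else {
      surr <- mu + sdv * (surr - mean(surr)) / stats::sd(surr)
    }
    maps[, b] <- surr
  }
  structure(list(maps = maps, bins = 0.5 * (brks[-1] + brks[-(nbins + 1)]),
                 gamma = gamma_emp, pairs = pairs, seed = seed,
                 scales = scales, resample = resample),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d surrogates x %d voxels (seed %d)\n",
              ncol(x$maps), nrow(x$maps), x$seed))
  invisible(x)
}

#' Filter annotation categories by retained-gene count
#' @param sets named list of gene-id vectors.
#' @param genes retained gene universe.
#' @param min_size,max_size inclusive annotation-count bounds (defaults
#'   10 and 200).
#' @return the sets intersected with `genes`, size-filtered.
#' @export
filter_categories <- function(sets, genes, min_size = 10, max_size = 200) {
  sets <- lapply(sets, intersect, genes)
  n <- lengths(sets)
  message(sprintf("category filter: %d -> %d categories with %d-%d genes",
                  length(sets), sum(n >= min_size & n <= max_size),
                  min_size, max_size))
  sets[n >= min_size & n <= max_size]
}

#' Ensemble-based gene-category enrichment analysis
#'
#' Each category's observed score is the mean gene score of its members.
#' The category-specific null recomputes sphere values and gene scores
#' for every surrogate map and takes the same category means, capturing
#' both the spatial autocorrelation of the map and the co-expression of
#' the category's members. The two-sided p compares the observed score
#' against the null centered on the null mean (gene-score nulls are not
#' mean-zero under spatial autocorrelation), with the add-one permutation
#' convention.
#'
#' @param scores_observed named gene-score vector from [gene_scores()].
#' @param sets category sets, already size-filtered.
#' @param expr sample x gene matrix (the same samples the observed sphere
#'   vector used).
#' @param sphere_op sparse operator from [sphere_operator()] (its `A`).
#' @param ensemble a `surrogate_ensemble` on the same mask.
#' @param alpha two-sided significance threshold (default 0.05).
#' @param min_ensemble refuse smaller ensembles (p resolution); default
#'   100.
#' @return data.frame per category: id, n_genes, score, null_mean,
#'   null_sd, p, direction, significant.
#' @export
gcea <- function(scores_observed, sets, expr, sphere_op, ensemble,
                 alpha = 0.05, min_ensemble = 100) {
  n_surr <- ncol(ensemble$maps)
  if (n_surr < min_ensemble) {
    stop(sprintf("ensemble of %d surrogates is below the minimum of %d",
                 n_surr, min_ensemble))
  }
  genes <- colnames(expr)
  memb <- Matrix::sparseMatrix(
    i = rep(seq_along(sets), lengths(sets)),
    j = match(unlist(sets), genes),
    x = 1, dims = c(length(sets), length(genes)))
  sizes <- Matrix::rowSums(memb)
  obs_cat <- as.numeric(memb %*% scores_observed[genes]) / sizes

  # surrogate gene scores in one pass: sphere-sample all maps, then
  # column-correlate expression against every surrogate sphere vector
  sphere_null <- as.matrix(sphere_op %*% ensemble$maps)
  score_null <- suppressWarnings(stats::cor(expr, sphere_null))
  score_null[is.na(score_null)] <- 0
  cat_null <- as.matrix(memb %*% score_null) / sizes

  null_mean <- rowMeans(cat_null)
  null_sd <- apply(cat_null, 1L, stats::sd)
  dev_obs <- abs(obs_cat - null_mean)
  p <- vapply(seq_along(sets), function(i) {
    (1 + sum(abs(cat_null[i, ] - null_mean[i]) >= dev_obs[i])) /
      (n_surr + 1)
  }, numeric(1))
  data.frame(
    id = names(sets), n_genes = as.integer(sizes), score = obs_cat,
    null_mean = null_mean, null_sd = null_sd, p = p,
    direction = ifelse(obs_cat >= null_mean, "above", "below"),
    significant = p < alpha, row.names = NULL)
}
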