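# Coordinate-based meta-analysis: per-study effect-map reconstruction from
# reported peaks, random-effects pooling, permutation-null thresholding,
# and robustness diagnostics (jackknife, heterogeneity, Egger/funnel).

#' Effect size and its variance from a peak t-value
#'
#' d = J * t * sqrt(1/n1 + 1/n2) with the Hedges small-sample correction
#' J = 1 - 3/(4*df - 1); var(d) = (n1+n2)/(n1*n2) + d^2 / (2*(n1+n2)).
#' @param t peak t-value.
#' @param n1,n2 group sizes.
#' @export
peak_d <- function(t, n1, n2) {
  j <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  j * t * sqrt(1 / n1 + 1 / n2)
}

#' @rdname peak_d
#' @param d effect size.
#' @export
d_variance <- function(d, n1, n2) {
  (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
}

# Precompute the Gaussian kernel footprint: 0-based ijk offsets within
# 2*FWHM of a voxel center and their kernel weights (1 at distance 0,
# 0.5 at FWHM/2 by definition of full width at half maximum).
kernel_footprint <- function(grid, fwhm) {
  stopifnot(fwhm > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r_max <- 2 * fwhm
  noff <- ceiling(r_max / grid$voxel_size)
  off <- as.matrix(expand.grid(i = -noff[1]:noff[1],
                               j = -noff[2]:noff[2],
                               k = -noff[3]:noff[3]))
  dmm <- sweep(off, 2L, grid$voxel_size, `*`)
  r <- sqrt(rowSums(dmm^2))
  keep <- r <= r_max
  list(offsets = off[keep, , drop = FALSE],
       weights = exp(-r[keep]^2 / (2 * sigma^2)))
}

#' Reconstruct a study's signed effect-size map from its peaks
#'
#' Each peak's t is converted to d and spread with an isotropic Gaussian
#' kernel of the stated FWHM, truncated at 2*FWHM. Where kernels overlap,
#' the contribution with the larger magnitude wins (signed maximum
#' magnitude), preventing effect inflation at adjacent peaks. Voxels no
#' kernel reaches carry d = 0 (a null study everywhere it reported
#' nothing). The variance map applies the standard d-variance formula
#' voxelwise.
#'
#' @param study one element of a `study_set` (id, group sizes, peaks).
#' @param grid a `volume_grid`.
#' @param fwhm kernel full width at half maximum in mm (field default 20).
#' @param footprint optional precomputed [kernel_footprint()] for reuse.
#' @param peak_idx optional replacement 1-based voxel linear indices for
#'   the peaks (used by the relocation null).
#' @return list with in-mask numeric vectors `d` and `v`.
#' @export
reconstruct_effect_map <- function(study, grid, fwhm = 20, footprint = NULL,
                                   peak_idx = NULL) {
  if (is.null(footprint)) footprint <- kernel_footprint(grid, fwhm)
  nvox <- prod(grid$dims)
  acc <- numeric(nvox)
  if (nrow(study$peaks) == 0L) {
    message(sprintf("study '%s' has no peaks: flat zero map", study$id))
  } else {
    if (is.null(peak_idx)) {
      peak_idx <- nearest_voxel(grid, as.matrix(study$peaks[, c("x", "y", "z")]))
    }
    dvals <- peak_d(study$peaks$t, study$n_patients, study$n_controls)
    pk_ijk <- arrayInd(peak_idx, grid$dims) - 1L
    d1 <- grid$dims[1]; d2 <- grid$dims[2]; d3 <- grid$dims[3]
    off <- footprint$offsets
    w <- footprint$weights
    for (p in seq_along(peak_idx)) {
      if (is.na(peak_idx[p])) next
      i <- off[, 1] + pk_ijk[p, 1]
      j <- off[, 2] + pk_ijk[p, 2]
      k <- off[, 3] + pk_ijk[p, 3]
      ok <- i >= 0 & i < d1 & j >= 0 & j < d2 & k >= 0 & k < d3
      lin <- 1L + i[ok] + d1 * (j[ok] + d2 * k[ok])
      contrib <- dvals[p] * w[ok]
      replace <- abs(contrib) > abs(acc[lin])
      acc[lin[replace]] <- contrib[replace]
    }
  }
  d <- acc[grid$mask]
  list(d = d, v = d_variance(d, study$n_patients, study$n_controls))
}

#' DerSimonian-Laird random-effects pooling, voxelwise
#'
#' @param d_mat,v_mat k-study x n-voxel matrices of effects and variances.
#' @return list with per-voxel `mean`, `se`, `z`, `tau2`, `q` (Cochran Q)
#'   and `k` (number of studies).
#' @export
pool_random_effects <- function(d_mat, v_mat) {
  k <- nrow(d_mat)
  if (k < 2L) {
    warning("single study: pooled map degenerates to that study's map")
    return(list(mean = drop(d_mat), se = sqrt(drop(v_mat)),
                z = drop(d_mat) / sqrt(drop(v_mat)),
                tau2 = rep(0, ncol(d_mat)), q = rep(0, ncol(d_mat)), k = k))
  }
  w <- 1 / v_mat
  sw <- colSums(w)
  mu_fixed <- colSums(w * d_mat) / sw
  q <- colSums(w * sweep(d_mat, 2L, mu_fixed)^2)
  c_const <- sw - colSums(w^2) / sw
  tau2 <- pmax(0, (q - (k - 1)) / c_const)
  wstar <- 1 / sweep(v_mat, 2L, tau2, `+`)
  swstar <- colSums(wstar)
  mu <- colSums(wstar * d_mat) / swstar
  se <- 1 / sqrt(swstar)
  list(mean = mu, se = se, z = mu / se, tau2 = tau2, q = q, k = k)
}

#' Reconstruct and pool every study in a study set
#'
#' Stacks per-study reconstructions into k x V matrices and pools them
#' voxelwise with [pool_random_effects()].
#' @param ss a `study_set`.
#' @param grid a `volume_grid`.
#' @param fwhm kernel FWHM in mm.
#' @param footprint optional precomputed [kernel_footprint()].
#' @param peak_idx_list optional per-study replacement peak voxel indices
#'   (used by the relocation null).
#' @return list: `pool` (per-voxel DL fit), `d_mat`, `v_mat`.
#' @export
pool_study_set <- function(ss, grid, fwhm = 20, footprint = NULL,
                           peak_idx_list = NULL) {
  if (is.null(footprint)) footprint <- kernel_footprint(grid, fwhm)
  recs <- lapply(seq_along(ss$studies), function(i) {
    reconstruct_effect_map(ss$studies[[i]], grid, fwhm, footprint,
                           peak_idx = peak_idx_list[[i]])
  })
  d_mat <- do.call(rbind, lapply(recs, `[[`, "d"))
  v_mat <- do.call(rbind, lapply(recs, `[[`, "v"))
  list(pool = pool_random_effects(d_mat, v_mat), d_mat = d_mat,
       v_mat = v_mat)
}

#' Peak-relocation permutation null for the pooled z-map
#'
#' Each null iteration relocates every study's peaks uniformly at random
#' within the analysis mask (keeping their effect sizes), re-reconstructs
#' and re-pools. The pooled |z| values across iterations and voxels form
#' the voxel-level null distribution.
#'
#' @param ss a `study_set`.
#' @param grid a `volume_grid`.
#' @param fwhm kernel FWHM in mm.
#' @param n_null number of relocation iterations (default 200).
#' @param seed RNG seed.
#' @return numeric vector of pooled null |z| values (n_null x n voxels).
#' @export
build_null_ensemble <- function(ss, grid, fwhm = 20, n_null = 200,
                                seed = 1) {
  if (n_null < 1) stop("null ensemble must contain at least one iteration")
  footprint <- kernel_footprint(grid, fwhm)
  mask_idx <- which(grid$mask)
  set.seed(seed)
  out <- vector("list", n_null)
  for (b in seq_len(n_null)) {
    idx_list <- lapply(ss$studies, function(s) {
      sample(mask_idx, nrow(s$peaks), replace = TRUE)
    })
    out[[b]] <- abs(pool_study_set(ss, grid, fwhm, footprint,
                                   peak_idx_list = idx_list)$pool$z)
  }
  unlist(out)
}

# 26-connected components among the given in-grid voxel linear indices.
# Returns a list of integer vectors of linear indices.
connected_components <- function(grid, lin_idx) {
  if (!length(lin_idx)) return(list())
  d1 <- grid$dims[1]; d2 <- grid$dims[2]; d3 <- grid$dims[3]
  ijk <- arrayInd(lin_idx, grid$dims)
  lookup <- integer(prod(grid$dims))
  lookup[lin_idx] <- seq_along(lin_idx)
  noff <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  noff <- noff[rowSums(abs(noff)) > 0, , drop = FALSE]
  visited <- logical(length(lin_idx))
  comps <- list()
  for (s in seq_along(lin_idx)) {
    if (visited[s]) next
    queue <- s
    visited[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, cur)
      ni <- noff[, 1] + ijk[cur, 1]
      nj <- noff[, 2] + ijk[cur, 2]
      nk <- noff[, 3] + ijk[cur, 3]
      ok <- ni >= 1 & ni <= d1 & nj >= 1 & nj <= d2 & nk >= 1 & nk <= d3
      nlin <- ni[ok] + d1 * (nj[ok] - 1L + d2 * (nk[ok] - 1L))
      nb <- lookup[nlin]
      nb <- nb[nb > 0L]
      nb <- nb[!visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- lin_idx[members]
  }
  comps
}

#' Threshold a pooled z-map against the relocation null and extract clusters
#'
#' Voxel p is the empirical upper-tail rank of |z| in the pooled null;
#' suprathreshold voxels (p < voxel_p) are grouped into 26-connected
#' components separately for increases and decreases; clusters must reach
#' the peak-height and extent thresholds.
#'
#' @param z_map in-mask z vector (as from [pool_random_effects()]).
#' @param grid a `volume_grid`.
#' @param null_abs_z pooled null |z| values from [build_null_ensemble()].
#' @param voxel_p voxel-level p threshold (default 0.005).
#' @param peak_z minimum cluster peak |z| (default 1).
#' @param extent minimum cluster size in voxels (default 50).
#' @return data.frame of clusters: x, y, z (the cluster location,
#'   reported as the |z|-weighted center of mass — a more stable
#'   localization estimate than the argmax voxel under peak-coordinate
#'   jitter), px, py, pz (the peak voxel), peak_z, extent, sign, voxel p
#'   at peak; plus attribute "voxels" (list of in-mask linear-index
#'   vectors) and "z_threshold".
#' @export
threshold_and_cluster <- function(z_map, grid, null_abs_z,
                                  voxel_p = 0.005, peak_z = 1,
                                  extent = 50) {
  if (!length(null_abs_z)) stop("empty null ensemble")
  z_thr <- stats::quantile(null_abs_z, 1 - voxel_p, names = FALSE,
                           type = 1)
  mask_idx <- which(grid$mask)
  clusters <- list()
  voxel_lists <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * z_map > z_thr & sgn * z_map >= 0)
    comps <- connected_components(grid, mask_idx[supra])
    for (comp in comps) {
      if (length(comp) < extent) next
      zvals <- z_map[match(comp, mask_idx)]
      pk <- which.max(abs(zvals))
      if (abs(zvals[pk]) < peak_z) next
      pxyz <- voxel_to_world(grid, arrayInd(comp[pk], grid$dims) - 1L)
      all_xyz <- voxel_to_world(grid, arrayInd(comp, grid$dims) - 1L)
      cent <- colSums(all_xyz * abs(zvals)) / sum(abs(zvals))
      p_emp <- (1 + sum(null_abs_z >= abs(zvals[pk]))) /
        (length(null_abs_z) + 1)
      clusters[[length(clusters) + 1L]] <- data.frame(
        x = cent[1], y = cent[2], z = cent[3],
        px = pxyz[1], py = pxyz[2], pz = pxyz[3], peak_z = zvals[pk],
        extent = length(comp), sign = sgn, p = p_emp
      )
      voxel_lists[[length(voxel_lists) + 1L]] <- comp
    }
  }
  out <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               px = numeric(0), py = numeric(0), pz = numeric(0),
               peak_z = numeric(0), extent = integer(0), sign = numeric(0),
               p = numeric(0))
  ord <- order(-abs(out$peak_z))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "voxels") <- voxel_lists[ord]
  attr(out, "z_threshold") <- z_thr
  out
}

#' Jackknife sensitivity of the main clusters
#'
#' Re-pools the meta-analysis leaving each study out in turn and counts,
#' for each main-analysis cluster, the leave-one-out runs that reproduce
#' an overlapping same-sign cluster. Thresholding reuses the main run's
#' null-derived z threshold so that survival reflects the data, not null
#' re-estimation noise.
#'
#' @param ss a `study_set` (>= 3 studies).
#' @param grid,fwhm as in the main analysis.
#' @param clusters result of [threshold_and_cluster()] on the full set.
#' @param null_abs_z the main run's null ensemble values.
#' @param voxel_p,peak_z,extent main-analysis thresholds.
#' @return the cluster table with columns `jk_survived` (count) and
#'   `jackknife` ("k/n" as conventionally reported).
#' @export
jackknife <- function(ss, grid, clusters, null_abs_z, fwhm = 20,
                      voxel_p = 0.005, peak_z = 1, extent = 50) {
  n <- length(ss$studies)
  if (n < 3L) stop("jackknife needs at least 3 studies")
  if (!nrow(clusters)) {
    clusters$jk_survived <- integer(0)
    clusters$jackknife <- character(0)
    return(clusters)
  }
  main_vox <- attr(clusters, "voxels")
  footprint <- kernel_footprint(grid, fwhm)
  survived <- integer(nrow(clusters))
  for (drop_i in seq_len(n)) {
    sub <- ss
    sub$studies <- ss$studies[-drop_i]
    z_sub <- pool_study_set(sub, grid, fwhm, footprint)$pool$z
    cl_sub <- threshold_and_cluster(z_sub, grid, null_abs_z, voxel_p,
                                    peak_z, extent)
    sub_vox <- attr(cl_sub, "voxels")
    for (ci in seq_len(nrow(clusters))) {
      hit <- FALSE
      for (cj in seq_len(nrow(cl_sub))) {
        if (cl_sub$sign[cj] == clusters$sign[ci] &&
            length(intersect(sub_vox[[cj]], main_vox[[ci]])) > 0) {
          hit <- TRUE
          break
        }
      }
      if (hit) survived[ci] <- survived[ci] + 1L
    }
  }
  clusters$jk_survived <- survived
  clusters$jackknife <- sprintf("%d/%d", survived, n)
  clusters
}

#' Between-study heterogeneity map and clusters
#'
#' Cochran Q per voxel against chi-square(k-1), expressed as an equivalent
#' z-score, then thresholded and clustered (conventionally with a smaller
#' extent than the main analysis).
#'
#' @param d_mat,v_mat k x V study effect/variance matrices.
#' @param grid a `volume_grid`.
#' @param p_thr voxel p threshold (default 0.005).
#' @param peak_z minimum peak z (default 1).
#' @param extent minimum cluster extent in voxels (default 10).
#' @return cluster data.frame as in [threshold_and_cluster()] (unsigned),
#'   with attribute "q" holding the per-voxel Q vector.
#' @export
heterogeneity_map <- function(d_mat, v_mat, grid, p_thr = 0.005,
                              peak_z = 1, extent = 10) {
  k <- nrow(d_mat)
  w <- 1 / v_mat
  sw <- colSums(w)
  mu_fixed <- colSums(w * d_mat) / sw
  q <- colSums(w * sweep(d_mat, 2L, mu_fixed)^2)
  p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  zq <- stats::qnorm(p, lower.tail = FALSE)
  mask_idx <- which(grid$mask)
  supra <- which(p < p_thr)
  comps <- connected_components(grid, mask_idx[supra])
  rows <- list()
  vox <- list()
  for (comp in comps) {
    if (length(comp) < extent) next
    zvals <- zq[match(comp, mask_idx)]
    pk <- which.max(zvals)
    if (zvals[pk] < peak_z) next
    xyz <- voxel_to_world(grid, arrayInd(comp[pk], grid$dims) - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      x = xyz[1], y = xyz[2], z = xyz[3], peak_z = zvals[pk],
      extent = length(comp), p = p[match(comp[pk], mask_idx)]
    )
    vox[[length(vox) + 1L]] <- comp
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               peak_z = numeric(0), extent = integer(0), p = numeric(0))
  rownames(out) <- NULL
  attr(out, "voxels") <- vox
  attr(out, "q") <- q
  out
}

#' Egger regression and funnel points at a cluster peak
#'
#' Per-study effect = reconstructed d at the peak voxel, SE = sqrt(v);
#' Egger's test regresses d/SE on 1/SE and tests the intercept (two-sided).
#' Studies whose kernel does not reach the peak (d = 0) do not contribute.
#'
#' @param peak_xyz cluster peak MNI coordinates.
#' @param d_mat,v_mat k x V study matrices (in-mask columns).
#' @param grid a `volume_grid`.
#' @return list with `egger_intercept`, `egger_p` (NA if < 3 contributing
#'   studies) and a `funnel` data.frame (effect, se, precision).
#' @export
egger_and_funnel <- function(peak_xyz, d_mat, v_mat, grid) {
  mask_idx <- which(grid$mask)
  col <- match(nearest_voxel(grid, matrix(peak_xyz, nrow = 1)), mask_idx)
  if (is.na(col)) stop("cluster peak lies outside the analysis mask")
  d <- d_mat[, col]
  se <- sqrt(v_mat[, col])
  keep <- d != 0
  funnel <- data.frame(effect = d[keep], se = se[keep],
                       precision = 1 / se[keep])
  if (sum(keep) < 3L) {
    return(list(egger_intercept = NA_real_, egger_p = NA_real_,
                funnel = funnel))
  }
  fit <- stats::lm(I(d[keep] / se[keep]) ~ I(1 / se[keep]))
  sm <- summary(fit)$coefficients
  list(egger_intercept = sm[1, 1], egger_p = sm[1, 4], funnel = funnel)
}

#' Full coordinate-based meta-analysis
#'
#' Runs reconstruction, pooling, null thresholding, clustering, jackknife,
#' heterogeneity and Egger diagnostics with the field-standard defaults
#' (FWHM 20 mm, voxel p < 0.005, peak z >= 1, extent 50; heterogeneity
#' extent 10).
#'
#' @param ss a `study_set`.
#' @param grid a `volume_grid`.
#' @param fwhm,voxel_p,peak_z,extent,het_extent analysis thresholds.
#' @param n_null relocation-null iterations.
#' @param seed RNG seed for the null ensemble.
#' @param diagnostics run jackknife/Egger (slower) if TRUE.
#' @return a `meta_result`: z `stat_map`, cluster table, heterogeneity
#'   clusters, per-cluster diagnostics, the null z threshold.
#' @export
run_cbma <- function(ss, grid, fwhm = 20, voxel_p = 0.005, peak_z = 1,
                     extent = 50, het_extent = 10, n_null = 200, seed = 1,
                     diagnostics = TRUE) {
  fitted <- pool_study_set(ss, grid, fwhm)
  null_abs_z <- build_null_ensemble(ss, grid, fwhm, n_null = n_null,
                                    seed = seed)
  clusters <- threshold_and_cluster(fitted$pool$z, grid, null_abs_z,
                                    voxel_p, peak_z, extent)
  het <- heterogeneity_map(fitted$d_mat, fitted$v_mat, grid,
                           p_thr = voxel_p, peak_z = peak_z,
                           extent = het_extent)
  diag_rows <- NULL
  if (diagnostics && nrow(clusters)) {
    clusters <- jackknife(ss, grid, clusters, null_abs_z, fwhm, voxel_p,
                          peak_z, extent)
    eg <- lapply(seq_len(nrow(clusters)), function(i) {
      egger_and_funnel(c(clusters$px[i], clusters$py[i], clusters$pz[i]),
                       fitted$d_mat, fitted$v_mat, grid)
    })
    clusters$egger_p <- vapply(eg, `[[`, numeric(1), "egger_p")
    het_vox <- attr(het, "voxels")
    clusters$heterogeneity <- vapply(seq_len(nrow(clusters)), function(i) {
      any(vapply(het_vox, function(hv) {
        length(intersect(hv, attr(clusters, "voxels")[[i]])) > 0
      }, logical(1)))
    }, logical(1))
    diag_rows <- lapply(eg, `[[`, "funnel")
  }
  structure(list(
    z_map = stat_map(grid, fitted$pool$z, kind = "z"),
    mean_map = stat_map(grid, fitted$pool$mean, kind = "d"),
    clusters = clusters,
    heterogeneity_clusters = het,
    funnel = diag_rows,
    z_threshold = attr(clusters, "z_threshold"),
    n_null = n_null
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d cluster(s), |z| threshold %.3f\n",
              nrow(x$clusters), x$z_threshold))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
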