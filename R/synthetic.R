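# Synthetic-data generators. Every pipeline input (peak tables, expression
# atlas, category annotation, scored interaction edges, receptor maps) is
# generated with known ground truth so each analysis stage has a closed
# acceptance surface. All generators are pure functions of (parameters,
# seed).

#' Ground truth for a synthetic dataset
#'
#' @param effect_loci data.frame with columns x, y, z (MNI mm) and d
#'   (signed effect size). Defaults: two loci with |d| = 0.8, one increase
#'   in the right medial temporal region and one decrease in the left
#'   putamen area, inside the default ellipsoid mask.
#' @param n_genes total genes in the synthetic atlas.
#' @param n_signal number of signal genes whose expression tracks the
#'   effect map.
#' @param signal_rho target spatial correlation(s) of signal genes with the
#'   effect map (recycled over signal genes).
#' @param n_categories number of annotation categories; `n_enriched` of
#'   them are planted to be enriched for signal genes.
#' @param n_enriched planted enriched categories.
#' @param n_nodes,n_hubs interaction-network size and planted hub count.
#' @param receptor_rho named vector of target spatial correlations for the
#'   receptor/transporter panel; defaults emulate a nine-system panel with
#'   five truly anticorrelated systems.
#' @param seed master seed; all generators derive their streams from it.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(effect_loci = data.frame(
                           x = c(22, -32), y = c(-2, -6), z = c(-32, -4),
                           d = c(0.8, -0.8)),
                         n_genes = 1000, n_signal = 60, signal_rho = 0.9,
                         n_categories = 120, n_enriched = 5,
                         n_nodes = 100, n_hubs = 10,
                         receptor_rho = c(
                           "5HT4" = -0.38, D1 = -0.35, D2 = -0.36,
                           DAT = -0.32, VAChT = -0.38, GABAa = 0,
                           NMDA = 0, SERT = 0, mGluR5 = 0),
                         seed = 1) {
  stopifnot(all(abs(signal_rho) <= 1), all(abs(receptor_rho) <= 1),
            n_signal <= n_genes, n_hubs < n_nodes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  signal_genes <- genes[seq_len(n_signal)]
  structure(list(
    effect_loci = effect_loci,
    genes = genes,
    signal_genes = signal_genes,
    signal_rho = rep_len(signal_rho, n_signal),
    enriched_categories = sprintf("CAT%03d", seq_len(n_enriched)),
    n_categories = n_categories,
    hub_nodes = sprintf("G%04d", seq_len(n_hubs)),
    n_nodes = n_nodes,
    receptor_rho = receptor_rho,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

# Deterministic per-stage substream seeds below 2^31.
stage_seed <- function(seed, stage) {
  offs <- c(studies = 101L, atlas = 211L, categories = 307L, ppi = 401L,
            receptors = 503L, field = 601L, cbma_null = 701L,
            surrogates = 809L, demo = 907L)
  (as.integer(seed) %% 1000000L) * 1009L + offs[[stage]]
}

#' Serialize / load ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$receptor_rho <- as.list(x$receptor_rho) # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$effect_loci <- as.data.frame(x$effect_loci)
  x$receptor_rho <- unlist(x$receptor_rho)
  structure(x, class = "ground_truth")
}

#' Continuous ground-truth effect map
#'
#' Gaussian bumps (FWHM `fwhm`) at the planted loci on top of a weak
#' smooth background field, the latent alteration pattern that signal
#' genes and receptor maps track. The background emulates the continuous
#' spatial variation of a real meta-analytic map; without it the map is
#' zero almost everywhere and its value distribution is far heavier-
#' tailed than any real statistical brain map. Deterministic given the
#' truth's seed.
#'
#' @param truth a `ground_truth`.
#' @param grid a `volume_grid`.
#' @param fwhm bump full width at half maximum in mm.
#' @param background_sd background amplitude as a fraction of the largest
#'   |d| (default 0.3); 0 gives pure bumps.
#' @param background_scale background correlation length in mm.
#' @return a d-kind `stat_map`.
#' @export
true_effect_map <- function(truth, grid, fwhm = 20, background_sd = 0.3,
                            background_scale = 20) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  xyz <- voxel_centers(grid)
  vals <- numeric(nrow(xyz))
  for (i in seq_len(nrow(truth$effect_loci))) {
    r2 <- rowSums(sweep(xyz, 2L,
                        as.numeric(truth$effect_loci[i, c("x", "y", "z")]))^2)
    vals <- vals + truth$effect_loci$d[i] * exp(-r2 / (2 * sigma^2))
  }
  if (background_sd > 0) {
    bg <- smooth_field(grid, background_scale,
                       seed = stage_seed(truth$seed, "field"))
    amp <- background_sd * max(abs(truth$effect_loci$d))
    vals[grid$mask] <- vals[grid$mask] + amp * mask_values(bg)
  }
  stat_map(grid, vals, kind = "d")
}

#' Spatially autocorrelated standard-normal field
#'
#' White noise smoothed with a separable Gaussian kernel (squared-
#' exponential autocorrelation, length scale in mm) and re-standardized
#' over the mask.
#' @param grid a `volume_grid`.
#' @param scale_mm kernel length scale in mm (default 10).
#' @param seed RNG seed (omit to draw from the current RNG stream).
#' @return a `stat_map` of kind "z".
#' @export
smooth_field <- function(grid, scale_mm = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arr <- array(stats::rnorm(prod(grid$dims)), dim = grid$dims)
  for (ax in 1:3) {
    sig_vox <- scale_mm / grid$voxel_size[ax]
    half <- max(1L, ceiling(3 * sig_vox))
    kern <- exp(-(-half:half)^2 / (2 * sig_vox^2))
    kern <- kern / sum(kern)
    arr <- apply(arr, setdiff(1:3, ax), function(v) {
      stats::filter(c(rev(v[seq_len(half)]), v, rev(v[length(v) -
        seq_len(half) + 1L])), kern, sides = 2)[half + seq_along(v)]
    })
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  v <- arr[grid$mask]
  arr[grid$mask] <- (v - mean(v)) / stats::sd(v)
  stat_map(grid, as.numeric(arr), kind = "z")
}

#' Simulate a set of VBM studies reporting peak coordinates
#'
#' Each study reports each planted locus with probability 1 - miss_rate at
#' Gaussian-jittered coordinates; the reported t is drawn consistent with
#' the planted d and the study's group sizes (observed d ~ N(d, var(d)),
#' t = d * sqrt(n1 n2 / (n1 + n2))). Optional spurious peaks are placed
#' uniformly in the mask.
#'
#' @param truth a `ground_truth`.
#' @param n_studies number of studies (default 15, the meta-analytic scale
#'   emulated throughout).
#' @param n_range inclusive range for both group sizes (default 13..67).
#' @param peak_noise_sd isotropic coordinate jitter sd in mm (default 8).
#' @param miss_rate per-study probability of not reporting a locus.
#' @param spurious_rate expected number of spurious peaks per study
#'   (Poisson); needs `grid` when positive.
#' @param grid optional `volume_grid` for spurious-peak placement.
#' @param seed RNG seed (defaults to the truth's studies substream).
#' @return a `study_set`.
#' @export
simulate_study_set <- function(truth, n_studies = 15, n_range = c(13, 67),
                               peak_noise_sd = 8, miss_rate = 0.1,
                               spurious_rate = 0, grid = NULL,
                               seed = stage_seed(truth$seed, "studies")) {
  stopifnot(n_studies >= 1)
  if (spurious_rate > 0 && is.null(grid)) {
    stop("spurious peaks need a grid to be placed in")
  }
  set.seed(seed)
  loci <- truth$effect_loci
  rows <- list()
  for (s in seq_len(n_studies)) {
    n1 <- sample(n_range[1]:n_range[2], 1L)
    n2 <- sample(n_range[1]:n_range[2], 1L)
    for (i in seq_len(nrow(loci))) {
      if (stats::runif(1) < miss_rate) next
      xyz <- as.numeric(loci[i, c("x", "y", "z")]) +
        stats::rnorm(3, sd = peak_noise_sd)
      d_i <- loci$d[i]
      d_obs <- stats::rnorm(1, d_i, sqrt(d_variance(d_i, n1, n2)))
      tval <- d_obs * sqrt(n1 * n2 / (n1 + n2))
      rows[[length(rows) + 1L]] <- data.frame(
        study = sprintf("S%02d", s), n_patients = n1, n_controls = n2,
        x = xyz[1], y = xyz[2], z = xyz[3], stat = tval, stat_kind = "t",
        space = "MNI",
        sign = if (tval >= 0) "increase" else "decrease")
    }
    if (spurious_rate > 0) {
      n_sp <- stats::rpois(1, spurious_rate)
      if (n_sp > 0) {
        idx <- sample(which(grid$mask), n_sp, replace = TRUE)
        xyzs <- voxel_to_world(grid, arrayInd(idx, grid$dims) - 1L)
        for (q in seq_len(n_sp)) {
          d_obs <- stats::rnorm(1, 0, sqrt(d_variance(0.3, n1, n2)))
          tval <- d_obs * sqrt(n1 * n2 / (n1 + n2))
          rows[[length(rows) + 1L]] <- data.frame(
            study = sprintf("S%02d", s), n_patients = n1, n_controls = n2,
            x = xyzs[q, 1], y = xyzs[q, 2], z = xyzs[q, 3], stat = tval,
            stat_kind = "t", space = "MNI",
            sign = if (tval >= 0) "increase" else "decrease")
        }
      }
    }
  }
  study_set_from_df(do.call(rbind, rows))
}

#' Simulate a donor-based expression atlas bundle
#'
#' Emulates the structure of a post-mortem microarray atlas: spatially
#' localized tissue samples from several donors, a probe-by-sample matrix
#' with multiple probes per gene (one faithful, others degraded or below
#' background), background-intensity flags, and an RNA-seq reference
#' matrix correlated with the faithful probes.
#'
#' Signal genes' expression mixes the standardized effect-map value at
#' the sample locations with an independent spatially autocorrelated
#' field; the mixing weight is calibrated (including the probe
#' measurement noise) so the population spatial correlation of the
#' faithful probe with the effect map equals rho. Null genes are
#' spatially autocorrelated noise: a fraction share their spatial profile
#' across donors (donor-stable, high differential stability), the rest
#' have independent profiles per donor (donor-unstable).
#'
#' @param truth a `ground_truth`.
#' @param grid a `volume_grid`.
#' @param effect_map the latent effect `stat_map` genes track (defaults to
#'   [true_effect_map()]).
#' @param n_donors number of donors (default 6; the first `n_rh_donors`
#'   also sample the right hemisphere).
#' @param n_rh_donors donors with right-hemisphere samples (default 2).
#' @param n_samples_per_donor tissue samples per donor.
#' @param n_probes_per_gene probes per gene (>= 1; probe 1 is faithful).
#' @param noise_sd measurement noise added to each probe.
#' @param frac_unstable fraction of null genes with donor-specific
#'   spatial profiles.
#' @param frac_low_intensity fraction of degraded probes planted to fail
#'   the 50% above-background rule.
#' @param frac_bad_probe fraction of degraded probes that are pure noise
#'   (RNA-seq correlation near 0, below the r >= 0.2 selection rule).
#' @param autocorr_scale spatial scale (mm) of null-gene fields.
#' @param frac_outside fraction of samples deliberately placed outside the
#'   mask (exercises gray-matter restriction).
#' @param seed RNG seed.
#' @return an `atlas_bundle` list: samples, expr (probe x sample),
#'   annotation, above_background, rnaseq (gene x sample), in_mask_truth.
#' @export
simulate_expression_atlas <- function(truth, grid,
                                      effect_map = true_effect_map(truth, grid),
                                      n_donors = 6, n_rh_donors = 2,
                                      n_samples_per_donor = 120,
                                      n_probes_per_gene = 3,
                                      noise_sd = 0.3,
                                      frac_unstable = 0.6,
                                      frac_low_intensity = 0.25,
                                      frac_bad_probe = 0.25,
                                      autocorr_scale = 15,
                                      frac_outside = 0,
                                      seed = stage_seed(truth$seed, "atlas")) {
  stopifnot(n_donors >= 2, n_rh_donors <= n_donors)
  set.seed(seed)
  genes <- truth$genes
  n_genes <- length(genes)

  # --- sample locations -----------------------------------------------
  mask_idx <- which(grid$mask)
  centers <- voxel_to_world(grid, arrayInd(mask_idx, grid$dims) - 1L)
  # strict margin: half-voxel jitter must not cross the midline
  left_idx <- mask_idx[centers[, 1] <= -grid$voxel_size[1] / 2]
  samp <- list()
  sid <- 0L
  for (d in seq_len(n_donors)) {
    pool <- if (d <= n_rh_donors) mask_idx else left_idx
    pick <- sample(pool, n_samples_per_donor, replace = TRUE)
    xyz <- voxel_to_world(grid, arrayInd(pick, grid$dims) - 1L) +
      matrix(stats::runif(3 * n_samples_per_donor, -0.5, 0.5) *
               rep(grid$voxel_size, each = n_samples_per_donor), ncol = 3)
    samp[[d]] <- data.frame(
      sample_id = sprintf("D%02d_S%03d", d, seq_len(n_samples_per_donor)),
      donor = sprintf("D%02d", d),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    sid <- sid + n_samples_per_donor
  }
  samples <- do.call(rbind, samp)
  in_mask_truth <- rep(TRUE, nrow(samples))
  if (frac_outside > 0) {
    n_out <- round(frac_outside * nrow(samples))
    out_rows <- sample(nrow(samples), n_out)
    # push outside the mask along x, well clear of the ellipsoid
    samples$x[out_rows] <- samples$x[out_rows] +
      ifelse(samples$x[out_rows] >= 0, 120, -120)
    in_mask_truth[out_rows] <- FALSE
  }
  ns <- nrow(samples)

  # --- latent gene expression at samples ------------------------------
  eff_std <- mask_values(effect_map)
  eff_std <- (eff_std - mean(eff_std)) / stats::sd(eff_std)
  vox_of_sample <- nearest_voxel(grid, as.matrix(samples[, c("x", "y", "z")]))
  eff_at_sample <- rep(0, ns)
  hit <- !is.na(vox_of_sample) & grid$mask[ifelse(is.na(vox_of_sample), 1L,
                                                  vox_of_sample)]
  eff_at_sample[hit] <- eff_std[match(vox_of_sample[hit], mask_idx)]
  # standardize over the sample distribution so the mixing weight below
  # is the population spatial correlation at sample locations
  if (stats::sd(eff_at_sample) > 0) {
    eff_at_sample <- (eff_at_sample - mean(eff_at_sample)) /
      stats::sd(eff_at_sample)
  }

  # spatially correlated noise across samples: squared-exponential kernel
  sxyz <- as.matrix(samples[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(sxyz))^2
  kmat <- exp(-d2 / (2 * autocorr_scale^2)) + diag(1e-6, ns)
  lchol <- t(chol(kmat))

  n_signal <- length(truth$signal_genes)
  expr_gene <- matrix(0, nrow = ns, ncol = n_genes,
                      dimnames = list(samples$sample_id, genes))
  # inflate the latent mixing weight so that after probe noise the
  # faithful probe's correlation with the effect map equals rho
  rho_lat <- pmin(1, truth$signal_rho * sqrt(1 + noise_sd^2))
  sig_noise <- lchol %*% matrix(stats::rnorm(ns * n_signal), ns)
  expr_gene[, seq_len(n_signal)] <-
    outer(eff_at_sample, rho_lat) +
    sig_noise %*% diag(sqrt(1 - rho_lat^2), n_signal)
  null_cols <- setdiff(seq_len(n_genes), seq_len(n_signal))
  unstable <- sample(null_cols, round(frac_unstable * length(null_cols)))
  stable <- setdiff(null_cols, unstable)
  if (length(stable)) {
    expr_gene[, stable] <- lchol %*%
      matrix(stats::rnorm(ns * length(stable)), ns)
  }
  if (length(unstable)) {
    # independent smooth profile per donor
    for (dn in unique(samples$donor)) {
      rows <- which(samples$donor == dn)
      ld <- t(chol(kmat[rows, rows]))
      expr_gene[rows, unstable] <- ld %*%
        matrix(stats::rnorm(length(rows) * length(unstable)), length(rows))
    }
  }

  # --- probes, background flags, RNA-seq reference --------------------
  n_probes <- n_genes * n_probes_per_gene
  probe_ids <- sprintf("P%05d", seq_len(n_probes))
  annotation <- data.frame(probe_id = probe_ids,
                           gene = rep(genes, each = n_probes_per_gene))
  expr <- matrix(0, nrow = n_probes, ncol = ns,
                 dimnames = list(probe_ids, samples$sample_id))
  above <- matrix(TRUE, nrow = n_probes, ncol = ns,
                  dimnames = list(probe_ids, samples$sample_id))
  bad_probe <- logical(n_probes)
  low_int <- logical(n_probes)
  for (g in seq_len(n_genes)) {
    base_row <- (g - 1L) * n_probes_per_gene
    expr[base_row + 1L, ] <- expr_gene[, g] +
      stats::rnorm(ns, sd = noise_sd)
    if (n_probes_per_gene > 1L) {
      for (pp in 2:n_probes_per_gene) {
        r <- base_row + pp
        if (stats::runif(1) < frac_bad_probe) {
          bad_probe[r] <- TRUE
          expr[r, ] <- stats::rnorm(ns)
        } else {
          expr[r, ] <- expr_gene[, g] + stats::rnorm(ns, sd = 3 * noise_sd)
        }
        if (stats::runif(1) < frac_low_intensity) {
          low_int[r] <- TRUE
          above[r, ] <- stats::runif(ns) < 0.3
        }
      }
    }
  }
  rnaseq <- t(expr_gene) + matrix(stats::rnorm(n_genes * ns, sd = noise_sd),
                                  n_genes, ns)
  dimnames(rnaseq) <- list(genes, samples$sample_id)

  structure(list(samples = samples, expr = expr, annotation = annotation,
                 above_background = above, rnaseq = rnaseq,
                 in_mask_truth = in_mask_truth,
                 planted_low_intensity = probe_ids[low_int],
                 planted_bad_probe = probe_ids[bad_probe]),
            class = "atlas_bundle")
}

#' Simulate GMT-style gene-category annotation
#'
#' Planted enriched categories draw at least `enriched_fraction` of their
#' members from the truth's signal genes; null categories draw uniformly.
#'
#' @param truth a `ground_truth`.
#' @param size_range inclusive category size range (default 10..60).
#' @param enriched_fraction fraction of an enriched category's members
#'   taken from the signal genes.
#' @param n_undersized extra categories planted below the size filter.
#' @param seed RNG seed.
#' @return named list of gene-id character vectors (a GMT in memory).
#' @export
simulate_category_sets <- function(truth, size_range = c(10, 60),
                                   enriched_fraction = 0.8,
                                   n_undersized = 0,
                                   seed = stage_seed(truth$seed, "categories")) {
  stopifnot(size_range[1] >= 1, size_range[2] <= length(truth$genes))
  set.seed(seed)
  n_cat <- truth$n_categories
  ids <- sprintf("CAT%03d", seq_len(n_cat))
  sets <- vector("list", n_cat)
  names(sets) <- ids
  for (i in seq_len(n_cat)) {
    size <- sample(size_range[1]:size_range[2], 1L)
    if (ids[i] %in% truth$enriched_categories) {
      n_sig <- min(length(truth$signal_genes),
                   max(1L, round(enriched_fraction * size)))
      members <- c(sample(truth$signal_genes, n_sig),
                   sample(setdiff(truth$genes, truth$signal_genes),
                          size - n_sig))
    } else {
      members <- sample(truth$genes, size)
    }
    sets[[i]] <- sort(members)
  }
  if (n_undersized > 0) {
    for (j in seq_len(n_undersized)) {
      sets[[sprintf("SMALL%02d", j)]] <- sort(sample(truth$genes, 5L))
    }
  }
  sets
}

#' Write / read gene sets in GMT format
#' @param sets named list of gene-id vectors.
#' @param path .gmt file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  sets
}

#' Simulate a confidence-scored interaction edge list
#'
#' Background nodes get Erdos-Renyi-style edges at an expected background
#' degree; planted hubs are wired to reach `hub_degree`. A stated fraction
#' of background edges is scored below the confidence cutoff to exercise
#' filtering; hub edges are scored high so planted structure survives it.
#'
#' @param truth a `ground_truth`.
#' @param background_degree expected degree of non-hub nodes.
#' @param hub_degree degree of planted hubs (> background_degree).
#' @param low_conf_frac fraction of background edges scored in [0.4, 0.9).
#' @param seed RNG seed.
#' @return data.frame (node1, node2, combined_score).
#' @export
simulate_ppi_edges <- function(truth, background_degree = 4,
                               hub_degree = 30, low_conf_frac = 0.3,
                               seed = stage_seed(truth$seed, "ppi")) {
  stopifnot(hub_degree > background_degree)
  set.seed(seed)
  nodes <- truth$genes[seq_len(truth$n_nodes)]
  hubs <- truth$hub_nodes
  n <- length(nodes)
  p_bg <- background_degree / (n - 1)
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_bg
  edges <- data.frame(node1 = pairs[1, keep], node2 = pairs[2, keep])
  for (h in hubs) {
    cur <- sum(edges$node1 == h | edges$node2 == h)
    need <- hub_degree - cur
    if (need > 0) {
      partners <- setdiff(nodes, h)
      linked <- union(edges$node2[edges$node1 == h],
                      edges$node1[edges$node2 == h])
      new_p <- sample(setdiff(partners, linked), min(need,
                      length(setdiff(partners, linked))))
      edges <- rbind(edges, data.frame(node1 = h, node2 = new_p))
    }
  }
  is_hub_edge <- edges$node1 %in% hubs | edges$node2 %in% hubs
  score <- stats::runif(nrow(edges), 0.9, 0.999)
  low <- !is_hub_edge & stats::runif(nrow(edges)) < low_conf_frac
  score[low] <- stats::runif(sum(low), 0.4, 0.899)
  edges$combined_score <- round(score, 3)
  rownames(edges) <- NULL
  edges
}

#' Simulate a receptor/transporter map panel
#'
#' Each map is rho * standardized effect map + sqrt(1 - rho^2) * a
#' spatially autocorrelated field. The field is residualized against the
#' effect map before mixing, so the realized in-mask Pearson correlation
#' equals rho exactly rather than merely in expectation: smooth fields
#' over a brain-sized domain carry few effective degrees of freedom, and
#' without the residualization the realized correlation scatters around
#' rho by more than the recovery tolerances downstream analyses quote.
#'
#' @param truth a `ground_truth` (supplies the named target correlations).
#' @param grid a `volume_grid`.
#' @param effect_map the reference `stat_map`.
#' @param autocorr_scale field length scale in mm (default 10).
#' @param seed RNG seed.
#' @return named list of `stat_map`s.
#' @export
simulate_receptor_maps <- function(truth, grid,
                                   effect_map = true_effect_map(truth, grid),
                                   autocorr_scale = 10,
                                   seed = stage_seed(truth$seed, "receptors")) {
  set.seed(seed)
  eff <- mask_values(effect_map)
  eff <- (eff - mean(eff)) / stats::sd(eff)
  out <- list()
  for (nm in names(truth$receptor_rho)) {
    rho <- truth$receptor_rho[[nm]]
    noise <- mask_values(smooth_field(grid, autocorr_scale))
    noise <- stats::residuals(stats::lm(noise ~ eff))
    noise <- (noise - mean(noise)) / stats::sd(noise)
    out[[nm]] <- stat_map(grid, rho * eff + sqrt(1 - rho^2) * noise,
                          kind = "z")
  }
  out
}
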