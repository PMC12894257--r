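# Spatial correlation between the gray-matter alteration map and a panel
# of receptor/transporter maps, with spatial-autocorrelation-corrected
# permutation inference (surrogates of the GM map) and FDR / Bonferroni
# control across the panel.

#' Correlate a GM alteration map with a receptor/transporter panel
#'
#' Observed Pearson r per receptor map over in-mask voxels (or over
#' parcel means when a parcellation is supplied). The null correlates
#' variogram-matched surrogates of the GM map with each receptor map, so
#' one ensemble serves the whole panel; the two-sided permutation p uses
#' the add-one convention. q is Benjamini-Hochberg across the panel and
#' p_bonf = min(1, p * m).
#'
#' @param gm_map the meta-analytic `stat_map`.
#' @param panel named list of `stat_map`s on the same grid/mask.
#' @param grid a `volume_grid`.
#' @param n_perm spatial permutations (default 5000; scaled down in
#'   tests).
#' @param seed RNG seed for the surrogate ensemble.
#' @param parcels optional integer parcel label per in-mask voxel; values
#'   are averaged per parcel before correlating.
#' @param alpha significance threshold on q (default 0.01, the
#'   conventional panel threshold).
#' @param ensemble optional precomputed `surrogate_ensemble` of the GM
#'   map (overrides n_perm/seed).
#' @return data.frame per map: r, p_perm, q_fdr, p_bonf, n_permutations,
#'   significance flags.
#' @export
panel_correlate <- function(gm_map, panel, grid, n_perm = 5000, seed = 1,
                            parcels = NULL, alpha = 0.01,
                            ensemble = NULL) {
  gm <- mask_values(gm_map)
  vals <- lapply(panel, mask_values)
  if (is.null(ensemble)) {
    ensemble <- make_surrogates(gm, n = n_perm, seed = seed, grid = grid)
  }
  surr <- ensemble$maps
  if (!is.null(parcels)) {
    agg <- function(v) as.numeric(rowsum(v, parcels) /
                                    tabulate(parcels, max(parcels)))
    gm <- agg(gm)
    vals <- lapply(vals, agg)
    surr <- apply(surr, 2L, agg)
  }
  if (length(gm) < 100) {
    stop("fewer than 100 analysis units in the common mask")
  }
  n_surr <- ncol(surr)
  r_obs <- vapply(vals, function(v) stats::cor(gm, v), numeric(1))
  r_null <- stats::cor(surr, do.call(cbind, vals)) # n_surr x n_maps
  p_perm <- vapply(seq_along(vals), function(m) {
    (1 + sum(abs(r_null[, m]) >= abs(r_obs[m]))) / (n_surr + 1)
  }, numeric(1))
  q_fdr <- bh_fdr(p_perm)
  p_bonf <- pmin(1, p_perm * length(vals))
  data.frame(
    map = names(panel), r = unname(r_obs), p_perm = p_perm,
    q_fdr = q_fdr, p_bonf = p_bonf, n_permutations = n_surr,
    sig_fdr = q_fdr < alpha, sig_bonf = p_bonf < alpha,
    row.names = NULL)
}

#' Cubic-block parcellation of the mask
#'
#' Simple parcel labels for the optional parcel-level analysis: in-mask
#' voxels grouped into cubes of `block_mm` edge length.
#' @param grid a `volume_grid`.
#' @param block_mm cube edge in mm (default 12).
#' @return integer parcel label per in-mask voxel (1..n_parcels).
#' @export
block_parcellation <- function(grid, block_mm = 12) {
  xyz <- voxel_centers(grid)[which(grid$mask), , drop = FALSE]
  key <- paste(floor(xyz[, 1] / block_mm), floor(xyz[, 2] / block_mm),
               floor(xyz[, 3] / block_mm))
  as.integer(factor(key))
}

#' Write / read a receptor panel as a NIfTI directory with a manifest
#' @param panel named list of `stat_map`s.
#' @param dir output directory.
#' @export
write_receptor_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(names(panel), function(nm) {
    f <- paste0(gsub("[^A-Za-z0-9_]", "_", nm), ".nii.gz")
    write_stat_map(panel[[nm]], file.path(dir, f))
    f
  }, character(1))
  jsonlite::write_json(as.list(files), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_receptor_panel
#' @param grid the expected `volume_grid`.
#' @export
read_receptor_panel <- function(dir, grid) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- lapply(manifest, function(f) {
    read_stat_map(file.path(dir, f), grid, kind = "z")
  })
  names(out) <- names(manifest)
  out
}
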