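# End-to-end demo pipeline on freshly generated synthetic data. Every
# stage consumes the previous stage's outputs exactly as the file-based
# drivers do, and all randomness flows from one master seed via named
# substreams, so two runs with the same seed are bit-identical.

#' Default pipeline configuration
#'
#' Defaults follow the field-standard thresholds the analysis stages
#' document: CBMA at FWHM 20 mm, voxel p < 0.005, peak z >= 1, extent 50
#' (heterogeneity extent 10); atlas thresholds 0.5 / 0.2 / DS 0.5 (with
#' 0.4 and 0.6 sensitivity alternates); sphere radius 3 mm; category
#' sizes 10-200, two-sided alpha 0.05; confidence cutoff 0.9, hub
#' fraction 0.1; panel alpha 0.01. Simulation scale and the surrogate /
#' permutation counts are sized for a desk run.
#'
#' @param seed master seed.
#' @param ... overrides for any config entry.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    voxel_mm = 6,
    cbma = list(fwhm = 20, voxel_p = 0.005, peak_z = 1, extent = 50,
                het_extent = 10, n_null = 100),
    studies = list(n_studies = 15, n_range = c(13, 67), peak_noise_sd = 8,
                   miss_rate = 0.1),
    ahba = list(intensity = 0.5, probe_r = 0.2, ds_fraction = 0.5,
                ds_alternates = c(0.4, 0.6), n_regions = 30),
    atlas = list(n_donors = 6, n_samples_per_donor = 120),
    assoc = list(radius = 3, n_surrogates = 300, go_min = 10,
                 go_max = 200, alpha = 0.05),
    enrich = list(psi = 0.05, string_cutoff = 0.9, hub_fraction = 0.1),
    neuro = list(n_perm = 300, alpha = 0.01)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full pipeline on synthetic data
#'
#' Generates every input with known ground truth, runs CBMA, atlas
#' preprocessing, gene scores + GCEA, specificity enrichment, hub
#' detection and the receptor-panel correlation, and writes result tables
#' plus a recovery report under `out_dir`.
#'
#' @param seed master seed (drives all substreams).
#' @param out_dir output directory.
#' @param config a [pipeline_config()]; its seed is overridden by `seed`.
#' @return invisibly, the report list.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("gmtx_demo_"),
                     config = pipeline_config(seed)) {
  config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed (seed %d): %s", name,
                   config$seed, conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- ground_truth(seed = config$seed)
  grid <- stage("grid", ellipsoid_mask(make_grid(config$voxel_mm)))
  write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))

  # --- CBMA ------------------------------------------------------------
  ss <- stage("simulate", do.call(simulate_study_set,
    c(list(truth = truth), config$studies)))
  write_peak_table(ss, file.path(out_dir, "peaks.csv"))
  meta <- stage("cbma", run_cbma(
    ss, grid, fwhm = config$cbma$fwhm, voxel_p = config$cbma$voxel_p,
    peak_z = config$cbma$peak_z, extent = config$cbma$extent,
    het_extent = config$cbma$het_extent, n_null = config$cbma$n_null,
    seed = stage_seed(config$seed, "cbma_null")))
  utils::write.csv(meta$clusters, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)
  write_stat_map(meta$z_map, file.path(out_dir, "z_map.nii.gz"))

  loci <- truth$effect_loci
  recovered <- vapply(seq_len(nrow(loci)), function(i) {
    if (!nrow(meta$clusters)) return(FALSE)
    dist <- sqrt((meta$clusters$x - loci$x[i])^2 +
                 (meta$clusters$y - loci$y[i])^2 +
                 (meta$clusters$z - loci$z[i])^2)
    any(dist <= 10 & sign(meta$clusters$peak_z) == sign(loci$d[i]))
  }, logical(1))

  # --- expression atlas ------------------------------------------------
  effect_map <- true_effect_map(truth, grid)
  bundle <- stage("atlas", simulate_expression_atlas(
    truth, grid, effect_map = effect_map,
    n_donors = config$atlas$n_donors,
    n_samples_per_donor = config$atlas$n_samples_per_donor))
  prep <- stage("ahba", preprocess_atlas(
    bundle, grid, min_fraction = config$ahba$intensity,
    min_r = config$ahba$probe_r, ds_fraction = config$ahba$ds_fraction,
    n_regions = config$ahba$n_regions,
    seed = stage_seed(config$seed, "atlas")))
  write_sample_gene_matrix(prep, out_dir)

  # --- gene scores + GCEA ---------------------------------------------
  op <- stage("scores", sphere_operator(grid, prep$samples,
                                        radius = config$assoc$radius))
  expr_kept <- prep$expr[op$kept, , drop = FALSE]
  sphere_obs <- as.numeric(op$A %*% mask_values(meta$z_map))
  scores <- stage("scores", gene_scores(expr_kept, sphere_obs))
  utils::write.table(
    data.frame(gene = names(scores), score = scores),
    file.path(out_dir, "gene_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  sets <- stage("categories", simulate_category_sets(truth))
  sets_f <- filter_categories(sets, colnames(expr_kept),
                              config$assoc$go_min, config$assoc$go_max)
  ens <- stage("surrogates", make_surrogates(
    mask_values(meta$z_map), n = config$assoc$n_surrogates,
    seed = stage_seed(config$seed, "surrogates"), grid = grid))
  gc_res <- stage("gcea", gcea(scores, sets_f, expr_kept, op$A, ens,
                               alpha = config$assoc$alpha))
  utils::write.csv(gc_res, file.path(out_dir, "gcea.csv"),
                   row.names = FALSE)

  # --- specificity enrichment and hubs --------------------------------
  sig_genes <- names(scores)[rank(-abs(scores)) <=
                               length(truth$signal_genes)]
  panel_sets <- list(
    planted_tissue = truth$signal_genes,
    other_tissue = sample(truth$genes, 80)
  )
  enr <- stage("enrich", fisher_enrichment(sig_genes, panel_sets,
                                           colnames(expr_kept)))
  utils::write.csv(enr, file.path(out_dir, "specificity.csv"),
                   row.names = FALSE)

  edges <- stage("ppi", simulate_ppi_edges(truth))
  write_edge_list(edges, file.path(out_dir, "edges.tsv"))
  hubs <- stage("hubs", hub_detection(edges,
                                      cutoff = config$enrich$string_cutoff,
                                      fraction = config$enrich$hub_fraction))
  utils::write.csv(hubs$degrees, file.path(out_dir, "degrees.csv"),
                   row.names = FALSE)

  # --- receptor panel --------------------------------------------------
  panel <- stage("receptors", simulate_receptor_maps(truth, grid,
                                                     effect_map = effect_map))
  neuro <- stage("neuro", panel_correlate(
    effect_map, panel, grid, n_perm = config$neuro$n_perm,
    seed = stage_seed(config$seed, "surrogates") + 1L,
    alpha = config$neuro$alpha))
  utils::write.csv(neuro, file.path(out_dir, "neuro_correlations.csv"),
                   row.names = FALSE)

  report <- list(
    seed = config$seed,
    cbma = list(n_clusters = nrow(meta$clusters),
                loci_recovered = sum(recovered),
                loci_total = nrow(loci)),
    gcea = list(
      n_categories = nrow(gc_res),
      planted_detected = sum(gc_res$significant &
        gc_res$id %in% truth$enriched_categories &
        gc_res$direction == "above"),
      planted_total = sum(truth$enriched_categories %in% gc_res$id),
      n_significant = sum(gc_res$significant)),
    hubs = list(recovered = length(intersect(hubs$hubs, truth$hub_nodes)),
                planted = length(truth$hub_nodes)),
    receptors = list(
      n_sig_fdr = sum(neuro$sig_fdr),
      planted_nonzero = sum(truth$receptor_rho != 0),
      max_abs_r_error = max(abs(neuro$r - truth$receptor_rho[neuro$map])))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
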