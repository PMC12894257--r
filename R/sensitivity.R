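# Sensitivity of category enrichment to the differential-stability
# cutoff: the preprocessing-to-GCEA chain is rerun at alternative DS
# retention fractions and the significant category sets are compared.

#' DS-threshold sensitivity harness
#'
#' Reruns atlas preprocessing at several DS retention fractions, computes
#' gene scores against the supplied map and runs GCEA for each, sharing
#' one surrogate ensemble. Reports the per-fraction significant category
#' sets and their pairwise Jaccard overlap.
#'
#' @param bundle an `atlas_bundle`.
#' @param grid a `volume_grid`.
#' @param map the `stat_map` gene scores are computed against.
#' @param sets category annotation (named list of gene-id vectors).
#' @param fractions DS fractions to compare (default 0.4, 0.5, 0.6).
#' @param radius sphere radius in mm.
#' @param n_surrogates ensemble size shared across fractions.
#' @param seed RNG seed (ensemble + region assignment).
#' @param alpha GCEA significance threshold.
#' @return list: `results` (per-fraction GCEA tables), `significant`
#'   (per-fraction id sets), `jaccard` (pairwise overlap matrix).
#' @export
run_ds_sensitivity <- function(bundle, grid, map, sets,
                               fractions = c(0.4, 0.5, 0.6), radius = 3,
                               n_surrogates = 200, seed = 1,
                               alpha = 0.05) {
  ens <- make_surrogates(mask_values(map), n = n_surrogates, seed = seed,
                         grid = grid)
  results <- list()
  sig <- list()
  for (f in fractions) {
    key <- sprintf("%.2f", f)
    prep <- preprocess_atlas(bundle, grid, ds_fraction = f, seed = seed)
    op <- sphere_operator(grid, prep$samples, radius = radius)
    expr <- prep$expr[op$kept, , drop = FALSE]
    sc <- gene_scores(expr, as.numeric(op$A %*% mask_values(map)))
    sets_f <- filter_categories(sets, colnames(expr))
    res <- gcea(sc, sets_f, expr, op$A, ens, alpha = alpha)
    results[[key]] <- res
    sig[[key]] <- res$id[res$significant]
  }
  nf <- length(fractions)
  jac <- matrix(1, nf, nf, dimnames = list(names(sig), names(sig)))
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    u <- union(sig[[i]], sig[[j]])
    jac[i, j] <- if (length(u)) {
      length(intersect(sig[[i]], sig[[j]])) / length(u)
    } else 1
  }
  list(results = results, significant = sig, jaccard = jac)
}
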