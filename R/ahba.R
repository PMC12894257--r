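# Expression-atlas preprocessing: intensity-based probe filtering,
# RNA-seq-guided probe selection, scaled robust sigmoid normalization,
# differential-stability gene filtering and gray-matter-mask restriction.
# Pipeline order is fixed: intensity filter -> probe selection ->
# normalization -> DS filter -> mask restriction.

#' Write / read an atlas bundle as a TSV directory
#'
#' Files: samples.tsv, probes.tsv (probe x sample expression),
#' annotation.tsv, background.tsv (0/1 flags), rnaseq.tsv.
#' @param bundle an `atlas_bundle`.
#' @param dir output directory (created if missing).
#' @export
write_atlas_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_mat <- function(m, f) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_mat(bundle$expr, "probes.tsv")
  write_mat(bundle$above_background * 1L, "background.tsv")
  write_mat(bundle$rnaseq, "rnaseq.tsv")
  invisible(dir)
}

#' @rdname write_atlas_bundle
#' @export
read_atlas_bundle <- function(dir) {
  read_mat <- function(f) {
    df <- utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  structure(list(
    samples = utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                                header = TRUE),
    expr = read_mat("probes.tsv"),
    annotation = utils::read.table(file.path(dir, "annotation.tsv"),
                                   sep = "\t", header = TRUE),
    above_background = read_mat("background.tsv") != 0,
    rnaseq = read_mat("rnaseq.tsv")
  ), class = "atlas_bundle")
}

#' Intensity-based probe filtering
#'
#' Retains probes whose signal exceeds the background noise threshold in
#' at least `min_fraction` of samples across the full donor cohort.
#' @param bundle an `atlas_bundle`.
#' @param min_fraction minimum above-background fraction (default 0.5).
#' @export
filter_probes_by_intensity <- function(bundle, min_fraction = 0.5) {
  frac <- rowMeans(bundle$above_background)
  keep <- frac >= min_fraction
  message(sprintf("intensity filter: %d -> %d probes (min fraction %.2f)",
                  length(keep), sum(keep), min_fraction))
  bundle$expr <- bundle$expr[keep, , drop = FALSE]
  bundle$above_background <- bundle$above_background[keep, , drop = FALSE]
  bundle$annotation <- bundle$annotation[
    bundle$annotation$probe_id %in% rownames(bundle$expr), , drop = FALSE]
  bundle
}

#' RNA-seq-guided probe selection
#'
#' For every probe, Pearson correlation with the matched gene's RNA-seq
#' profile over shared samples; probes with r < `min_r` are excluded and,
#' among survivors, the max-r probe represents its gene. Genes absent from
#' the RNA-seq reference, or with no surviving probe, are dropped. Without
#' an RNA-seq reference the max-variance probe is used instead (loudly:
#' the correlation rule cannot run).
#'
#' @param bundle an `atlas_bundle` (after intensity filtering).
#' @param min_r minimum probe/RNA-seq correlation (default 0.2).
#' @return list: `expr` (sample x gene matrix), `samples`, `probe_map`
#'   (gene -> chosen probe, with its r).
#' @export
select_probe_per_gene <- function(bundle, min_r = 0.2) {
  ann <- bundle$annotation
  ann <- ann[ann$probe_id %in% rownames(bundle$expr), , drop = FALSE]
  have_rnaseq <- !is.null(bundle$rnaseq)
  if (!have_rnaseq) {
    warning(paste("no RNA-seq reference available: falling back to the",
                  "maximum-variance probe per gene"))
  } else {
    ann <- ann[ann$gene %in% rownames(bundle$rnaseq), , drop = FALSE]
    shared <- intersect(colnames(bundle$expr), colnames(bundle$rnaseq))
  }
  chosen <- list()
  for (g in unique(ann$gene)) {
    probes <- ann$probe_id[ann$gene == g]
    if (have_rnaseq) {
      r <- vapply(probes, function(p) {
        suppressWarnings(stats::cor(bundle$expr[p, shared],
                                    bundle$rnaseq[g, shared]))
      }, numeric(1))
      r[is.na(r)] <- 0
      ok <- r >= min_r
      if (!any(ok)) next
      best <- probes[ok][which.max(r[ok])]
      chosen[[g]] <- data.frame(gene = g, probe_id = best,
                                r = max(r[ok]))
    } else {
      v <- apply(bundle$expr[probes, , drop = FALSE], 1L, stats::var)
      chosen[[g]] <- data.frame(gene = g, probe_id = probes[which.max(v)],
                                r = NA_real_)
    }
  }
  probe_map <- do.call(rbind, chosen)
  rownames(probe_map) <- NULL
  message(sprintf("probe selection: %d genes represented (min r %.2f)",
                  nrow(probe_map), min_r))
  expr <- t(bundle$expr[probe_map$probe_id, , drop = FALSE])
  colnames(expr) <- probe_map$gene
  list(expr = expr, samples = bundle$samples, probe_map = probe_map)
}

#' Scaled robust sigmoid normalization of one vector
#'
#' y = 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35))), then min-max
#' rescaled to [0, 1]. IQR/1.35 approximates the SD under normality, so
#' the sigmoid has unit-SD-like scale while staying outlier-robust.
#' Degenerate vectors (IQR = 0) map to a constant 0.5.
#' @param x numeric vector.
#' @export
srs <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0) {
    message("srs: zero IQR, vector set to constant 0.5")
    return(rep(0.5, length(x)))
  }
  y <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  (y - min(y)) / (max(y) - min(y))
}

#' Scaled robust sigmoid normalization of a sample-by-gene matrix
#'
#' Applied within-sample (across genes) and then within-gene (across
#' samples), in that order by default.
#' @param expr sample x gene matrix.
#' @param order "sample_then_gene" or "gene_then_sample".
#' @export
srs_normalize <- function(expr, order = c("sample_then_gene",
                                          "gene_then_sample")) {
  order <- match.arg(order)
  within_sample <- function(m) t(apply(m, 1L, srs))
  within_gene <- function(m) apply(m, 2L, srs)
  out <- if (order == "sample_then_gene") {
    within_gene(within_sample(expr))
  } else {
    within_sample(within_gene(expr))
  }
  dimnames(out) <- dimnames(expr)
  out
}

#' Spatial parcellation of samples for differential stability
#'
#' k-means on sample MNI coordinates; the synthetic stand-in for an
#' anatomical region assignment.
#' @param samples data.frame with x, y, z.
#' @param n_regions number of parcels (default 30).
#' @param seed RNG seed for k-means initialization.
#' @return integer region label per sample.
#' @export
assign_regions <- function(samples, n_regions = 30, seed = 1) {
  set.seed(seed)
  km <- stats::kmeans(as.matrix(samples[, c("x", "y", "z")]),
                      centers = n_regions, nstart = 3, iter.max = 50)
  km$cluster
}

#' Differential stability of each gene
#'
#' For every donor pair, each gene's expression is aggregated to mean
#' regional profiles over the regions the pair shares, and the profiles
#' are correlated (Spearman by default, robust to per-donor monotone
#' distortion). DS is the mean over donor pairs. Pairs sharing fewer than
#' two regions are skipped; a gene with zero variance within a donor
#' contributes 0 for that pair.
#'
#' @param expr sample x gene matrix.
#' @param donors donor label per sample.
#' @param regions region label per sample.
#' @param method "spearman" (default) or "pearson".
#' @return named numeric vector of DS values per gene.
#' @export
differential_stability <- function(expr, donors, regions,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  donor_ids <- unique(donors)
  stopifnot(length(donor_ids) >= 2)
  # per-donor region x gene mean profiles
  profiles <- lapply(donor_ids, function(d) {
    rows <- donors == d
    m <- rowsum(expr[rows, , drop = FALSE], regions[rows])
    cnt <- as.vector(table(factor(regions[rows], levels = rownames(m))))
    m / cnt
  })
  names(profiles) <- donor_ids
  pairs <- utils::combn(donor_ids, 2L, simplify = FALSE)
  acc <- matrix(0, nrow = length(pairs), ncol = ncol(expr))
  used <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    a <- profiles[[pairs[[i]][1]]]
    b <- profiles[[pairs[[i]][2]]]
    shared <- intersect(rownames(a), rownames(b))
    if (length(shared) < 2L) {
      message(sprintf("DS: donor pair %s-%s shares <2 regions, skipped",
                      pairs[[i]][1], pairs[[i]][2]))
      next
    }
    used[i] <- TRUE
    r <- suppressWarnings(
      stats::cor(a[shared, , drop = FALSE], b[shared, , drop = FALSE],
                 method = method))
    acc[i, ] <- ifelse(is.na(diag(r)), 0, diag(r))
  }
  if (!any(used)) stop("no donor pair shares enough regions for DS")
  ds <- colMeans(acc[used, , drop = FALSE])
  names(ds) <- colnames(expr)
  ds
}

#' Retain the top fraction of genes by differential stability
#' @param ds_values named DS vector.
#' @param fraction fraction retained (default 0.5; sensitivity runs use
#'   0.4 and 0.6).
#' @return character vector of retained gene ids (ceiling(fraction * G),
#'   ties broken by DS then name).
#' @export
filter_top_fraction <- function(ds_values, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  n_keep <- ceiling(fraction * length(ds_values))
  ord <- order(-ds_values, names(ds_values))
  sort(names(ds_values)[ord[seq_len(n_keep)]])
}

#' Restrict samples to the gray-matter analysis mask
#'
#' Samples whose nearest voxel lies outside the mask (or the grid) are
#' dropped, with before/after counts logged.
#' @param expr sample x gene matrix.
#' @param samples sample metadata (x, y, z in MNI mm).
#' @param grid a `volume_grid` carrying the mask.
#' @return list(expr, samples) restricted to in-mask samples.
#' @export
restrict_to_mask <- function(expr, samples, grid) {
  idx <- nearest_voxel(grid, as.matrix(samples[, c("x", "y", "z")]))
  keep <- !is.na(idx) & grid$mask[ifelse(is.na(idx), 1L, idx)]
  if (!any(keep)) stop("all samples fall outside the analysis mask")
  message(sprintf("mask restriction: %d -> %d samples", length(keep),
                  sum(keep)))
  list(expr = expr[keep, , drop = FALSE],
       samples = samples[keep, , drop = FALSE])
}

#' Full atlas preprocessing chain
#'
#' intensity filter -> probe selection -> SRS normalization -> DS filter
#' -> mask restriction, producing the analysis-ready sample-by-gene
#' matrix.
#'
#' @param bundle an `atlas_bundle`.
#' @param grid a `volume_grid`.
#' @param min_fraction,min_r,ds_fraction stage thresholds (defaults 0.5,
#'   0.2, 0.5).
#' @param n_regions parcels for the DS region assignment.
#' @param left_only drop right-hemisphere (x > 0) samples first, the
#'   common practice when few donors cover the right hemisphere.
#' @param seed seed for the region assignment.
#' @return list: `expr` (normalized, in [0,1]), `samples`, `ds` (DS per
#'   retained gene), `probe_map`.
#' @export
preprocess_atlas <- function(bundle, grid, min_fraction = 0.5, min_r = 0.2,
                             ds_fraction = 0.5, n_regions = 30,
                             left_only = FALSE, seed = 1) {
  if (left_only) {
    keep <- bundle$samples$x <= 0
    message(sprintf("left-hemisphere restriction: %d -> %d samples",
                    length(keep), sum(keep)))
    bundle$samples <- bundle$samples[keep, , drop = FALSE]
    bundle$expr <- bundle$expr[, keep, drop = FALSE]
    bundle$above_background <- bundle$above_background[, keep, drop = FALSE]
    bundle$rnaseq <- bundle$rnaseq[, keep, drop = FALSE]
  }
  b <- filter_probes_by_intensity(bundle, min_fraction)
  sel <- select_probe_per_gene(b, min_r)
  norm <- srs_normalize(sel$expr)
  regions <- assign_regions(sel$samples, n_regions, seed = seed)
  ds <- differential_stability(norm, sel$samples$donor, regions)
  kept_genes <- filter_top_fraction(ds, ds_fraction)
  message(sprintf("DS filter: %d -> %d genes (top %d%%)", length(ds),
                  length(kept_genes), round(100 * ds_fraction)))
  norm <- norm[, kept_genes, drop = FALSE]
  res <- restrict_to_mask(norm, sel$samples, grid)
  list(expr = res$expr, samples = res$samples, ds = ds[kept_genes],
       probe_map = sel$probe_map)
}

#' Read back a written sample-by-gene matrix
#' @param dir directory written by [write_sample_gene_matrix()].
#' @return list with `expr`, `samples` and `ds`.
#' @export
read_sample_gene_matrix <- function(dir) {
  df <- utils::read.table(file.path(dir, "sample_by_gene.tsv"),
                          sep = "\t", header = TRUE, check.names = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  list(expr = expr, samples = as.data.frame(meta$samples),
       ds = unlist(meta$ds))
}

#' Write the final sample-by-gene matrix with metadata
#' @param prep result of [preprocess_atlas()].
#' @param dir output directory.
#' @export
write_sample_gene_matrix <- function(prep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(sample_id = rownames(prep$expr), prep$expr,
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "sample_by_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(samples = prep$samples, ds = as.list(prep$ds))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
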