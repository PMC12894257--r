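#!/usr/bin/env Rscript
# Stage 4: transcriptome-neuroimaging spatial association. Samples the
# meta-analytic z-map in 3 mm spheres at each tissue-sample location,
# computes one Pearson "gene score" per gene, builds variogram-matched
# surrogate maps of the z-map, and tests every gene category's mean
# score against its spatially constrained null (two-sided p < 0.05).

library(gmtx)

grid <- read_mask("results/inputs/gm_mask.nii.gz",
                  ellipsoid_mask(make_grid(6)))
zmap <- read_stat_map("results/cbma/z_map.nii.gz", grid, kind = "z")
mat <- read_sample_gene_matrix("results/expression")
truth <- read_ground_truth("results/inputs/ground_truth.json")

op <- sphere_operator(grid, mat$samples, radius = 3)
expr <- mat$expr[op$kept, ]
scores <- gene_scores(expr, as.numeric(op$A %*% mask_values(zmap)))

dir.create("results/assoc", showWarnings = FALSE)
write.table(data.frame(gene = names(scores), score = scores),
            "results/assoc/gene_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("gene scores: %d genes, planted-gene mean %.3f",
                length(scores),
                mean(scores[names(scores) %in% truth$signal_genes])))

sets <- filter_categories(read_gmt("results/inputs/categories.gmt"),
                          colnames(expr), 10, 200)
ens <- make_surrogates(mask_values(zmap), n = 1000, seed = 31,
                       grid = grid)
res <- gcea(scores, sets, expr, op$A, ens, alpha = 0.05)
res <- res[order(res$p, -abs(res$score - res$null_mean)), ]
write.csv(res, "results/assoc/gcea.csv", row.names = FALSE)

planted <- res[res$id %in% truth$enriched_categories, ]
message(sprintf(
  "GCEA: %d/%d categories significant; planted categories detected %d/%d",
  sum(res$significant), nrow(res), sum(planted$significant),
  nrow(planted)))
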