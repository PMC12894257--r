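#!/usr/bin/env Rscript
# Stage 5: specificity enrichment of the map-associated gene set
# (Fisher's exact test with Benjamini-Hochberg FDR across the panel) and
# hub detection in the confidence-scored interaction network (edges at
# combined score >= 0.9, hubs = top 10% of nodes by degree).

library(gmtx)

truth <- read_ground_truth("results/inputs/ground_truth.json")
scores <- read.table("results/assoc/gene_scores.tsv", sep = "\t",
                     header = TRUE)

# candidate set: genes whose |score| ranks with the planted signal count
n_cand <- length(truth$signal_genes)
cand <- scores$gene[rank(-abs(scores$score)) <= n_cand]
background <- scores$gene

panel <- read_gmt("results/inputs/specificity_panel.gmt")
enr <- fisher_enrichment(cand, panel, background, alpha = 0.05)
dir.create("results/enrichment", showWarnings = FALSE)
write.csv(enr, "results/enrichment/specificity.csv", row.names = FALSE)
message(sprintf("top specificity label: %s (q = %.2g)", enr$label[1],
                enr$q[1]))

edges <- read_edge_list("results/inputs/edges.tsv")
hubs <- hub_detection(edges, cutoff = 0.9, fraction = 0.10)
print(hubs)
write.csv(hubs$degrees, "results/enrichment/degrees.csv",
          row.names = FALSE)
writeLines(hubs$hubs, "results/enrichment/hubs.txt")
write_graphml(hubs, edges, "results/enrichment/network.graphml")
message(sprintf("hub recovery: %d/%d planted hubs",
                length(intersect(hubs$hubs, truth$hub_nodes)),
                length(truth$hub_nodes)))
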