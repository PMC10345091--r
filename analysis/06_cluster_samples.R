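#!/usr/bin/env Rscript
# Stage 6: cluster samples by their pooled topic attributions
# (1 - Pearson distance, complete linkage, cut at 2) and measure how often
# the two siblings of a family land in the same cluster.

suppressPackageStartupMessages(library(topicomics))
out <- "results/analysis"
cohort <- readRDS(file.path(out, "state", "cohort.rds"))
xo <- readRDS(file.path(out, "state", "crossomic.rds"))

sc <- cluster_samples(xo$attribution, n_clusters = 2,
                      metadata = cohort$metadata)
utils::write.table(data.frame(sample_id = names(sc$cluster_labels),
                              cluster = unname(sc$cluster_labels)),
                   file.path(out, "sample_clusters.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(sc, file.path(out, "state", "sample_clusters.rds"))
cat(sprintf("Samples split %s; sibling co-clustering rate %.2f\n",
            paste(table(sc$cluster_labels), collapse = " / "),
            sc$sibling_coclustering_rate))
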