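#!/usr/bin/env Rscript
# Stage 2: pick a normalization per omic by the sibling distance ratio
# (mean within-sibling-pair distance / mean between-family distance, lower
# is better), then log-transform and discretize for the topic model.

suppressPackageStartupMessages(library(topicomics))
out <- "results/analysis"
cohort <- readRDS(file.path(out, "state", "cohort.rds"))

normalized <- list()
for (nm in names(cohort$omics$tables)) {
  tab <- cohort$omics$tables[[nm]]
  sel <- select_normalization(tab, cohort$metadata,
                              candidates = c("rle", "none", "total_sum"))
  utils::write.table(
    data.frame(candidate = rownames(sel$grid), round(sel$grid, 4)),
    file.path(out, paste0("sibling_ratio_grid_", nm, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: winner = %s (wins %d of %d metrics)\n", nm, sel$winner,
              sum(sel$winner_per_metric == sel$winner),
              length(sel$winner_per_metric)))
  factors <- if (sel$winner == "rle") rle_size_factors(tab) else
    if (sel$winner == "none") setNames(rep(1, ncol(tab$values)),
                                       colnames(tab$values)) else {
      tot <- colSums(tab$values); tot / median(tot)
    }
  normalized[[nm]] <- normalize_log_discretize(tab, factors)
}
saveRDS(normalized, file.path(out, "state", "normalized.rds"))
cat("Wrote per-omic ratio grids and discretized tables.\n")
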