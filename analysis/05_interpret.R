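#!/usr/bin/env Rscript
# Stage 5: interpret topics. Features defining each topic are those passing
# both the 1.5-SD specificity criterion and the SVD loading-percentile
# criterion; topic attributions are also correlated with the metadata
# covariates (Spearman, starred at p < 0.05).

suppressPackageStartupMessages(library(topicomics))
out <- "results/analysis"
cohort <- readRDS(file.path(out, "state", "cohort.rds"))
models <- readRDS(file.path(out, "state", "models.rds"))
xo <- readRDS(file.path(out, "state", "crossomic.rds"))

all_sel <- list()
for (nm in names(models)) {
  fr <- select_topic_features(models[[nm]]$beta, percentile = 99)
  sel <- fr$selected
  if (nrow(sel)) sel$omic <- nm
  all_sel[[nm]] <- sel
  cat(sprintf("%s: %d of %d features pass both criteria\n",
              nm, nrow(sel), nrow(fr$features)))
}
sel_tab <- do.call(rbind, all_sel)
utils::write.table(sel_tab, file.path(out, "topic_features.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

mc <- topic_metadata_correlation(xo$attribution, cohort$metadata)
mc$rho <- round(mc$rho, 4)
utils::write.table(mc, file.path(out, "topic_metadata_correlation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d topic-covariate pairs significant at p < 0.05\n",
            sum(mc$significant), nrow(mc)))
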