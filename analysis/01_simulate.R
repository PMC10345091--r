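#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-omic sibling-pair cohort that the
# rest of the workflow analyses. Three omic count tables share one
# per-sample topic distribution; covariates are linear in the topics; four
# abundant features carry a planted case/control fold change.

suppressPackageStartupMessages(library(topicomics))
seed <- 20260921L
out <- "results/analysis"
dir.create(file.path(out, "state"), showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(
  n_families = 30L,
  omic_specs = list(`16S` = list(V = 120L, N_d = 2000L),
                    MTG = list(V = 150L, N_d = 2000L),
                    MBX = list(V = 100L, N_d = 2000L)),
  K_true = 4L, sibling_correlation = 0.6, n_covariates = 4L,
  seed = seed)
cohort <- generate_cohort(cfg)

# plant case/control differentials on abundant 16S features
ab <- rowMeans(cohort$omics$tables$`16S`$values)
set.seed(seed + 1L)
spec <- lapply(sample(order(ab, decreasing = TRUE)[5:20], 4), function(f)
  list(omic = "16S", feature = f, log2fc = 1.5))
pl <- plant_differentials(cohort$omics, cohort$truth, spec, cohort$metadata,
                          seed = seed + 2L)
cohort$omics <- pl$omics
cohort$truth <- pl$truth

# per-sample sequencing-depth variation (log-normal), the nuisance the
# median-of-ratios normalization exists to remove; multiplying a whole
# column preserves planted fold changes
set.seed(seed + 3L)
for (nm in names(cohort$omics$tables)) {
  tab <- cohort$omics$tables[[nm]]
  depth <- exp(rnorm(ncol(tab$values), sd = 0.5))
  cohort$omics$tables[[nm]] <- count_table(
    round(sweep(tab$values, 2, depth, "*")), omic_name = nm)
}

write_cohort(cohort, file.path(out, "cohort"))
saveRDS(cohort, file.path(out, "state", "cohort.rds"))

cat("Simulated", length(cohort$omics$tables), "omics over",
    length(cohort$omics$shared_samples), "samples (",
    cfg$n_families, "sibling-pair families ).\n")
cat("Planted features:",
    paste(vapply(cohort$truth$planted, `[[`, "", "feature_id"),
          collapse = ", "), "\n")
cat("Wrote TSVs + truth.json under", file.path(out, "cohort"), "\n")
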