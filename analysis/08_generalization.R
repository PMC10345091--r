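#!/usr/bin/env Rscript
# Stage 8: do topics define consistent feature-feature relationships across
# cohorts? Split the cohort into two disjoint halves, refit the 16S model
# on each, and compare the beta-derived cosine distance matrices with a
# Mantel permutation test (joint row/column relabeling null).

suppressPackageStartupMessages(library(topicomics))
seed <- 20260981L
out <- "results/analysis"
normalized <- readRDS(file.path(out, "state", "normalized.rds"))
models <- readRDS(file.path(out, "state", "models.rds"))

disc <- normalized$`16S`$discretized
D <- ncol(disc$values)
half1 <- count_table(disc$values[, 1:(D %/% 2)], "16S", is_discrete = TRUE)
half2 <- count_table(disc$values[, (D %/% 2 + 1):D], "16S",
                     is_discrete = TRUE)
K <- models$`16S`$K
m1 <- fit_lda_gibbs(half1, K = K, alpha = 50 / K, gamma = 0.1,
                    n_iterations = 500, burn_in = 200, thin = 5,
                    seed = seed + 1L, drop_empty = TRUE)
m2 <- fit_lda_gibbs(half2, K = K, alpha = 50 / K, gamma = 0.1,
                    n_iterations = 500, burn_in = 200, thin = 5,
                    seed = seed + 2L, drop_empty = TRUE)

mt <- mantel_test(beta_cosine_distance(m1), beta_cosine_distance(m2),
                  n_permutations = 9999, seed = seed + 3L)
jsonlite::write_json(
  list(r = mt$r, z = mt$z, p = mt$p, null_mean = mt$null_mean,
       null_sd = mt$null_sd, n_features = mt$n_features,
       n_permutations = mt$n_permutations),
  file.path(out, "mantel_split_cohort.json"), auto_unbox = TRUE, digits = NA)
cat(sprintf("Split-cohort Mantel: r = %.3f, z = %.1f, p = %.4g (%d features)\n",
            mt$r, mt$z, mt$p, mt$n_features))
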