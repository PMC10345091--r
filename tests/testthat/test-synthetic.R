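test_that("generated cohorts satisfy the generative-model invariants", {
  cfg <- small_cohort_config(seed = 31, n_families = 20L)
  cohort <- generate_cohort(cfg)
  truth <- cohort$truth

  for (nm in names(truth$theta_true)) {
    expect_lt(max(abs(rowSums(truth$theta_true[[nm]]) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(truth$beta_true[[nm]]) - 1)), 1e-9)
    expect_true(all(colSums(cohort$omics$tables[[nm]]$values) == 1000L))
  }
  # one case and one control sibling per family
  md <- cohort$metadata
  per_fam <- table(md$family_id, md$phenotype)
  expect_true(all(per_fam == 1L))

  # determinism
  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort$omics$tables$A$values, cohort2$omics$tables$A$values)
  expect_identical(cohort$metadata$age, cohort2$metadata$age)
})

test_that("sibling_correlation = 1 duplicates theta; = 0 removes family structure", {
  cfg1 <- small_cohort_config(seed = 32, sibling_correlation = 1)
  th <- generate_cohort(cfg1)$truth$theta_shared
  odd <- th[seq(1, nrow(th), 2), ]
  even <- th[seq(2, nrow(th), 2), ]
  expect_equal(odd, even, ignore_attr = TRUE)

  # Monte-Carlo oracle: at s = 0 the within/between theta distance ratio -> 1
  cfg0 <- generator_config(
    n_families = 250L, omic_specs = list(A = list(V = 20L, N_d = 10L)),
    K_true = 4L, sibling_correlation = 0, seed = 33L, n_covariates = 0L)
  th0 <- generate_cohort(cfg0)$truth$theta_shared
  dm <- as.matrix(dist(th0))
  fam <- rep(seq_len(250L), each = 2L)
  same <- outer(fam, fam, "==") & upper.tri(dm)
  diff_ <- outer(fam, fam, "!=") & upper.tri(dm)
  ratio <- mean(dm[same]) / mean(dm[diff_])
  expect_lt(abs(ratio - 1), 0.05)

  # high sibling correlation pulls the ratio well below 1
  cfg9 <- generator_config(
    n_families = 250L, omic_specs = list(A = list(V = 20L, N_d = 10L)),
    K_true = 4L, sibling_correlation = 0.9, seed = 34L, n_covariates = 0L)
  th9 <- generate_cohort(cfg9)$truth$theta_shared
  dm9 <- as.matrix(dist(th9))
  expect_lt(mean(dm9[same]) / mean(dm9[diff_]), 0.5)
})

test_that("empirical feature frequencies converge to theta %*% beta", {
  cfg <- generator_config(
    n_families = 5L, omic_specs = list(A = list(V = 40L, N_d = 100000L)),
    K_true = 3L, seed = 35L, n_covariates = 0L)
  cohort <- generate_cohort(cfg)
  tab <- cohort$omics$tables$A$values
  mu <- t(cohort$truth$theta_true$A %*% cohort$truth$beta_true$A)
  freq <- sweep(tab, 2L, colSums(tab), "/")
  big <- mu > 0.01
  rel_err <- abs(freq[big] - mu[big]) / mu[big]
  # per-cell multinomial noise at p ~ 0.01 has relative SD ~ 3%, so the
  # typical error sits well under 5% while the max over ~200 cells can
  # brush past it
  expect_lt(mean(rel_err), 0.05)
  expect_lt(max(rel_err), 0.15)
})

test_that("config validation rejects impossible specs", {
  expect_error(generator_config(alpha_true = 0), "positive")
  expect_error(generator_config(sibling_correlation = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(
    omic_specs = list(A = list(V = 3L, N_d = 100L)), K_true = 4L),
    "exceeds V")
  cohort <- generate_cohort(small_cohort_config(seed = 36, n_families = 5L))
  expect_error(
    plant_differentials(cohort$omics, cohort$truth,
                        list(list(omic = "nope", feature = 1, log2fc = 1)),
                        cohort$metadata),
    "not in the set")
  expect_error(
    plant_differentials(cohort$omics, cohort$truth,
                        list(list(omic = "A", feature = 1, log2fc = 1),
                             list(omic = "A", feature = 1, log2fc = 2)),
                        cohort$metadata),
    "twice")
})

test_that("planted fold-changes shift case means by 2^log2fc", {
  cfg <- generator_config(
    n_families = 100L, omic_specs = list(A = list(V = 30L, N_d = 10000L)),
    K_true = 3L, seed = 37L, n_covariates = 0L, gamma_true = 5)
  cohort <- generate_cohort(cfg)

  # log2fc = 0 leaves the table unchanged
  p0 <- plant_differentials(cohort$omics, cohort$truth,
                            list(list(omic = "A", feature = 2, log2fc = 0)),
                            cohort$metadata, seed = 38)
  expect_identical(p0$omics$tables$A$values, cohort$omics$tables$A$values)
  expect_equal(p0$truth$planted[[1]]$feature, 2)

  # log2fc = 1 doubles the case-group mean (within 3 SE at depth 1e4)
  p1 <- plant_differentials(cohort$omics, cohort$truth,
                            list(list(omic = "A", feature = 5, log2fc = 1)),
                            cohort$metadata, seed = 39)
  vals <- p1$omics$tables$A$values[5, ]
  is_case <- cohort$metadata$phenotype[
    match(names(vals), cohort$metadata$sample_id)] == "case"
  base <- cohort$omics$tables$A$values[5, ]
  ratio <- mean(vals[is_case]) / mean(base[is_case])
  n <- sum(is_case)
  se <- sqrt(var(vals[is_case]) / n) / mean(base[is_case])
  expect_lt(abs(ratio - 2), 3 * se + 0.02)
  # controls untouched
  expect_identical(vals[!is_case], base[!is_case])

  # thinning direction
  pm <- plant_differentials(cohort$omics, cohort$truth,
                            list(list(omic = "A", feature = 7, log2fc = -1)),
                            cohort$metadata, seed = 40)
  vm <- pm$omics$tables$A$values[7, ]
  base7 <- cohort$omics$tables$A$values[7, ]
  expect_lt(mean(vm[is_case]) / mean(base7[is_case]), 0.7)
})

test_that("shared theta couples omics; the null switch decouples them", {
  ch_s <- generate_cohort(small_cohort_config(seed = 41, n_families = 60L))
  ch_i <- generate_cohort(small_cohort_config(seed = 41, n_families = 60L,
                                              shared_theta = FALSE))
  cor_across <- function(ch) {
    tA <- ch$truth$theta_true$A; tB <- ch$truth$theta_true$B
    max(abs(cor(tA, tB)))
  }
  expect_gt(cor_across(ch_s), 0.99)  # identical theta
  expect_lt(cor_across(ch_i), 0.5)

  # covariates track their loaded topic
  md <- ch_s$metadata
  th <- ch_s$truth$theta_shared
  expect_gt(cor(md$cov01, th[, 1]), 0.5)
})

test_that("a cohort written to disk reads back identically", {
  cohort <- generate_cohort(small_cohort_config(seed = 42, n_families = 6L))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_count_table(file.path(dir, "counts_A.tsv"), "A")
  expect_equal(back$values, cohort$omics$tables$A$values)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_identical(md$phenotype, cohort$metadata$phenotype)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
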