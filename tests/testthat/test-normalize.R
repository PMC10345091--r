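test_that("median-of-ratios size factors match the hand computation", {
  tab <- count_table(matrix(c(2, 8, 2, 4, 16, 4), 3, 2), "x")
  sf <- rle_size_factors(tab)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4)

  # identical samples -> unit factors
  tab2 <- count_table(matrix(c(3, 5, 9, 3, 5, 9), 3, 2), "x")
  expect_equal(unname(rle_size_factors(tab2)), c(1, 1))

  # scaling one column by c: on 2-sample tables the factors become
  # (1/sqrt(c), c/sqrt(c) * original) relative to shifted geometric means
  c_ <- 5
  tab3 <- count_table(matrix(c(2, 8, 2, c_ * 2, c_ * 8, c_ * 2), 3, 2), "x")
  sf3 <- rle_size_factors(tab3)
  expect_equal(unname(sf3), c(1 / sqrt(c_), sqrt(c_)), tolerance = 1e-10)
})

test_that("size factors are invariant to feature and sample permutations", {
  set.seed(7)
  vals <- matrix(rpois(60, 20) + 1, 10, 6,
                 dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  sf <- rle_size_factors(count_table(vals))
  pf <- sample(10); ps <- sample(6)
  sf_perm <- rle_size_factors(count_table(vals[pf, ps]))
  expect_equal(sf_perm, sf[ps])
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  # odd reference-feature count: the sample median picks one element, so
  # median-of-ratios and DESeq2's exp(median(log ratios)) coincide exactly
  set.seed(11)
  vals <- matrix(rpois(210, 30) + 1, 21, 10)
  sf <- rle_size_factors(count_table(vals))
  ref <- DESeq2::estimateSizeFactorsForMatrix(vals)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("sparse tables fall back to prevalent reference features", {
  set.seed(3)
  vals <- matrix(rpois(100, 10) + 1, 10, 10)
  vals[cbind(1:10, 1:10)] <- 0  # every feature has one zero
  expect_silent(sf <- rle_size_factors(count_table(vals)))
  expect_true(all(sf > 0))
  expect_error(rle_size_factors(count_table(vals),
                                fallback_prevalence = 1.01),
               "no reference features")
})

test_that("normalize/log/discretize follows the arithmetic and preserves zeros", {
  tab <- count_table(matrix(c(0, 7, 3, 1), 2, 2), "x")
  nt <- normalize_log_discretize(tab, factors = c(1, 1))
  expect_equal(nt$log2[2, 1], log2(8))  # count 7 -> log2(8) = 3
  expect_equal(nt$discretized$values[2, 1], 3)
  expect_equal(nt$normalized[1, 1], 0)
  expect_equal(nt$discretized$values[1, 1], 0)
  expect_true(nt$discretized$is_discrete)

  # monotone in the raw count within a sample
  tab2 <- count_table(matrix(sort(rpois(30, 50)), 30, 1), "x")
  d <- normalize_log_discretize(tab2, factors = 2)$discretized$values[, 1]
  expect_true(all(diff(d) >= 0))

  expect_error(normalize_log_discretize(tab, factors = c(1, -1)), "positive")
  expect_error(normalize_log_discretize(tab, factors = 1), "one size factor")
})

test_that("community distances match hand-computed values", {
  for (met in distance_metrics()) {
    x <- c(1, 2, 3)
    if (met == "inverse_correlation") {
      expect_equal(community_distance(x, x, met), 0, tolerance = 1e-12)
    } else {
      expect_equal(community_distance(x, x, met), 0, tolerance = 1e-12,
                   label = met)
    }
  }
  expect_equal(community_distance(c(1, 2), c(2, 1), "bray_curtis"), 2 / 6,
               tolerance = 1e-12)
  expect_equal(community_distance(c(1, 0), c(0, 1), "canberra"), 1.0,
               tolerance = 1e-12)
  expect_equal(community_distance(c(1, 2), c(2, 1), "manhattan"), 2)
  expect_equal(community_distance(c(0, 3), c(4, 0), "euclidean"), 5)
  # jaccard via the Bray-Curtis transform 2B/(1+B)
  b <- 2 / 6
  expect_equal(community_distance(c(1, 2), c(2, 1), "jaccard"),
               2 * b / (1 + b), tolerance = 1e-12)
  # alt_gower: mean |x-y| over non-double-zero features
  expect_equal(community_distance(c(0, 0, 2), c(0, 1, 4), "alt_gower"),
               (1 + 2) / 2, tolerance = 1e-12)
  expect_equal(community_distance(c(1, 0), c(1, 1), "cosine"),
               1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_error(community_distance(1:3, 1:4, "euclidean"), "length mismatch")
  expect_error(community_distance(1:3, 1:3, "nope"))
})

test_that("distance matrices are symmetric, nonnegative, zero-diagonal; L1/L2 obey the triangle inequality", {
  set.seed(5)
  vals <- matrix(rexp(8 * 12), 8, 12)
  for (met in distance_metrics()) {
    dm <- sample_distance_matrix(vals, met)
    expect_true(all(abs(dm - t(dm)) < 1e-12), label = met)
    expect_true(all(diag(dm) == 0), label = met)
    expect_true(all(dm >= 0), label = met)
  }
  for (met in c("manhattan", "euclidean")) {
    big <- matrix(rexp(6 * 200), 6, 200)
    dm <- sample_distance_matrix(big, met)
    set.seed(6)
    for (rep_i in 1:1000) {
      ijk <- sample(200, 3)
      expect_lte(dm[ijk[1], ijk[3]],
                 dm[ijk[1], ijk[2]] + dm[ijk[2], ijk[3]] + 1e-12)
    }
  }
})

test_that("sibling-ratio grid reproduces hand arithmetic and prefers RLE under depth noise", {
  # hand case: within distances {1,1}, between {2,2} -> ratio 0.5
  # 1-D manhattan: siblings at 0/1 and 10/11; cross-family distances ~ 10
  vals <- matrix(c(4, 5, 44, 45), 1, 4,
                 dimnames = list("f", c("a1", "a2", "b1", "b2")))
  md <- sample_metadata(data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    individual_id = paste0("i", 1:4),
    family_id = c("fa", "fa", "fb", "fb"),
    phenotype = c("ASD", "TD", "ASD", "TD")))
  # use raw manhattan on a table engineered so log2(x/1+1) distances are known
  tab <- count_table(matrix(2^c(1, 2, 10, 11) - 1, 1, 4), feature_ids = "f",
                     sample_ids = c("a1", "a2", "b1", "b2"))
  sel <- select_normalization(tab, md, candidates = "none",
                              metrics = "manhattan")
  # log2(x+1) maps the samples to 1, 2, 10, 11
  expect_equal(unname(sel$grid["none", "manhattan"]),
               mean(c(1, 1)) / mean(c(9, 10, 8, 9)), tolerance = 1e-12)
  expect_identical(sel$winner, "none")

  # depth-noise cohort: RLE should beat no normalization on most metrics
  cfg <- generator_config(n_families = 15L,
                          omic_specs = list(A = list(V = 120L, N_d = 2000L)),
                          K_true = 3L, sibling_correlation = 0.9, seed = 21L)
  cohort <- generate_cohort(cfg)
  tab <- cohort$omics$tables$A
  set.seed(22)
  depth <- exp(rnorm(ncol(tab$values), sd = 0.6))
  noisy <- count_table(round(sweep(tab$values, 2, depth, "*")),
                       omic_name = "A")
  sel <- select_normalization(noisy, cohort$metadata,
                              candidates = c("rle", "none"))
  wins <- sum(sel$winner_per_metric == "rle")
  expect_gte(wins, 6)
  expect_identical(sel$winner, "rle")

  # the ratio is a mean/mean: rescaling every distance by c cancels exactly,
  # so a metric that scales with the data leaves the grid unchanged
  dm_ratio <- function(scale_) {
    vv <- log2(noisy$values + 1) * scale_
    dm <- sample_distance_matrix(vv, "manhattan")
    meta <- cohort$metadata
    fam <- meta$family_id[match(colnames(vv), meta$sample_id)]
    pairs <- split(seq_along(fam), fam)
    within <- vapply(pairs, function(ix) dm[ix[1], ix[2]], numeric(1))
    between <- outer(fam, fam, "!=") & upper.tri(dm)
    mean(within) / mean(dm[between])
  }
  expect_equal(dm_ratio(1), dm_ratio(3.7), tolerance = 1e-12)

  md1 <- sample_metadata(data.frame(
    sample_id = c("a1", "a2"), individual_id = c("i1", "i2"),
    family_id = c("fa", "fa"), phenotype = c("ASD", "TD")))
  tab1 <- count_table(matrix(1:4, 2, 2), feature_ids = c("f1", "f2"),
                      sample_ids = c("a1", "a2"))
  expect_error(select_normalization(tab1, md1, candidates = "none"),
               "2 families")
})
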