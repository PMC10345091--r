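test_that("Spearman topic correlations match rank arithmetic and calibrate under the null", {
  att <- rbind(a = c(1, 2, 3, 4, 5), b = c(5, 4, 3, 2, 1),
               c = c(2, 1, 4, 3, 5))
  cm <- topic_correlation_matrix(att)
  expect_equal(diag(cm$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$rho["a", "b"], -1)
  expect_true(all(abs(cm$rho - t(cm$rho)) < 1e-12))
  expect_error(topic_correlation_matrix(att[, 1:3]), "4")

  # null calibration: fraction of p < 0.05 across independent pairs
  set.seed(71)
  n <- 80
  hits <- vapply(seq_len(1000), function(i) {
    x <- rbind(rnorm(n), rnorm(n))
    topic_correlation_matrix(x)$p[1, 2] < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("topic clustering reproduces the 1-D toy ratios and degenerate cases", {
  # four topics at 0, 1, 10, 11 on one axis: clusters {0,1} and {10,11},
  # each with within/between ratio 1/10
  exact <- matrix(c(0, 1, 10, 11), 4, 4)
  rownames(exact) <- paste0("t", 1:4)
  ca <- cluster_topics(exact, n_range = 2:3, metrics = "manhattan")
  labs <- ca$labels_per_metric$manhattan[, 1]
  expect_equal(labs[1], labs[2])
  expect_equal(labs[3], labs[4])
  expect_false(labs[1] == labs[3])
  expect_equal(unname(ca$ratio_grid["2", "manhattan"]), 0.1,
               tolerance = 1e-12)

  # duplicated attribution vectors: zero within-distance, perfect recovery
  dup <- rbind(matrix(rep(c(1, 2, 3, 4), 2), 2, 4, byrow = TRUE),
               matrix(rep(c(9, 1, 7, 2), 2), 2, 4, byrow = TRUE))
  rownames(dup) <- paste0("t", 1:4)
  cd <- cluster_topics(dup, n_range = 2:2, metrics = "euclidean")
  expect_equal(unname(cd$ratio_grid[1, 1]), 0)
})

test_that("topic clustering is invariant to topic order and distance scale", {
  set.seed(72)
  att <- matrix(rbeta(8 * 30, 0.5, 2), 8, 30)
  rownames(att) <- paste0("t", 1:8)
  c1 <- cluster_topics(att)
  p <- sample(8)
  c2 <- cluster_topics(att[p, ])
  expect_equal(adjusted_rand(c1$cluster_labels[rownames(att)[p]],
                             c2$cluster_labels), 1)
  # scaling all attributions leaves the selected n unchanged
  c3 <- cluster_topics(att * 10)
  expect_equal(c3$n_clusters, c1$n_clusters)
  expect_equal(unname(c3$ratio_grid[, "inverse_correlation"]),
               unname(c1$ratio_grid[, "inverse_correlation"]),
               tolerance = 1e-10)
})

test_that("shared-theta cohorts yield recoverable cross-omic topic clusters", {
  cohort <- generate_cohort(small_cohort_config(seed = 73, n_families = 30L,
                                                K_true = 4L))
  models <- fit_cohort(cohort, K = 4, seed = 74)
  att <- pool_topics(models, cohort$omics$shared_samples)
  ca <- cluster_topics(att, n_range = 2:8)

  # planted grouping: fitted topic k of each omic matched to its true topic
  planted <- integer(0)
  for (nm in names(models)) {
    pmatch_ <- match_topics(models[[nm]]$theta,
                            cohort$truth$theta_true[[nm]][models[[nm]]$sample_ids, ])
    planted <- c(planted, pmatch_)
  }
  labels4 <- cutree(ca$tree, k = 4)
  expect_gte(adjusted_rand(labels4, planted), 0.8)
})

test_that("null tables preserve column sums and self-resampling preserves expectations", {
  sim <- make_lda_data(D = 15, V = 25, K = 2, N_d = 200, seed = 75)
  nt <- null_count_table(sim$table, seed = 76)
  expect_identical(colSums(nt$values), colSums(sim$table$values))
  expect_identical(dimnames(nt$values), dimnames(sim$table$values))

  # identity donor: expected frequencies equal the sample's own distribution
  deep <- count_table(vapply(1:6, function(d)
    as.integer(rmultinom(1, 10000, rexp(30))), integer(30)),
    is_discrete = TRUE)
  reps <- 40
  acc <- matrix(0, 30, 6)
  for (r in seq_len(reps))
    acc <- acc + null_count_table(deep, seed = 100 + r,
                                  resample_self = TRUE)$values
  mu <- deep$values
  p <- sweep(mu, 2, colSums(mu), "/")
  se <- sqrt(p * (1 - p) * 10000 / reps)
  expect_gte(mean(abs(acc / reps - mu) <= 3 * se + 1e-9), 0.99)
})

test_that("dominant uninformative topics are flagged only when both clauses hold", {
  m <- list(K = 3L,
            theta = matrix(c(0.98, 0.01, 0.01), 50, 3, byrow = TRUE),
            beta = NULL)
  class(m) <- "lda_model"
  rep_none <- list(features = data.frame(topic_index = integer(),
                                         passed_sd_criterion = logical(),
                                         passed_svd_criterion = logical()))
  expect_equal(flag_dominant_topic(m, rep_none), 1L)

  # attributed features on the dominant topic veto the flag
  rep_attr <- list(features = data.frame(topic_index = 1L,
                                         passed_sd_criterion = TRUE,
                                         passed_svd_criterion = TRUE))
  expect_length(flag_dominant_topic(m, rep_attr), 0)

  # uniform theta: nothing flagged
  mu <- m; mu$theta <- matrix(1 / 3, 50, 3)
  expect_length(flag_dominant_topic(mu, rep_none), 0)

  # K = 1: no comparison possible
  m1 <- m; m1$K <- 1L; m1$theta <- matrix(1, 50, 1)
  expect_length(flag_dominant_topic(m1, rep_none), 0)
})

test_that("sample clustering separates planted groups and co-clusters siblings", {
  # identical topic vectors -> distance 0, same cluster
  att <- cbind(s1 = c(0.9, 0.1), s2 = c(0.9, 0.1), s3 = c(0.1, 0.9),
               s4 = c(0.05, 0.95))
  att <- att + matrix(rnorm(8, sd = 1e-6), 2, 4)
  sc <- cluster_samples(att, 2)
  expect_equal(sc$cluster_labels[["s1"]], sc$cluster_labels[["s2"]])
  expect_equal(sc$cluster_labels[["s3"]], sc$cluster_labels[["s4"]])
  expect_false(sc$cluster_labels[["s1"]] == sc$cluster_labels[["s3"]])

  # two planted sample groups with disjoint dominant topics: exact recovery
  set.seed(77)
  n <- 40
  grp <- rep(1:2, each = n / 2)
  att2 <- sapply(grp, function(g) {
    base <- if (g == 1) c(0.85, 0.05, 0.05, 0.05) else c(0.05, 0.05, 0.85, 0.05)
    p <- base + runif(4, 0, 0.03); p / sum(p)
  })
  colnames(att2) <- paste0("s", 1:n)
  sc2 <- cluster_samples(att2, 2)
  expect_equal(adjusted_rand(sc2$cluster_labels, grp), 1)

  # siblings at high sibling correlation co-cluster most of the time
  cohort <- generate_cohort(small_cohort_config(
    seed = 78, n_families = 40L, sibling_correlation = 0.8, K_true = 3L))
  models <- fit_cohort(cohort, K = 3, seed = 79)
  att3 <- pool_topics(models, cohort$omics$shared_samples)
  sc3 <- cluster_samples(att3, 2, metadata = cohort$metadata)
  expect_gte(sc3$sibling_coclustering_rate, 0.85)
})
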