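test_that("self-comparison drives all three fit metrics to 1", {
  sim <- make_lda_data(D = 15, V = 20, K = 2, N_d = 100, seed = 51)
  m <- fit_lda_gibbs(sim$table, K = 2, n_iterations = 60, burn_in = 20,
                     thin = 2, seed = 52)
  identity_sim <- function(model, depths, seed) sim$table
  met <- fit_metrics(sim$table, m, n_simulations = 2, seed = 1,
                     simulator = identity_sim)
  expect_equal(unname(met), c(1, 1, 1), tolerance = 1e-12)
})

test_that("unrelated tables give near-zero pairwise-marginal correlation", {
  simA <- make_lda_data(D = 50, V = 100, K = 3, N_d = 400, seed = 53)
  m <- fit_lda_gibbs(simA$table, K = 3, n_iterations = 80, burn_in = 30,
                     thin = 2, seed = 54)
  unrelated <- function(model, depths, seed) {
    make_lda_data(D = 50, V = 100, K = 3, N_d = 400, seed = 1000 + seed)$table
  }
  met <- fit_metrics(simA$table, m, n_simulations = 3, seed = 55,
                     simulator = unrelated)
  expect_lt(abs(met[["pairwise_marginal_corr"]]), 0.1)
})

test_that("metrics match a direct formula evaluation and are permutation-invariant", {
  set.seed(56)
  obs <- matrix(rpois(9, 10) + 1, 3, 3,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  per <- obs[c(2, 3, 1), c(3, 1, 2)]
  dimnames(per) <- dimnames(obs)
  obs_t <- count_table(obs, is_discrete = TRUE)
  m <- fit_lda_gibbs(obs_t, K = 2, n_iterations = 40, burn_in = 10,
                     thin = 2, seed = 57)
  stub <- function(model, depths, seed) count_table(per, is_discrete = TRUE)
  met <- fit_metrics(obs_t, m, n_simulations = 1, seed = 1, simulator = stub)

  # direct evaluation of the three formulas
  probs <- seq(0.01, 0.99, 0.01)
  qs <- function(mat, mar) as.numeric(apply(mat, mar, quantile, probs = probs,
                                            names = FALSE))
  tri <- function(mat) { r <- cor(t(mat)); r[upper.tri(r)] }
  expect_equal(met[["sample_quantile_corr"]], cor(qs(obs, 2), qs(per, 2)))
  expect_equal(met[["feature_quantile_corr"]], cor(qs(obs, 1), qs(per, 1)))
  expect_equal(met[["pairwise_marginal_corr"]], cor(tri(obs), tri(per)))

  # identical permutation of observed and simulated tables leaves the
  # metrics unchanged (fixed simulated table via a stub)
  sim2 <- make_lda_data(D = 12, V = 15, K = 2, N_d = 150, seed = 58)
  m2 <- fit_lda_gibbs(sim2$table, K = 2, n_iterations = 60, burn_in = 20,
                      thin = 2, seed = 59)
  fixed_sim <- simulate_counts(m2, colSums(sim2$table$values), seed = 60)
  met_a <- fit_metrics(sim2$table, m2, n_simulations = 1, seed = 1,
                       simulator = function(model, depths, seed) fixed_sim)
  pf <- sample(15); ps <- sample(12)
  perm_tab <- count_table(sim2$table$values[pf, ps], is_discrete = TRUE)
  perm_sim <- count_table(fixed_sim$values[pf, ps], is_discrete = TRUE)
  m2p <- m2
  m2p$beta <- m2$beta[, pf]
  m2p$theta <- m2$theta[ps, ]
  m2p$feature_ids <- m2$feature_ids[pf]
  m2p$sample_ids <- m2$sample_ids[ps]
  met_b <- fit_metrics(perm_tab, m2p, n_simulations = 1, seed = 1,
                       simulator = function(model, depths, seed) perm_sim)
  expect_equal(met_a, met_b, tolerance = 1e-10)
})

test_that("the elbow rule picks the smallest candidate within tolerance", {
  mk <- function(pm, sq = NULL, fq = NULL) {
    data.frame(K = seq_along(pm) + 1L, sample_quantile_corr = sq %||% pm,
               feature_quantile_corr = fq %||% pm,
               pairwise_marginal_corr = pm)
  }
  # flat metrics -> smallest K
  expect_equal(select_k(mk(rep(0.9, 4)))$K, 2L)
  # the worked gap example: K=4 is the first within 2% of 0.935
  sel <- select_k(mk(c(0.50, 0.80, 0.92, 0.93, 0.935),
                     sq = rep(0.9, 5), fq = rep(0.9, 5)),
                  rel_tolerance = 0.02)
  expect_equal(sel$K, 4L)
  expect_true(sel$strict)
  # conjunction unsatisfiable -> pairwise-marginal-only fallback
  sel2 <- select_k(mk(c(0.5, 0.92, 0.93), sq = c(0.99, 0.5, 0.5),
                      fq = c(0.99, 0.5, 0.5)), rel_tolerance = 0.02)
  expect_equal(sel2$K, 3L)
  expect_false(sel2$strict)
  expect_error(select_k(mk(0.9)), "2 candidate")
})

test_that("pairwise-marginal fit improves up to the true K on synthetic data", {
  sim <- make_lda_data(D = 60, V = 40, K = 3, N_d = 300, seed = 61)
  diag_ <- fit_diagnostics(sim$table, candidate_ks = 1:3, n_simulations = 3,
                           seed = 62, alpha = 0.5, gamma = 0.1,
                           n_iterations = 300, burn_in = 100, thin = 5)
  pm <- diag_$metrics$pairwise_marginal_corr
  expect_gt(cor(seq_along(pm), pm, method = "spearman"), 0)
})
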