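# Shared fixtures and oracles, built in code at test time.

# Draw a small table from a known LDA truth; returns table + truth.
make_lda_data <- function(D, V, K, N_d, alpha = 0.5, gamma = 0.1, seed = 1) {
  set.seed(seed)
  theta <- matrix(rgamma(D * K, alpha), D, K)
  theta <- theta / rowSums(theta)
  beta <- matrix(rgamma(K * V, gamma), K, V)
  beta <- beta / rowSums(beta)
  probs <- theta %*% beta
  counts <- vapply(seq_len(D),
                   function(d) as.integer(rmultinom(1L, N_d, probs[d, ])),
                   integer(V))
  tab <- count_table(counts, omic_name = "sim", is_discrete = TRUE)
  list(table = tab, theta = theta, beta = beta)
}

# All permutations of 1..n (n <= 6); used for brute-force bipartite matching.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# Mean cosine similarity between rows of A and the best-matching rows of B,
# maximised over row permutations of B (independent label-switching oracle).
best_match_cosine <- function(A, B) {
  K <- nrow(A)
  cossim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  S <- outer(seq_len(K), seq_len(K),
             Vectorize(function(i, j) cossim(A[i, ], B[j, ])))
  perms <- all_perms(K)
  max(vapply(perms, function(p) mean(S[cbind(seq_len(K), p)]), numeric(1)))
}

# Match fitted topics to true topics by theta-column cosine (greedy-free,
# exhaustive over permutations); returns the permutation p with fitted k
# matching true p[k].
match_topics <- function(theta_fit, theta_true) {
  K <- ncol(theta_fit)
  cossim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  S <- outer(seq_len(K), seq_len(K),
             Vectorize(function(i, j) cossim(theta_fit[, i], theta_true[, j])))
  perms <- all_perms(K)
  scores <- vapply(perms, function(p) mean(S[cbind(seq_len(K), p)]),
                   numeric(1))
  unlist(perms[[which.max(scores)]])
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  # closed-form fallback
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab); si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Small multi-omic cohort config for fast cross-omic tests.
small_cohort_config <- function(seed = 1, n_families = 30L, K_true = 4L,
                                shared_theta = TRUE, V = 80L, N_d = 1000L,
                                sibling_correlation = 0.5, ...) {
  generator_config(
    n_families = n_families,
    omic_specs = list(A = list(V = V, N_d = N_d),
                      B = list(V = V, N_d = N_d),
                      C = list(V = V, N_d = N_d)),
    K_true = K_true, shared_theta = shared_theta,
    sibling_correlation = sibling_correlation, seed = seed, ...)
}

# Quick Gibbs settings for cohort-scale fits in tests.
fast_fit <- function(table, K, seed = 1, ...) {
  fit_lda_gibbs(table, K = K, alpha = 50 / K, gamma = 0.1,
                n_iterations = 400L, burn_in = 150L, thin = 5L,
                seed = seed, drop_empty = TRUE, ...)
}

# Discretize + fit all omics of a generated cohort at K.
fit_cohort <- function(cohort, K, seed = 1) {
  models <- list()
  for (nm in names(cohort$omics$tables)) {
    disc <- normalize_log_discretize(cohort$omics$tables[[nm]])$discretized
    models[[nm]] <- fast_fit(disc, K, seed = seed + match(nm, names(cohort$omics$tables)))
  }
  models
}

`%||%` <- function(a, b) if (is.null(a)) b else a
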