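#' Posterior-predictive fit metrics for a topic model
#'
#' Simulates tables from the model at the observed per-sample depths and
#' compares them with the observed table using three correlations:
#' \describe{
#'   \item{sample_quantile_corr}{per-sample 1st-99th percentiles of the
#'     feature-count vector, concatenated over samples; Pearson correlation
#'     between observed and simulated.}
#'   \item{feature_quantile_corr}{the same with features and samples
#'     swapped.}
#'   \item{pairwise_marginal_corr}{Pearson correlation between the
#'     upper-triangle entries of the feature-feature correlation matrices of
#'     the observed and simulated tables ("correlation of feature
#'     correlations").}
#' }
#' Each metric is computed per simulation and averaged over
#' `n_simulations`.
#'
#' @param true_table the observed (discretized) [count_table()] the model
#'   was trained on.
#' @param model an `lda_model` over the same features and samples.
#' @param n_simulations number of simulated tables (default 5).
#' @param seed integer seed.
#' @param simulator simulation function `(model, depths, seed) ->
#'   count_table`; replaceable for testing.
#' @return named numeric triple.
#' @export
fit_metrics <- function(true_table, model, n_simulations = 5L, seed = 1L,
                        simulator = simulate_counts) {
  if (!setequal(feature_ids(true_table), model$feature_ids) ||
      !setequal(sample_ids(true_table), model$sample_ids))
    stop("model and table dimensions/identifiers do not match", call. = FALSE)
  obs <- true_table$values[model$feature_ids, model$sample_ids, drop = FALSE]
  depths <- colSums(obs)
  probs <- seq(0.01, 0.99, by = 0.01)

  q_concat <- function(mat, margin) {
    as.numeric(apply(mat, margin, stats::quantile, probs = probs,
                     names = FALSE))
  }
  cor_triangle <- function(mat) {
    r <- suppressWarnings(stats::cor(t(mat)))
    r[upper.tri(r)]
  }

  obs_sq <- q_concat(obs, 2L)
  obs_fq <- q_concat(obs, 1L)
  obs_tri <- cor_triangle(obs)

  acc <- matrix(NA_real_, n_simulations, 3L)
  for (s in seq_len(n_simulations)) {
    sim <- simulator(model, depths, seed = seed + s - 1L)
    simv <- sim$values[model$feature_ids, model$sample_ids, drop = FALSE]
    sim_tri <- cor_triangle(simv)
    ok <- is.finite(obs_tri) & is.finite(sim_tri)
    acc[s, ] <- c(
      stats::cor(obs_sq, q_concat(simv, 2L)),
      stats::cor(obs_fq, q_concat(simv, 1L)),
      stats::cor(obs_tri[ok], sim_tri[ok])
    )
  }
  c(sample_quantile_corr = mean(acc[, 1L]),
    feature_quantile_corr = mean(acc[, 2L]),
    pairwise_marginal_corr = mean(acc[, 3L]))
}

#' Fit-metric grid over candidate topic counts
#'
#' Fits one model per candidate K and scores it with [fit_metrics()].
#'
#' @param table discretized [count_table()].
#' @param candidate_ks ascending integer vector of topic counts.
#' @param n_simulations simulations per K.
#' @param seed integer seed (per-K seeds derived deterministically).
#' @param ... passed to [fit_lda_gibbs()] (alpha, gamma, iterations, ...).
#' @return A `fit_diagnostics`: list with `omic_name`, `metrics` (data
#'   frame, one row per K), `models` (fitted models, named by K), `seed`.
#' @export
fit_diagnostics <- function(table, candidate_ks, n_simulations = 5L,
                            seed = 1L, ...) {
  candidate_ks <- sort(unique(as.integer(candidate_ks)))
  rows <- vector("list", length(candidate_ks))
  models <- vector("list", length(candidate_ks))
  for (i in seq_along(candidate_ks)) {
    K <- candidate_ks[i]
    m <- fit_lda_gibbs(table, K = K, seed = seed + 17L * K, ...)
    met <- fit_metrics(table, m, n_simulations = n_simulations,
                       seed = seed + 1000L + K)
    rows[[i]] <- data.frame(K = K, t(met))
    models[[i]] <- m
  }
  names(models) <- candidate_ks
  structure(
    list(omic_name = table$omic_name, metrics = do.call(rbind, rows),
         models = models, n_simulations = n_simulations, seed = seed),
    class = "fit_diagnostics"
  )
}

#' Select the number of topics by the elbow rule
#'
#' Takes the smallest candidate K whose pairwise-marginal metric is within
#' `rel_tolerance` (relative) of that metric's maximum over all candidates
#' and whose two quantile metrics are within `2 * rel_tolerance` of their
#' maxima. The pairwise-marginal metric is prioritised: if no candidate
#' satisfies all three conditions, the smallest K within tolerance on the
#' pairwise-marginal metric alone is returned.
#'
#' @param diagnostics a `fit_diagnostics` (or its `metrics` data frame).
#' @param rel_tolerance relative tolerance (default 0.02).
#' @return list with `K`, `rationale` (per-K per-metric relative gaps), and
#'   `strict` (whether the conjunctive rule was satisfiable).
#' @export
select_k <- function(diagnostics, rel_tolerance = 0.02) {
  met <- if (inherits(diagnostics, "fit_diagnostics")) diagnostics$metrics
         else diagnostics
  if (is.null(met) || nrow(met) < 2L)
    stop("need metrics for at least 2 candidate topic counts", call. = FALSE)
  met <- met[order(met$K), , drop = FALSE]
  cols <- c("pairwise_marginal_corr", "sample_quantile_corr",
            "feature_quantile_corr")
  maxima <- vapply(cols, function(cl) max(met[[cl]]), numeric(1L))
  gap <- sapply(cols, function(cl) (maxima[cl] - met[[cl]]) / abs(maxima[cl]))
  gap <- matrix(gap, nrow = nrow(met), dimnames = list(met$K, cols))
  ok_pm <- gap[, 1L] <= rel_tolerance
  ok_all <- ok_pm & gap[, 2L] <= 2 * rel_tolerance &
    gap[, 3L] <= 2 * rel_tolerance
  strict <- any(ok_all)
  pick <- if (strict) which(ok_all)[1L] else which(ok_pm)[1L]
  list(K = met$K[pick], rationale = gap, strict = strict)
}
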