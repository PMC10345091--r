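#' Fit LDA by collapsed Gibbs sampling
#'
#' Treats samples as documents and omic features as words. Each discretized
#' count c(v, d) contributes c tokens of word v to document d; the sampler
#' sweeps the collapsed conditional
#' p(z = k) proportional to (n_dk + alpha) (n_kv + gamma) / (n_k + V gamma)
#' over all tokens. The returned theta (samples x topics) and beta
#' (topics x features) are posterior means of the smoothed count ratios,
#' averaged over post-burn-in sweeps.
#'
#' @param table a discrete [count_table()] (see [normalize_log_discretize()]).
#' @param K number of topics (K <= number of features).
#' @param alpha symmetric document-topic Dirichlet concentration
#'   (default 50/K).
#' @param gamma symmetric topic-word Dirichlet concentration (default 0.1).
#' @param n_iterations,burn_in,thin Gibbs schedule; `n_iterations` must
#'   exceed `burn_in`.
#' @param seed integer seed; fixed seed gives a bit-identical fit.
#' @param max_tokens cap on per-document tokens; documents above it are
#'   proportionally downscaled (memory bound).
#' @param drop_empty if `TRUE`, all-zero samples are dropped with a warning
#'   instead of raising an error (pipeline mode).
#' @param debug if `TRUE`, the sampler verifies its count caches after every
#'   sweep.
#' @return An `lda_model`: list with `omic_name`, `K`, `alpha`, `gamma`,
#'   `theta` (D x K, rows sum to 1), `beta` (K x V, rows sum to 1),
#'   `feature_ids`, `sample_ids`, `seed`, `n_iterations`, `burn_in`, `thin`.
#' @export
fit_lda_gibbs <- function(table, K, alpha = 50 / K, gamma = 0.1,
                          n_iterations = 2000L, burn_in = 500L, thin = 10L,
                          seed = 1L, max_tokens = 1e5, drop_empty = FALSE,
                          debug = FALSE) {
  stopifnot(inherits(table, "count_table"))
  v <- table$values
  if (!table$is_discrete || any(v != round(v)))
    stop("LDA requires a discretized count table; see normalize_log_discretize()",
         call. = FALSE)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > nrow(v))
    stop("K (", K, ") exceeds the number of features (", nrow(v), ")",
         call. = FALSE)
  if (n_iterations <= burn_in)
    stop("n_iterations must exceed burn_in", call. = FALSE)
  empty <- colSums(v) == 0
  if (any(empty)) {
    if (drop_empty) {
      warning("dropping all-zero sample(s): ",
              paste(colnames(v)[empty], collapse = ", "), call. = FALSE)
      v <- v[, !empty, drop = FALSE]
    } else {
      stop("all-zero sample(s) after discretization: ",
           paste(colnames(v)[empty], collapse = ", "), call. = FALSE)
    }
  }
  tot <- colSums(v)
  over <- tot > max_tokens
  if (any(over)) {
    v[, over] <- round(sweep(v[, over, drop = FALSE], 2L,
                             max_tokens / tot[over], "*"))
  }
  storage.mode(v) <- "integer"

  set.seed(seed)
  fit <- gibbs_lda_cpp(v, as.integer(K), alpha, gamma,
                       as.integer(n_iterations), as.integer(burn_in),
                       as.integer(thin), isTRUE(debug))
  theta <- fit$theta
  beta <- fit$beta
  dimnames(theta) <- list(colnames(v), paste0("topic", seq_len(K)))
  dimnames(beta) <- list(paste0("topic", seq_len(K)), rownames(v))
  structure(
    list(omic_name = table$omic_name, K = as.integer(K), alpha = alpha,
         gamma = gamma, theta = theta, beta = beta,
         feature_ids = rownames(v), sample_ids = colnames(v),
         seed = as.integer(seed), n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         n_saved = fit$n_saved, n_tokens = fit$n_tokens),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf(
    "lda_model '%s': K=%d, D=%d samples, V=%d features (alpha=%.3g, gamma=%.3g)\n",
    x$omic_name, x$K, nrow(x$theta), ncol(x$beta), x$alpha, x$gamma))
  invisible(x)
}

#' Simulate a count table from a fitted LDA model
#'
#' For each sample d, N_d tokens are drawn from the topic mixture: topic
#' z from Mult(theta_d), then word from Mult(beta_z) — realised as a single
#' multinomial over the mixed word distribution theta_d %*% beta. Column
#' sums equal `depths` exactly.
#'
#' @param model an `lda_model`.
#' @param depths per-sample token counts (length D).
#' @param seed integer seed.
#' @return A discrete [count_table()] with the model's feature/sample ids.
#' @export
simulate_counts <- function(model, depths, seed = 1L) {
  stopifnot(inherits(model, "lda_model"))
  D <- nrow(model$theta)
  if (length(depths) != D)
    stop("depths must have one entry per sample (", D, ")", call. = FALSE)
  if (any(depths < 1)) stop("depths must be positive", call. = FALSE)
  set.seed(seed)
  probs <- model$theta %*% model$beta  # D x V mixed word distributions
  out <- matrix(0L, ncol(model$beta), D,
                dimnames = list(model$feature_ids, model$sample_ids))
  for (d in seq_len(D)) {
    out[, d] <- as.integer(stats::rmultinom(1L, depths[d], probs[d, ]))
  }
  count_table(out, omic_name = model$omic_name, is_discrete = TRUE)
}

#' Token log-likelihood of a count table under a fitted model
#'
#' Sums count(v, d) * log(theta_d . beta_v) over all cells; used to compare
#' fits at different K on the same samples.
#'
#' @param model an `lda_model`.
#' @param table a [count_table()] with the model's features and samples.
#' @return scalar log-likelihood.
#' @export
lda_log_likelihood <- function(model, table) {
  v <- table$values[model$feature_ids, model$sample_ids, drop = FALSE]
  probs <- model$theta %*% model$beta  # D x V
  sum(t(v) * log(probs))
}

#' Save a fitted model as TSVs plus a JSON sidecar
#' @param model an `lda_model`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix (default the omic name).
#' @return the directory, invisibly.
#' @export
write_lda_model <- function(model, dir, prefix = model$omic_name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(model$theta, file.path(dir, paste0(prefix, "_theta.tsv")),
                   id_header = "sample_id")
  write_matrix_tsv(model$beta, file.path(dir, paste0(prefix, "_beta.tsv")),
                   id_header = "topic")
  meta <- model[c("omic_name", "K", "alpha", "gamma", "seed",
                  "n_iterations", "burn_in", "thin")]
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_model.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
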