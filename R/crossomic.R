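#' Pool topic attribution vectors across omics
#'
#' Extracts each model's per-sample topic attributions (theta columns)
#' restricted to the shared samples, stacking them into one topics-by-samples
#' matrix with row names `<omic>.t<k>`.
#'
#' @param models list of `lda_model` objects (named by omic or using their
#'   `omic_name`).
#' @param shared_samples sample ids present in every model (default: the
#'   intersection, lexicographically ordered).
#' @param drop_topics optional character vector of row names (e.g.
#'   `"MTT.t3"`) to exclude, typically dominant uninformative topics.
#' @return matrix (total topics x shared samples).
#' @export
pool_topics <- function(models, shared_samples = NULL, drop_topics = NULL) {
  stopifnot(length(models) >= 1L)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "omic_name")
  if (is.null(shared_samples)) {
    shared_samples <- Reduce(intersect, lapply(models, `[[`, "sample_ids"))
    shared_samples <- sort(shared_samples, method = "radix")
  }
  if (length(shared_samples) == 0L)
    stop("models share no samples", call. = FALSE)
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    th <- t(m$theta[shared_samples, , drop = FALSE])
    rownames(th) <- sprintf("%s.t%d", nm, seq_len(m$K))
    th
  })
  att <- do.call(rbind, rows)
  if (!is.null(drop_topics))
    att <- att[setdiff(rownames(att), drop_topics), , drop = FALSE]
  att
}

#' Spearman correlation matrix between topics, with p-values
#'
#' Average-rank ties; p-values from the t approximation with n - 2 degrees
#' of freedom.
#'
#' @param attribution topics-by-samples matrix (see [pool_topics()]).
#' @return list with `rho` (diagonal 1) and `p` (diagonal NA).
#' @export
topic_correlation_matrix <- function(attribution) {
  n <- ncol(attribution)
  if (n < 4L)
    stop("need at least 4 shared samples for Spearman p-values",
         call. = FALSE)
  rho <- suppressWarnings(stats::cor(t(attribution), method = "spearman"))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  r <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  list(rho = rho, p = p, n = n)
}

.ratio_score <- function(dm, labels) {
  ks <- sort(unique(labels))
  ratios <- vapply(ks, function(k) {
    inside <- which(labels == k)
    outside <- which(labels != k)
    within <- if (length(inside) < 2L) 0 else {
      mean(dm[inside, inside][upper.tri(diag(length(inside)))])
    }
    if (length(outside) == 0L) return(NA_real_)
    between <- mean(dm[inside, outside, drop = FALSE])
    if (between == 0) return(NA_real_)
    within / between
  }, numeric(1L))
  mean(ratios, na.rm = TRUE)
}

#' Cluster pooled topics into cross-omic topics
#'
#' Hierarchical clustering (average linkage) of topic attribution vectors.
#' For each candidate cluster count n and each metric, the score is the mean
#' over clusters of (mean within-cluster pairwise distance) / (mean distance
#' from cluster members to all non-members); scores are averaged over the
#' metrics and the smallest n whose score is within `rel_tolerance` of the
#' minimum is selected. Final labels at the selected n come from the
#' Spearman-correlation tree (distance 1 - rho), matching the convention of
#' clustering topics by their correlation across samples; per-metric labels
#' are also returned.
#'
#' @param attribution topics-by-samples matrix (see [pool_topics()]).
#' @param n_range candidate cluster counts (subset of 2..n_topics-1).
#' @param metrics distance metrics for the score grid.
#' @param rel_tolerance relative slack on the minimum score (default 0.05).
#' @return A `crossomic_assignment`: list with `cluster_labels`,
#'   `n_clusters`, `ratio_grid` (n x metric), `score` (per n),
#'   `correlation` ([topic_correlation_matrix()] output),
#'   `labels_per_metric`, `attribution`.
#' @export
cluster_topics <- function(attribution, n_range = NULL,
                           metrics = c("manhattan", "euclidean",
                                       "inverse_correlation"),
                           rel_tolerance = 0.05) {
  nt <- nrow(attribution)
  if (nt < 2L) stop("need at least 2 topics", call. = FALSE)
  if (is.null(n_range)) n_range <- 2:max(2L, nt - 1L)
  n_range <- sort(unique(as.integer(n_range)))
  if (length(n_range) == 0L || min(n_range) < 2L || max(n_range) > nt)
    stop("n_range must lie in [2, n_topics]", call. = FALSE)

  trees <- lapply(metrics, function(met) {
    dm <- sample_distance_matrix(t(attribution), met)
    list(dm = dm, tree = stats::hclust(stats::as.dist(dm),
                                       method = "average"))
  })
  names(trees) <- metrics

  grid <- matrix(NA_real_, length(n_range), length(metrics),
                 dimnames = list(n_range, metrics))
  labels_per_metric <- list()
  for (met in metrics) {
    cuts <- stats::cutree(trees[[met]]$tree, k = n_range)
    cuts <- matrix(cuts, nrow = nt)
    for (i in seq_along(n_range))
      grid[i, met] <- .ratio_score(trees[[met]]$dm, cuts[, i])
    labels_per_metric[[met]] <- cuts
  }
  score <- rowMeans(grid)
  lo <- min(score)
  sel_i <- which(score <= lo + rel_tolerance * abs(lo) + 1e-15)[1L]
  n_sel <- n_range[sel_i]

  corr <- topic_correlation_matrix(attribution)
  sp_tree <- stats::hclust(stats::as.dist(1 - corr$rho), method = "average")
  labels <- stats::cutree(sp_tree, k = n_sel)
  names(labels) <- rownames(attribution)

  structure(
    list(cluster_labels = labels, n_clusters = n_sel,
         ratio_grid = grid, score = stats::setNames(score, n_range),
         correlation = corr, labels_per_metric = labels_per_metric,
         attribution = attribution, tree = sp_tree,
         rel_tolerance = rel_tolerance),
    class = "crossomic_assignment"
  )
}

#' @export
print.crossomic_assignment <- function(x, ...) {
  cat(sprintf("crossomic_assignment: %d topics -> %d clusters (score %.4g)\n",
              nrow(x$attribution), x$n_clusters,
              x$score[as.character(x$n_clusters)]))
  invisible(x)
}

.count_significant_within <- function(attribution, labels, alpha = 0.05) {
  corr <- topic_correlation_matrix(attribution)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(same)
  sum(same[ut] & corr$p[ut] < alpha, na.rm = TRUE)
}

#' Build one multinomial null count table
#'
#' Each sample's column is drawn from a multinomial whose total equals the
#' sample's original total and whose probabilities are the empirical feature
#' distribution of a uniformly chosen *other* sample (of the same omic).
#'
#' @param table a discrete [count_table()].
#' @param seed integer seed.
#' @param resample_self if `TRUE`, each sample is resampled from its own
#'   distribution (diagnostic mode: preserves per-sample expectations).
#' @return a discrete [count_table()] with the same ids and column sums.
#' @export
null_count_table <- function(table, seed = 1L, resample_self = FALSE) {
  v <- table$values
  D <- ncol(v)
  set.seed(seed)
  out <- v
  for (d in seq_len(D)) {
    donor <- if (resample_self) d else {
      pool <- setdiff(seq_len(D), d)
      pool[sample.int(length(pool), 1L)]
    }
    p <- v[, donor]
    if (sum(p) == 0) stop("all-zero donor sample", call. = FALSE)
    out[, d] <- stats::rmultinom(1L, sum(v[, d]), p / sum(p))
  }
  count_table(out, omic_name = table$omic_name, is_discrete = TRUE)
}

#' Validate cross-omic correlation structure against a multinomial null
#'
#' Generates `n_tables` null versions of every omic table, refits LDA per
#' omic with the same K/alpha/gamma/schedule/seed as the true fits, clusters
#' the pooled null topics into the same number of clusters as the true data,
#' and counts within-cluster topic pairs with Spearman p < `alpha`. The true
#' data's count is compared with the null distribution.
#'
#' @param omics an `omic_set` of *discretized* tables (the LDA training
#'   space).
#' @param models list of `lda_model` objects, one per omic table (same
#'   order/names).
#' @param n_clusters number of cross-omic clusters to use (default: selected
#'   from the true data by [cluster_topics()]).
#' @param n_tables number of null tables (default 15).
#' @param seed integer seed for null-table draws.
#' @param alpha significance level for the Spearman count (default 0.05,
#'   uncorrected).
#' @param drop_topics passed to [pool_topics()] for the true data.
#' @return A `null_ensemble_report`: list with `true_count`, `null_counts`,
#'   `n_clusters`, `n_tables`, `seed`, `exceeds_all`.
#' @export
null_validation <- function(omics, models, n_clusters = NULL, n_tables = 15L,
                            seed = 1L, alpha = 0.05, drop_topics = NULL) {
  if (n_tables < 2L) stop("n_tables must be >= 2", call. = FALSE)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "omic_name")
  shared <- omics$shared_samples
  att_true <- pool_topics(models, shared, drop_topics = drop_topics)
  if (is.null(n_clusters)) {
    n_clusters <- cluster_topics(att_true)$n_clusters
  }
  cl_true <- stats::cutree(
    stats::hclust(stats::as.dist(1 - topic_correlation_matrix(att_true)$rho),
                  method = "average"), k = n_clusters)
  true_count <- .count_significant_within(att_true, cl_true, alpha)

  null_counts <- integer(n_tables)
  for (t in seq_len(n_tables)) {
    null_models <- lapply(names(models), function(nm) {
      m <- models[[nm]]
      nt <- null_count_table(omics$tables[[nm]],
                             seed = seed + 7919L * t +
                               match(nm, names(models)))
      fit_lda_gibbs(nt, K = m$K, alpha = m$alpha, gamma = m$gamma,
                    n_iterations = m$n_iterations, burn_in = m$burn_in,
                    thin = m$thin, seed = m$seed, drop_empty = TRUE)
    })
    names(null_models) <- names(models)
    att_null <- pool_topics(null_models,
                            intersect(shared,
                                      Reduce(intersect,
                                             lapply(null_models, `[[`,
                                                    "sample_ids"))))
    cl_null <- stats::cutree(
      stats::hclust(stats::as.dist(
        1 - topic_correlation_matrix(att_null)$rho), method = "average"),
      k = min(n_clusters, nrow(att_null) - 1L))
    null_counts[t] <- .count_significant_within(att_null, cl_null, alpha)
  }
  structure(
    list(true_count = true_count, null_counts = null_counts,
         n_clusters = n_clusters, n_tables = n_tables, seed = seed,
         alpha = alpha, exceeds_all = true_count > max(null_counts)),
    class = "null_ensemble_report"
  )
}

#' @export
print.null_ensemble_report <- function(x, ...) {
  cat(sprintf(
    "null_ensemble_report: true within-cluster significant count %d vs null [%d, %d] over %d tables\n",
    x$true_count, min(x$null_counts), max(x$null_counts), x$n_tables))
  invisible(x)
}

#' Flag dominant uninformative topics
#'
#' A topic is flagged when its total attributable weight across samples
#' (theta column sum) is at least `attribution_ratio_threshold` times the
#' next-largest topic's total *and* no feature attributed to it passes both
#' interpretation criteria — the signature of an over-attributed topic that
#' does not discriminate between samples.
#'
#' @param model an `lda_model`.
#' @param feature_report a `feature_attribution_report` from
#'   [select_topic_features()] for this model's beta.
#' @param attribution_ratio_threshold dominance ratio (default 10).
#' @return integer vector of flagged topic indices (possibly empty).
#' @export
flag_dominant_topic <- function(model, feature_report,
                                attribution_ratio_threshold = 10) {
  if (model$K < 2L) return(integer())
  totals <- colSums(model$theta)
  ord <- order(totals, decreasing = TRUE)
  flagged <- integer()
  top <- ord[1L]
  if (totals[top] >= attribution_ratio_threshold * totals[ord[2L]]) {
    attributed <- feature_report$features$topic_index[
      feature_report$features$passed_sd_criterion &
        feature_report$features$passed_svd_criterion]
    if (!top %in% attributed) flagged <- top
  }
  flagged
}

#' Cluster samples by their topic distribution
#'
#' Samples are represented by their concatenated topic attributions across
#' omics; pairwise distance is 1 - Pearson correlation; complete-linkage
#' hierarchical clustering is cut at `n_clusters`. When metadata is given,
#' the sibling co-clustering rate (fraction of two-sample families whose
#' members land in the same cluster) is reported.
#'
#' @param attribution topics-by-samples matrix (see [pool_topics()]).
#' @param n_clusters number of sample clusters (default 2).
#' @param metadata optional `sample_metadata`.
#' @return A `sample_clustering`: list with `cluster_labels` (named by
#'   sample), `n_clusters`, `linkage`, `tree`, and
#'   `sibling_coclustering_rate` (NA without metadata).
#' @export
cluster_samples <- function(attribution, n_clusters = 2L, metadata = NULL) {
  if (ncol(attribution) < n_clusters)
    stop("fewer samples than requested clusters", call. = FALSE)
  dm <- sample_distance_matrix(attribution, "inverse_correlation")
  tree <- stats::hclust(stats::as.dist(dm), method = "complete")
  labels <- stats::cutree(tree, k = n_clusters)
  names(labels) <- colnames(attribution)
  rate <- NA_real_
  if (!is.null(metadata)) {
    meta <- metadata[match(names(labels), metadata$sample_id), ]
    fams <- split(labels, meta$family_id)
    pairs <- Filter(function(x) length(x) == 2L, fams)
    if (length(pairs))
      rate <- mean(vapply(pairs, function(x) x[1L] == x[2L], logical(1L)))
  }
  structure(
    list(cluster_labels = labels, n_clusters = n_clusters,
         linkage = "complete", tree = tree,
         sibling_coclustering_rate = rate),
    class = "sample_clustering"
  )
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("sample_clustering: %d samples -> %d clusters",
              length(x$cluster_labels), x$n_clusters))
  if (!is.na(x$sibling_coclustering_rate))
    cat(sprintf("; sibling co-clustering rate %.2f",
                x$sibling_coclustering_rate))
  cat("\n")
  invisible(x)
}
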