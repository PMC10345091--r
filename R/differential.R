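#' One shadow-feature importance trial
#'
#' Implements one round of the shadow-feature (Boruta-style) screen: the
#' table is extended with an independently permuted shadow copy of every
#' feature, a random-forest classifier is fit on phenotype `n_runs` times,
#' and permutation importance (mean decrease in out-of-bag accuracy) is
#' collected per column and run. Each column's Z score is its mean
#' importance divided by its SD across runs; a feature is "important" when
#' its Z exceeds the maximum Z over all shadow columns.
#'
#' The shadow permutation is drawn once per trial (runs differ only in the
#' forest randomness), so under a global null the features and their shadows
#' are exchangeable and the max-shadow rule is conservative: each feature
#' beats all F shadows with probability about 1/(F + 1). Fresh shadows are
#' drawn on every call, so repeated trials (see [tally_and_test()]) average
#' over shadow permutations.
#'
#' @param values numeric feature-by-sample matrix (normalized log-scale
#'   values, not the discretized LDA input).
#' @param labels phenotype per sample (`"case"`/`"control"`, character or
#'   factor, both classes with >= 3 samples).
#' @param n_runs random-forest fits per trial (default 100).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed.
#' @return logical vector named by feature, with attributes `z`
#'   (per-feature Z) and `max_shadow_z`.
#' @export
boruta_trial <- function(values, labels, n_runs = 100L, n_trees = 500L,
                         seed = 1L) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  if (min(table(labels)) < 3L)
    stop("each phenotype class needs >= 3 samples", call. = FALSE)
  F_ <- nrow(values)
  feat_names <- rownames(values)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(F_))

  set.seed(seed)
  shadows <- t(apply(values, 1L, sample))
  X <- cbind(t(values), t(shadows))
  colnames(X) <- c(paste0("f", seq_len(F_)), paste0("sh", seq_len(F_)))
  imp <- matrix(NA_real_, n_runs, 2L * F_)
  for (r in seq_len(n_runs)) {
    fit <- ranger::ranger(
      x = as.data.frame(X), y = labels, num.trees = n_trees,
      importance = "permutation",
      seed = sample.int(.Machine$integer.max, 1L),
      num.threads = 1L, verbose = FALSE)
    imp[r, ] <- fit$variable.importance
  }
  mu <- colMeans(imp)
  sdv <- apply(imp, 2L, stats::sd)
  z <- ifelse(sdv < 1e-12, 0, mu / sdv)
  feat_z <- z[seq_len(F_)]
  max_shadow <- max(z[F_ + seq_len(F_)])
  out <- feat_z > max_shadow
  names(out) <- feat_names
  attr(out, "z") <- stats::setNames(feat_z, feat_names)
  attr(out, "max_shadow_z") <- max_shadow
  out
}

#' Repeated shadow-feature tally followed by Wilcoxon/BH testing
#'
#' Runs [boruta_trial()] `n_repeats` times with derived seeds and tallies
#' how often each feature is deemed important. Features with a tally at or
#' above the `percentile_cut` percentile of all tallies (linear
#' interpolation; ties at the cut included) are passed to a two-sided
#' Wilcoxon rank-sum test between the phenotype groups (exact for small
#' tie-free groups, normal approximation with continuity correction
#' otherwise), and Benjamini-Hochberg adjustment is applied over the
#' survivor set only.
#'
#' @inheritParams boruta_trial
#' @param n_repeats tally repetitions (default 100).
#' @param percentile_cut tally percentile for the filter (default 90).
#' @param alpha reporting threshold on the BH-adjusted p (default 0.05).
#' @param cluster_id optional label recorded in the report.
#' @return A `differential_report`: list with `table` (survivors: feature,
#'   tally, tally_percentile, statistic, p, p_adj, direction, reported),
#'   `tallies` (all features), `n_repeats`, `alpha`, `cluster_id`.
#'   An empty survivor set yields an empty table, not an error.
#' @export
tally_and_test <- function(values, labels, n_repeats = 100L, n_runs = 100L,
                           n_trees = 500L, percentile_cut = 90,
                           alpha = 0.05, seed = 1L, cluster_id = NA) {
  labels <- factor(as.character(labels))
  tally <- integer(nrow(values))
  for (rep_i in seq_len(n_repeats)) {
    flags <- boruta_trial(values, labels, n_runs = n_runs,
                          n_trees = n_trees, seed = seed + 104729L * rep_i)
    tally <- tally + as.integer(flags)
  }
  names(tally) <- rownames(values)
  cut <- stats::quantile(tally, probs = percentile_cut / 100, names = FALSE)
  survivors <- which(tally >= cut & tally > 0L)

  if (length(survivors) == 0L) {
    message("no features survived the importance filter")
    tab <- data.frame(feature_id = character(), tally = integer(),
                      tally_percentile = numeric(), statistic = numeric(),
                      p = numeric(), p_adj = numeric(),
                      direction = integer(), reported = logical())
  } else {
    is_case <- labels == levels(labels)[match("case", levels(labels),
                                              nomatch = 1L)]
    if ("case" %in% levels(labels)) is_case <- labels == "case"
    rows <- lapply(survivors, function(fi) {
      x <- values[fi, is_case]
      y <- values[fi, !is_case]
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                                correct = TRUE))
      data.frame(feature_id = names(tally)[fi], tally = tally[fi],
                 tally_percentile = mean(tally <= tally[fi]) * 100,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 direction = sign(stats::median(x) - stats::median(y)))
    })
    tab <- do.call(rbind, rows)
    tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
    tab$reported <- tab$p_adj < alpha
    tab <- tab[order(tab$p_adj, tab$p), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(
    list(table = tab, tallies = tally, n_repeats = n_repeats,
         percentile_cut = percentile_cut, alpha = alpha,
         cluster_id = cluster_id, seed = seed),
    class = "differential_report"
  )
}

#' @export
print.differential_report <- function(x, ...) {
  cat(sprintf(
    "differential_report%s: %d survivors, %d reported at BH-adjusted p < %.2g\n",
    if (is.na(x$cluster_id)) "" else paste0(" [cluster ", x$cluster_id, "]"),
    nrow(x$table), sum(x$table$reported), x$alpha))
  invisible(x)
}

#' Differential testing within each sample cluster
#'
#' Applies [tally_and_test()] separately within each sample cluster, per
#' omic, on normalized log-scale values.
#'
#' @param normalized a `normalized_table` (its `log2` stage is used).
#' @param metadata `sample_metadata` with phenotype labels.
#' @param clustering a `sample_clustering` from [cluster_samples()].
#' @param ... passed to [tally_and_test()].
#' @return named list of `differential_report`s, one per cluster (clusters
#'   lacking both phenotypes are skipped with a message).
#' @export
differential_by_cluster <- function(normalized, metadata, clustering, ...) {
  vals <- normalized$log2
  labels_all <- metadata$phenotype[match(colnames(vals),
                                         metadata$sample_id)]
  out <- list()
  for (cl in sort(unique(clustering$cluster_labels))) {
    ids <- names(clustering$cluster_labels)[clustering$cluster_labels == cl]
    ids <- intersect(ids, colnames(vals))
    lab <- labels_all[match(ids, colnames(vals))]
    if (length(unique(lab)) < 2L || min(table(lab)) < 3L) {
      message("cluster ", cl, ": not enough samples in both phenotypes; skipped")
      next
    }
    out[[as.character(cl)]] <- tally_and_test(
      vals[, ids, drop = FALSE], lab, cluster_id = cl, ...)
  }
  out
}
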