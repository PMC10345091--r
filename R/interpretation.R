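#' Select the features that define each topic
#'
#' Dual criterion on the topic-feature matrix beta:
#' \enumerate{
#'   \item Specificity: feature v passes when its maximum weight over topics
#'     exceeds the median weight by more than 1.5 sample standard deviations
#'     (computed over the K weights) — excluding features ubiquitous across
#'     topics.
#'   \item Drivers: singular value decomposition of the column-centered
#'     beta; feature v passes when the absolute value of its loading on any
#'     of the top K - 1 right-singular axes exceeds the given percentile of
#'     absolute loadings on that axis — keeping the features that drive
#'     between-topic variation.
#' }
#' Reported features pass both criteria and are attributed to their argmax
#' topic.
#'
#' @param beta K x V row-stochastic matrix (K >= 2), columns named by
#'   feature.
#' @param percentile loading percentile in (0, 100); the convention is 99
#'   for tables on the 16S/metabolite scale and 99.9 for the larger
#'   KO tables.
#' @param sd_multiplier specificity multiplier (default 1.5).
#' @return A `feature_attribution_report`: list with `features` (data frame
#'   over all features: `feature_id`, `topic_index`, `weight`,
#'   `passed_sd_criterion`, `passed_svd_criterion`), `selected` (the
#'   passing subset), `percentile`, `sd_multiplier`.
#' @export
select_topic_features <- function(beta, percentile = 99,
                                  sd_multiplier = 1.5) {
  K <- nrow(beta)
  if (K < 2L)
    stop("need K >= 2 topics (SD over one value is undefined)",
         call. = FALSE)
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)", call. = FALSE)
  V <- ncol(beta)
  if (is.null(colnames(beta))) colnames(beta) <- paste0("f", seq_len(V))

  mx <- apply(beta, 2L, max)
  med <- apply(beta, 2L, stats::median)
  sdv <- apply(beta, 2L, stats::sd)
  pass_sd <- mx > med + sd_multiplier * sdv

  centered <- sweep(beta, 2L, colMeans(beta))
  sv <- svd(centered, nu = 0L, nv = min(K - 1L, V))
  n_axes <- min(K - 1L, ncol(sv$v))
  pass_svd <- rep(FALSE, V)
  for (a in seq_len(n_axes)) {
    load <- abs(sv$v[, a])
    cut <- stats::quantile(load, probs = percentile / 100, names = FALSE)
    pass_svd <- pass_svd | (load > cut)
  }

  features <- data.frame(
    feature_id = colnames(beta),
    topic_index = apply(beta, 2L, which.max),
    weight = mx,
    passed_sd_criterion = pass_sd,
    passed_svd_criterion = pass_svd,
    row.names = NULL
  )
  structure(
    list(features = features,
         selected = features[pass_sd & pass_svd, , drop = FALSE],
         percentile = percentile, sd_multiplier = sd_multiplier),
    class = "feature_attribution_report"
  )
}

#' @export
print.feature_attribution_report <- function(x, ...) {
  cat(sprintf(
    "feature_attribution_report: %d of %d features pass both criteria (percentile %.1f)\n",
    nrow(x$selected), nrow(x$features), x$percentile))
  invisible(x)
}

#' Correlate topic attributions with metadata covariates
#'
#' Spearman correlation between each topic's per-sample attribution and each
#' covariate, with a significance star at p < 0.05 (uncorrected, matching
#' exploratory topic-metadata heat maps). Missing covariate values are
#' dropped pairwise.
#'
#' @param attribution topics-by-samples matrix (see [pool_topics()]).
#' @param metadata `sample_metadata` covering the attribution's samples.
#' @param covariates covariate names (default: all covariates recorded in
#'   the metadata, plus `age` when present).
#' @return data frame with columns `topic`, `covariate`, `rho`, `p`,
#'   `significant`.
#' @export
topic_metadata_correlation <- function(attribution, metadata,
                                       covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- attr(metadata, "covariates")
    if ("age" %in% names(metadata)) covariates <- c("age", covariates)
  }
  meta <- metadata[match(colnames(attribution), metadata$sample_id), ,
                   drop = FALSE]
  rows <- list()
  for (cv in covariates) {
    x <- suppressWarnings(as.numeric(meta[[cv]]))
    if (all(is.na(x))) {
      warning("covariate '", cv, "' entirely missing or non-numeric; skipped",
              call. = FALSE)
      next
    }
    for (ti in seq_len(nrow(attribution))) {
      y <- attribution[ti, ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 4L) {
        warning("fewer than 4 complete pairs for topic '",
                rownames(attribution)[ti], "' vs '", cv, "'; skipped",
                call. = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        topic = rownames(attribution)[ti], covariate = cv,
        rho = unname(ct$estimate), p = ct$p.value,
        significant = ct$p.value < 0.05)
    }
  }
  do.call(rbind, rows)
}
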