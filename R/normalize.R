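#' Median-of-ratios (RLE) size factors
#'
#' The size factor of sample d is the median, over reference features, of the
#' ratio of the sample's count to the feature's geometric mean across samples
#' — the estimator used by the RLE / DESeq family of normalizations. The
#' reference set is the features with strictly positive counts in every
#' sample; when that set is empty (sparse omics), features positive in at
#' least `fallback_prevalence` of samples are used instead, with geometric
#' means taken over their positive entries only.
#'
#' @param table a [count_table()].
#' @param fallback_prevalence fraction of samples in which a feature must be
#'   positive to enter the fallback reference set (default 0.9).
#' @return named positive numeric vector of per-sample size factors.
#' @export
rle_size_factors <- function(table, fallback_prevalence = 0.9) {
  v <- table$values
  all_pos <- rowSums(v > 0) == ncol(v)
  if (any(all_pos)) {
    ref <- v[all_pos, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
  } else {
    prev <- rowMeans(v > 0)
    keep <- prev >= fallback_prevalence
    if (!any(keep))
      stop("no reference features: none positive in >= ",
           round(100 * fallback_prevalence),
           "% of samples; lower fallback_prevalence or filter features",
           call. = FALSE)
    ref <- v[keep, , drop = FALSE]
    geo <- exp(apply(ref, 1L, function(x) mean(log(x[x > 0]))))
  }
  sf <- apply(ref, 2L, function(col) {
    r <- col / geo
    stats::median(r[col > 0])
  })
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("non-positive size factor; sample(s): ",
         paste(colnames(v)[!is.finite(sf) | sf <= 0], collapse = ", "),
         call. = FALSE)
  sf
}

#' Normalize, log-transform and discretize a count table
#'
#' Divides each sample by its size factor, applies log2(x + 1), and rounds
#' half-to-even to integers — the count-space input the Gibbs sampler needs.
#' Both the continuous log stage and the discrete stage are retained.
#'
#' @param table a [count_table()].
#' @param factors per-sample positive size factors; default from
#'   [rle_size_factors()].
#' @return A `normalized_table`: list with `source`, `size_factors`,
#'   `normalized` (counts/factor), `log2` (log2(normalized + 1)) and
#'   `discretized` (a discrete [count_table()]).
#' @export
normalize_log_discretize <- function(table, factors = rle_size_factors(table)) {
  stopifnot(inherits(table, "count_table"))
  if (length(factors) != ncol(table$values))
    stop("one size factor per sample required", call. = FALSE)
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  normalized <- sweep(table$values, 2L, factors, "/")
  logged <- log2(normalized + 1)
  disc <- round(logged)  # round() in R is round-half-to-even
  structure(
    list(source = table, size_factors = factors, normalized = normalized,
         log2 = logged,
         discretized = count_table(disc, omic_name = table$omic_name,
                                   is_discrete = TRUE)),
    class = "normalized_table"
  )
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("normalized_table '%s': %d x %d, size factors in [%.3g, %.3g]\n",
              x$source$omic_name, nrow(x$normalized), ncol(x$normalized),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

.ecology_metrics <- c(manhattan = "manhattan", euclidean = "euclidean",
                      canberra = "canberra", clark = "clark",
                      bray_curtis = "bray", kulczynski = "kulczynski",
                      jaccard = "jaccard", alt_gower = "altGower")

#' Distance metrics understood by [community_distance()]
#' @return character vector of metric labels.
#' @export
distance_metrics <- function() {
  c(names(.ecology_metrics), "inverse_correlation", "cosine")
}

#' Distance between two community vectors
#'
#' The eight community-ecology metrics (manhattan, euclidean, canberra,
#' clark, bray_curtis, kulczynski, jaccard, alt_gower) follow vegan's
#' conventions: canberra and clark are scaled by the number of non-double-zero
#' feature pairs, jaccard is the Bray-Curtis transform 2B/(1+B), and
#' alt_gower is the mean absolute difference over non-double-zero features.
#' `inverse_correlation` is 1 - Pearson r and `cosine` is 1 - cosine
#' similarity.
#'
#' @param x,y numeric vectors of equal length.
#' @param metric one of [distance_metrics()].
#' @return a single distance.
#' @export
community_distance <- function(x, y, metric) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y), call. = FALSE)
  m <- sample_distance_matrix(cbind(a = x, b = y), metric)
  m[1L, 2L]
}

#' Pairwise sample distance matrix
#'
#' Columns of `values` are the samples; rows are features.
#'
#' @param values numeric matrix (features x samples).
#' @param metric one of [distance_metrics()].
#' @return symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
sample_distance_matrix <- function(values, metric) {
  metric <- match.arg(metric, distance_metrics())
  n <- ncol(values)
  if (metric %in% names(.ecology_metrics)) {
    if (any(values < 0))
      stop("ecological metric '", metric,
           "' requires nonnegative entries", call. = FALSE)
    d <- vegan::vegdist(t(values), method = .ecology_metrics[[metric]])
    m <- as.matrix(d)
  } else if (metric == "inverse_correlation") {
    r <- suppressWarnings(stats::cor(values))
    if (any(is.na(r))) {
      warning("constant sample vector(s): undefined correlations set to 0 ",
              "(distance 1)", call. = FALSE)
      r[is.na(r)] <- 0
    }
    m <- 1 - r
    diag(m) <- 0
  } else { # cosine
    nrm <- sqrt(colSums(values^2))
    if (any(nrm == 0))
      stop("all-zero vector: cosine distance undefined", call. = FALSE)
    m <- 1 - crossprod(values) / tcrossprod(nrm)
    m[m < 0] <- 0
    diag(m) <- 0
  }
  m <- (m + t(m)) / 2
  dimnames(m) <- list(colnames(values), colnames(values))
  m
}

.apply_normalization <- function(table, method) {
  switch(method,
    none = table$values,
    rle = sweep(table$values, 2L, rle_size_factors(table), "/"),
    total_sum = {
      tot <- colSums(table$values)
      if (any(tot == 0)) stop("all-zero sample", call. = FALSE)
      sweep(table$values, 2L, tot / stats::median(tot), "/")
    },
    stop("unknown normalization method: ", method, call. = FALSE)
  )
}

#' Select a normalization by the sibling distance ratio
#'
#' For each candidate normalization and distance metric, computes
#' mean(distance between the two siblings of each family) divided by
#' mean(distance between samples from different families); the winner for a
#' metric is the candidate minimizing the ratio, and the overall winner is
#' the candidate winning the most metrics (ties broken by candidate order).
#' Distances are computed on log2(normalized + 1) values.
#'
#' @param table a [count_table()].
#' @param metadata a `sample_metadata` data frame covering the table's
#'   samples; families with exactly two samples present define sibling pairs.
#' @param candidates normalization labels among `"rle"`, `"none"`,
#'   `"total_sum"`.
#' @param metrics distance metric labels (default: the eight ecology metrics).
#' @return list with `grid` (candidate x metric ratio matrix),
#'   `winner_per_metric`, and `winner`.
#' @export
select_normalization <- function(table, metadata,
                                 candidates = c("rle", "none", "total_sum"),
                                 metrics = names(.ecology_metrics)) {
  ids <- sample_ids(table)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$family_id))
    stop("metadata missing for sample(s): ",
         paste(ids[is.na(meta$family_id)], collapse = ", "), call. = FALSE)
  fam <- split(seq_along(ids), meta$family_id)
  pairs <- Filter(function(ix) length(ix) == 2L, fam)
  if (length(pairs) < 2L)
    stop("need >= 2 families with exactly 2 samples each", call. = FALSE)
  fam_of <- meta$family_id
  between_mask <- outer(fam_of, fam_of, "!=") & upper.tri(diag(length(ids)))

  grid <- matrix(NA_real_, length(candidates), length(metrics),
                 dimnames = list(candidates, metrics))
  for (cand in candidates) {
    logged <- log2(.apply_normalization(table, cand) + 1)
    for (met in metrics) {
      dm <- sample_distance_matrix(logged, met)
      within <- vapply(pairs, function(ix) dm[ix[1L], ix[2L]], numeric(1L))
      grid[cand, met] <- mean(within) / mean(dm[between_mask])
    }
  }
  winner_per_metric <- apply(grid, 2L, function(col) {
    candidates[which.min(col)]
  })
  votes <- table(factor(winner_per_metric, levels = candidates))
  list(grid = grid, winner_per_metric = winner_per_metric,
       winner = candidates[which.max(votes)])
}
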