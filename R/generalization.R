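#' Feature-feature cosine distance from a fitted model's beta
#'
#' Each feature is a K-vector (its column of beta); the distance between two
#' features is 1 minus the cosine of the angle between their topic-weight
#' vectors. Features that load on the same topics are close regardless of
#' absolute abundance.
#'
#' @param model an `lda_model`.
#' @param features optional feature-id subset.
#' @return symmetric matrix in \[0, 2\] with zero diagonal, dimnames =
#'   feature ids, attribute `K`.
#' @export
beta_cosine_distance <- function(model, features = NULL) {
  b <- model$beta
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(b))
    if (length(missing))
      stop("feature(s) not in model: ", paste(missing, collapse = ", "),
           call. = FALSE)
    b <- b[, features, drop = FALSE]
  }
  zero <- colSums(b^2) == 0
  if (any(zero))
    stop("all-zero beta column for feature(s): ",
         paste(colnames(b)[zero], collapse = ", "), call. = FALSE)
  dm <- sample_distance_matrix(b, "cosine")
  attr(dm, "K") <- model$K
  dm
}

#' Mantel test between two feature distance matrices
#'
#' Restricts both matrices to their common feature ids, computes the Pearson
#' correlation r of the upper-triangle entries, and builds the null by
#' jointly permuting the rows and columns of the second matrix
#' `n_permutations` times (joint relabeling keeps each permuted matrix a
#' valid distance matrix). One-sided concordance alternative with the
#' add-one convention: p = (1 + #\{null r >= observed\}) / (1 + P); the
#' z-score is (observed - null mean) / null SD.
#'
#' @param A,B symmetric distance matrices with feature-id dimnames sharing
#'   at least 5 features.
#' @param n_permutations permutation count (default 10000).
#' @param seed integer seed.
#' @return A `mantel_result`: list with `r`, `p`, `z`, `null_mean`,
#'   `null_sd`, `null_r` (the permutation statistics), `n_features`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(A, B, n_permutations = 10000L, seed = 1L) {
  common <- intersect(rownames(A), rownames(B))
  if (length(common) < 5L)
    stop("need at least 5 common features (found ", length(common), ")",
         call. = FALSE)
  common <- sort(common, method = "radix")
  A <- A[common, common]
  B <- B[common, common]
  ut <- upper.tri(A)
  a <- A[ut]
  if (stats::sd(a) == 0 || stats::sd(B[ut]) == 0)
    stop("zero-variance distance triangle", call. = FALSE)
  r_obs <- stats::cor(a, B[ut])

  n <- length(common)
  set.seed(seed)
  null_r <- vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(n)
    stats::cor(a, B[p, p][ut])
  }, numeric(1L))
  null_sd <- stats::sd(null_r)
  structure(
    list(r = r_obs,
         p = (1 + sum(null_r >= r_obs)) / (1 + n_permutations),
         z = if (null_sd > 0) (r_obs - mean(null_r)) / null_sd else NA_real_,
         null_mean = mean(null_r), null_sd = null_sd, null_r = null_r,
         n_features = n, n_permutations = n_permutations, seed = seed),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "mantel_result: r = %.4f, z = %.2f, p = %.4g (%d features, %d permutations)\n",
    x$r, x$z, x$p, x$n_features, x$n_permutations))
  invisible(x)
}
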