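#' Configuration for the synthetic multi-omic cohort generator
#'
#' The generator emulates the cohort structure the analysis assumes: families
#' of two siblings (one case, one control), a per-sample topic distribution
#' theta shared by all omics, per-omic topic-feature distributions beta, and
#' metadata covariates linearly driven by theta. Defaults give a cohort small
#' enough for minutes-scale test runs.
#'
#' @param n_families number of sibling-pair families (2 samples each).
#' @param omic_specs named list; each element a list with `V` (feature
#'   count) and `N_d` (sequencing depth). All omics share `K_true`.
#' @param K_true number of latent topics.
#' @param alpha_true,gamma_true symmetric Dirichlet concentrations for theta
#'   and beta.
#' @param sibling_correlation in \[0, 1\]; each sibling's theta is
#'   `s * family_draw + (1 - s) * individual_draw`. 1 makes siblings
#'   identical; 0 makes them independent.
#' @param shared_theta if `FALSE`, each omic gets an independent theta —
#'   the negative control for cross-omic structure.
#' @param n_covariates number of metadata covariates.
#' @param covariate_topic_loadings `n_covariates x K_true` matrix; default
#'   ties covariate j to topic `(j - 1) %% K_true + 1` with loading 1.
#' @param covariate_noise_sd Gaussian noise SD added to loadings %*% theta.
#' @param differential_spec list of lists with elements `omic`, `feature`
#'   (index or `"random"`), `log2fc`, and optionally `cluster` (`"all"` or a
#'   topic index whose high-theta samples are affected); applied by
#'   [plant_differentials()].
#' @param seed integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_families = 40L,
                             omic_specs = list(
                               `16S` = list(V = 150L, N_d = 2000L),
                               MTG = list(V = 300L, N_d = 2000L),
                               MTT = list(V = 300L, N_d = 2000L),
                               MBX = list(V = 120L, N_d = 2000L)),
                             K_true = 4L,
                             alpha_true = 0.8, gamma_true = 0.1,
                             sibling_correlation = 0.5,
                             shared_theta = TRUE,
                             n_covariates = 4L,
                             covariate_topic_loadings = NULL,
                             covariate_noise_sd = 0.1,
                             differential_spec = list(),
                             seed = 1L) {
  if (alpha_true <= 0 || gamma_true <= 0)
    stop("Dirichlet concentrations must be positive", call. = FALSE)
  if (sibling_correlation < 0 || sibling_correlation > 1)
    stop("sibling_correlation must lie in [0, 1]", call. = FALSE)
  for (nm in names(omic_specs)) {
    sp <- omic_specs[[nm]]
    if (sp$N_d < 1) stop("depth must be >= 1 for omic ", nm, call. = FALSE)
    if (K_true > sp$V)
      stop("K_true (", K_true, ") exceeds V (", sp$V, ") for omic ", nm,
           call. = FALSE)
  }
  if (is.null(covariate_topic_loadings) && n_covariates > 0L) {
    covariate_topic_loadings <- matrix(0, n_covariates, K_true)
    for (j in seq_len(n_covariates))
      covariate_topic_loadings[j, (j - 1L) %% K_true + 1L] <- 1
  }
  structure(
    list(n_families = as.integer(n_families), omic_specs = omic_specs,
         K_true = as.integer(K_true), alpha_true = alpha_true,
         gamma_true = gamma_true, sibling_correlation = sibling_correlation,
         shared_theta = isTRUE(shared_theta),
         n_covariates = as.integer(n_covariates),
         covariate_topic_loadings = covariate_topic_loadings,
         covariate_noise_sd = covariate_noise_sd,
         differential_spec = differential_spec, seed = as.integer(seed)),
    class = "generator_config"
  )
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic multi-omic cohort
#'
#' Per family: a family topic vector is drawn from Dir(alpha_true); each of
#' the two siblings mixes it with an individual Dir(alpha_true) draw using
#' `sibling_correlation`; one sibling is labelled case, the other control.
#' Per omic: topic rows beta_k ~ Dir(gamma_true) over that omic's features,
#' and each sample's counts are N_d multinomial tokens from the LDA
#' generative process (topic from theta, word from beta). Covariates are
#' `loadings %*% theta` plus Gaussian noise. Any `differential_spec` entries
#' are applied via [plant_differentials()].
#'
#' @param config a [generator_config()].
#' @return list with `omics` (an `omic_set`), `metadata`
#'   (`sample_metadata`), and `truth` (a `synthetic_truth`: `theta_true`
#'   per omic, `beta_true` per omic, `planted`, family/phenotype
#'   assignments).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nf <- config$n_families
  K <- config$K_true
  D <- 2L * nf
  fam_ids <- sprintf("F%03d", seq_len(nf))
  sample_id <- sprintf("F%03d_%s", rep(seq_len(nf), each = 2L),
                       rep(c("case", "ctrl"), nf))
  metadata <- data.frame(
    sample_id = sample_id,
    individual_id = sample_id,
    family_id = rep(fam_ids, each = 2L),
    phenotype = rep(c("ASD", "TD"), nf),
    age = round(stats::runif(D, 2, 7), 1),
    stringsAsFactors = FALSE
  )

  draw_theta <- function() {
    fam_theta <- .rdirichlet(nf, rep(config$alpha_true, K))
    ind_theta <- .rdirichlet(D, rep(config$alpha_true, K))
    s <- config$sibling_correlation
    th <- s * fam_theta[rep(seq_len(nf), each = 2L), , drop = FALSE] +
      (1 - s) * ind_theta
    rownames(th) <- sample_id
    colnames(th) <- paste0("topic", seq_len(K))
    th
  }

  shared <- draw_theta()
  tables <- list()
  theta_true <- list()
  beta_true <- list()
  for (nm in names(config$omic_specs)) {
    sp <- config$omic_specs[[nm]]
    th <- if (config$shared_theta) shared else draw_theta()
    be <- .rdirichlet(K, rep(config$gamma_true, sp$V))
    rownames(be) <- paste0("topic", seq_len(K))
    colnames(be) <- sprintf("%s_f%04d", nm, seq_len(sp$V))
    probs <- th %*% be
    counts <- matrix(0L, sp$V, D,
                     dimnames = list(colnames(be), sample_id))
    for (d in seq_len(D))
      counts[, d] <- as.integer(stats::rmultinom(1L, sp$N_d, probs[d, ]))
    tables[[nm]] <- count_table(counts, omic_name = nm, is_discrete = TRUE)
    theta_true[[nm]] <- th
    beta_true[[nm]] <- be
  }

  if (config$n_covariates > 0L) {
    L <- config$covariate_topic_loadings
    cov <- shared %*% t(L) +
      matrix(stats::rnorm(D * nrow(L), sd = config$covariate_noise_sd),
             D, nrow(L))
    colnames(cov) <- sprintf("cov%02d", seq_len(nrow(L)))
    metadata <- cbind(metadata, as.data.frame(cov))
  }
  metadata <- sample_metadata(metadata)

  truth <- structure(
    list(theta_true = theta_true, beta_true = beta_true,
         theta_shared = if (config$shared_theta) shared else NULL,
         planted = list(), family_id = metadata$family_id,
         phenotype = metadata$phenotype, config = config),
    class = "synthetic_truth"
  )
  omics <- align_omics(tables)
  out <- list(omics = omics, metadata = metadata, truth = truth)
  if (length(config$differential_spec)) {
    out <- plant_differentials(out$omics, out$truth, config$differential_spec,
                               metadata = out$metadata,
                               seed = config$seed + 1000L)
    out$metadata <- metadata
  }
  out
}

#' Plant phenotype-differential features into generated counts
#'
#' For each spec entry, case-sample counts of the chosen feature are scaled
#' in expectation by `2^log2fc`: fold-changes below 1 by binomial thinning
#' (each token kept with probability fc), above 1 by adding
#' Poisson(count * (fc - 1)) extra tokens — both leave the expected count at
#' exactly `count * fc`. Non-planted features are untouched.
#'
#' @param omics an `omic_set` from [generate_cohort()].
#' @param truth the matching `synthetic_truth` (updated in the output).
#' @param spec list of entries with `omic`, `feature` (index or
#'   `"random"`), `log2fc`, optional `cluster` (`"all"` or a topic index:
#'   only case samples whose dominant true topic matches are affected).
#' @param metadata `sample_metadata` giving case/control labels.
#' @param seed integer seed for thinning/inflation draws.
#' @return list with updated `omics`, `truth` (with `planted` filled in).
#' @export
plant_differentials <- function(omics, truth, spec, metadata, seed = 1L) {
  set.seed(seed)
  planted <- list()
  seen <- character()
  for (entry in spec) {
    nm <- entry$omic
    if (!nm %in% names(omics$tables))
      stop("differential spec names omic '", nm, "' not in the set",
           call. = FALSE)
    tab <- omics$tables[[nm]]
    fi <- entry$feature
    if (identical(fi, "random"))
      fi <- sample.int(nrow(tab$values), 1L)
    if (fi < 1L || fi > nrow(tab$values))
      stop("feature index ", fi, " out of range for omic ", nm, call. = FALSE)
    key <- paste0(nm, "#", fi)
    if (key %in% seen)
      stop("feature ", fi, " in omic ", nm, " planted twice", call. = FALSE)
    seen <- c(seen, key)
    fc <- 2^entry$log2fc

    meta <- metadata[match(sample_ids(tab), metadata$sample_id), ]
    affected <- meta$phenotype == "case"
    cluster <- entry$cluster
    if (!is.null(cluster) && !identical(cluster, "all")) {
      th <- truth$theta_true[[nm]][sample_ids(tab), , drop = FALSE]
      affected <- affected & (max.col(th) == cluster)
    }
    if (fc != 1 && any(affected)) {
      cnt <- tab$values[fi, affected]
      new <- if (fc < 1) {
        stats::rbinom(length(cnt), size = as.integer(cnt), prob = fc)
      } else {
        as.integer(cnt) + stats::rpois(length(cnt), lambda = cnt * (fc - 1))
      }
      tab$values[fi, affected] <- new
      omics$tables[[nm]] <- tab
    }
    planted[[length(planted) + 1L]] <- list(
      omic = nm, feature = fi, feature_id = feature_ids(tab)[fi],
      log2fc = entry$log2fc,
      cluster = if (is.null(cluster)) "all" else cluster)
  }
  truth$planted <- c(truth$planted, planted)
  list(omics = omics, truth = truth)
}

#' Write a generated cohort to disk (count TSVs, metadata TSV, truth JSON)
#' @param cohort output of [generate_cohort()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$omics$tables))
    write_count_table(cohort$omics$tables[[nm]],
                      file.path(dir, paste0("counts_", nm, ".tsv")))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(theta_true = lapply(truth$theta_true, function(m)
           as.data.frame(m, row.names = rownames(m))),
         beta_true = lapply(truth$beta_true, function(m)
           as.data.frame(m, row.names = rownames(m))),
         planted = truth$planted),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
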