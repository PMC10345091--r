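#' Pipeline configuration
#'
#' Collects every stage's parameters in one validated object. Input is
#' either a generated cohort (`generator` = a [generator_config()]) or a
#' directory of TSVs written by [write_cohort()] (`cohort_dir`).
#'
#' @param generator a [generator_config()], or `NULL` when reading from
#'   `cohort_dir`.
#' @param cohort_dir directory with `counts_<omic>.tsv` + `metadata.tsv`.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param normalization list: `method` (`"rle"`, `"none"`, `"total_sum"`),
#'   `select` (run the sibling-ratio grid and use its winner).
#' @param lda list: `k` (single K or named per omic; `NULL` = select),
#'   `k_grid`, `alpha` (`NULL` = 50/K), `gamma`, `n_iterations`, `burn_in`,
#'   `thin`, `n_simulations`, `rel_tolerance`.
#' @param crossomic list: `n_clusters` (`NULL` = select), `null_tables`
#'   (0 disables null validation), `drop_dominant`,
#'   `dominance_threshold`.
#' @param interpretation list: `percentile`, `sd_multiplier`.
#' @param sample_clusters number of sample clusters for the phenotype
#'   comparison.
#' @param differential list: `n_repeats`, `n_runs`, `n_trees`,
#'   `percentile_cut`, `alpha`; `enabled` to switch the stage off.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(generator = NULL, cohort_dir = NULL, seed = 1L,
                            normalization = list(),
                            lda = list(), crossomic = list(),
                            interpretation = list(),
                            sample_clusters = 2L,
                            differential = list()) {
  defaults <- list(
    normalization = list(method = "rle", select = FALSE),
    lda = list(k = NULL, k_grid = 2:6, alpha = NULL, gamma = 0.1,
               n_iterations = 2000L, burn_in = 500L, thin = 10L,
               n_simulations = 5L, rel_tolerance = 0.02),
    crossomic = list(n_clusters = NULL, null_tables = 15L,
                     drop_dominant = TRUE, dominance_threshold = 10),
    interpretation = list(percentile = 99, sd_multiplier = 1.5),
    differential = list(enabled = TRUE, n_repeats = 100L, n_runs = 100L,
                        n_trees = 500L, percentile_cut = 90, alpha = 0.05)
  )
  fill <- function(user, def, block) {
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop("unknown ", block, " parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    utils::modifyList(def, user)
  }
  cfg <- list(
    generator = generator, cohort_dir = cohort_dir, seed = as.integer(seed),
    normalization = fill(normalization, defaults$normalization,
                         "normalization"),
    lda = fill(lda, defaults$lda, "lda"),
    crossomic = fill(crossomic, defaults$crossomic, "crossomic"),
    interpretation = fill(interpretation, defaults$interpretation,
                          "interpretation"),
    sample_clusters = as.integer(sample_clusters),
    differential = fill(differential, defaults$differential, "differential")
  )
  problems <- character()
  if (is.null(generator) && is.null(cohort_dir))
    problems <- c(problems, "either generator or cohort_dir is required")
  if (!is.null(generator) && !inherits(generator, "generator_config"))
    problems <- c(problems, "generator must be a generator_config")
  if (!cfg$normalization$method %in% c("rle", "none", "total_sum"))
    problems <- c(problems, "unknown normalization method")
  if (cfg$lda$n_iterations <= cfg$lda$burn_in)
    problems <- c(problems, "lda: n_iterations must exceed burn_in")
  if (cfg$sample_clusters < 2L)
    problems <- c(problems, "sample_clusters must be >= 2")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

.stage_seed <- function(seed, stage, i = 0L) {
  # counter-based derivation keeps per-stage seeds reproducible and distinct
  (seed * 131L + match(stage, c("simulate", "normalize", "fit", "crossomic",
                                "interpret", "cluster", "differential")) *
     10007L + i * 97L) %% .Machine$integer.max
}

#' Run the full topic-modeling analysis
#'
#' Executes: simulate/ingest -> normalization (+ optional data-driven
#' selection) -> per-omic LDA with topic-count selection -> cross-omic topic
#' clustering with optional null-ensemble validation and dominant-topic
#' removal -> topic interpretation and metadata correlation -> sample
#' clustering -> per-cluster differential testing. Artifacts are written
#' under `outdir` and recorded (with checksums) in the returned manifest.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return list with `results` (all stage objects) and `manifest` (config
#'   hash, stage timings, file inventory with md5 checksums, seeds used).
#' @export
run_pipeline <- function(config, outdir = tempfile("topicomics_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  seeds <- list()
  res <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  # --- ingest / simulate ----------------------------------------------
  res$cohort <- clock("ingest", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- .stage_seed(config$seed, "simulate")
      seeds$simulate <- gen$seed
      generate_cohort(gen)
    } else {
      files <- list.files(config$cohort_dir, "^counts_.*\\.tsv$",
                          full.names = TRUE)
      if (!length(files))
        stop("no counts_<omic>.tsv files in ", config$cohort_dir,
             call. = FALSE)
      tabs <- lapply(files, function(f)
        read_count_table(f, sub("^counts_(.*)\\.tsv$", "\\1", basename(f))))
      list(omics = align_omics(tabs),
           metadata = read_metadata(file.path(config$cohort_dir,
                                              "metadata.tsv")),
           truth = NULL)
    }
  })
  omics <- res$cohort$omics
  metadata <- res$cohort$metadata

  # --- normalization ---------------------------------------------------
  res$normalized <- clock("normalize", {
    lapply(omics$tables, function(tab) {
      method <- config$normalization$method
      if (isTRUE(config$normalization$select)) {
        sel <- select_normalization(tab, metadata)
        method <- sel$winner
      }
      factors <- switch(method,
        rle = rle_size_factors(tab),
        none = stats::setNames(rep(1, ncol(tab$values)),
                               colnames(tab$values)),
        total_sum = {
          tot <- colSums(tab$values)
          tot / stats::median(tot)
        })
      normalize_log_discretize(tab, factors)
    })
  })

  # --- per-omic LDA with K selection ----------------------------------
  res$models <- clock("fit", {
    models <- list()
    res$selection <- list()
    for (nm in names(res$normalized)) {
      disc <- res$normalized[[nm]]$discretized
      kcfg <- config$lda
      fixed_k <- if (is.list(kcfg$k) || length(kcfg$k) > 1L)
        kcfg$k[[nm]] else kcfg$k
      seed_fit <- .stage_seed(config$seed, "fit",
                              match(nm, names(res$normalized)))
      seeds[[paste0("fit_", nm)]] <- seed_fit
      if (is.null(fixed_k)) {
        diag_ <- fit_diagnostics(
          disc, kcfg$k_grid, n_simulations = kcfg$n_simulations,
          seed = seed_fit, gamma = kcfg$gamma,
          n_iterations = kcfg$n_iterations, burn_in = kcfg$burn_in,
          thin = kcfg$thin, drop_empty = TRUE)
        sel <- select_k(diag_, rel_tolerance = kcfg$rel_tolerance)
        res$selection[[nm]] <- list(diagnostics = diag_$metrics,
                                     selected = sel)
        models[[nm]] <- diag_$models[[as.character(sel$K)]]
      } else {
        alpha <- if (is.null(kcfg$alpha)) 50 / fixed_k else kcfg$alpha
        models[[nm]] <- fit_lda_gibbs(
          disc, K = fixed_k, alpha = alpha, gamma = kcfg$gamma,
          n_iterations = kcfg$n_iterations, burn_in = kcfg$burn_in,
          thin = kcfg$thin, seed = seed_fit, drop_empty = TRUE)
      }
      write_lda_model(models[[nm]], outdir, prefix = nm)
    }
    models
  })

  # --- interpretation (needed before dominant-topic flagging) ---------
  res$interpretation <- clock("interpret", {
    lapply(res$models, function(m)
      select_topic_features(m$beta,
                            percentile = config$interpretation$percentile,
                            sd_multiplier = config$interpretation$sd_multiplier))
  })

  # --- cross-omic topics ----------------------------------------------
  res$crossomic <- clock("crossomic", {
    drop <- character()
    if (isTRUE(config$crossomic$drop_dominant)) {
      for (nm in names(res$models)) {
        fl <- flag_dominant_topic(
          res$models[[nm]], res$interpretation[[nm]],
          attribution_ratio_threshold = config$crossomic$dominance_threshold)
        if (length(fl)) drop <- c(drop, sprintf("%s.t%d", nm, fl))
      }
    }
    att <- pool_topics(res$models, omics$shared_samples, drop_topics = drop)
    assign_ <- cluster_topics(att)
    if (!is.null(config$crossomic$n_clusters) &&
        config$crossomic$n_clusters != assign_$n_clusters) {
      n_forced <- config$crossomic$n_clusters
      assign_$cluster_labels <- stats::cutree(assign_$tree, k = n_forced)
      assign_$n_clusters <- n_forced
    }
    nullrep <- NULL
    if (config$crossomic$null_tables >= 2L) {
      disc_set <- omics
      disc_set$tables <- lapply(res$normalized, `[[`, "discretized")
      seeds$crossomic_null <- .stage_seed(config$seed, "crossomic")
      nullrep <- null_validation(
        disc_set, res$models, n_clusters = assign_$n_clusters,
        n_tables = config$crossomic$null_tables,
        seed = seeds$crossomic_null, drop_topics = drop)
    }
    list(assignment = assign_, null_report = nullrep, dropped_topics = drop)
  })
  att <- res$crossomic$assignment$attribution

  res$metadata_correlation <- topic_metadata_correlation(att, metadata)

  # --- sample clustering ----------------------------------------------
  res$sample_clusters <- clock("cluster", {
    cluster_samples(att, n_clusters = config$sample_clusters,
                    metadata = metadata)
  })

  # --- per-cluster differential testing -------------------------------
  if (isTRUE(config$differential$enabled)) {
    res$differential <- clock("differential", {
      dcfg <- config$differential
      out <- list()
      for (nm in names(res$normalized)) {
        seeds[[paste0("differential_", nm)]] <-
          .stage_seed(config$seed, "differential",
                      match(nm, names(res$normalized)))
        norm_shared <- res$normalized[[nm]]
        norm_shared$log2 <- norm_shared$log2[, omics$shared_samples,
                                             drop = FALSE]
        out[[nm]] <- differential_by_cluster(
          norm_shared, metadata, res$sample_clusters,
          n_repeats = dcfg$n_repeats, n_runs = dcfg$n_runs,
          n_trees = dcfg$n_trees, percentile_cut = dcfg$percentile_cut,
          alpha = dcfg$alpha,
          seed = seeds[[paste0("differential_", nm)]])
      }
      out
    })
  }

  # --- artifacts + manifest -------------------------------------------
  write_matrix_tsv(att, file.path(outdir, "topic_attribution.tsv"),
                   id_header = "topic")
  write_matrix_tsv(res$crossomic$assignment$correlation$rho,
                   file.path(outdir, "topic_correlation.tsv"),
                   id_header = "topic")
  utils::write.table(
    data.frame(topic = names(res$crossomic$assignment$cluster_labels),
               cluster = unname(res$crossomic$assignment$cluster_labels)),
    file.path(outdir, "topic_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(res$sample_clusters$cluster_labels),
               cluster = unname(res$sample_clusters$cluster_labels)),
    file.path(outdir, "sample_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(res$metadata_correlation))
    utils::write.table(res$metadata_correlation,
                       file.path(outdir, "topic_metadata_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$differential)) {
    for (nm in names(res$differential))
      for (cl in names(res$differential[[nm]]))
        utils::write.table(
          res$differential[[nm]][[cl]]$table,
          file.path(outdir, sprintf("differential_%s_cluster%s.tsv", nm, cl)),
          sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("topicomics")),
    seed = config$seed, seeds = seeds, timings = timings,
    config_hash = .config_hash(config),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       row.names = NULL)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(results = res, manifest = manifest, outdir = outdir)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}
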