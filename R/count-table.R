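#' Construct a count table
#'
#' A `count_table` holds one omic's feature-by-sample matrix of nonnegative
#' values together with its identifiers. In the topic-model view the samples
#' are the documents and the features (ASVs, KEGG orthologs, metabolites) are
#' the words; column sums are the per-sample totals.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row and column names are used as feature/sample identifiers unless
#'   `feature_ids`/`sample_ids` are given.
#' @param omic_name label for the omic (e.g. `"16S"`, `"MTG"`).
#' @param feature_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @param is_discrete logical; `TRUE` when all values are integers (required
#'   by the Gibbs sampler).
#'
#' @return An object of class `count_table`: a list with elements
#'   `omic_name`, `values` (named matrix), and `is_discrete`.
#' @export
count_table <- function(values, omic_name = "omic", feature_ids = NULL,
                        sample_ids = NULL, is_discrete = NULL) {
  values <- as.matrix(values)
  if (!is.null(feature_ids)) rownames(values) <- feature_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("count table must have at least one feature and one sample",
         call. = FALSE)
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature identifier(s): ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("count table values must be finite numbers", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  if (is.null(is_discrete))
    is_discrete <- all(values == round(values))
  structure(
    list(omic_name = omic_name, values = values,
         is_discrete = isTRUE(is_discrete)),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table '%s': %d features x %d samples (%s)\n",
              x$omic_name, nrow(x$values), ncol(x$values),
              if (x$is_discrete) "discrete" else "continuous"))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a count table from TSV
#'
#' Expects a tab-delimited UTF-8 file whose header row holds sample ids and
#' whose first column holds feature ids.
#'
#' @param path file path.
#' @param omic_name label attached to the returned table.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, omic_name = "omic") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    stop("duplicate sample identifier(s) in header: ",
         paste(dup, collapse = ", "), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty count table: ", path, call. = FALSE)
  feats <- df[[1L]]
  dupf <- unique(feats[duplicated(feats)])
  if (length(dupf))
    stop("duplicate feature identifier(s): ", paste(dupf, collapse = ", "),
         call. = FALSE)
  mat <- matrix(NA_real_, nrow(df), length(samples),
                dimnames = list(feats, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at feature '%s', sample '%s': '%s'",
                   feats[bad[1L]], samples[j], col[bad[1L]]), call. = FALSE)
    neg <- which(num < 0)
    if (length(neg))
      stop(sprintf("negative value at feature '%s', sample '%s'",
                   feats[neg[1L]], samples[j]), call. = FALSE)
    mat[, j] <- num
  }
  count_table(mat, omic_name = omic_name)
}

#' Write a count table to TSV
#'
#' @param table a [count_table()].
#' @param path output path.
#' @param digits significant digits used when formatting non-integer values.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, digits = 10L) {
  stopifnot(inherits(table, "count_table"))
  v <- table$values
  chr <- if (all(v == round(v))) {
    format(v, scientific = FALSE, trim = TRUE)
  } else {
    formatC(v, digits = digits, format = "g")
  }
  chr <- matrix(trimws(chr), nrow(v), ncol(v))
  lines <- c(
    paste(c("feature_id", colnames(v)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], chr[i, ]), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `individual_id`, `family_id`, `phenotype`.
#' `age` is optional; every other column is kept as a covariate. Phenotype
#' strings are mapped case-insensitively through `phenotype_map` onto the
#' canonical labels `"case"` and `"control"`.
#'
#' @param path file path.
#' @param phenotype_map named character vector mapping raw labels to
#'   `"case"`/`"control"`; default maps ASD to case and TD to control.
#' @return A `sample_metadata` data frame with attribute `covariates`
#'   naming the covariate columns.
#' @export
read_metadata <- function(path,
                          phenotype_map = c(asd = "case", td = "control",
                                            case = "case", control = "control")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  sample_metadata(df, phenotype_map = phenotype_map)
}

#' Validate a sample metadata data frame
#'
#' @param df data frame with the columns described in [read_metadata()].
#' @inheritParams read_metadata
#' @return The validated `sample_metadata` data frame.
#' @export
sample_metadata <- function(df,
                            phenotype_map = c(asd = "case", td = "control",
                                              case = "case", control = "control")) {
  required <- c("sample_id", "individual_id", "family_id", "phenotype")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  raw <- tolower(trimws(as.character(df$phenotype)))
  names(phenotype_map) <- tolower(names(phenotype_map))
  unknown <- setdiff(unique(raw), names(phenotype_map))
  if (length(unknown))
    stop("unmappable phenotype value(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  df$phenotype <- unname(phenotype_map[raw])
  df$sample_id <- as.character(df$sample_id)
  df$individual_id <- as.character(df$individual_id)
  df$family_id <- as.character(df$family_id)
  covars <- setdiff(names(df), c(required, "age"))
  attr(df, "covariates") <- covars
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata to TSV
#' @param metadata a `sample_metadata` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align omic tables to their shared samples
#'
#' Restricts every table to the samples present in all of them, reordered
#' lexicographically so that downstream seeded runs are reproducible.
#'
#' @param tables list of [count_table()] objects.
#' @return An `omic_set`: list with `tables` (aligned, named by omic),
#'   `shared_samples`, and `sample_counts` (per-omic before/after counts).
#' @export
align_omics <- function(tables) {
  stopifnot(length(tables) >= 1L)
  for (t in tables) stopifnot(inherits(t, "count_table"))
  sets <- lapply(tables, sample_ids)
  shared <- Reduce(intersect, sets)
  before <- vapply(sets, length, integer(1L))
  if (length(shared) == 0L)
    stop("no samples shared by all tables; per-table sample counts: ",
         paste(sprintf("%s=%d", vapply(tables, `[[`, "", "omic_name"), before),
               collapse = ", "), call. = FALSE)
  shared <- sort(shared, method = "radix")
  aligned <- lapply(tables, function(t) {
    t$values <- t$values[, shared, drop = FALSE]
    t
  })
  names(aligned) <- vapply(tables, `[[`, "", "omic_name")
  structure(
    list(tables = aligned, shared_samples = shared,
         sample_counts = data.frame(
           omic = names(aligned), before = unname(before),
           after = length(shared))),
    class = "omic_set"
  )
}

#' @export
print.omic_set <- function(x, ...) {
  cat(sprintf("omic_set: %d omics, %d shared samples\n",
              length(x$tables), length(x$shared_samples)))
  invisible(x)
}

#' Keep one sample per individual
#'
#' Individuals with repeated samples are collapsed to their first sample in
#' metadata row order; how the original study collapsed repeats is not
#' recorded, so this default is deliberately simple and explicit.
#'
#' @param metadata a `sample_metadata` data frame.
#' @return The subset metadata.
#' @export
first_sample_per_individual <- function(metadata) {
  keep <- !duplicated(metadata$individual_id)
  out <- metadata[keep, , drop = FALSE]
  attr(out, "covariates") <- attr(metadata, "covariates")
  class(out) <- class(metadata)
  out
}

#' Write a generic numeric matrix as TSV (theta, beta, distance, correlation)
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_header header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_header = "id") {
  lines <- c(
    paste(c(id_header, colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i],
              formatC(mat[i, ], digits = 10L, format = "g")),
            collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
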