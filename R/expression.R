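#' Read a genes-by-samples expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column; remaining cells must be numeric. Rows containing any
#' non-numeric or empty cell are dropped (missing-value imputation is out of
#' scope) and the number of dropped rows is reported. Duplicate gene
#' identifiers are resolved by keeping the copy with the highest standard
#' deviation across samples, consistent with downstream variance filtering.
#'
#' @param path Path to a tab-separated expression file.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 3)
    stop("expression file must have at least 2 sample columns")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in expression file header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw[, -1, drop = FALSE])),
           nrow = nrow(raw),
           dimnames = list(NULL, sample_ids)))
  vals[as.matrix(raw[, -1, drop = FALSE]) == ""] <- NA
  complete <- stats::complete.cases(vals)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message("read_expression: dropped ", n_dropped,
            " row(s) with missing or non-numeric values")
  vals <- vals[complete, , drop = FALSE]
  gene_ids <- gene_ids[complete]

  if (anyDuplicated(gene_ids)) {
    sds <- apply(vals, 1, stats::sd)
    keep <- rep(TRUE, length(gene_ids))
    for (g in unique(gene_ids[duplicated(gene_ids)])) {
      idx <- which(gene_ids == g)
      best <- idx[which.max(sds[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    message("read_expression: resolved ", sum(!keep),
            " duplicate gene identifier row(s) by keeping the max-SD copy")
    vals <- vals[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }

  if (length(gene_ids) < 2 || length(sample_ids) < 2)
    stop("expression matrix must have at least 2 genes and 2 samples ",
         "after parsing (got ", length(gene_ids), " x ", length(sample_ids), ")")
  rownames(vals) <- gene_ids
  assert_expression(vals)
}

#' Filter genes by standard deviation
#'
#' Retains genes whose sample standard deviation (n-1 denominator) across
#' samples is strictly greater than `threshold`, preserving gene order. The
#' conventional cutoff for selecting highly variable genes on log-scale
#' microarray data is `threshold = 0.8`.
#'
#' @param expr Numeric genes x samples matrix.
#' @param threshold Non-negative SD cutoff; genes with SD > threshold are kept.
#' @return The filtered expression matrix.
#' @export
filter_by_sd <- function(expr, threshold = 0.8) {
  assert_expression(expr)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  sds <- apply(expr, 1, stats::sd)
  keep <- sds > threshold
  if (!any(keep))
    stop(sprintf(
      "no genes retained at SD > %g (observed SD range: %.4g to %.4g)",
      threshold, min(sds), max(sds)))
  message("filter_by_sd: retained ", sum(keep), " of ", length(keep),
          " genes at SD > ", threshold)
  expr[keep, , drop = FALSE]
}

#' Read a sample annotation table (sample_id, known_label)
#'
#' @param path Two-column tab-separated file with a header.
#' @return Named character vector: known label per sample identifier.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2) stop("annotation file must have 2 columns")
  ids <- df[[1]]; labs <- df[[2]]
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in annotation")
  if (any(!nzchar(labs))) stop("empty labels in annotation")
  stats::setNames(labs, ids)
}

#' Read a survival table (sample_id, time, event)
#'
#' @param path Three-column tab-separated file with a header; `time` must be
#'   non-negative and `event` must be 0 (censored) or 1 (event observed).
#' @return A data frame with columns sample_id, time, event.
#' @export
read_survival <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 3) stop("survival file must have 3 columns")
  out <- data.frame(sample_id = as.character(df[[1]]),
                    time = as.numeric(df[[2]]),
                    event = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample identifiers in survival table")
  if (anyNA(out$time) || any(out$time < 0)) stop("survival times must be non-negative")
  if (!all(out$event %in% c(0L, 1L))) stop("event indicator must be 0 or 1")
  out
}
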