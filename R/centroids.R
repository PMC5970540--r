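#' Build per-community (optionally shrunken) gene centroids
#'
#' Nearest-shrunken-centroid construction: for gene g and community c the
#' standardized contrast is
#' `d_gc = (xbar_gc - xbar_g) / (m_c * (s_g + s0))`, where `s_g` is the
#' pooled within-community standard deviation, `s0` the median of the
#' `s_g`, and `m_c = sqrt(1/n_c - 1/n)`. Soft-thresholding
#' `d'_gc = sign(d_gc) * max(|d_gc| - delta, 0)` shrinks weak contrasts to
#' zero, and the shrunken centroid is
#' `xbar_g + m_c * (s_g + s0) * d'_gc`. At `delta = 0` the centroids are the
#' per-community gene means. Downstream assignment uses Pearson correlation
#' with the centroids, not the discriminant score, so `delta = 0` is the
#' default and shrinkage is an option for denoising centroids.
#'
#' @param expr Numeric genes x samples matrix.
#' @param communities Named vector: community per sample id, covering the
#'   matrix columns; every community needs at least 2 samples.
#' @param delta Non-negative shrinkage threshold.
#' @return Object of class `centroid_set`: list with `gene_ids`,
#'   `community_ids`, `centroids` (genes x communities), `overall_mean`,
#'   `delta`, `genes_retained` (genes with at least one nonzero shrunken
#'   contrast) and `d_shrunk`.
#' @export
build_centroids <- function(expr, communities, delta = 0) {
  assert_expression(expr)
  stopifnot(delta >= 0)
  labs <- communities[colnames(expr)]
  if (anyNA(labs)) stop("community assignment missing for some samples")
  labs <- as.character(labs)
  comms <- sort(unique(labs))
  n <- ncol(expr)
  counts <- table(labs)
  small <- names(counts)[counts < 2]
  if (length(small) > 0)
    stop("community with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  overall <- rowMeans(expr)
  means <- sapply(comms, function(cc) rowMeans(expr[, labs == cc, drop = FALSE]))
  # pooled within-community SD per gene
  ss <- rowSums(sapply(comms, function(cc) {
    sub <- expr[, labs == cc, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }))
  s <- sqrt(ss / (n - length(comms)))
  s0 <- stats::median(s)
  m_c <- sqrt(1 / as.numeric(counts[comms]) - 1 / n)
  d <- sweep(means - overall, 1, s + s0, "/")
  d <- sweep(d, 2, m_c, "/")
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  centroids <- overall + sweep(sweep(d_shrunk, 1, s + s0, "*"), 2, m_c, "*")
  dimnames(centroids) <- list(rownames(expr), comms)
  retained <- rownames(expr)[rowSums(d_shrunk != 0) > 0]
  structure(list(gene_ids = rownames(expr), community_ids = comms,
                 centroids = centroids, overall_mean = overall,
                 delta = delta, genes_retained = retained,
                 d_shrunk = d_shrunk),
            class = "centroid_set")
}

#' Assign samples to communities by Pearson correlation with centroids
#'
#' Each sample of the new cohort is assigned to the community whose centroid
#' its expression profile correlates with most strongly over the genes
#' shared between the centroid set and the new matrix. Gene matching is by
#' exact identifier; the shared fraction must reach `min_overlap` of the
#' centroid genes. Samples with zero variance over the shared genes are left
#' unassigned (`NA`) with a warning.
#'
#' @param cent A `centroid_set`.
#' @param expr_new Numeric genes x samples matrix for the new cohort.
#' @param min_overlap Minimum shared-gene fraction (default 0.5).
#' @return List with `assignment` (data frame: sample_id, community) and
#'   `correlations` (samples x communities matrix).
#' @export
assign_by_correlation <- function(cent, expr_new, min_overlap = 0.5) {
  stopifnot(inherits(cent, "centroid_set"))
  assert_expression(expr_new)
  shared <- intersect(cent$gene_ids, rownames(expr_new))
  frac <- length(shared) / length(cent$gene_ids)
  if (frac < min_overlap)
    stop(sprintf("gene overlap %.1f%% below the required %.1f%%",
                 100 * frac, 100 * min_overlap))
  message(sprintf("assign_by_correlation: using %d shared genes (%.1f%%)",
                  length(shared), 100 * frac))
  ctr <- cent$centroids[shared, , drop = FALSE]
  x <- expr_new[shared, , drop = FALSE]
  cors <- matrix(NA_real_, ncol(x), ncol(ctr),
                 dimnames = list(colnames(x), colnames(ctr)))
  assigned <- rep(NA_character_, ncol(x))
  for (j in seq_len(ncol(x))) {
    if (stats::sd(x[, j]) == 0) next
    cors[j, ] <- apply(ctr, 2, function(cc) stats::cor(x[, j], cc))
    assigned[j] <- colnames(ctr)[which.max(cors[j, ])]
  }
  if (anyNA(assigned))
    warning(sum(is.na(assigned)),
            " sample(s) with zero variance over shared genes left unassigned")
  list(assignment = data.frame(sample_id = colnames(x),
                               community = assigned,
                               stringsAsFactors = FALSE),
       correlations = cors)
}

#' Choose the shrinkage threshold by cross-validation
#'
#' Seeded k-fold cross-validation over a delta grid, scoring each delta by
#' misclassification of held-out samples under correlation assignment; the
#' smallest delta attaining the minimum error is returned.
#'
#' @param expr Numeric genes x samples matrix.
#' @param communities Named community vector as in [build_centroids()].
#' @param grid Numeric vector of candidate deltas.
#' @param nfolds Number of folds (default 10, capped by the smallest class).
#' @param seed Optional seed for fold assignment.
#' @return List with `delta` (chosen), and `errors` (per-grid error rates).
#' @export
choose_delta_cv <- function(expr, communities, grid = seq(0, 2, by = 0.25),
                            nfolds = 10, seed = NULL) {
  assert_expression(expr)
  labs <- communities[colnames(expr)]
  set_stream(seed, "delta-cv")
  n <- ncol(expr)
  nfolds <- min(nfolds, min(table(labs)))
  fold <- sample(rep_len(seq_len(nfolds), n))
  errs <- vapply(grid, function(delta) {
    wrong <- 0L; total <- 0L
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      if (length(unique(labs[tr])) < 2 || min(table(labs[tr])) < 2) next
      cent <- build_centroids(expr[, tr, drop = FALSE], labs[tr], delta)
      pred <- suppressMessages(
        assign_by_correlation(cent, expr[, !tr, drop = FALSE]))
      ok <- !is.na(pred$assignment$community)
      wrong <- wrong + sum(pred$assignment$community[ok] !=
                             as.character(labs[!tr][ok]))
      total <- total + sum(ok)
    }
    if (total == 0) NA_real_ else wrong / total
  }, 0)
  best <- grid[which(errs == min(errs, na.rm = TRUE))]
  list(delta = min(best), errors = stats::setNames(errs, grid))
}
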