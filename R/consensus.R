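#' Base clusterers
#'
#' The three base algorithms applied inside the consensus resampling loop,
#' each partitioning samples (rows of `x`) into exactly `k` clusters.
#'
#' * `base_cluster_hc()`: agglomerative hierarchical clustering with
#'   Euclidean distance and average linkage, tree cut at `k`.
#' * `base_cluster_km()`: k-means with the Euclidean objective and multiple
#'   random restarts (distinct rows sampled as initial centers; the restart
#'   with the lowest total within-cluster sum of squares is kept).
#' * `base_cluster_nmf()`: the input is transformed to non-negative values
#'   (see [nonneg_transform()]), transposed to features x samples, factorized
#'   with [nmf_factorize()], and sample `j` is assigned to the factor with
#'   the largest coefficient in column `j` of `H` (ties to the lowest index,
#'   the `which.max` convention).
#'
#' @param x Numeric samples x features matrix.
#' @param k Number of clusters, `2 <= k <= nrow(x)`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (the consensus loop relies on this to keep one stream per run).
#' @param nstart Number of k-means restarts.
#' @param nonneg Non-negativity mode for NMF, `"shift"` or `"posneg"`.
#' @param ... Passed through to [nmf_factorize()].
#' @return Integer vector of cluster labels in `1..k`, one per row of `x`.
#' @name base_clusterers
NULL

#' @rdname base_clusterers
#' @export
base_cluster_hc <- function(x, k) {
  stopifnot(is.matrix(x))
  if (k > nrow(x)) stop("k (", k, ") exceeds number of samples (", nrow(x), ")")
  unname(stats::cutree(stats::hclust(stats::dist(x), method = "average"), k = k))
}

#' @rdname base_clusterers
#' @export
base_cluster_km <- function(x, k, seed = NULL, nstart = 10) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds number of samples (", n, ")")
  if (!is.null(seed)) set.seed(seed)
  ux <- unique(x)
  if (nrow(ux) < k)
    stop("fewer than k distinct samples; cannot form ", k, " clusters")
  best <- NULL
  for (i in seq_len(nstart)) {
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    fit <- suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 50))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  unname(best$cluster)
}

#' @rdname base_clusterers
#' @export
base_cluster_nmf <- function(x, k, seed = NULL, nonneg = "shift", ...) {
  stopifnot(is.matrix(x))
  if (k > nrow(x)) stop("k (", k, ") exceeds number of samples (", nrow(x), ")")
  v <- nonneg_transform(t(x), mode = nonneg)
  fit <- nmf_factorize(v, k, seed = seed, ...)
  unname(apply(fit$h, 2, which.max))
}

#' Subsampled consensus matrix for one (algorithm, k)
#'
#' Repeats a base clustering over random subsamples of the samples
#' (`fraction` of them, without replacement, `resamplings` times) and records
#' for every sample pair the fraction of jointly subsampled runs in which the
#' pair was co-clustered. Pairs that were never co-sampled get consensus 0
#' with a warning. The diagonal is set to 1.
#'
#' @param expr Numeric genes x samples matrix (already variance-filtered).
#' @param algorithm One of `"hc"`, `"km"`, `"nmf"`.
#' @param k Number of clusters.
#' @param resamplings Number of subsampled clustering runs (default 100).
#' @param fraction Fraction of samples drawn per run (default 0.8).
#' @param seed Master seed; one independent RNG stream is derived per
#'   (algorithm, k) so each run is reproducible in isolation.
#' @param nmf_nonneg Non-negativity mode handed to the NMF base clusterer.
#' @return An object of class `consensus_run` with elements `algorithm`,
#'   `k`, `consensus` (samples x samples, in `[0, 1]`), `cosample_counts`
#'   and `params`.
#' @export
consensus_matrix <- function(expr, algorithm = c("hc", "km", "nmf"), k,
                             resamplings = 100, fraction = 0.8, seed = NULL,
                             nmf_nonneg = "shift") {
  assert_expression(expr)
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 2, resamplings >= 1, fraction > 0, fraction <= 1)
  x <- samples_by_genes(expr)
  n <- nrow(x)
  m <- ceiling(fraction * n)
  if (k > m) stop("k (", k, ") exceeds subsample size (", m, ")")
  set_stream(seed, "consensus", algorithm, k)
  base <- switch(algorithm,
                 hc = function(sub) base_cluster_hc(sub, k),
                 km = function(sub) base_cluster_km(sub, k),
                 nmf = function(sub) base_cluster_nmf(sub, k, nonneg = nmf_nonneg))
  conn <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (r in seq_len(resamplings)) {
    idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
    labs <- base(x[idx, , drop = FALSE])
    same <- outer(labs, labs, "==")
    conn[idx, idx] <- conn[idx, idx] + same
    cnt[idx, idx] <- cnt[idx, idx] + 1L
  }
  cons <- matrix(0, n, n)
  pos <- cnt > 0
  cons[pos] <- conn[pos] / cnt[pos]
  never <- !pos & upper.tri(cnt)
  if (any(never))
    warning(sum(never), " sample pair(s) were never co-sampled; their ",
            "consensus is set to 0 (", algorithm, ", k=", k, ")")
  diag(cons) <- 1
  dimnames(cons) <- list(rownames(x), rownames(x))
  dimnames(cnt) <- dimnames(cons)
  structure(list(algorithm = algorithm, k = k, consensus = cons,
                 cosample_counts = cnt,
                 params = list(resamplings = resamplings, fraction = fraction,
                               seed = seed, nmf_nonneg = nmf_nonneg)),
            class = "consensus_run")
}

#' Final cluster labels from a consensus matrix
#'
#' Hierarchically clusters the samples on the dissimilarity `1 - consensus`
#' (average linkage) and cuts the tree at `k`, yielding the algorithm's
#' final cluster assignment.
#'
#' @param run A `consensus_run`.
#' @param k Number of clusters; defaults to the run's own `k`.
#' @return Named integer vector of labels in `1..k` (names are sample ids).
#' @export
consensus_labels <- function(run, k = run$k) {
  stopifnot(inherits(run, "consensus_run"))
  d <- stats::as.dist(1 - run$consensus)
  if (max(d) == min(d))
    stop("degenerate consensus matrix (all off-diagonal values equal) for ",
         run$algorithm, ", k=", k)
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' Cophenetic correlation coefficient of a consensus run
#'
#' Pearson correlation between the `1 - consensus` dissimilarities and the
#' cophenetic distances of the average-linkage tree built on them. Values
#' near 1 indicate the consensus matrix is close to ultrametric, i.e. the
#' clustering is stable. Returns `NA` when either distance vector has zero
#' variance (the score is undefined and that k is treated as non-preferred).
#'
#' @param run A `consensus_run`.
#' @return A single numeric value in `[-1, 1]`, or `NA`.
#' @export
cophenetic_coefficient <- function(run) {
  stopifnot(inherits(run, "consensus_run"))
  d <- stats::as.dist(1 - run$consensus)
  if (stats::sd(d) == 0) return(NA_real_)
  cc <- stats::cophenetic(stats::hclust(d, method = "average"))
  if (stats::sd(cc) == 0) return(NA_real_)
  stats::cor(d, cc)
}

#' Silhouette widths for a labeled dissimilarity
#'
#' Computes the per-sample silhouette width s(i) = (b(i) - a(i)) /
#' max(a(i), b(i)), where a(i) is the mean dissimilarity to the sample's own
#' cluster (excluding itself) and b(i) the smallest mean dissimilarity to any
#' other cluster; members of singleton clusters score 0. Delegates to
#' [cluster::silhouette()].
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param labels Integer cluster labels (at least 2 distinct values).
#' @return List with `widths` (named per-sample values) and `mean`.
#' @export
silhouette_widths <- function(d, labels) {
  dm <- as.matrix(d)
  if (length(labels) != nrow(dm))
    stop("labels length does not match dissimilarity dimension")
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(as.integer(labels), dmatrix = dm)
  widths <- sil[, "sil_width"]
  names(widths) <- if (!is.null(rownames(dm))) rownames(dm) else names(labels)
  list(widths = widths, mean = mean(widths))
}

#' Sweep consensus clustering over algorithms and k values
#'
#' Runs [consensus_matrix()] for every requested (algorithm, k), derives
#' final labels, and scores each run with the cophenetic correlation
#' coefficient and the mean silhouette width on the `1 - consensus`
#' dissimilarity. These two scores drive the choice of k (see [choose_k()]).
#'
#' @inheritParams consensus_matrix
#' @param algorithms Character vector from `c("hc", "km", "nmf")`.
#' @param k_range Integer vector of k values (default `2:10`). May also be a
#'   named list giving a different k vector per algorithm.
#' @return An object of class `k_sweep`: list with `metrics` (data frame:
#'   algorithm, k, cophenetic, mean_silhouette, min_cluster_size) and `runs`
#'   (named list of `consensus_run` objects, each augmented with `labels`
#'   and `silhouette`).
#' @export
k_sweep <- function(expr, algorithms = c("hc", "km", "nmf"), k_range = 2:10,
                    resamplings = 100, fraction = 0.8, seed = NULL,
                    nmf_nonneg = "shift") {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  ks_for <- function(alg) {
    ks <- if (is.list(k_range)) k_range[[alg]] else k_range
    sort(unique(as.integer(ks)))
  }
  runs <- list()
  rows <- list()
  for (alg in algorithms) {
    for (k in ks_for(alg)) {
      run <- consensus_matrix(expr, alg, k, resamplings = resamplings,
                              fraction = fraction, seed = seed,
                              nmf_nonneg = nmf_nonneg)
      run$labels <- consensus_labels(run)
      run$cophenetic <- cophenetic_coefficient(run)
      run$silhouette <- silhouette_widths(1 - run$consensus, run$labels)
      runs[[paste0(alg, "_", k)]] <- run
      rows[[paste0(alg, "_", k)]] <- data.frame(
        algorithm = alg, k = k,
        cophenetic = run$cophenetic,
        mean_silhouette = run$silhouette$mean,
        min_cluster_size = min(table(run$labels)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(metrics = do.call(rbind, c(rows, make.row.names = FALSE)),
                 runs = runs),
            class = "k_sweep")
}

#' Choose the number of clusters per algorithm
#'
#' In `"explicit"` mode the user-supplied `overrides` (named vector, e.g.
#' `c(hc = 6, km = 7, nmf = 6)`) are returned verbatim after checking they
#' were swept. In `"auto"` mode the rule returns, per algorithm, the largest
#' k whose cophenetic coefficient AND mean silhouette are both within `eps`
#' (absolute) of that algorithm's maxima over the sweep — a reproducible
#' codification of preferring the finest stratification whose quality scores
#' are approximately as good as the best. Runs with an undefined (NA)
#' cophenetic score are never preferred.
#'
#' @param metrics A `k_sweep` object or its `metrics` data frame.
#' @param mode `"auto"` or `"explicit"`.
#' @param overrides Named integer vector of k per algorithm (explicit mode).
#' @param eps Absolute tolerance for "approximately equal" (default 0.01).
#' @return Named integer vector: chosen k per algorithm.
#' @export
choose_k <- function(metrics, mode = c("auto", "explicit"), overrides = NULL,
                     eps = 0.01) {
  mode <- match.arg(mode)
  if (inherits(metrics, "k_sweep")) metrics <- metrics$metrics
  algs <- unique(metrics$algorithm)
  if (mode == "explicit") {
    if (is.null(overrides) || is.null(names(overrides)))
      stop("explicit mode requires a named overrides vector")
    out <- integer(0)
    for (alg in names(overrides)) {
      k <- as.integer(overrides[[alg]])
      swept <- metrics$k[metrics$algorithm == alg]
      if (!k %in% swept)
        stop("override k=", k, " for '", alg, "' is outside the swept range (",
             paste(range(swept), collapse = ":"), ")")
      out[alg] <- k
    }
    return(out)
  }
  out <- integer(0)
  for (alg in algs) {
    sub <- metrics[metrics$algorithm == alg & !is.na(metrics$cophenetic), ,
                   drop = FALSE]
    if (nrow(sub) == 0)
      stop("no scored k available for algorithm '", alg, "'")
    ok <- sub$cophenetic >= max(sub$cophenetic) - eps &
      sub$mean_silhouette >= max(sub$mean_silhouette) - eps
    out[alg] <- max(sub$k[ok])
  }
  out
}

#' @export
print.consensus_run <- function(x, ...) {
  cat("Consensus run:", x$algorithm, "k =", x$k, "|",
      nrow(x$consensus), "samples,", x$params$resamplings, "resamplings\n")
  invisible(x)
}

#' @export
print.k_sweep <- function(x, ...) {
  cat("Consensus k sweep:\n")
  print(x$metrics, ...)
  invisible(x)
}
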