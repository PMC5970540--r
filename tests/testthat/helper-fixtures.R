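# Shared fixtures and independent oracles for the test suite.

# Independent hypergeometric upper-tail oracle by direct enumeration of the
# counting formula (never calls phyper).
enum_hyper_p <- function(n_total, n_a, n_b, overlap) {
  lo <- max(overlap, 0, n_a + n_b - n_total)
  hi <- min(n_a, n_b)
  if (lo > hi) return(0)
  sum(vapply(lo:hi, function(j)
    choose(n_a, j) * choose(n_total - n_a, n_b - j), 0)) / choose(n_total, n_b)
}

# Exhaustive-merge average-linkage oracle: repeatedly merge the cluster pair
# with the smallest average inter-cluster distance until k clusters remain.
avg_linkage_oracle <- function(dmat, k) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labs <- integer(n)
  for (i in seq_along(clusters)) labs[clusters[[i]]] <- i
  labs
}

# Brute-force minimum within-cluster sum of squares over all 2-partitions.
brute_min_wss_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {   # fix point 1 in cluster 1 (symmetry)
    in1 <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
    if (all(in1) || !any(in1)) next
    wss <- function(sub) sum(sweep(sub, 2, colMeans(sub))^2)
    best <- min(best, wss(x[in1, , drop = FALSE]) + wss(x[!in1, , drop = FALSE]))
  }
  best
}

wss_of_labels <- function(x, labs) {
  sum(vapply(unique(labs), function(l) {
    sub <- x[labs == l, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, 0))
}

# Same-cluster partition equality up to label renaming.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Two well-separated communities, no sub-structure.
make_blobs <- function(n_samples = 24, n_genes = 120, mpg = 30,
                       effect = 6, seed = 101) {
  generate_expression(planted_design(
    n_samples = n_samples, n_genes = n_genes, n_communities = 2,
    subclusters_per_community = 1, marker_genes_per_group = mpg,
    effect_size = effect, sub_effect_size = 0, noise_sd = 1,
    hazards = c(0.1, 0.3), seed = seed))
}

# Nested two-algorithm labeling: algorithm A's 2 clusters are exact unions of
# algorithm B's 4 clusters (80 samples).
nested_labels <- function() {
  ids <- sprintf("s%02d", 1:80)
  a <- stats::setNames(rep(1:2, each = 40), ids)
  b <- stats::setNames(rep(1:4, each = 20), ids)
  list(coarse = a, fine = b)
}
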