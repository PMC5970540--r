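#' Build cluster nodes from per-algorithm label vectors
#'
#' Each cluster from each algorithm becomes one node of the reconciliation
#' network, carrying its member sample set. All algorithms must partition the
#' same sample set.
#'
#' @param labels_list Named list (one element per algorithm) of named integer
#'   label vectors (names are sample ids).
#' @return Object of class `cluster_nodes`: list with `nodes` (named list of
#'   `list(algorithm, cluster_index, members)`), `samples` and `algorithms`.
#' @export
make_cluster_nodes <- function(labels_list) {
  if (is.null(names(labels_list)) || any(!nzchar(names(labels_list))))
    stop("labels_list must be a named list (one element per algorithm)")
  samples <- sort(names(labels_list[[1]]))
  nodes <- list()
  for (alg in names(labels_list)) {
    labs <- labels_list[[alg]]
    if (is.null(names(labs)))
      stop("labels for '", alg, "' must be named by sample id")
    if (!identical(sort(names(labs)), samples))
      stop("algorithm '", alg, "' does not label the same sample set")
    for (cl in sort(unique(labs))) {
      id <- paste0(alg, ".", cl)
      nodes[[id]] <- list(algorithm = alg, cluster_index = as.integer(cl),
                          members = names(labs)[labs == cl])
    }
  }
  structure(list(nodes = nodes, samples = samples,
                 algorithms = names(labels_list)),
            class = "cluster_nodes")
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing an overlap at least as large as `overlap` between
#' a cluster of size `n_a` and a cluster of size `n_b` drawn from a
#' population of `n_total` samples: `P(X >= overlap)` for
#' `X ~ Hypergeometric(n_total, n_a, n_b)`.
#'
#' @param n_total Population size (number of samples clustered).
#' @param n_a,n_b Sizes of the two clusters.
#' @param overlap Observed intersection size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_overlap_p <- function(n_total, n_a, n_b, overlap) {
  stopifnot(n_a <= n_total, n_b <= n_total, overlap >= 0)
  if (overlap > min(n_a, n_b))
    stop("overlap (", overlap, ") exceeds the smaller cluster size (",
         min(n_a, n_b), ")")
  if (overlap < n_a + n_b - n_total)
    stop("impossible overlap: smaller than forced intersection")
  stats::phyper(overlap - 1, n_a, n_total - n_a, n_b, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment, order-preserving with the input and clipped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order and length.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Proportion of maximum intersection (PMI) between two clusters
#'
#' `PMI = |A intersect B| / min(|A|, |B|)`: the overlap of two clusters as a
#' proportion of the largest overlap their sizes allow. PMI is 0 when the
#' clusters are disjoint and 1 when the smaller cluster is contained in the
#' larger; unlike the Jaccard index it scores a small sub-subtype nested in a
#' large cluster as highly as two identical equal-sized clusters.
#'
#' @param a,b Character vectors of member sample ids, or cluster-node lists
#'   with a `members` element.
#' @return A value in `[0, 1]`.
#' @export
pmi <- function(a, b) {
  members <- function(x) if (is.list(x)) x$members else x
  a <- members(a); b <- members(b)
  if (length(a) == 0 || length(b) == 0)
    stop("PMI is undefined for empty clusters")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Build a cluster-overlap reconciliation network
#'
#' Nodes are the clusters of all algorithms; candidate edges are all
#' cross-algorithm cluster pairs. In `"hyp"` mode each pair's overlap is
#' tested with [hypergeom_overlap_p()], p-values are BH-adjusted jointly over
#' all pairs, edges with FDR below `fdr_alpha` are kept, and the propagation
#' weight is `-log10(FDR)` (floored at 1e-300) so stronger overlaps carry
#' larger weight. In `"pmi"` mode edges with PMI at or above `pmi_min` are
#' kept, weighted by the PMI itself. A network with no surviving edges is
#' valid: every node then forms its own community.
#'
#' @param nodes A `cluster_nodes` object (from [make_cluster_nodes()]).
#' @param mode `"hyp"` or `"pmi"`.
#' @param fdr_alpha FDR threshold for edge inclusion in HYP mode.
#' @param pmi_min Minimum PMI for edge inclusion in PMI mode.
#' @return Object of class `recon_network`: list with `nodes`, `edges`
#'   (data frame: node_a, node_b, overlap, raw_stat, fdr, weight), `mode`
#'   and `params`. `fdr` is `NA` in PMI mode.
#' @export
build_network <- function(nodes, mode = c("hyp", "pmi"), fdr_alpha = 0.05,
                          pmi_min = 0.1) {
  stopifnot(inherits(nodes, "cluster_nodes"))
  mode <- match.arg(mode)
  if (length(nodes$algorithms) < 2)
    stop("reconciliation requires cluster sets from at least 2 algorithms")
  n_total <- length(nodes$samples)
  ids <- names(nodes$nodes)
  pairs <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      a <- nodes$nodes[[ids[i]]]; b <- nodes$nodes[[ids[j]]]
      if (a$algorithm == b$algorithm) next
      ov <- length(intersect(a$members, b$members))
      pairs[[length(pairs) + 1L]] <- data.frame(
        node_a = ids[i], node_b = ids[j], overlap = ov,
        n_a = length(a$members), n_b = length(b$members),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (mode == "hyp") {
    pairs$raw_stat <- mapply(function(na, nb, ov)
      hypergeom_overlap_p(n_total, na, nb, ov),
      pairs$n_a, pairs$n_b, pairs$overlap)
    pairs$fdr <- bh_fdr(pairs$raw_stat)
    keep <- pairs$fdr < fdr_alpha
    pairs$weight <- -log10(pmax(pairs$fdr, 1e-300))
  } else {
    pairs$raw_stat <- pairs$overlap / pmin(pairs$n_a, pairs$n_b)
    pairs$fdr <- NA_real_
    keep <- pairs$raw_stat >= pmi_min
    pairs$weight <- pairs$raw_stat
  }
  edges <- pairs[keep, c("node_a", "node_b", "overlap", "raw_stat", "fdr",
                         "weight"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = toupper(mode),
                 params = list(fdr_alpha = fdr_alpha, pmi_min = pmi_min)),
            class = "recon_network")
}

#' Weighted asynchronous label propagation community detection
#'
#' Every node starts with a unique label. Nodes are visited in a seeded
#' random order; each adopts the label whose incident edge weights sum
#' highest among its neighbors (keeping its current label when that label
#' already attains the maximum; ties between competing labels are broken
#' uniformly at random from the seeded stream). Sweeps repeat until every
#' node's label attains its neighborhood maximum; isolated nodes keep their
#' unique labels. Communities are renumbered 1..C by decreasing total sample
#' membership (ties by node count, then by first node id).
#'
#' @param net A `recon_network`.
#' @param seed Optional integer seed for visit order and tie-breaks.
#' @param max_sweeps Sweep cap; exceeding it raises a convergence warning.
#' @return Named integer vector mapping cluster node id to community id.
#' @export
label_propagation <- function(net, seed = NULL, max_sweeps = 1000) {
  stopifnot(inherits(net, "recon_network"))
  ids <- names(net$nodes$nodes)
  n <- length(ids)
  lab <- stats::setNames(seq_len(n), ids)
  if (!is.null(seed)) set.seed(seed)
  nbr <- lapply(stats::setNames(ids, ids), function(v) {
    a <- net$edges$node_b[net$edges$node_a == v]
    b <- net$edges$node_a[net$edges$node_b == v]
    w <- c(net$edges$weight[net$edges$node_a == v],
           net$edges$weight[net$edges$node_b == v])
    list(ids = c(a, b), w = w)
  })
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    stable <- TRUE
    for (v in sample(ids)) {
      nb <- nbr[[v]]
      if (length(nb$ids) == 0) next
      wsum <- tapply(nb$w, lab[nb$ids], sum)
      best <- as.integer(names(wsum)[wsum == max(wsum)])
      if (lab[v] %in% best) next
      stable <- FALSE
      lab[v] <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
    }
    if (stable) { converged <- TRUE; break }
  }
  if (!converged)
    warning("label propagation did not converge within ", max_sweeps, " sweeps")
  # renumber by decreasing community sample membership
  sizes <- vapply(net$nodes$nodes, function(nd) length(nd$members), 0L)
  comm <- unique(unname(lab))
  msize <- vapply(comm, function(cc) sum(sizes[names(lab)[lab == cc]]), 0)
  ncount <- vapply(comm, function(cc) sum(lab == cc), 0L)
  first <- vapply(comm, function(cc) min(which(lab == cc)), 0L)
  ord <- comm[order(-msize, -ncount, first)]
  stats::setNames(match(lab, ord), ids)
}

#' Assign samples to communities by per-algorithm majority vote
#'
#' Each sample carries one vote per algorithm: the community of its cluster
#' under that algorithm. The majority community wins; ties are broken toward
#' the candidate whose voting clusters have the largest combined membership,
#' then toward the lowest community id.
#'
#' @param nodes A `cluster_nodes` object.
#' @param cluster_to_community Named vector from [label_propagation()].
#' @return Named integer vector: community per sample id.
#' @export
assign_samples_to_communities <- function(nodes, cluster_to_community) {
  stopifnot(inherits(nodes, "cluster_nodes"))
  sizes <- vapply(nodes$nodes, function(nd) length(nd$members), 0L)
  out <- stats::setNames(integer(length(nodes$samples)), nodes$samples)
  # node id of each sample's cluster, per algorithm
  sample_nodes <- lapply(nodes$algorithms, function(alg) {
    ids <- names(nodes$nodes)[vapply(nodes$nodes, function(nd)
      nd$algorithm == alg, TRUE)]
    map <- stats::setNames(rep(NA_character_, length(nodes$samples)),
                           nodes$samples)
    for (id in ids) map[nodes$nodes[[id]]$members] <- id
    map
  })
  for (s in nodes$samples) {
    vnodes <- vapply(sample_nodes, function(map) map[[s]], "")
    if (anyNA(vnodes) || any(!nzchar(vnodes)))
      stop("sample '", s, "' is missing from at least one algorithm's labeling")
    votes <- cluster_to_community[vnodes]
    tab <- table(votes)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) > 1) {
      support <- vapply(winners, function(cc)
        sum(sizes[vnodes[votes == cc]]), 0)
      winners <- winners[support == max(support)]
      winners <- min(winners)
    }
    out[s] <- winners[1]
  }
  out
}

#' Silhouette widths of a community assignment on expression data
#'
#' Scores sample-level communities with the silhouette width on the filtered
#' expression matrix, using Euclidean distance between sample profiles (the
#' clustering distance) or `1 - Pearson` correlation. With fewer than 2
#' communities the score is undefined and a sentinel (`NA` mean, no widths)
#' is returned; such a reconciliation cannot win selection.
#'
#' @param expr Numeric genes x samples matrix.
#' @param sample_to_community Named integer vector (names are sample ids).
#' @param distance `"euclidean"` or `"pearson"`.
#' @return List with `widths`, `mean`, `n_communities`.
#' @export
community_silhouette <- function(expr, sample_to_community,
                                 distance = c("euclidean", "pearson")) {
  assert_expression(expr)
  distance <- match.arg(distance)
  labs <- sample_to_community[colnames(expr)]
  if (anyNA(labs)) stop("community assignment missing for some samples")
  if (length(unique(labs)) < 2)
    return(list(widths = NULL, mean = NA_real_,
                n_communities = length(unique(labs))))
  d <- if (distance == "euclidean") stats::dist(samples_by_genes(expr))
       else stats::as.dist(1 - stats::cor(expr))
  sw <- silhouette_widths(d, labs)
  list(widths = sw$widths, mean = sw$mean,
       n_communities = length(unique(labs)))
}

#' Bundle one reconciliation into a community solution
#'
#' @param mode `"HYP"` or `"PMI"`.
#' @param cluster_to_community,sample_to_community Mappings from
#'   [label_propagation()] and [assign_samples_to_communities()].
#' @param silhouette Result of [community_silhouette()].
#' @return Object of class `community_solution`.
#' @export
community_solution <- function(mode, cluster_to_community,
                               sample_to_community, silhouette) {
  structure(list(mode = mode,
                 cluster_to_community = cluster_to_community,
                 sample_to_community = sample_to_community,
                 silhouette = silhouette,
                 mean_silhouette = silhouette$mean,
                 n_communities = length(unique(sample_to_community))),
            class = "community_solution")
}

#' Select the reconciliation with the higher average silhouette width
#'
#' Ties go to the hypergeometric solution; a solution with an undefined
#' (sentinel) silhouette cannot win. Both solutions and their scores are
#' retained in the report.
#'
#' @param hyp,pmi `community_solution` objects (either may be `NULL` if that
#'   reconciliation was not run).
#' @return List with `chosen` (a `community_solution`), `mode`, and `report`
#'   (data frame of both modes' mean silhouettes and status).
#' @export
select_reconciliation <- function(hyp = NULL, pmi = NULL) {
  score <- function(sol) if (is.null(sol)) NA_real_ else sol$mean_silhouette
  s_hyp <- score(hyp); s_pmi <- score(pmi)
  report <- data.frame(
    mode = c("HYP", "PMI"),
    mean_silhouette = c(s_hyp, s_pmi),
    status = c(if (is.null(hyp)) "not run" else "run",
               if (is.null(pmi)) "not run" else "run"),
    stringsAsFactors = FALSE)
  if (is.na(s_hyp) && is.na(s_pmi))
    stop("no reconciliation produced a scoreable community solution; ",
         "manual review required")
  mode <- if (is.na(s_pmi) || (!is.na(s_hyp) && s_hyp >= s_pmi)) "HYP" else "PMI"
  chosen <- if (mode == "HYP") hyp else pmi
  report$chosen <- report$mode == mode
  list(chosen = chosen, mode = mode, report = report)
}

#' Test association between a grouping and known sample labels
#'
#' For every (group, known label) cell, computes the upper-tail
#' hypergeometric probability of the observed overlap and BH-adjusts across
#' the whole table. Global association is tested with a seeded Monte-Carlo
#' permutation test of the chi-square statistic (the practical stand-in for
#' an r x c Fisher exact test). Unannotated samples are excluded with a
#' warning; annotation must cover at least half the samples.
#'
#' @param labels Named vector: group (cluster or community) per sample id.
#' @param annotations Named character vector: known label per sample id.
#' @param n_perm Number of Monte-Carlo permutations (default 1e5).
#' @param seed Optional seed for the permutation test.
#' @return List with `table` (data frame: group, known_label, overlap, p,
#'   fdr), `global_p` and `n_used`.
#' @export
enrichment_vs_known <- function(labels, annotations, n_perm = 1e5,
                                seed = NULL) {
  common <- intersect(names(labels), names(annotations))
  if (length(common) < 0.5 * length(labels))
    stop("annotation covers fewer than 50% of samples (",
         length(common), "/", length(labels), ")")
  if (length(common) < length(labels))
    warning(length(labels) - length(common),
            " unannotated sample(s) excluded from enrichment")
  grp <- as.character(labels[common])
  ann <- as.character(annotations[common])
  tab <- table(grp, ann)
  n <- length(common)
  cells <- expand.grid(group = rownames(tab), known_label = colnames(tab),
                       stringsAsFactors = FALSE)
  cells$overlap <- mapply(function(g, l) tab[g, l],
                          cells$group, cells$known_label)
  cells$p <- mapply(function(g, l)
    hypergeom_overlap_p(n, sum(tab[g, ]), sum(tab[, l]), tab[g, l]),
    cells$group, cells$known_label)
  cells$fdr <- bh_fdr(cells$p)
  global_p <- NA_real_
  if (ncol(tab) < 2 || nrow(tab) < 2) {
    warning("fewer than 2 groups or known labels; global association test skipped")
  } else {
    set_stream(seed, "enrichment-perm")
    global_p <- stats::chisq.test(tab, simulate.p.value = TRUE,
                                  B = n_perm)$p.value
  }
  list(table = cells, global_p = global_p, n_used = n)
}

#' @export
print.recon_network <- function(x, ...) {
  cat("Reconciliation network (", x$mode, "): ",
      length(x$nodes$nodes), " cluster nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
print.community_solution <- function(x, ...) {
  cat("Community solution (", x$mode, "): ", x$n_communities,
      " communities, mean silhouette ",
      formatC(x$mean_silhouette, digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}
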