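#' Describe a planted-structure synthetic cohort
#'
#' Defines a genes x samples design with top-level communities, optional
#' nested sub-clusters, block mean shifts for marker genes, Gaussian noise,
#' and community-dependent exponential survival. The defaults mirror a
#' desk-scale expression cohort: ~120 samples, 2000 variance-filtered genes,
#' three communities of two sub-clusters each, community markers shifted by
#' 6 noise SDs and sub-cluster markers by a further 3.
#'
#' @param n_samples Total samples (split as evenly as possible across
#'   sub-clusters).
#' @param n_genes Total genes.
#' @param n_communities Number of top-level communities.
#' @param subclusters_per_community Scalar or per-community vector of nested
#'   sub-cluster counts (1 = no nesting).
#' @param marker_genes_per_group Marker block size per community and per
#'   sub-cluster; all blocks are disjoint and must fit in `n_genes`.
#' @param effect_size Community marker shift, in units of `noise_sd`.
#' @param sub_effect_size Sub-cluster marker shift, in units of `noise_sd`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param hazards Per-community exponential event rates; default geometric
#'   spacing `0.05 * 3^(c-1)` so communities differ in prognosis.
#' @param censor_rate Exponential censoring rate (0 disables censoring).
#' @param seed Master seed for the generator.
#' @return Object of class `planted_design`.
#' @export
planted_design <- function(n_samples = 120, n_genes = 2000,
                           n_communities = 3, subclusters_per_community = 2,
                           marker_genes_per_group = 100,
                           effect_size = 6, sub_effect_size = 3,
                           noise_sd = 1,
                           hazards = 0.05 * 3^(seq_len(n_communities) - 1),
                           censor_rate = 0.05, seed = 1) {
  sub <- rep_len(as.integer(subclusters_per_community), n_communities)
  stopifnot(n_samples >= 2, n_genes >= 2, n_communities >= 1, all(sub >= 1),
            effect_size >= 0, sub_effect_size >= 0, noise_sd > 0,
            length(hazards) == n_communities, all(hazards > 0),
            censor_rate >= 0)
  total_sub <- sum(sub)
  base <- n_samples %/% total_sub
  sizes <- rep(base, total_sub)
  extra <- n_samples - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  n_blocks <- n_communities + if (any(sub > 1)) total_sub else 0L
  if (n_blocks * marker_genes_per_group > n_genes)
    stop("marker blocks (", n_blocks * marker_genes_per_group,
         " genes) exceed n_genes (", n_genes, ")")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_communities = n_communities, subclusters = sub,
                 subcluster_sizes = sizes,
                 marker_genes_per_group = marker_genes_per_group,
                 effect_size = effect_size, sub_effect_size = sub_effect_size,
                 noise_sd = noise_sd, hazards = hazards,
                 censor_rate = censor_rate, seed = seed),
            class = "planted_design")
}

#' Generate a planted-structure expression matrix
#'
#' Background is gene/sample Gaussian noise; each community's marker block
#' is shifted by `effect_size * noise_sd` in that community's samples, and
#' each sub-cluster's marker block by a further
#' `sub_effect_size * noise_sd`. Deterministic under the design seed.
#'
#' @param design A `planted_design`.
#' @return List with `expr` (genes x samples matrix), `community` and
#'   `subcluster` (named true-label vectors) and `design`.
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  set_stream(design$seed, "expression")
  n <- design$n_samples; p <- design$n_genes
  sample_ids <- sprintf("s%03d", seq_len(n))
  gene_ids <- sprintf("g%04d", seq_len(p))
  # global sub-cluster index and community per sample
  sub_of_comm <- rep(seq_len(design$n_communities), design$subclusters)
  sub_lab <- rep(seq_along(design$subcluster_sizes), design$subcluster_sizes)
  comm_lab <- sub_of_comm[sub_lab]
  expr <- matrix(stats::rnorm(p * n, 0, design$noise_sd), p, n,
                 dimnames = list(gene_ids, sample_ids))
  mpg <- design$marker_genes_per_group
  block <- function(i) ((i - 1) * mpg + 1):(i * mpg)
  for (cc in seq_len(design$n_communities)) {
    expr[block(cc), comm_lab == cc] <-
      expr[block(cc), comm_lab == cc] + design$effect_size * design$noise_sd
  }
  if (any(design$subclusters > 1)) {
    off <- design$n_communities
    for (sc in seq_along(design$subcluster_sizes)) {
      expr[block(off + sc), sub_lab == sc] <-
        expr[block(off + sc), sub_lab == sc] +
        design$sub_effect_size * design$noise_sd
    }
  }
  list(expr = expr,
       community = stats::setNames(comm_lab, sample_ids),
       subcluster = stats::setNames(sub_lab, sample_ids),
       design = design)
}

#' Generate community-dependent exponential survival records
#'
#' Event times are exponential at the sample's community hazard; censoring
#' times are exponential at `censor_rate` (none when the rate is 0). The
#' observed time is the minimum of the two and the event indicator records
#' whether the event preceded censoring.
#'
#' @param labels Named vector: community (1-based) per sample id.
#' @param design A `planted_design` supplying hazards, censor rate and seed.
#' @return Data frame with columns sample_id, time, event.
#' @export
generate_survival <- function(labels, design) {
  stopifnot(inherits(design, "planted_design"))
  comm <- as.integer(labels)
  if (anyNA(comm) || any(comm < 1 | comm > length(design$hazards)))
    stop("unknown community label in survival generation")
  set_stream(design$seed, "survival")
  n <- length(labels)
  t_event <- stats::rexp(n, design$hazards[comm])
  t_cens <- if (design$censor_rate > 0) stats::rexp(n, design$censor_rate)
            else rep(Inf, n)
  data.frame(sample_id = names(labels),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}
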