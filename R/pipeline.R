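#' Run the full subtype-community discovery pipeline
#'
#' Orchestrates: variance filtering, the consensus k sweep for each base
#' algorithm, the k choice (explicit or automatic), construction of the
#' hypergeometric and/or PMI reconciliation networks, weighted label
#' propagation, sample-to-community assignment, silhouette scoring of each
#' reconciliation, selection of the better one, and (optionally) enrichment
#' against known labels and a survival comparison across the chosen
#' communities. When `outdir` is given all artifacts plus a reproducibility
#' manifest are written with [write_outputs()].
#'
#' When explicit `k` values are supplied the sweep is restricted to those
#' values; the full `k_range` sweep is only run for automatic selection.
#'
#' @param expr Numeric genes x samples matrix (unfiltered).
#' @param outdir Optional output directory.
#' @param algorithms Base algorithms to run, from `c("hc", "km", "nmf")`.
#' @param k Named vector of explicit k per algorithm (e.g.
#'   `c(hc = 6, km = 7, nmf = 6)`), or `NULL` for automatic choice.
#' @param k_range k values swept in automatic mode (default `2:10`).
#' @param sd_threshold SD filter cutoff (default 0.8); `NULL` skips filtering.
#' @param resamplings,fraction Consensus subsampling parameters.
#' @param reconcile Reconciliation modes to run, subset of `c("hyp", "pmi")`.
#' @param fdr_alpha,pmi_min Edge-inclusion thresholds (see [build_network()]).
#' @param distance Distance for community silhouettes (`"euclidean"` or
#'   `"pearson"`).
#' @param annotations Optional named known-label vector for enrichment.
#' @param survival Optional survival data frame (sample_id, time, event).
#' @param nmf_nonneg NMF non-negativity mode (`"shift"` or `"posneg"`).
#' @param seed Master seed; all stochastic stages derive independent
#'   streams from it.
#' @param choose_k_eps Tolerance for the automatic k rule.
#' @return Object of class `polyrecon_result`: list with `filtered_expr`,
#'   `sweep`, `chosen_k`, `labels`, `networks`, `solutions`, `selection`,
#'   `enrichment`, `survival`, `params`.
#' @export
run_pipeline <- function(expr, outdir = NULL,
                         algorithms = c("hc", "km", "nmf"),
                         k = NULL, k_range = 2:10,
                         sd_threshold = 0.8,
                         resamplings = 100, fraction = 0.8,
                         reconcile = c("hyp", "pmi"),
                         fdr_alpha = 0.05, pmi_min = 0.1,
                         distance = "euclidean",
                         annotations = NULL, survival = NULL,
                         nmf_nonneg = "shift", seed = NULL,
                         choose_k_eps = 0.01) {
  assert_expression(expr)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  reconcile <- match.arg(reconcile, c("hyp", "pmi"), several.ok = TRUE)
  stage <- function(...) message("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)

  stage("filter: variance filtering")
  filt <- if (is.null(sd_threshold)) expr else filter_by_sd(expr, sd_threshold)

  explicit <- !is.null(k)
  if (explicit) {
    missing_alg <- setdiff(algorithms, names(k))
    if (length(missing_alg) > 0)
      stop("explicit k missing for algorithm(s): ",
           paste(missing_alg, collapse = ", "))
    sweep_ks <- lapply(stats::setNames(algorithms, algorithms),
                       function(a) as.integer(k[[a]]))
  } else {
    sweep_ks <- k_range
  }
  stage("sweep: consensus clustering (",
        paste(algorithms, collapse = ", "), ")")
  sw <- k_sweep(filt, algorithms = algorithms, k_range = sweep_ks,
                resamplings = resamplings, fraction = fraction,
                seed = seed, nmf_nonneg = nmf_nonneg)

  stage("choose_k: ", if (explicit) "explicit" else "auto")
  chosen_k <- choose_k(sw, mode = if (explicit) "explicit" else "auto",
                       overrides = if (explicit) k[algorithms] else NULL,
                       eps = choose_k_eps)

  labels_list <- lapply(stats::setNames(algorithms, algorithms), function(a)
    sw$runs[[paste0(a, "_", chosen_k[[a]])]]$labels)
  nodes <- make_cluster_nodes(labels_list)

  networks <- list(); solutions <- list()
  for (m in reconcile) {
    stage("reconcile: ", toupper(m), " network + label propagation")
    net <- build_network(nodes, mode = m, fdr_alpha = fdr_alpha,
                         pmi_min = pmi_min)
    c2c <- label_propagation(net, seed = derive_seed(seed, "lpa", m))
    s2c <- assign_samples_to_communities(nodes, c2c)
    sil <- community_silhouette(filt, s2c, distance = distance)
    networks[[m]] <- net
    solutions[[m]] <- community_solution(toupper(m), c2c, s2c, sil)
  }

  stage("select: best reconciliation by mean silhouette")
  selection <- select_reconciliation(hyp = solutions[["hyp"]],
                                     pmi = solutions[["pmi"]])
  chosen <- selection$chosen

  enrichment <- NULL
  if (!is.null(annotations)) {
    stage("enrichment: association with known labels")
    enrichment <- enrichment_vs_known(chosen$sample_to_community, annotations,
                                      seed = derive_seed(seed, "perm"))
  }
  surv_out <- NULL
  if (!is.null(survival)) {
    stage("survival: Kaplan-Meier + log-rank across communities")
    groups <- chosen$sample_to_community[survival$sample_id]
    keep <- !is.na(groups)
    surv_out <- list(
      km = km_estimate(survival[keep, , drop = FALSE], groups[keep]),
      logrank = logrank_test(survival[keep, , drop = FALSE], groups[keep]))
  }

  res <- structure(list(filtered_expr = filt, sweep = sw,
                        chosen_k = chosen_k, labels = labels_list,
                        nodes = nodes, networks = networks,
                        solutions = solutions, selection = selection,
                        enrichment = enrichment, survival = surv_out,
                        params = list(algorithms = algorithms, k = k,
                                      k_range = k_range,
                                      sd_threshold = sd_threshold,
                                      resamplings = resamplings,
                                      fraction = fraction,
                                      reconcile = reconcile,
                                      fdr_alpha = fdr_alpha,
                                      pmi_min = pmi_min, distance = distance,
                                      nmf_nonneg = nmf_nonneg, seed = seed,
                                      choose_k_eps = choose_k_eps)),
                   class = "polyrecon_result")
  if (!is.null(outdir)) {
    stage("write: artifacts to ", outdir)
    write_outputs(res, outdir)
  }
  res
}

#' Write all pipeline artifacts to a directory
#'
#' Emits tab-separated tables with deterministic (ID-sorted) row order:
#' per-algorithm label tables, the per-k metrics table, each reconciliation
#' network as a weighted edge list and GraphML, cluster- and sample-level
#' community tables, silhouette tables, the selection report, optional
#' enrichment and survival tables, and a plain-text `manifest.txt` recording
#' the parameters and seed.
#'
#' @param res A `polyrecon_result` from [run_pipeline()].
#' @param outdir Directory to create/write into.
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(res, outdir) {
  stopifnot(inherits(res, "polyrecon_result"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0)
    stop("cannot write to output directory: ", outdir)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv(df, path)
    files <<- c(files, path)
  }
  for (alg in names(res$labels)) {
    labs <- res$labels[[alg]]
    df <- data.frame(sample_id = names(labs), cluster = unname(labs),
                     stringsAsFactors = FALSE)
    put(df[order(df$sample_id), ], paste0("labels_", alg, ".tsv"))
  }
  put(res$sweep$metrics, "k_metrics.tsv")
  for (m in names(res$networks)) {
    net <- res$networks[[m]]
    edges <- net$edges[order(net$edges$node_a, net$edges$node_b), ,
                       drop = FALSE]
    put(edges, paste0("network_", m, "_edges.tsv"))
    g <- igraph::graph_from_data_frame(
      edges[, c("node_a", "node_b", "weight")],
      directed = FALSE,
      vertices = data.frame(
        name = names(net$nodes$nodes),
        algorithm = vapply(net$nodes$nodes, `[[`, "", "algorithm"),
        size = vapply(net$nodes$nodes,
                      function(nd) length(nd$members), 0L)))
    gpath <- file.path(outdir, paste0("network_", m, ".graphml"))
    igraph::write_graph(g, gpath, format = "graphml")
    files <- c(files, gpath)
  }
  for (m in names(res$solutions)) {
    sol <- res$solutions[[m]]
    c2c <- data.frame(cluster_id = names(sol$cluster_to_community),
                      community = unname(sol$cluster_to_community),
                      stringsAsFactors = FALSE)
    put(c2c[order(c2c$cluster_id), ], paste0("communities_", m, "_clusters.tsv"))
    s2c <- data.frame(sample_id = names(sol$sample_to_community),
                      community = unname(sol$sample_to_community),
                      stringsAsFactors = FALSE)
    put(s2c[order(s2c$sample_id), ], paste0("communities_", m, "_samples.tsv"))
    if (!is.null(sol$silhouette$widths)) {
      sil <- data.frame(sample_id = names(sol$silhouette$widths),
                        community = unname(
                          sol$sample_to_community[names(sol$silhouette$widths)]),
                        sil_width = unname(sol$silhouette$widths),
                        stringsAsFactors = FALSE)
      put(sil[order(sil$sample_id), ], paste0("silhouette_", m, ".tsv"))
    }
  }
  put(res$selection$report, "selection.tsv")
  if (!is.null(res$enrichment)) {
    tab <- res$enrichment$table
    put(tab[order(tab$group, tab$known_label), ], "enrichment.tsv")
  }
  if (!is.null(res$survival)) {
    put(res$survival$km[order(res$survival$km$group, res$survival$km$time), ],
        "survival_km.tsv")
    lr <- res$survival$logrank
    put(data.frame(chi_square = lr$chi_square, df = lr$df,
                   p_value = lr$p_value), "survival_logrank.tsv")
  }
  p <- res$params
  manifest <- c(
    paste0("package_version=", as.character(utils::packageVersion("polyrecon"))),
    paste0("algorithms=", paste(p$algorithms, collapse = ",")),
    paste0("k=", if (is.null(p$k)) "auto" else
      paste(names(p$k), unname(p$k), sep = "=", collapse = ",")),
    paste0("k_range=", paste(range(p$k_range), collapse = ":")),
    paste0("sd_threshold=", if (is.null(p$sd_threshold)) "none" else p$sd_threshold),
    paste0("resamplings=", p$resamplings),
    paste0("subsample_fraction=", p$fraction),
    paste0("reconcile=", paste(p$reconcile, collapse = ",")),
    paste0("fdr_alpha=", p$fdr_alpha),
    paste0("pmi_min=", p$pmi_min),
    paste0("distance=", p$distance),
    paste0("nmf_nonneg=", p$nmf_nonneg),
    paste0("seed=", if (is.null(p$seed)) "none" else p$seed),
    paste0("choose_k_eps=", p$choose_k_eps))
  mpath <- file.path(outdir, "manifest.txt")
  writeLines(manifest, mpath)
  invisible(c(files, mpath))
}

#' @export
print.polyrecon_result <- function(x, ...) {
  cat("polyrecon pipeline result\n")
  cat("  chosen k:", paste(names(x$chosen_k), x$chosen_k, sep = "=",
                           collapse = ", "), "\n")
  print(x$selection$report)
  cat("  selected:", x$selection$mode, "with",
      x$selection$chosen$n_communities, "communities\n")
  invisible(x)
}
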