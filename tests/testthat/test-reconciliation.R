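test_that("hypergeometric overlap p matches enumeration on spot checks", {
  expect_equal(hypergeom_overlap_p(10, 5, 4, 0), 1.0)
  expect_equal(hypergeom_overlap_p(10, 10, 4, 4), 1.0)   # cluster = population
  expect_equal(hypergeom_overlap_p(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  for (cfg in list(c(8, 3, 5, 2), c(12, 6, 6, 4), c(9, 4, 4, 1))) {
    expect_equal(hypergeom_overlap_p(cfg[1], cfg[2], cfg[3], cfg[4]),
                 enum_hyper_p(cfg[1], cfg[2], cfg[3], cfg[4]),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_overlap_p(10, 5, 4, 5), "exceeds")
  expect_error(hypergeom_overlap_p(10, 11, 4, 2), "n_a")
})

test_that("BH adjustment is order-preserving, clipped and monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(1)
  p <- sort(runif(20))
  expect_true(all(diff(bh_fdr(p)) >= -1e-15))
  expect_true(all(bh_fdr(p) <= 1))
})

test_that("PMI is symmetric, bounded and 1 exactly on nested clusters", {
  expect_equal(pmi(paste0("s", 1:6), paste0("s", 7:10)), 0)
  expect_equal(pmi(paste0("s", 1:6), paste0("s", 1:4)), 1)
  expect_equal(pmi(paste0("s", 1:10), paste0("s", c(1, 2, 11, 12))), 0.5)
  expect_error(pmi(character(0), "s1"), "empty")

  set.seed(7)
  universe <- paste0("s", 1:30)
  for (i in 1:25) {
    a <- sample(universe, sample(1:15, 1))
    b <- sample(universe, sample(1:15, 1))
    v <- pmi(a, b)
    expect_equal(v, pmi(b, a))
    expect_true(v >= 0 && v <= 1)
    nested <- all(a %in% b) || all(b %in% a)
    expect_identical(v == 1, nested)
  }
})

test_that("hand-built three-algorithm network matches the per-pair table", {
  ids <- paste0("s", 1:5)
  labels <- list(
    a1 = stats::setNames(c(1, 1, 1, 2, 2), ids),
    a2 = stats::setNames(c(1, 1, 2, 2, 2), ids),
    a3 = stats::setNames(c(1, 2, 2, 2, 2), ids))
  nodes <- make_cluster_nodes(labels)
  expect_identical(length(nodes$nodes), 6L)

  # enumerate all 12 cross-algorithm pairs by hand
  members <- lapply(nodes$nodes, `[[`, "members")
  pair_ids <- t(combn(names(members), 2))
  cross <- pair_ids[apply(pair_ids, 1, function(p)
    nodes$nodes[[p[1]]]$algorithm != nodes$nodes[[p[2]]]$algorithm), ]
  hand_p <- apply(cross, 1, function(p) {
    ov <- length(intersect(members[[p[1]]], members[[p[2]]]))
    enum_hyper_p(5, length(members[[p[1]]]), length(members[[p[2]]]), ov)
  })
  hand_fdr <- bh_fdr(hand_p)
  net <- build_network(nodes, "hyp", fdr_alpha = 0.05)
  full <- build_network(nodes, "hyp", fdr_alpha = 1.0000001)
  expect_identical(nrow(full$edges), nrow(cross))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(full$edges$node_a, full$edges$node_b),
             key(cross[, 1], cross[, 2]))
  expect_equal(full$edges$raw_stat, hand_p[m], tolerance = 1e-12)
  expect_equal(full$edges$fdr, hand_fdr[m], tolerance = 1e-12)
  expect_true(all(net$edges$fdr < 0.05))
  expect_equal(net$edges$weight, -log10(pmax(net$edges$fdr, 1e-300)))

  pnet <- build_network(nodes, "pmi", pmi_min = 0.1)
  hand_pmi <- apply(cross, 1, function(p) pmi(members[[p[1]]], members[[p[2]]]))
  mp <- match(key(pnet$edges$node_a, pnet$edges$node_b),
              key(cross[, 1], cross[, 2]))
  expect_equal(pnet$edges$raw_stat, hand_pmi[mp])
  expect_true(all(pnet$edges$raw_stat >= 0.1))
})

test_that("identical partitions give a perfect-matching HYP network", {
  ids <- sprintf("s%02d", 1:20)
  labs <- stats::setNames(rep(1:2, each = 10), ids)
  nodes <- make_cluster_nodes(list(a = labs, b = labs))
  net <- build_network(nodes, "hyp")
  expect_identical(nrow(net$edges), 2L)
  expect_setequal(paste(net$edges$node_a, net$edges$node_b),
                  c("a.1 b.1", "a.2 b.2"))
})

test_that("nested partitions give PMI edges of exactly 1 to the parent", {
  nl <- nested_labels()
  nodes <- make_cluster_nodes(list(coarse = nl$coarse, fine = nl$fine))
  net <- build_network(nodes, "pmi", pmi_min = 0.1)
  expect_identical(nrow(net$edges), 4L)
  expect_true(all(net$edges$weight == 1))
})

test_that("weighted label propagation finds the obvious communities", {
  tri <- function(a, b, c, w) data.frame(
    node_a = c(a, a, b), node_b = c(b, c, c), overlap = 1,
    raw_stat = NA, fdr = NA, weight = w)
  mk_net <- function(edges, ids) {
    nodes <- structure(list(
      nodes = stats::setNames(lapply(ids, function(i)
        list(algorithm = substr(i, 1, 1), cluster_index = 1L,
             members = paste0(i, "_m"))), ids),
      samples = paste0(ids, "_m"), algorithms = unique(substr(ids, 1, 1))),
      class = "cluster_nodes")
    structure(list(nodes = nodes, edges = edges, mode = "HYP",
                   params = list()), class = "recon_network")
  }
  ids <- c("a1", "b1", "c1", "a2", "b2", "c2")
  disconnected <- mk_net(rbind(tri("a1", "b1", "c1", 5),
                               tri("a2", "b2", "c2", 5)), ids)
  for (seed in 1:5) {
    comm <- label_propagation(disconnected, seed = seed)
    expect_identical(length(unique(comm)), 2L)
    expect_identical(length(unique(comm[c("a1", "b1", "c1")])), 1L)
  }
  # one weight-1 bridge cannot overcome weight-5 triangle interiors
  bridged <- mk_net(rbind(tri("a1", "b1", "c1", 5),
                          tri("a2", "b2", "c2", 5),
                          data.frame(node_a = "c1", node_b = "a2",
                                     overlap = 1, raw_stat = NA, fdr = NA,
                                     weight = 1)), ids)
  for (seed in 1:10) {
    comm <- label_propagation(bridged, seed = seed)
    expect_identical(length(unique(comm)), 2L)
  }
  # cross-check against an independent community detector
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_data_frame(
    bridged$edges[, c("node_a", "node_b", "weight")], directed = FALSE)
  set.seed(4)
  ig <- igraph::cluster_label_prop(g, weights = igraph::E(g)$weight)
  expect_identical(length(ig), 2L)

  # isolated node keeps its own community
  lonely <- mk_net(tri("a1", "b1", "c1", 2), c("a1", "b1", "c1", "a2"))
  comm <- label_propagation(lonely, seed = 1)
  expect_identical(length(unique(comm)), 2L)
  expect_identical(sum(comm == comm[["a2"]]), 1L)
})

test_that("communities are renumbered by decreasing sample membership", {
  ids <- sprintf("s%02d", 1:30)
  labs_a <- stats::setNames(c(rep(1, 20), rep(2, 10)), ids)
  nodes <- make_cluster_nodes(list(a = labs_a, b = labs_a))
  net <- build_network(nodes, "pmi")
  comm <- label_propagation(net, seed = 3)
  expect_identical(unname(comm[c("a.1", "b.1")]), c(1L, 1L))  # bigger first
  expect_identical(unname(comm[c("a.2", "b.2")]), c(2L, 2L))
})

test_that("sample assignment uses majority vote with size tie-breaks", {
  ids <- c(paste0("x", 1:2), paste0("y", 1:2))
  labels <- list(
    a = stats::setNames(c(1, 1, 2, 2), ids),
    b = stats::setNames(c(1, 1, 2, 2), ids),
    c = stats::setNames(c(1, 2, 2, 2), ids))
  nodes <- make_cluster_nodes(labels)
  # unanimity and strict majority via a hand map
  c2c <- c(a.1 = 1L, a.2 = 2L, b.1 = 1L, b.2 = 2L, c.1 = 1L, c.2 = 2L)
  s2c <- assign_samples_to_communities(nodes, c2c)
  expect_identical(unname(s2c[c("x1", "x2")]), c(1L, 1L))  # 3 and 2:1 votes
  expect_identical(unname(s2c[c("y1", "y2")]), c(2L, 2L))

  # three-way tie: community of the largest voting cluster wins
  ids3 <- sprintf("s%02d", 1:60)
  labels3 <- list(
    a = stats::setNames(rep(1:2, c(30, 30)), ids3),
    b = stats::setNames(rep(1:3, c(20, 20, 20)), ids3),
    c = stats::setNames(rep(1:6, each = 10), ids3))
  nodes3 <- make_cluster_nodes(labels3)
  c2c3 <- c(a.1 = 1L, a.2 = 4L, b.1 = 2L, b.2 = 5L, b.3 = 6L,
            c.1 = 3L, c.2 = 3L, c.3 = 5L, c.4 = 5L, c.5 = 6L, c.6 = 6L)
  s2c3 <- assign_samples_to_communities(nodes3, c2c3)
  # sample s01: votes 1 (a.1, size 30), 2 (b.1, size 20), 3 (c.1, size 10)
  expect_identical(unname(s2c3[["s01"]]), 1L)
})

test_that("community silhouette separates planted blobs and not noise", {
  # marker-dominated blobs: Euclidean silhouette needs the between-community
  # signal to dwarf the noise floor over all genes
  g <- make_blobs(n_samples = 20, n_genes = 80, mpg = 40, effect = 20,
                  seed = 31)
  cs <- community_silhouette(g$expr, g$community)
  expect_gt(cs$mean, 0.9)

  # structureless data with arbitrary labels scores near zero
  means <- replicate(20, {
    m <- matrix(rnorm(40 * 30), 40, 30,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
    labs <- stats::setNames(rep(1:2, 15), colnames(m))
    community_silhouette(m, labs)$mean
  })
  expect_lt(abs(mean(means)), 0.1)

  # 4-sample worked example: {0,1} vs {10,11} on one gene
  m4 <- matrix(c(0, 1, 10, 11), 2, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m4["g2", ] <- c(0, 0, 0, 0.001)  # second gene nearly flat
  labs4 <- stats::setNames(c(1, 1, 2, 2), paste0("s", 1:4))
  cs4 <- community_silhouette(m4, labs4)
  d <- as.matrix(dist(t(m4)))
  a1 <- d[1, 2]; b1 <- mean(d[1, 3:4])
  expect_equal(unname(cs4$widths[1]), (b1 - a1) / max(a1, b1),
               tolerance = 1e-12)

  one <- community_silhouette(g$expr,
                              stats::setNames(rep(1, 20), colnames(g$expr)))
  expect_true(is.na(one$mean))
})

test_that("selection prefers the higher mean silhouette, ties to HYP", {
  mk <- function(mode, mean_sil) structure(
    list(mode = mode, mean_silhouette = mean_sil,
         silhouette = list(mean = mean_sil), n_communities = 3),
    class = "community_solution")
  sel <- select_reconciliation(hyp = mk("HYP", 0.06), pmi = mk("PMI", 0.07))
  expect_identical(sel$mode, "PMI")
  expect_identical(select_reconciliation(mk("HYP", 0.07),
                                         mk("PMI", 0.07))$mode, "HYP")
  expect_identical(select_reconciliation(mk("HYP", 0.3),
                                         mk("PMI", NA_real_))$mode, "HYP")
  not_run <- select_reconciliation(hyp = mk("HYP", 0.2), pmi = NULL)
  expect_identical(not_run$report$status[not_run$report$mode == "PMI"],
                   "not run")
  expect_error(select_reconciliation(mk("HYP", NA_real_),
                                     mk("PMI", NA_real_)), "manual review")
})

test_that("enrichment against known labels uses the overlap test per cell", {
  ids <- paste0("s", 1:10)
  grp <- stats::setNames(rep(c("c1", "c2"), each = 5), ids)
  ann <- stats::setNames(rep(c("L1", "L2"), each = 5), ids)
  ann_shift <- ann; ann_shift[5] <- "L2"; ann_shift[6] <- "L1"
  res <- enrichment_vs_known(grp, ann_shift, n_perm = 2000, seed = 9)
  cell <- res$table[res$table$group == "c1" & res$table$known_label == "L1", ]
  expect_equal(cell$overlap, 4)
  expect_equal(cell$p, enum_hyper_p(10, 5, 5, 4), tolerance = 1e-12)

  # perfect concordance: diagonal FDR minimal within each row
  res2 <- enrichment_vs_known(grp, ann, n_perm = 2000, seed = 9)
  for (g in c("c1", "c2")) {
    sub <- res2$table[res2$table$group == g, ]
    diag_lab <- if (g == "c1") "L1" else "L2"
    expect_identical(sub$known_label[which.min(sub$fdr)], diag_lab)
  }
  expect_lt(res2$global_p, 0.05)

  expect_warning(
    enrichment_vs_known(grp, ann[1:8], n_perm = 500, seed = 1),
    "unannotated")
  expect_error(enrichment_vs_known(grp, ann[1:4]), "fewer than 50%")
  expect_warning(
    res3 <- enrichment_vs_known(grp, stats::setNames(rep("L1", 10), ids),
                                n_perm = 500, seed = 1),
    "skipped")
  expect_true(is.na(res3$global_p))
})

test_that("null enrichment p-values are approximately uniform", {
  # 3x3 tables keep the chi-square statistic nearly continuous; small 2x2
  # tables fail KS through discreteness alone
  set.seed(12)
  pvals <- replicate(150, {
    ids <- paste0("s", 1:150)
    grp <- stats::setNames(sample(rep(paste0("c", 1:3), 50)), ids)
    ann <- stats::setNames(sample(rep(paste0("L", 1:3), 50)), ids)
    enrichment_vs_known(grp, ann, n_perm = 2000,
                        seed = sample.int(1e6, 1))$global_p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
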