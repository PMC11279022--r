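make_norm <- function(cpm, kingdom = "bacteria") {
  structure(list(cpm = cpm,
                 tmm_factors = setNames(rep(1, ncol(cpm)), colnames(cpm)),
                 lib_sizes = setNames(rep(1e4, ncol(cpm)), colnames(cpm)),
                 kingdom = kingdom),
            class = "normalized_table")
}

test_that("Spearman matrix equals rank-then-Pearson and handles NAs", {
  set.seed(4)
  cpm <- matrix(rexp(5 * 8), 5, 8,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:8)))
  cpm[5, ] <- 3         # constant profile -> undefined correlation
  sp <- spearman_matrix(make_norm(cpm))
  expect_equal(diag(sp$r)[1:4], rep(1, 4), ignore_attr = TRUE)
  # perfectly monotone nonlinear pair
  cpm2 <- cpm
  cpm2[2, ] <- exp(cpm2[1, ])
  sp2 <- spearman_matrix(make_norm(cpm2))
  expect_equal(sp2$r["t1", "t2"], 1)
  # brute-force oracle on one pair
  r_oracle <- cor(rank(cpm[1, ]), rank(cpm[3, ]))
  expect_equal(sp$r["t1", "t3"], r_oracle, tolerance = 1e-12)
  expect_true(all(is.na(sp$r["t5", c("t1", "t2", "t3", "t4")])))
})

test_that("cross-kingdom pairs are excluded when within_kingdom is set", {
  set.seed(5)
  b <- matrix(rexp(3 * 8), 3, 8,
              dimnames = list(paste0("b", 1:3), paste0("s", 1:8)))
  f <- b + matrix(rnorm(24, sd = 0.01), 3, 8)
  rownames(f) <- paste0("f", 1:3)
  sp <- spearman_matrix(list(make_norm(b, "bacteria"),
                             make_norm(f, "fungi")), within_kingdom = TRUE)
  expect_true(all(is.na(sp$r[paste0("b", 1:3), paste0("f", 1:3)])))
  spx <- spearman_matrix(list(make_norm(b, "bacteria"),
                              make_norm(f, "fungi")), within_kingdom = FALSE)
  expect_false(anyNA(spx$r[paste0("b", 1:3), paste0("f", 1:3)]))
  net <- build_network(sp, 0.6, 0.05)
  if (igraph::ecount(net$graph) > 0) {
    ends <- igraph::as_data_frame(net$graph, "edges")
    expect_true(all(substr(ends$from, 1, 1) == substr(ends$to, 1, 1)))
  }
})

test_that("network construction applies thresholds and is monotone", {
  r <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  r[upper.tri(r)] <- c(0.9, 0.9, 0.9, 0.3, 0.2, 0.1)  # clique on t1-t3
  r <- r + t(r); diag(r) <- 1
  p <- matrix(1e-9, 4, 4)
  dimnames(p) <- dimnames(r)
  sp <- structure(list(r = r, p = p,
                       kingdom = setNames(rep("bacteria", 4), paste0("t", 1:4)),
                       n_samples = 10), class = "spearman_result")
  net <- build_network(sp, 0.6, 0.001)
  expect_equal(igraph::vcount(net$graph), 3)  # t4 isolated, dropped
  expect_equal(igraph::ecount(net$graph), 3)  # 3-clique among t1-t3
  empty <- build_network(sp, 0.95, 0.001)
  expect_equal(igraph::ecount(empty$graph), 0)
  m <- topology_metrics(empty)
  expect_equal(m$n_nodes, 0); expect_equal(m$n_edges, 0)
  # monotonicity over a threshold grid
  counts <- sapply(seq(0, 0.95, by = 0.05), function(rm)
    igraph::ecount(build_network(sp, rm, 0.001)$graph))
  expect_true(all(diff(counts) <= 0))
})

test_that("edges concentrate within ground-truth correlated blocks", {
  spec <- synthetic_spec(n_taxa = 200, n_samples_per_group = 15,
                         reads_per_sample = 10000, n_differential = 0,
                         seed = 23)
  ds <- generate_dataset(spec)
  filt <- prevalence_filter(ds$table, 5, 2)
  sp <- spearman_matrix(tmm_normalize(filt))
  bl <- ds$truth$block[rownames(sp$r)]
  both <- outer(!is.na(bl), !is.na(bl), "&")
  same <- both & outer(bl, bl, "==")
  edge <- !is.na(sp$r) & sp$r > 0.6 & sp$p < 0.001
  ut <- upper.tri(sp$r)
  within <- mean(edge[ut & same %in% TRUE])
  between <- mean(edge[ut & !(same %in% TRUE)])
  expect_gt(within, between)
})

test_that("greedy modularity reproduces closed-form partitions", {
  tri2 <- igraph::graph_from_edgelist(rbind(
    c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
    c("b1", "b2"), c("b2", "b3"), c("b1", "b3")), directed = FALSE)
  net <- greedy_modules(as_co_network(tri2))
  expect_equal(net$Q, 0.5)
  expect_equal(length(unique(net$modules)), 2)
  expect_equal(length(unique(net$modules[c("a1", "a2", "a3")])), 1)

  clique <- igraph::make_full_graph(5)
  igraph::V(clique)$name <- paste0("v", 1:5)
  expect_equal(greedy_modules(as_co_network(clique))$Q, 0, tolerance = 1e-12)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- paste0("v", 1:3)
  nete <- greedy_modules(as_co_network(edgeless))
  expect_equal(nete$Q, 0)
  expect_equal(length(unique(nete$modules)), 3)
})

test_that("two-block graphs are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  ari <- sapply(1:20, function(s) {
    set.seed(s)
    g <- igraph::sample_sbm(30, matrix(c(0.5, 0.05, 0.05, 0.5), 2),
                            c(15, 15))
    igraph::V(g)$name <- paste0("n", 1:30)
    net <- greedy_modules(as_co_network(g))
    mclust::adjustedRandIndex(net$modules, rep(1:2, each = 15))
  })
  expect_gte(mean(ari), 0.9)
})

test_that("topology metrics match closed forms and exhaustive oracles", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  m <- topology_metrics(as_co_network(star))
  expect_equal(m$assortativity, -1)
  expect_equal(m$mean_betweenness, 0.2)   # hub 1, leaves 0

  path3 <- igraph::make_ring(3, circular = FALSE)
  igraph::V(path3)$name <- paste0("p", 1:3)
  expect_equal(topology_metrics(as_co_network(path3))$mean_betweenness, 1 / 3)

  # regular graph: degree variance zero, assortativity undefined
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("r", 1:6)
  expect_true(is.na(topology_metrics(as_co_network(ring))$assortativity))

  # random 20-node graph vs independent oracles
  set.seed(13)
  g <- igraph::sample_gnp(20, 0.25)
  igraph::V(g)$name <- paste0("n", 1:20)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  m2 <- topology_metrics(as_co_network(g))
  expect_equal(m2$mean_betweenness, mean(betweenness_oracle(adj)),
               tolerance = 1e-9)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  x <- c(deg[el[, 1]], deg[el[, 2]])
  y <- c(deg[el[, 2]], deg[el[, 1]])
  expect_equal(m2$assortativity, cor(x, y), tolerance = 1e-9)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(19)
  g <- igraph::sample_gnp(15, 0.3)
  igraph::V(g)$name <- paste0("n", 1:15)
  g2 <- igraph::permute(g, sample(15))
  m1 <- topology_metrics(as_co_network(g))
  m2 <- topology_metrics(as_co_network(g2))
  expect_equal(m1$mean_betweenness, m2$mean_betweenness, tolerance = 1e-12)
  expect_equal(m1$assortativity, m2$assortativity, tolerance = 1e-12)
  q1 <- greedy_modules(as_co_network(g))$Q
  expect_gte(q1, 0)
})

test_that("module summaries aggregate CPM and flag sensitive modules", {
  spec <- synthetic_spec(n_taxa = 200, n_samples_per_group = 15,
                         reads_per_sample = 10000, n_differential = 10,
                         fold_change = 6, n_corr_blocks = 4, block_size = 8,
                         seed = 41)
  ds <- generate_dataset(spec)
  filt <- prevalence_filter(ds$table, 5, 2)
  nt <- tmm_normalize(filt)
  dd <- nb_lrt_differential(filt, ds$metadata, nt)
  iv <- indval(filt, ds$metadata, n_perm = 199, seed = 6)
  hs <- identify_hsasvs(dd, iv)
  net <- greedy_modules(build_network(spearman_matrix(nt), 0.6, 0.001))
  ms <- module_summary(net, nt, hs, ds$metadata)
  expect_true(all(ms$modules$n_members >= 1))
  expect_true(all(abs(tapply(ms$class_composition$proportion,
                             ms$class_composition$module, sum) - 1) < 1e-9))
  # sensitive modules are those holding the seeded differential taxa
  diff_mods <- unique(net$modules[intersect(ds$truth$differential$taxon_id,
                                            names(net$modules))])
  flagged <- ms$modules$module[ms$modules$sensitive]
  expect_true(all(flagged %in% diff_mods))
  expect_false(any(ms$modules$sensitive & ms$modules$hs_fraction == 0))
})

test_that("network exports are readable", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- paste0("t", 1:4)
  igraph::V(g)$kingdom <- "bacteria"
  igraph::E(g)$r <- 0.9; igraph::E(g)$p <- 1e-5
  net <- greedy_modules(as_co_network(g))
  ep <- tempfile(fileext = ".tsv")
  write_edge_list(net, ep)
  el <- utils::read.table(ep, header = TRUE, sep = "\t")
  expect_equal(nrow(el), 6)
  gp <- tempfile(fileext = ".graphml")
  write_graphml(net, gp, layout = TRUE, seed = 2)
  g2 <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::vcount(g2), 4)
  expect_true("module" %in% igraph::vertex_attr_names(g2))
})
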