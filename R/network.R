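#' Spearman correlation and p-value matrices between taxa
#'
#' Mid-rank Spearman correlations of (normalized) taxon abundance profiles
#' across samples, with p-values from the t approximation on n - 2 degrees
#' of freedom. When `within_kingdom = TRUE` (the construction used for the
#' meta network), only pairs from the same kingdom are evaluated;
#' cross-kingdom cells are NA. Constant taxon profiles yield NA
#' correlations, which can never become edges.
#'
#' @param norm A `normalized_table`, or a list of them sharing the same
#'   samples (e.g. bacteria + fungi for a meta network).
#' @param within_kingdom Restrict evaluation to same-kingdom pairs.
#' @return List of class `spearman_result`: `r`, `p` (taxa x taxa),
#'   `kingdom` (named vector), `n_samples`.
#' @export
spearman_matrix <- function(norm, within_kingdom = TRUE) {
  cm <- .combine_norm(norm)
  n <- ncol(cm$cpm)
  if (n < 5) stop("need >= 5 samples for correlation networks")
  suppressWarnings(r <- stats::cor(t(cm$cpm), method = "spearman"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  if (within_kingdom) {
    cross <- outer(cm$kingdom, cm$kingdom, "!=")
    r[cross] <- NA
    p[cross] <- NA
  }
  structure(list(r = r, p = p, kingdom = cm$kingdom, n_samples = n),
            class = "spearman_result")
}

.combine_norm <- function(norm) {
  if (inherits(norm, "normalized_table")) norm <- list(norm)
  stopifnot(length(norm) >= 1,
            all(vapply(norm, inherits, TRUE, "normalized_table")))
  ids <- colnames(norm[[1]]$cpm)
  cpm <- do.call(rbind, lapply(norm, function(nt) {
    if (!identical(colnames(nt$cpm), ids))
      stop("normalized tables must share the same samples in the same order")
    nt$cpm
  }))
  kingdom <- unlist(lapply(norm, function(nt)
    stats::setNames(rep(nt$kingdom, nrow(nt$cpm)), rownames(nt$cpm))))
  if (anyDuplicated(rownames(cpm)))
    stop("taxon ids collide across tables")
  list(cpm = cpm, kingdom = kingdom)
}

#' Threshold a correlation matrix into a co-occurrence network
#'
#' Keeps an edge iff r > `r_min` and p < `p_max` (raw p-values, as in the
#' source workflow; set `bh_adjust = TRUE` for an optional BH-corrected
#' mode). Isolated nodes are dropped. Study thresholds: meta network
#' r > 0.6, p < 0.001; per-group networks r > 0.8 (bacteria) / 0.7 (fungi),
#' p < 0.01.
#'
#' @param sp A [spearman_matrix] result.
#' @param r_min Correlation threshold (edges require r strictly above it).
#' @param p_max Significance threshold (strictly below).
#' @param positive_only Keep only positive correlations (implied whenever
#'   `r_min >= 0`).
#' @param bh_adjust Apply Benjamini-Hochberg to the evaluated p-values
#'   before thresholding (off by default).
#' @return List of class `co_network`: `graph` (undirected igraph with
#'   vertex attribute `kingdom`, edge attributes `r`, `p`), `thresholds`,
#'   `modules` (NULL until [greedy_modules]), `Q` (NULL).
#' @export
build_network <- function(sp, r_min, p_max, positive_only = TRUE,
                          bh_adjust = FALSE) {
  stopifnot(inherits(sp, "spearman_result"), r_min >= -1, r_min <= 1,
            p_max > 0, p_max <= 1)
  r <- sp$r
  p <- sp$p
  ut <- upper.tri(r)
  if (bh_adjust) {
    idx <- which(ut & !is.na(p))
    p[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  keep <- ut & !is.na(r) & r > r_min & p < p_max
  if (positive_only) keep <- keep & r > 0
  ij <- which(keep, arr.ind = TRUE)
  if (nrow(ij) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- data.frame(from = rownames(r)[ij[, 1]],
                        to = colnames(r)[ij[, 2]],
                        r = r[ij], p = p[ij], stringsAsFactors = FALSE)
    nodes <- unique(c(edges$from, edges$to))
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = nodes,
                            kingdom = unname(sp$kingdom[nodes]),
                            stringsAsFactors = FALSE))
  }
  structure(list(graph = g,
                 thresholds = list(r_min = r_min, p_max = p_max,
                                   positive_only = positive_only,
                                   bh_adjust = bh_adjust),
                 modules = NULL, Q = NULL),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network: %d nodes, %d edges (r > %.2f, p < %g)%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$thresholds$r_min, x$thresholds$p_max,
              if (!is.null(x$Q)) sprintf(", %d modules, Q = %.3f",
                                         length(unique(x$modules)), x$Q)
              else ""))
  invisible(x)
}

#' Greedy modularity optimization
#'
#' Clauset-Newman-Moore agglomerative maximization of Newman modularity
#' Q = sum_c (e_cc - a_c^2) on the unweighted graph (igraph's
#' `cluster_fast_greedy`, the algorithm named in the source workflow;
#' deterministic agglomeration order). An edgeless network gets one module
#' per node and Q = 0.
#'
#' @param net A [build_network] result.
#' @return The `co_network` with `modules` (named integer vector over
#'   nodes) and `Q` filled in.
#' @export
greedy_modules <- function(net) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0) {
    net$modules <- stats::setNames(seq_len(igraph::vcount(g)),
                                   igraph::V(g)$name)
    net$Q <- 0
    return(net)
  }
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  mem <- igraph::membership(cl)
  q <- igraph::modularity(g, mem)
  # the agglomeration must never do worse than the connected-components
  # partition (Q = 0 for a connected graph)
  comp <- igraph::components(g)$membership
  q_comp <- igraph::modularity(g, comp)
  if (q < q_comp) {
    mem <- comp
    q <- q_comp
  }
  net$modules <- stats::setNames(as.integer(mem), igraph::V(g)$name)
  net$Q <- q
  net
}

#' Topology metrics of a co-occurrence network
#'
#' Node and edge counts, mean normalized shortest-path betweenness
#' centrality (Brandes, unweighted; node betweenness divided by
#' (n-1)(n-2)/2), and Newman degree assortativity (Pearson correlation of
#' end-point degrees over edges). Assortativity is NA when the degree
#' variance over edge endpoints is zero (e.g. regular graphs).
#'
#' @param net A `co_network`.
#' @return data.frame with columns n_nodes, n_edges, mean_betweenness,
#'   assortativity, modularity (NA until [greedy_modules] has run).
#' @export
topology_metrics <- function(net) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  nv <- igraph::vcount(g)
  mb <- if (nv >= 3) {
    mean(igraph::betweenness(g, directed = FALSE, normalized = TRUE))
  } else if (nv > 0) 0 else NA_real_
  assort <- if (igraph::ecount(g) > 0)
    igraph::assortativity_degree(g, directed = FALSE) else NA_real_
  if (!is.na(assort) && !is.finite(assort)) assort <- NA_real_
  data.frame(n_nodes = nv, n_edges = igraph::ecount(g),
             mean_betweenness = mb, assortativity = assort,
             modularity = if (is.null(net$Q)) NA_real_ else net$Q)
}

#' Summarize network modules against abundance, hsASVs, and taxonomy
#'
#' Per module: member count, hsASV counts per assigned group, cumulative
#' CPM (per-sample sum over members) summarized as mean +/- SD per group,
#' and class-level composition (proportional ASV numbers per class).
#' Modules are flagged "sensitive" when their hsASV fraction is positive
#' and exceeds the given quantile of all module hsASV fractions.
#'
#' @param net A `co_network` after [greedy_modules].
#' @param norm The `normalized_table` (or list) the network was built from.
#' @param hs An [identify_hsasvs] report.
#' @param meta A [sample_metadata].
#' @param tax Optional [taxonomy_table] for class composition.
#' @param sensitive_quantile Quantile of module hsASV fractions a sensitive
#'   module must exceed.
#' @return List of class `module_summary`: `modules` (data.frame module,
#'   n_members, n_hs_HL, n_hs_NL, hs_fraction, sensitive, cpm_mean_HL,
#'   cpm_sd_HL, cpm_mean_NL, cpm_sd_NL) and `class_composition`
#'   (data.frame module, class, proportion).
#' @export
module_summary <- function(net, norm, hs, meta, tax = NULL,
                           sensitive_quantile = 0.5) {
  stopifnot(inherits(net, "co_network"))
  if (is.null(net$modules)) stop("run greedy_modules() first")
  cm <- .combine_norm(norm)
  g <- meta$group[match(colnames(cm$cpm), meta$sample_id)]
  mods <- sort(unique(net$modules))
  rows <- lapply(mods, function(mo) {
    members <- names(net$modules)[net$modules == mo]
    h <- hs[hs$taxon_id %in% members & hs$hs_flag, , drop = FALSE]
    csum <- colSums(cm$cpm[intersect(members, rownames(cm$cpm)), ,
                           drop = FALSE])
    data.frame(module = mo, n_members = length(members),
               n_hs_HL = sum(h$assigned_group == "HL", na.rm = TRUE),
               n_hs_NL = sum(h$assigned_group == "NL", na.rm = TRUE),
               hs_fraction = nrow(h) / length(members),
               cpm_mean_HL = mean(csum[g == "HL"]),
               cpm_sd_HL = stats::sd(csum[g == "HL"]),
               cpm_mean_NL = mean(csum[g == "NL"]),
               cpm_sd_NL = stats::sd(csum[g == "NL"]))
  })
  out <- do.call(rbind, rows)
  out$sensitive <- out$hs_fraction >
    stats::quantile(out$hs_fraction, sensitive_quantile, names = FALSE) &
    out$hs_fraction > 0
  comp <- do.call(rbind, lapply(mods, function(mo) {
    members <- names(net$modules)[net$modules == mo]
    cls <- rank_of(tax, members, "class")
    tb <- table(cls) / length(members)
    data.frame(module = mo, class = names(tb),
               proportion = as.numeric(tb), stringsAsFactors = FALSE)
  }))
  structure(list(modules = out, class_composition = comp),
            class = "module_summary")
}

#' Export a network as an edge-list TSV or GraphML
#'
#' @param net A `co_network`.
#' @param path Output path.
#' @param layout Add Fruchterman-Reingold display coordinates (GraphML
#'   only; presentation-only, never used by any metric).
#' @param seed Seed for the layout.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- igraph::as_data_frame(net$graph, what = "edges")
  names(e)[1:2] <- c("source", "target")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path, layout = FALSE, seed = 1) {
  g <- net$graph
  if (!is.null(net$modules))
    g <- igraph::set_vertex_attr(g, "module",
                                 value = as.integer(net$modules[igraph::V(g)$name]))
  if (layout && igraph::vcount(g) > 0) {
    set.seed(seed)
    xy <- igraph::layout_with_fr(g)
    g <- igraph::set_vertex_attr(g, "x", value = xy[, 1])
    g <- igraph::set_vertex_attr(g, "y", value = xy[, 2])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
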