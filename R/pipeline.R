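#' Pipeline configuration
#'
#' Bundles inputs, thresholds, permutation counts, seed, and output
#' directory for [run_pipeline]. Defaults are the study workflow's:
#' prevalence filters (bacteria: 5 samples with >= 2 reads; fungi: 3
#' samples with >= 2 reads), meta-network thresholds r > 0.6 / p < 0.001,
#' per-group network thresholds r > 0.8 (bacteria) and r > 0.7 (fungi) at
#' p < 0.01, hsASV thresholds q < 0.05 and indicator p < 0.05, 999
#' PERMANOVA permutations, 9999 IndVal permutations, 30,000 swap
#' simulations with 500 burn-in, and 1000 NCM bootstrap replicates.
#' Reduced permutation counts are appropriate for smoke runs.
#'
#' @param counts_bacteria,counts_fungi Count-table TSV paths or
#'   [count_table] objects (at least one kingdom required).
#' @param metadata Metadata TSV path or [sample_metadata].
#' @param taxonomy Optional taxonomy TSV path or [taxonomy_table].
#' @param out_dir Output directory for the run.
#' @param prevalence Named list: `bacteria = c(min_samples, min_reads)`,
#'   `fungi = ...`.
#' @param meta_network List with `r_min`, `p_max`.
#' @param group_network Named list per kingdom with `r_min`, `p_max`.
#' @param hs_q,hs_p hsASV thresholds.
#' @param n_perm_permanova,n_perm_indval,n_sim_swap,burn_in_swap,n_bootstrap_ncm
#'   Permutation/simulation counts.
#' @param seed Global seed; per-stage sub-seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_bacteria = NULL, counts_fungi = NULL,
                            metadata, taxonomy = NULL, out_dir,
                            prevalence = list(bacteria = c(5, 2),
                                              fungi = c(3, 2)),
                            meta_network = list(r_min = 0.6, p_max = 0.001),
                            group_network = list(
                              bacteria = list(r_min = 0.8, p_max = 0.01),
                              fungi = list(r_min = 0.7, p_max = 0.01)),
                            hs_q = 0.05, hs_p = 0.05,
                            n_perm_permanova = 999, n_perm_indval = 9999,
                            n_sim_swap = 30000, burn_in_swap = 500,
                            n_bootstrap_ncm = 1000, seed = 1) {
  if (is.null(counts_bacteria) && is.null(counts_fungi))
    stop("at least one of counts_bacteria / counts_fungi is required")
  stopifnot(hs_q > 0, hs_q <= 1, hs_p > 0, hs_p <= 1,
            n_perm_permanova >= 1, n_perm_indval >= 1, n_sim_swap >= 1,
            burn_in_swap >= 0, n_bootstrap_ncm >= 0)
  cfg <- list(counts_bacteria = counts_bacteria, counts_fungi = counts_fungi,
              metadata = metadata, taxonomy = taxonomy, out_dir = out_dir,
              prevalence = prevalence, meta_network = meta_network,
              group_network = group_network, hs_q = hs_q, hs_p = hs_p,
              n_perm_permanova = n_perm_permanova,
              n_perm_indval = n_perm_indval, n_sim_swap = n_sim_swap,
              burn_in_swap = burn_in_swap, n_bootstrap_ncm = n_bootstrap_ncm,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic per-stage sub-seed derivation from the global seed
.stage_seed <- function(seed, stage) {
  offs <- c(alpha = 11L, ordination = 23L, indval = 37L, swap = 53L,
            ncm = 71L, layout = 89L)
  (seed + offs[[stage]]) %% .Machine$integer.max
}

.load_input <- function(obj, reader, kingdom = NULL) {
  if (is.null(obj)) return(NULL)
  if (is.character(obj)) {
    if (identical(reader, "counts")) read_count_table(obj, "tsv", kingdom)
    else if (identical(reader, "metadata")) read_sample_metadata(obj)
    else read_taxonomy(obj)
  } else obj
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full two-group endophyte analysis pipeline
#'
#' Stage order: prevalence filter -> alpha diversity with group tests ->
#' Bray-Curtis / NMDS / PERMANOVA -> TMM/CPM normalization -> NB-LRT
#' differential + IndVal -> hsASV intersection -> meta co-occurrence
#' network with greedy modules and module summaries -> per-group networks
#' with topology metrics -> niche breadth + NCM + C-score per kingdom and
#' group -> run summary. Every artifact is written under `cfg$out_dir`
#' with a provenance file (config, seed, package version, input digests);
#' given the same config and seed, all numeric artifacts are
#' byte-identical across reruns (the wall-clock log is the one exception).
#' A failing stage halts with the stage name; completed artifacts persist.
#'
#' @param cfg A [pipeline_config].
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat("leafendo pipeline run\n", file = log_path)
  t0 <- proc.time()[["elapsed"]]
  logmsg <- function(...) cat(sprintf("[%8.2fs] ", proc.time()[["elapsed"]] - t0),
                              sprintf(...), "\n", sep = "", file = log_path,
                              append = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logmsg("stage %s: done", name)
    res
  }

  meta <- .load_input(cfg$metadata, "metadata")
  tax <- .load_input(cfg$taxonomy, "taxonomy")
  tables <- list()
  for (kd in c("bacteria", "fungi")) {
    tb <- .load_input(cfg[[paste0("counts_", kd)]], "counts", kd)
    if (!is.null(tb)) tables[[kd]] <- tb
  }
  kingdoms <- names(tables)

  # provenance: config with file inputs replaced by path + digest
  prov <- cfg
  for (f in c("counts_bacteria", "counts_fungi", "metadata", "taxonomy")) {
    if (is.character(prov[[f]]) && file.exists(prov[[f]]))
      prov[[f]] <- list(path = prov[[f]], md5 = unname(tools::md5sum(prov[[f]])))
    else if (!is.null(prov[[f]])) prov[[f]] <- "<in-memory object>"
  }
  prov$package_version <- as.character(utils::packageVersion("leafendo"))
  class(prov) <- NULL
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$provenance <- file.path(out, "provenance.json")

  filtered <- list(); norms <- list(); hs_reports <- list()
  for (kd in kingdoms) {
    tb <- tables[[kd]]
    pv <- cfg$prevalence[[kd]]
    filt <- stage(paste0("filter_", kd),
                  prevalence_filter(tb, pv[1], pv[2]))
    filtered[[kd]] <- filt

    al <- stage(paste0("alpha_", kd),
                alpha_diversity(tb, meta, seed = .stage_seed(cfg$seed, "alpha")))
    paths[[paste0("alpha_", kd)]] <-
      .write_tsv(al$samples, file.path(out, paste0("alpha_", kd, ".tsv")))
    paths[[paste0("alpha_tests_", kd)]] <-
      .write_tsv(al$tests, file.path(out, paste0("alpha_tests_", kd, ".tsv")))

    bc <- stage(paste0("beta_", kd), bray_curtis(tb))
    .write_tsv(data.frame(sample_id = rownames(bc), bc,
                          check.names = FALSE),
               file.path(out, paste0("bray_curtis_", kd, ".tsv")))
    ord <- stage(paste0("nmds_", kd),
                 nmds(bc, k = 2, seed = .stage_seed(cfg$seed, "ordination")))
    ord_path <- file.path(out, paste0("nmds_", kd, ".tsv"))
    cat(sprintf("# NMDS k=%d stress=%.6f converged=%s\n", ord$k, ord$stress,
                ord$converged), file = ord_path)
    suppressWarnings(utils::write.table(
      data.frame(sample_id = rownames(ord$points), ord$points),
      ord_path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    paths[[paste0("nmds_", kd)]] <- ord_path
    pm <- stage(paste0("permanova_", kd),
                permanova(bc, meta, cfg$n_perm_permanova,
                          seed = .stage_seed(cfg$seed, "ordination")))
    jsonlite::write_json(unclass(pm),
                         file.path(out, paste0("permanova_", kd, ".json")),
                         auto_unbox = TRUE, digits = NA)
    paths[[paste0("permanova_", kd)]] <-
      file.path(out, paste0("permanova_", kd, ".json"))

    nt <- stage(paste0("tmm_", kd), tmm_normalize(filt))
    norms[[kd]] <- nt
    .write_tsv(data.frame(sample_id = names(nt$tmm_factors),
                          lib_size = nt$lib_sizes,
                          tmm_factor = nt$tmm_factors),
               file.path(out, paste0("tmm_", kd, ".tsv")))

    dd <- stage(paste0("differential_", kd),
                nb_lrt_differential(filt, meta, nt))
    iv <- stage(paste0("indval_", kd),
                indval(filt, meta, n_perm = cfg$n_perm_indval,
                       seed = .stage_seed(cfg$seed, "indval")))
    hs <- stage(paste0("hsasv_", kd),
                identify_hsasvs(dd, iv, cfg$hs_q, cfg$hs_p))
    hs_reports[[kd]] <- hs
    paths[[paste0("hsasv_", kd)]] <-
      .write_tsv(hs, file.path(out, paste0("hsasv_", kd, ".tsv")))
  }

  # meta network over all kingdoms, within-kingdom pairs
  sp <- stage("meta_spearman", spearman_matrix(unname(norms), TRUE))
  net <- stage("meta_network",
               greedy_modules(build_network(sp, cfg$meta_network$r_min,
                                            cfg$meta_network$p_max)))
  paths$meta_edges <- write_edge_list(net, file.path(out, "meta_edges.tsv"))
  write_graphml(net, file.path(out, "meta_network.graphml"),
                layout = TRUE, seed = .stage_seed(cfg$seed, "layout"))
  .write_tsv(topology_metrics(net), file.path(out, "meta_metrics.tsv"))
  hs_all <- do.call(rbind, unname(hs_reports))
  ms <- stage("module_summary",
              module_summary(net, unname(norms), hs_all, meta, tax))
  paths$module_summary <-
    .write_tsv(ms$modules, file.path(out, "meta_module_summary.tsv"))
  .write_tsv(ms$class_composition,
             file.path(out, "meta_module_classes.tsv"))

  # per-group networks and assembly processes
  summary_rows <- list()
  for (kd in kingdoms) {
    for (gr in c("HL", "NL")) {
      ids <- meta$sample_id[meta$group == gr]
      ids <- intersect(ids, sample_ids(tables[[kd]]))
      sub_full <- subset_samples(tables[[kd]], ids)
      pv <- cfg$prevalence[[kd]]
      tag <- paste0(kd, "_", gr)

      gnet <- stage(paste0("network_", tag), {
        subf <- prevalence_filter(sub_full, pv[1], pv[2])
        gsp <- spearman_matrix(tmm_normalize(subf), TRUE)
        build_network(gsp, cfg$group_network[[kd]]$r_min,
                      cfg$group_network[[kd]]$p_max)
      })
      gmet <- topology_metrics(greedy_modules(gnet))
      paths[[paste0("network_metrics_", tag)]] <-
        .write_tsv(gmet, file.path(out, paste0("network_", tag,
                                               "_metrics.tsv")))
      write_edge_list(gnet, file.path(out, paste0("network_", tag,
                                                  "_edges.tsv")))

      nb <- stage(paste0("breadth_", tag), levins_breadth(sub_full))
      .write_tsv(nb$taxon_breadth,
                 file.path(out, paste0("breadth_taxa_", tag, ".tsv")))
      paths[[paste0("breadth_", tag)]] <-
        .write_tsv(nb$community_breadth,
                   file.path(out, paste0("breadth_", tag, ".tsv")))

      fit <- stage(paste0("ncm_", tag),
                   ncm_fit(sub_full, n_bootstrap = cfg$n_bootstrap_ncm,
                           seed = .stage_seed(cfg$seed, "ncm")))
      jsonlite::write_json(list(m = fit$m, m_ci = fit$m_ci, R2 = fit$R2,
                                N_comm = fit$N_comm, d = fit$d,
                                n_samples = fit$n_samples),
                           file.path(out, paste0("ncm_", tag, ".json")),
                           auto_unbox = TRUE, digits = NA)
      paths[[paste0("ncm_", tag)]] <- file.path(out, paste0("ncm_", tag, ".json"))
      .write_tsv(fit$taxa, file.path(out, paste0("ncm_taxa_", tag, ".tsv")))

      cs <- stage(paste0("cscore_", tag),
                  sequential_swap_null(presence_absence(sub_full),
                                       n_sim = cfg$n_sim_swap,
                                       burn_in = cfg$burn_in_swap,
                                       seed = .stage_seed(cfg$seed, "swap")))
      jsonlite::write_json(list(c_obs = cs$c_obs, null_mean = cs$null_mean,
                                null_sd = cs$null_sd, ses = cs$ses,
                                n_sim = cs$n_sim, burn_in = cs$burn_in),
                           file.path(out, paste0("cscore_", tag, ".json")),
                           auto_unbox = TRUE, digits = NA)
      paths[[paste0("cscore_", tag)]] <-
        file.path(out, paste0("cscore_", tag, ".json"))

      al <- utils::read.table(paths[[paste0("alpha_", kd)]], header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
      al <- al[al$group == gr, ]
      summary_rows[[tag]] <- data.frame(
        kingdom = kd, group = gr,
        mean_richness = mean(al$richness), mean_shannon = mean(al$shannon),
        n_nodes = gmet$n_nodes, n_edges = gmet$n_edges,
        mean_betweenness = gmet$mean_betweenness,
        assortativity = gmet$assortativity,
        mean_niche_breadth = mean(nb$community_breadth$breadth),
        ncm_m = fit$m, ncm_R2 = fit$R2, cscore_ses = cs$ses,
        stringsAsFactors = FALSE)
    }
  }
  paths$summary <- .write_tsv(do.call(rbind, summary_rows),
                              file.path(out, "summary.tsv"))
  logmsg("pipeline complete")
  invisible(paths)
}

#' Summarize a completed pipeline run
#'
#' Rebuilds the one-row-per-(kingdom x group) summary table from the
#' persisted stage artifacts -- the shape of the study's diversity,
#' network-topology, and assembly-process figures. Missing artifacts are
#' reported explicitly.
#'
#' @param run_dir A directory written by [run_pipeline].
#' @return data.frame with columns kingdom, group, mean_richness,
#'   mean_shannon, n_nodes, n_edges, mean_betweenness, assortativity,
#'   mean_niche_breadth, ncm_m, ncm_R2, cscore_ses.
#' @export
summarize_run <- function(run_dir) {
  kingdoms <- c("bacteria", "fungi")
  kingdoms <- kingdoms[file.exists(file.path(run_dir,
                                             paste0("alpha_", kingdoms, ".tsv")))]
  if (!length(kingdoms)) stop("no alpha artifacts found in ", run_dir)
  rows <- list()
  for (kd in kingdoms) {
    al <- utils::read.table(file.path(run_dir, paste0("alpha_", kd, ".tsv")),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    for (gr in c("HL", "NL")) {
      tag <- paste0(kd, "_", gr)
      need <- file.path(run_dir, c(paste0("network_", tag, "_metrics.tsv"),
                                   paste0("breadth_", tag, ".tsv"),
                                   paste0("ncm_", tag, ".json"),
                                   paste0("cscore_", tag, ".json")))
      missing <- need[!file.exists(need)]
      if (length(missing))
        stop("missing artifact(s): ", paste(basename(missing), collapse = ", "))
      met <- utils::read.table(need[1], header = TRUE, sep = "\t")
      br <- utils::read.table(need[2], header = TRUE, sep = "\t")
      fit <- jsonlite::fromJSON(need[3])
      cs <- jsonlite::fromJSON(need[4])
      alg <- al[al$group == gr, ]
      rows[[tag]] <- data.frame(
        kingdom = kd, group = gr,
        mean_richness = mean(alg$richness), mean_shannon = mean(alg$shannon),
        n_nodes = met$n_nodes, n_edges = met$n_edges,
        mean_betweenness = met$mean_betweenness,
        assortativity = met$assortativity,
        mean_niche_breadth = mean(br$breadth),
        ncm_m = fit$m, ncm_R2 = fit$R2,
        cscore_ses = if (is.null(cs$ses)) NA_real_ else cs$ses,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
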