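#' Specification for a synthetic two-group ASV dataset
#'
#' Defines the generative conditions the package's verification rests on:
#' a log-normal metacommunity, neutrally assembled local communities with
#' migration rate `migration_m` (Sloan-type drift), an NL group optionally
#' perturbed by deterministic selection and by fold-change shifts of known
#' differential taxa, and correlated taxon blocks shared by both groups.
#'
#' Defaults emulate a two-group leaf endophyte survey: 2 x 20 samples,
#' library sizes drawn uniformly between 5,000 and 75,000 reads, several
#' hundred taxa per kingdom.
#'
#' @param n_taxa Number of taxa in the metacommunity.
#' @param n_samples_per_group Samples per group (HL and NL).
#' @param reads_per_sample Either a single library size or a `c(lo, hi)`
#'   range sampled uniformly per sample.
#' @param migration_m Neutral migration rate m in (0, 1].
#' @param metacommunity_sigma Log-normal sigma of the species abundance
#'   distribution.
#' @param n_differential Number of taxa whose NL metacommunity abundance is
#'   shifted by `fold_change` (half up, half down).
#' @param fold_change Fold change (> 1) applied to differential taxa.
#' @param n_corr_blocks,block_size Number and size of correlated taxon
#'   blocks (shared latent factor per block per sample).
#' @param block_rho Target strength of within-block correlation in (0, 1);
#'   controls the latent factor's log-scale variance.
#' @param selection_strength Variance of log fitness multipliers applied to
#'   NL local communities after neutral drift (0 = no selection).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_taxa = 500,
                           n_samples_per_group = 20,
                           reads_per_sample = c(5000, 75000),
                           migration_m = 0.1,
                           metacommunity_sigma = 2,
                           n_differential = 20,
                           fold_change = 4,
                           n_corr_blocks = 4,
                           block_size = 10,
                           block_rho = 0.7,
                           selection_strength = 0,
                           seed = 1) {
  spec <- list(n_taxa = as.integer(n_taxa),
               n_samples_per_group = as.integer(n_samples_per_group),
               reads_per_sample = reads_per_sample,
               migration_m = migration_m,
               metacommunity_sigma = metacommunity_sigma,
               n_differential = as.integer(n_differential),
               fold_change = fold_change,
               n_corr_blocks = as.integer(n_corr_blocks),
               block_size = as.integer(block_size),
               block_rho = block_rho,
               selection_strength = selection_strength,
               seed = as.integer(seed))
  with(spec, {
    if (n_taxa < 2) stop("n_taxa must be >= 2")
    if (n_samples_per_group < 1) stop("n_samples_per_group must be >= 1")
    if (migration_m <= 0 || migration_m > 1)
      stop("migration_m must be in (0, 1]")
    if (n_differential > n_taxa) stop("n_differential exceeds n_taxa")
    if (n_differential > 0 && fold_change <= 1) stop("fold_change must be > 1")
    if (n_corr_blocks * block_size > n_taxa)
      stop("block_size * n_corr_blocks exceeds n_taxa")
    if (block_rho < 0 || block_rho >= 1) stop("block_rho must be in [0, 1)")
    if (selection_strength < 0) stop("selection_strength must be >= 0")
    if (!(length(reads_per_sample) %in% 1:2) || any(reads_per_sample < 1))
      stop("reads_per_sample must be a positive size or c(lo, hi) range")
  })
  class(spec) <- "synthetic_spec"
  spec
}

# Dirichlet(nm * p) local composition via normalized gammas; marginals are
# Beta(nm p_j, nm (1 - p_j)), the Sloan stationary distribution
.draw_local <- function(p, nm) {
  q <- numeric(length(p))
  pos <- p > 0
  q[pos] <- stats::rgamma(sum(pos), shape = nm * p[pos], rate = 1)
  if (sum(q) == 0) q[pos] <- p[pos]
  q / sum(q)
}

# deterministic per-sample sub-seed, order-independent across samples
.sample_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + idx) %% .Machine$integer.max
}

#' Draw one local community under the Sloan neutral model
#'
#' Local relative abundances are drawn jointly as Dirichlet(N m p_1, ...,
#' N m p_K) via normalized gammas, so each taxon's marginal is exactly the
#' Beta(N m p, N m (1 - p)) stationary abundance distribution of a local
#' community of size `n_reads` receiving migrants at rate `m` from a
#' metacommunity with relative abundances `meta_p`, and the vector sums to
#' one. The drawn composition is then multinomially sampled down to
#' `n_reads` observed counts.
#'
#' @param meta_p Metacommunity relative abundances (sums to 1).
#' @param n_reads Library size of the sample.
#' @param m Migration rate in (0, 1].
#' @param seed Optional integer seed.
#' @return Integer count vector of length `length(meta_p)`.
#' @export
sample_neutral_community <- function(meta_p, n_reads, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(meta_p) - 1) > 1e-8) stop("meta_p must sum to 1")
  if (n_reads <= 0) stop("n_reads must be positive")
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  k <- length(meta_p)
  if (k == 1 || any(meta_p >= 1 - 1e-12)) {
    out <- integer(k)
    out[which.max(meta_p)] <- as.integer(n_reads)
    return(out)
  }
  q <- .draw_local(meta_p, n_reads * m)
  as.integer(stats::rmultinom(1, size = n_reads, prob = q))
}

#' Generate a synthetic two-group dataset with ground truth
#'
#' Group HL is purely neutral. Group NL is drawn from the same metacommunity
#' after (a) multiplying the `n_differential` chosen taxa's metacommunity
#' abundance by `fold_change` (half up, half down; applied before drift, so
#' the shift is detectable but neutrality-preserving) and (b) deterministic
#' selection applied to the drift-sampled local proportions before read
#' sampling: taxon j in NL sample s is multiplied by
#' exp(sqrt(selection_strength) x z_j x w_s), where z_j ~ N(0, 1) is the
#' taxon's fixed susceptibility (the same in every NL sample) and w_s is a
#' positive per-leaf exposure weight (log-normal, unit second moment)
#' reflecting that decline severity varies among non-healthy leaves. The
#' marginal log-fitness variance is exactly `selection_strength`. Post-drift
#' selection distorts the occupancy-abundance relationship the neutral model
#' predicts and narrows within-group niche breadth. Correlated blocks are induced in
#' both groups via a shared latent log-normal factor per block per sample;
#' block members are the most abundant taxa so the correlation survives
#' prevalence filtering, and differential taxa are placed inside blocks
#' first (filling block 1, 2, ...) so module-level ground truth is
#' unambiguous.
#'
#' @param spec A [synthetic_spec].
#' @param kingdom Kingdom tag for the emitted table.
#' @return List with `table` ([count_table]), `metadata`
#'   ([sample_metadata]), and `truth`: a list with `differential`
#'   (data.frame taxon_id, direction), `block` (named integer vector, NA =
#'   no block), `true_m`, and `meta_p`.
#' @export
generate_dataset <- function(spec, kingdom = "bacteria") {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$n_taxa
  n <- spec$n_samples_per_group
  taxa <- sprintf("%s_asv_%04d", substr(kingdom, 1, 1), seq_len(k))
  samples <- c(sprintf("HL_%02d", seq_len(n)), sprintf("NL_%02d", seq_len(n)))
  grp <- rep(c("HL", "NL"), each = n)

  set.seed(spec$seed)
  meta_p <- stats::rlnorm(k, 0, spec$metacommunity_sigma)
  meta_p <- meta_p / sum(meta_p)

  # blocks on the most abundant taxa
  ord <- order(meta_p, decreasing = TRUE)
  block <- rep(NA_integer_, k)
  nb <- spec$n_corr_blocks * spec$block_size
  if (nb > 0)
    block[ord[seq_len(nb)]] <- rep(seq_len(spec$n_corr_blocks),
                                   each = spec$block_size)
  names(block) <- taxa

  # differential taxa: fill blocks first, then most abundant unblocked taxa
  diff_idx <- integer(0)
  if (spec$n_differential > 0) {
    pool <- c(ord[seq_len(nb)], setdiff(ord, ord[seq_len(nb)]))
    diff_idx <- pool[seq_len(spec$n_differential)]
  }
  direction <- rep(c(1, -1), length.out = length(diff_idx))

  suscept <- if (spec$selection_strength > 0) stats::rnorm(k) else numeric(k)

  lib <- if (length(spec$reads_per_sample) == 2)
    round(stats::runif(2 * n, spec$reads_per_sample[1], spec$reads_per_sample[2]))
  else rep(spec$reads_per_sample, 2 * n)

  meta_p_nl <- meta_p
  if (length(diff_idx)) {
    # preserve the modified subset's total mass so unmodified taxa keep
    # identical metacommunity abundance (no compositional spillover:
    # between-group structure comes only from the injected effects)
    mass <- sum(meta_p_nl[diff_idx])
    meta_p_nl[diff_idx] <- meta_p_nl[diff_idx] * spec$fold_change^direction
    meta_p_nl[diff_idx] <- meta_p_nl[diff_idx] * mass / sum(meta_p_nl[diff_idx])
  }
  meta_p_nl <- meta_p_nl / sum(meta_p_nl)

  # latent-factor scale calibrated so the realized within-block Spearman
  # correlation matches block_rho: rho = tau^2 / (tau^2 + v), with v the
  # typical log-abundance drift noise of a block member
  tau <- 0
  if (nb > 0 && spec$block_rho > 0) {
    pb <- meta_p[!is.na(block)]
    v_bar <- stats::median((1 - pb) * (1 / spec$migration_m + 1) /
                             (mean(lib) * pb))
    tau <- sqrt(spec$block_rho / (1 - spec$block_rho) * v_bar)
  }

  counts <- matrix(0L, k, 2 * n, dimnames = list(taxa, samples))
  nm <- NULL # per-sample: N * m
  for (i in seq_len(2 * n)) {
    set.seed(.sample_seed(spec$seed, i))
    # per-leaf selection exposure (unit second moment) drawn first so the
    # sample's stream layout is fixed
    w_i <- stats::rlnorm(1, 0, 0.5) * exp(-0.25)
    p <- if (grp[i] == "HL") meta_p else meta_p_nl
    q <- .draw_local(p, lib[i] * spec$migration_m)
    if (nb > 0 && tau > 0) {
      g <- stats::rlnorm(spec$n_corr_blocks, 0, tau)
      inb <- !is.na(block)
      q[inb] <- q[inb] * g[block[inb]]
    }
    if (grp[i] == "NL" && spec$selection_strength > 0)
      q <- q * exp(sqrt(spec$selection_strength) * suscept * w_i)
    if (sum(q) == 0) q <- p
    counts[, i] <- as.integer(stats::rmultinom(1, lib[i], q / sum(q)))
  }
  # multinomial conditioning guarantees library sizes match the spec exactly
  keep <- rowSums(counts) > 0
  truth <- list(
    differential = data.frame(
      taxon_id = taxa[diff_idx],
      direction = ifelse(direction > 0, "up_in_NL", "down_in_NL"),
      stringsAsFactors = FALSE),
    block = block[keep],
    true_m = spec$migration_m,
    meta_p = stats::setNames(meta_p, taxa),
    susceptibility = stats::setNames(suscept, taxa))
  list(table = count_table(counts[keep, , drop = FALSE], kingdom),
       metadata = sample_metadata(samples, grp),
       truth = truth)
}

#' Write a simulated two-kingdom dataset to disk
#'
#' Emits, per kingdom, a count-table TSV, plus a shared metadata TSV and a
#' ground-truth TSV -- the file set the pipeline consumes.
#'
#' @param out_dir Output directory (created if missing).
#' @param spec_bacteria,spec_fungi [synthetic_spec]s; `spec_fungi = NULL`
#'   reuses `spec_bacteria` with a shifted seed.
#' @return Named list of written paths, invisibly.
#' @export
simulate_tables <- function(out_dir, spec_bacteria = synthetic_spec(),
                            spec_fungi = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec_fungi)) {
    spec_fungi <- spec_bacteria
    spec_fungi$seed <- spec_bacteria$seed + 104729L
  }
  ds_b <- generate_dataset(spec_bacteria, "bacteria")
  ds_f <- generate_dataset(spec_fungi, "fungi")
  paths <- list(
    bacteria = file.path(out_dir, "counts_bacteria.tsv"),
    fungi = file.path(out_dir, "counts_fungi.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    truth_bacteria = file.path(out_dir, "truth_bacteria.tsv"),
    truth_fungi = file.path(out_dir, "truth_fungi.tsv"))
  write_count_table(ds_b$table, paths$bacteria, "tsv")
  write_count_table(ds_f$table, paths$fungi, "tsv")
  write_sample_metadata(ds_b$metadata, paths$metadata)
  for (kd in c("bacteria", "fungi")) {
    ds <- if (kd == "bacteria") ds_b else ds_f
    tr <- data.frame(taxon_id = names(ds$truth$block),
                     block = ds$truth$block,
                     differential = names(ds$truth$block) %in%
                       ds$truth$differential$taxon_id,
                     stringsAsFactors = FALSE)
    utils::write.table(tr, paths[[paste0("truth_", kd)]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
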