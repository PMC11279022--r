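#' Shannon diversity of one sample
#'
#' Natural-log Shannon index, -sum p ln p; zero-count taxa contribute 0.
#'
#' @param counts Non-negative count vector with positive total.
#' @return Shannon index (>= 0, <= ln(richness)).
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("all-zero sample")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Observed richness of one sample
#' @param counts Count vector.
#' @return Number of taxa with count > 0.
#' @export
richness <- function(counts) sum(counts > 0)

#' Per-sample alpha diversity with group contrasts
#'
#' Richness (observed ASVs) and Shannon index per sample, contrasted
#' between HL and NL with Welch's t-test (the package's default alpha
#' contrast). Counts are used as-is by default; set `rarefy_to` to subsample
#' every library to a common depth first.
#'
#' @param x A [count_table].
#' @param meta A [sample_metadata].
#' @param rarefy_to Optional common depth; `"min"` uses the smallest library.
#' @param seed Seed for the rarefaction subsampling (ignored otherwise).
#' @return List of class `alpha_result`: `samples` (data.frame sample_id,
#'   group, richness, shannon) and `tests` (data.frame metric, statistic, p).
#' @export
alpha_diversity <- function(x, meta, rarefy_to = NULL, seed = 1) {
  g <- group_vector(x, meta)
  m <- x$counts
  if (!is.null(rarefy_to)) {
    depth <- if (identical(rarefy_to, "min")) min(colSums(m)) else rarefy_to
    if (depth > min(colSums(m))) stop("rarefy_to exceeds the smallest library")
    set.seed(seed)
    m <- t(vegan::rrarefy(t(m), depth))
  }
  rich <- apply(m, 2, richness)
  shan <- apply(m, 2, shannon)
  tests <- do.call(rbind, lapply(list(richness = rich, shannon = shan),
                                 function(v) {
    ht <- group_contrast_test(v[g == "HL"], v[g == "NL"], "t_test")
    data.frame(statistic = ht$statistic, p = ht$p_value)
  }))
  tests <- data.frame(metric = rownames(tests), tests, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(
    samples = data.frame(sample_id = colnames(m), group = g, richness = rich,
                         shannon = shan, row.names = NULL,
                         stringsAsFactors = FALSE),
    tests = tests), class = "alpha_result")
}

#' Expected rarefaction curve of one sample
#'
#' Exact hypergeometric expectation of richness at each subsampling depth
#' (no Monte Carlo): E[S(d)] = S - sum_i C(total - n_i, d) / C(total, d).
#' Monotone non-decreasing in depth and equal to observed richness at the
#' full depth.
#'
#' @param counts Count vector.
#' @param depths Integer depths, each <= `sum(counts)`.
#' @return data.frame with columns `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(counts, depths) {
  total <- sum(counts)
  if (any(depths > total)) stop("depth exceeds sample total")
  if (any(depths < 1)) stop("depths must be >= 1")
  er <- vapply(depths, function(d)
    as.numeric(vegan::rarefy(counts, sample = d)), numeric(1))
  data.frame(depth = as.integer(depths), expected_richness = er)
}

#' Bray-Curtis distance matrix between samples
#'
#' @param x A [count_table].
#' @return Symmetric sample-by-sample matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis <- function(x) {
  stopifnot(ncol(x$counts) >= 2)
  as.matrix(vegan::vegdist(t(x$counts), method = "bray"))
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal's NMDS (stress-1, monotone regression on pooled distance ranks)
#' with random restarts; the best configuration is returned, centered.
#'
#' @param d Symmetric distance matrix or `dist`.
#' @param k Target dimensionality.
#' @param n_starts Number of random restarts.
#' @param seed Integer seed.
#' @return List of class `ordination_result`: `points` (n x k), `stress`
#'   (Kruskal stress-1, fraction in \[0, 1\]), `k`, `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1) {
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = k, try = n_starts,
                        trymax = n_starts, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  structure(list(points = pts, stress = fit$stress, k = k,
                 converged = isTRUE(fit$converged)),
            class = "ordination_result")
}

#' One-way PERMANOVA on a distance matrix
#'
#' Anderson's distance-based partition of the squared distances by group
#' label; significance by label permutation with the add-one convention, so
#' the smallest attainable p is 1/(n_permutations + 1).
#'
#' @param d Symmetric distance matrix or `dist` over samples.
#' @param meta A [sample_metadata] covering the samples of `d`.
#' @param n_permutations Number of label permutations (study default 999).
#' @param seed Integer seed.
#' @return List of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_permutations`.
#' @export
permanova <- function(d, meta, n_permutations = 999, seed = 1) {
  d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must carry sample ids")
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  g <- meta$group[idx]
  if (any(table(g) < 2)) stop("each group needs >= 2 samples")
  set.seed(seed)
  df <- data.frame(group = g)
  fit <- vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                        permutations = n_permutations)
  structure(list(pseudo_F = fit$F[1], R2 = fit$R2[1],
                 p = fit$`Pr(>F)`[1], n_permutations = n_permutations),
            class = "permanova_result")
}
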