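#' Sample metadata: health-status group labels
#'
#' Maps each sample to one of the two leaf-health groups: HL (healthy
#' leaves) or NL (non-healthy leaves).
#'
#' @param sample_id Character vector of sample ids.
#' @param group Character vector, each element `"HL"` or `"NL"`.
#' @return A `sample_metadata` data.frame with columns `sample_id`, `group`
#'   (factor with levels HL, NL).
#' @export
sample_metadata <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("sample_id and group must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(group), c("HL", "NL"))
  if (length(bad))
    stop("group labels must be HL or NL; got: ", paste(bad, collapse = ", "))
  out <- data.frame(sample_id = sample_id,
                    group = factor(group, levels = c("HL", "NL")),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Read sample metadata from a TSV file (columns: sample_id, group)
#' @param path File path.
#' @return A [sample_metadata] data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata TSV must have columns sample_id, group")
  sample_metadata(df$sample_id, df$group)
}

#' @rdname read_sample_metadata
#' @param meta A `sample_metadata` object.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Group labels aligned to the samples of a count table
#'
#' Validates the two-group contract: every sample of `x` has exactly one
#' label and both groups are non-empty.
#'
#' @param x A `count_table`.
#' @param meta A [sample_metadata].
#' @return Factor of group labels in `sample_ids(x)` order.
#' @export
group_vector <- function(x, meta) {
  idx <- match(sample_ids(x), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(sample_ids(x)[is.na(idx)], collapse = ", "))
  g <- meta$group[idx]
  if (any(table(g) == 0))
    stop("both groups (HL, NL) must be non-empty")
  g
}

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Taxonomy table with ranked lineages
#'
#' Stores one lineage (kingdom..genus) per taxon. Lookups are total over the
#' taxa present: unassigned ranks come back as `"unclassified"`.
#'
#' @param taxon_id Character vector.
#' @param lineage Character vector of semicolon-delimited lineages, ordered
#'   kingdom;phylum;class;order;family;genus (trailing ranks may be absent).
#' @return A `taxonomy_table` data.frame with one column per rank.
#' @export
taxonomy_table <- function(taxon_id, lineage) {
  taxon_id <- as.character(taxon_id)
  if (anyDuplicated(taxon_id)) stop("duplicate taxon ids in taxonomy")
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == "" | is.na(p)] <- "unclassified"
    c(p, rep("unclassified", length(RANKS)))[seq_along(RANKS)]
  }, character(length(RANKS))))
  colnames(m) <- RANKS
  out <- data.frame(taxon_id = taxon_id, m, stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Read a taxonomy TSV (columns: taxon_id, lineage)
#' @param path File path.
#' @return A [taxonomy_table].
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "lineage") %in% names(df)))
    stop("taxonomy TSV must have columns taxon_id, lineage")
  taxonomy_table(df$taxon_id, df$lineage)
}

#' Look up one rank for a set of taxa
#'
#' @param tax A [taxonomy_table] or NULL.
#' @param taxa Character vector of taxon ids.
#' @param rank One of kingdom, phylum, class, order, family, genus.
#' @return Character vector; `"unclassified"` for taxa absent from `tax`.
#' @export
rank_of <- function(tax, taxa, rank) {
  rank <- match.arg(rank, RANKS)
  if (is.null(tax)) return(rep("unclassified", length(taxa)))
  out <- tax[[rank]][match(taxa, tax$taxon_id)]
  out[is.na(out)] <- "unclassified"
  out
}

#' Per-group relative abundance collapsed to a taxonomic rank
#'
#' Pools counts within each group, collapses taxa to the requested rank, and
#' returns proportions (summing to 1 within each group) -- the quantity shown
#' in class-level composition barplots.
#'
#' @param x A `count_table`.
#' @param tax A [taxonomy_table].
#' @param rank Rank name to collapse to.
#' @param meta A [sample_metadata].
#' @return data.frame with columns `rank`, one proportion column per group.
#' @export
relative_abundance_by_rank <- function(x, tax, rank, meta) {
  g <- group_vector(x, meta)
  lab <- rank_of(tax, taxon_ids(x), rank)
  res <- lapply(levels(g), function(lv) {
    tot <- rowSums(x$counts[, g == lv, drop = FALSE])
    p <- tapply(tot, lab, sum) / sum(tot)
    p
  })
  labs <- sort(unique(lab))
  out <- data.frame(rank = labs, stringsAsFactors = FALSE)
  names(out)[1] <- rank
  for (i in seq_along(levels(g)))
    out[[levels(g)[i]]] <- as.numeric(res[[i]][labs])
  out[is.na(out)] <- 0
  out
}

#' Two-group location test
#'
#' Group contrast used throughout: Welch's unequal-variance t-test, or the
#' Wilcoxon rank-sum test on mid-ranks -- exact (full enumeration of label
#' splits, correct under ties) when the split count is small enough,
#' normal approximation otherwise. Both two-sided.
#'
#' @param x,y Numeric vectors, one per group.
#' @param method `"t_test"` (Welch) or `"wilcoxon"`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
group_contrast_test <- function(x, y, method = c("t_test", "wilcoxon")) {
  method <- match.arg(method)
  if (method == "t_test") {
    if (length(x) < 2 || length(y) < 2)
      stop("t_test needs >= 2 values per group")
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      stop("degenerate input: zero variance in both groups")
    ht <- stats::t.test(x, y, var.equal = FALSE)
  } else {
    if (length(x) < 1 || length(y) < 1)
      stop("wilcoxon needs >= 1 value per group")
    n1 <- length(x)
    n <- n1 + length(y)
    if (choose(n, n1) <= 1e5) {
      # exact mid-rank permutation null: two-sided p over all label splits
      r <- rank(c(x, y))
      w_obs <- sum(r[seq_len(n1)])
      ew <- n1 * (n + 1) / 2
      splits <- utils::combn(n, n1)
      ws <- colSums(matrix(r[splits], nrow = n1))
      pv <- mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
      return(list(statistic = w_obs - n1 * (n1 + 1) / 2, p_value = pv,
                  method = method))
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, method = method)
}
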