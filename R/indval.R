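#' Indicator species analysis (IndVal)
#'
#' Group-size-corrected indicator values per taxon and group:
#' A (specificity) = mean relative count in the group divided by the sum of
#' the group means; B (fidelity) = occurrence fraction within the group;
#' IndVal = sqrt(A x B). Significance comes from label permutations of the
#' max-over-groups statistic (two-sided association with health status),
#' add-one convention; `exact = TRUE` enumerates all distinct label splits
#' instead (feasible for small n), in which case p is the exact fraction of
#' splits with a statistic at least as large as observed.
#'
#' Relative counts (per-sample proportions) make the statistic invariant to
#' rescaling any single sample's library.
#'
#' @param x A [count_table].
#' @param meta A [sample_metadata].
#' @param n_perm Number of permutations (study default 9999).
#' @param seed Integer seed.
#' @param exact Enumerate all label splits instead of sampling.
#' @return List of class `indicator_result`: `table` (data.frame taxon_id,
#'   A_HL, A_NL, B_HL, B_NL, indval_HL, indval_NL, best_group, stat, p) and
#'   `n_perm` (splits enumerated when exact).
#' @export
indval <- function(x, meta, n_perm = 9999, seed = 1, exact = FALSE) {
  g <- group_vector(x, meta)
  m <- x$counts[rowSums(x$counts) > 0, , drop = FALSE]
  rel <- sweep(m, 2, colSums(x$counts), "/")
  pres <- (m > 0) * 1

  stat_for <- function(gv) {
    w <- cbind(HL = (gv == "HL") / sum(gv == "HL"),
               NL = (gv == "NL") / sum(gv == "NL"))
    amean <- rel %*% w              # taxa x 2 group mean relative counts
    occ <- pres %*% w               # taxa x 2 occurrence fractions
    A <- amean / pmax(rowSums(amean), .Machine$double.xmin)
    iv <- sqrt(A * occ)
    list(iv = iv, A = A, B = occ, stat = apply(iv, 1, max))
  }
  obs <- stat_for(g)

  n <- length(g)
  n_hl <- sum(g == "HL")
  if (exact) {
    splits <- utils::combn(n, n_hl)
    n_eff <- ncol(splits)
    ge <- integer(nrow(m))
    for (j in seq_len(n_eff)) {
      gv <- rep("NL", n); gv[splits[, j]] <- "HL"
      ge <- ge + (stat_for(gv)$stat >= obs$stat - 1e-12)
    }
    p <- ge / n_eff
  } else {
    set.seed(seed)
    ge <- integer(nrow(m))
    for (j in seq_len(n_perm)) {
      gv <- sample(as.character(g))
      ge <- ge + (stat_for(gv)$stat >= obs$stat - 1e-12)
    }
    p <- (ge + 1) / (n_perm + 1)
    n_eff <- n_perm
  }

  best <- colnames(obs$iv)[max.col(obs$iv, ties.method = "first")]
  out <- data.frame(taxon_id = rownames(m),
                    A_HL = obs$A[, "HL"], A_NL = obs$A[, "NL"],
                    B_HL = obs$B[, "HL"], B_NL = obs$B[, "NL"],
                    indval_HL = obs$iv[, "HL"], indval_NL = obs$iv[, "NL"],
                    best_group = best, stat = obs$stat, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = out, n_perm = n_eff, exact = exact),
            class = "indicator_result")
}

#' Intersect differential and indicator calls into health-sensitive ASVs
#'
#' A taxon is flagged health-sensitive (hsASV) iff its BH-adjusted
#' differential q-value and its indicator permutation p both fall below
#' their thresholds (study defaults: both 0.05). The assigned group is the
#' indicator's best group; when it disagrees with the sign of the
#' differential fold change the taxon is flagged discordant.
#'
#' @param diff A `differential_result`.
#' @param ind An `indicator_result`.
#' @param q_threshold FDR threshold on the differential q-value.
#' @param p_threshold Threshold on the indicator permutation p.
#' @return data.frame of class `hsasv_report`: taxon_id, log2fc, lrt_p,
#'   lrt_q, indval, indval_p, diff_flag, ind_flag, hs_flag, assigned_group,
#'   discordant.
#' @export
identify_hsasvs <- function(diff, ind, q_threshold = 0.05,
                            p_threshold = 0.05) {
  d <- diff$table
  i <- ind$table
  merged <- merge(d, i[, c("taxon_id", "best_group", "stat", "p")],
                  by = "taxon_id", suffixes = c("", ".ind"), all = TRUE)
  # taxa untested by either analysis cannot be confirmed by both
  diff_flag <- !is.na(merged$q) & merged$q < q_threshold
  ind_flag <- !is.na(merged$p.ind) & merged$p.ind < p_threshold
  hs <- diff_flag & ind_flag
  fc_group <- ifelse(merged$log2fc > 0, "NL", "HL")
  out <- data.frame(taxon_id = merged$taxon_id,
                    log2fc = merged$log2fc,
                    lrt_p = merged$p, lrt_q = merged$q,
                    indval = merged$stat, indval_p = merged$p.ind,
                    diff_flag = diff_flag, ind_flag = ind_flag,
                    hs_flag = hs,
                    assigned_group = ifelse(hs, merged$best_group, NA),
                    discordant = hs & (merged$best_group != fc_group),
                    stringsAsFactors = FALSE)
  class(out) <- c("hsasv_report", "data.frame")
  out
}
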