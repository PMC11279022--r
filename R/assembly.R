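#' Levins' niche breadth
#'
#' For taxon j across the N communities (samples) of the table,
#' B_j = 1 / sum_i P_ij^2 with P_ij the proportion of taxon j's total found
#' in sample i (so sum_i P_ij = 1). B_j = 1 for a single-site specialist
#' and N for a perfectly even generalist, and is invariant to rescaling a
#' taxon's counts. Community breadth per sample is the mean B over taxa
#' present (count > 0) in that sample.
#'
#' With metadata, each health-status group is treated as its own
#' metacommunity (B computed over that group's samples only) and the
#' per-sample community breadths are contrasted HL vs NL by the Wilcoxon
#' rank-sum test.
#'
#' @param x A [count_table] (raw counts by default, per the package's
#'   convention; pass a CPM matrix wrapped in a table to change that).
#' @param meta Optional [sample_metadata] for the per-group computation and
#'   contrast.
#' @return List of class `niche_breadth_result`: `taxon_breadth`
#'   (data.frame taxon_id, B, plus group when metadata given),
#'   `community_breadth` (data.frame sample_id, breadth, group if metadata
#'   given), `test` (Wilcoxon statistic and p, or NULL).
#' @export
levins_breadth <- function(x, meta = NULL) {
  breadth_one <- function(m, warn = FALSE) {
    zero <- rowSums(m) == 0
    if (any(zero)) {
      if (warn) warning("excluding ", sum(zero), " all-zero taxa")
      m <- m[!zero, , drop = FALSE]
    }
    P <- sweep(m, 1, rowSums(m), "/")
    B <- 1 / rowSums(P^2)
    comm <- vapply(seq_len(ncol(m)), function(i) mean(B[m[, i] > 0]),
                   numeric(1))
    list(B = B, comm = data.frame(sample_id = colnames(m), breadth = comm,
                                  stringsAsFactors = FALSE))
  }
  if (is.null(meta)) {
    r <- breadth_one(x$counts, warn = TRUE)
    return(structure(list(
      taxon_breadth = data.frame(taxon_id = names(r$B), B = r$B,
                                 row.names = NULL, stringsAsFactors = FALSE),
      community_breadth = r$comm, test = NULL),
      class = "niche_breadth_result"))
  }
  g <- group_vector(x, meta)
  per <- lapply(levels(g), function(lv) {
    r <- breadth_one(x$counts[, g == lv, drop = FALSE])
    r$comm$group <- lv
    list(tb = data.frame(taxon_id = names(r$B), group = lv, B = r$B,
                         row.names = NULL, stringsAsFactors = FALSE),
         comm = r$comm)
  })
  tb <- do.call(rbind, lapply(per, `[[`, "tb"))
  cb <- do.call(rbind, lapply(per, `[[`, "comm"))
  ht <- group_contrast_test(cb$breadth[cb$group == "HL"],
                            cb$breadth[cb$group == "NL"], "wilcoxon")
  structure(list(taxon_breadth = tb, community_breadth = cb,
                 test = data.frame(statistic = ht$statistic, p = ht$p_value)),
            class = "niche_breadth_result")
}

# Sloan occupancy prediction for a taxon at metacommunity relative
# abundance p in a local community of size N with migration rate m.
# threshold: detected iff local abundance exceeds d (classic convention).
# sampling:  detected iff >= 1 of N reads hits the taxon; for beta-
#            distributed local abundance, E[(1-q)^N] = B(a, b+N)/B(a, b).
.ncm_predict <- function(p, m, N, d, detection = "threshold") {
  a <- N * m * p
  b <- N * m * (1 - p)
  if (detection == "threshold") 1 - stats::pbeta(d, a, b)
  else 1 - exp(lbeta(a, b + N) - lbeta(a, b))
}

#' Fit the Sloan neutral community model
#'
#' Fits the migration rate m of the Sloan neutral model to the observed
#' occurrence-frequency vs mean-relative-abundance relationship: for taxon
#' j, p_j is its mean relative abundance over samples and freq_j the
#' fraction of samples where it is present; the model predicts
#' freq(p) = 1 - BetaCDF(d; N m p, N m (1 - p)) with N the mean library
#' size and detection limit d = 1/N by default. m is estimated by bounded
#' least squares (multi-start over a log grid on (1e-4, 1], then refined to
#' tolerance 1e-8); R^2 = 1 - SSres/SStot. A 95% prediction envelope
#' (Wilson binomial intervals around the predicted frequency at n =
#' number of samples) partitions taxa into above / within / below the
#' neutral expectation, and a bootstrap over taxa (the fit's observations)
#' gives the confidence interval on m.
#'
#' Two detection models are available. `"threshold"` (the default and the
#' classic convention) treats a taxon as detectable when its local
#' relative abundance exceeds d. `"sampling"` instead uses the exact
#' probability that at least one of the N multinomially sampled reads hits
#' the taxon, 1 - B(Nmp, Nm(1-p) + N) / B(Nmp, Nm(1-p)); it is the
#' likelihood-consistent choice for finite count data and recovers a known
#' migration rate without the modest upward bias the threshold convention
#' shows on read-sampled communities (see the methods vignette).
#'
#' @param x A [count_table] (>= 10 samples recommended).
#' @param n_bootstrap Bootstrap replicates for the CI on m (study default
#'   1000; 0 skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @param d Detection limit; default 1 / mean library size.
#' @param detection `"threshold"` or `"sampling"` (see Details).
#' @return List of class `ncm_fit`: `m`, `m_ci`, `N_comm`, `d`, `R2`,
#'   `taxa` (data.frame taxon_id, p, freq, predicted, lower, upper,
#'   partition), `n_samples`, `detection`.
#' @export
ncm_fit <- function(x, n_bootstrap = 1000, seed = 1, d = NULL,
                    detection = c("threshold", "sampling")) {
  detection <- match.arg(detection)
  m0 <- x$counts
  n_samp <- ncol(m0)
  rel <- sweep(m0, 2, colSums(m0), "/")
  p <- rowMeans(rel)
  freq <- rowMeans(m0 > 0)
  keep <- p > 0
  p <- p[keep]; freq <- freq[keep]
  N <- mean(colSums(m0))
  if (is.null(d)) d <- 1 / N
  if (all(freq >= 1)) stop("degenerate input: every taxon occurs everywhere")
  if (stats::var(freq) == 0) stop("degenerate input: no frequency gradient")

  fit_m <- function(pv, fv) ncm_fit_points(pv, fv, N, d, detection)$m
  m_hat <- fit_m(p, freq)
  pred <- .ncm_predict(p, m_hat, N, d, detection)
  r2 <- 1 - sum((freq - pred)^2) / sum((freq - mean(freq))^2)

  # Wilson 95% interval around the predicted frequency at n = sample count
  z <- stats::qnorm(0.975)
  wilson <- function(ph, n) {
    den <- 1 + z^2 / n
    ctr <- (ph + z^2 / (2 * n)) / den
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    cbind(pmax(0, ctr - hw), pmin(1, ctr + hw))
  }
  env <- wilson(pred, n_samp)
  partition <- ifelse(freq > env[, 2], "above",
                      ifelse(freq < env[, 1], "below", "within"))

  m_ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    set.seed(seed)
    nb <- length(p)
    boots <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(nb, nb, replace = TRUE)
      fit_m(p[idx], freq[idx])
    }, numeric(1))
    m_ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  structure(list(m = m_hat, m_ci = m_ci, N_comm = N, d = d, R2 = r2,
                 taxa = data.frame(taxon_id = names(p), p = p, freq = freq,
                                   predicted = pred, lower = env[, 1],
                                   upper = env[, 2], partition = partition,
                                   row.names = NULL, stringsAsFactors = FALSE),
                 n_samples = n_samp, detection = detection),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM fit: m = %.4f (95%% CI %.4f-%.4f), R2 = %.4f, N = %.0f, %d taxa\n",
              x$m, x$m_ci[1], x$m_ci[2], x$R2, x$N_comm, nrow(x$taxa)))
  invisible(x)
}

#' Low-level Sloan-model least-squares fit on (abundance, frequency) points
#'
#' The optimizer behind [ncm_fit], exposed for fitting pre-computed
#' occurrence-frequency vs relative-abundance relationships: bounded
#' least squares for m on (1e-4, 1] via a multi-start log grid refined by
#' golden-section search (tolerance 1e-9 on m).
#'
#' @param p Mean relative abundances (one per taxon).
#' @param freq Occurrence frequencies in \[0, 1\].
#' @param N Community size (reads per sample).
#' @param d Detection limit.
#' @param detection `"threshold"` or `"sampling"` (see [ncm_fit]).
#' @return List with `m`, `R2`, `predicted`.
#' @export
ncm_fit_points <- function(p, freq, N, d = 1 / N,
                           detection = c("threshold", "sampling")) {
  detection <- match.arg(detection)
  ss <- function(m) sum((freq - .ncm_predict(p, m, N, d, detection))^2)
  grid <- 10^seq(-4, 0, length.out = 25)
  vals <- vapply(grid, ss, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ss, interval = c(lo, hi), tol = 1e-9)
  pred <- .ncm_predict(p, opt$minimum, N, d, detection)
  list(m = opt$minimum,
       R2 = 1 - sum((freq - pred)^2) / sum((freq - mean(freq))^2),
       predicted = pred)
}

#' Presence/absence matrix of a count table
#' @param x A [count_table].
#' @return Binary (0/1) integer matrix, taxa x samples.
#' @export
presence_absence <- function(x) (x$counts > 0) * 1L

#' Checkerboard score (C-score)
#'
#' Mean number of checkerboard units over unordered taxon pairs of a binary
#' presence/absence matrix: CU_ij = (R_i - S_ij)(R_j - S_ij), with R the
#' row (taxon) totals and S_ij the number of shared presences.
#'
#' @param pa Binary matrix, taxa (rows) x samples (columns).
#' @return The C-score (a non-negative real).
#' @export
c_score <- function(pa) {
  pa <- as.matrix(pa) * 1
  stopifnot(nrow(pa) >= 2, all(pa %in% c(0, 1)))
  S <- tcrossprod(pa)
  R <- rowSums(pa)
  CU <- (R - S) * t(R - t(S))  # (R_i - S_ij)(R_j - S_ij)
  mean(CU[upper.tri(CU)])
}

#' Sequential-swap null model for the C-score
#'
#' Degenerate-matrix-preserving randomization: repeatedly pick a random
#' pair of rows and columns and, when the 2x2 submatrix is a checkerboard,
#' swap it -- preserving all row and column totals. After `burn_in`
#' iterations the C-score is recorded once per attempted swap for `n_sim`
#' steps (study defaults: 30,000 simulations, 500 burn-in). The
#' standardized effect size is SES = (C_obs - mean(null)) / sd(null);
#' SES < -2 indicates aggregation and SES > 2 segregation. A null SD of 0
#' leaves SES NA with a diagnostic.
#'
#' @param pa Binary matrix, taxa x samples.
#' @param n_sim Number of recorded post-burn-in steps.
#' @param burn_in Number of warm-up swap attempts.
#' @param seed Integer seed.
#' @return List of class `cscore_result`: `c_obs`, `null_mean`, `null_sd`,
#'   `ses`, `n_sim`, `burn_in`, `thin`, `null` (the recorded C-scores), and
#'   `final` (the last matrix of the chain).
#' @export
sequential_swap_null <- function(pa, n_sim = 30000, burn_in = 500,
                                 thin = 1, seed = 1) {
  pa <- as.matrix(pa) * 1
  stopifnot(all(pa %in% c(0, 1)), nrow(pa) >= 2, ncol(pa) >= 2)
  set.seed(seed)
  c_obs <- c_score(pa)
  nr <- nrow(pa); nc <- ncol(pa)
  A <- pa
  # incremental state: swaps only touch two rows, so only pairs involving
  # those rows change; maintain S = A A^T, row totals R, and the CU sum
  S <- tcrossprod(A)
  R <- rowSums(A)
  npairs <- nr * (nr - 1) / 2
  pair_cu <- function(i) {
    cu <- (R[i] - S[i, ]) * (R - S[i, ])
    sum(cu[-i])
  }
  CU <- (R - S) * t(R - t(S))
  cusum <- sum(CU[upper.tri(CU)])
  cur <- cusum / npairs
  nulls <- numeric(n_sim)
  total <- burn_in + n_sim * thin
  # pre-draw the random row/column pairs for speed
  r1 <- sample.int(nr, total, replace = TRUE)
  r2 <- sample.int(nr - 1L, total, replace = TRUE)
  r2 <- r2 + (r2 >= r1)
  c1 <- sample.int(nc, total, replace = TRUE)
  c2 <- sample.int(nc - 1L, total, replace = TRUE)
  c2 <- c2 + (c2 >= c1)
  for (t in seq_len(total)) {
    i1 <- r1[t]; i2 <- r2[t]; j1 <- c1[t]; j2 <- c2[t]
    a <- A[i1, j1]; b <- A[i1, j2]
    cc <- A[i2, j1]; dd <- A[i2, j2]
    if (a == dd && b == cc && a != b) {
      cu12 <- (R[i1] - S[i1, i2]) * (R[i2] - S[i1, i2])
      old <- pair_cu(i1) + pair_cu(i2) - cu12
      A[i1, j1] <- b; A[i1, j2] <- a
      A[i2, j1] <- dd; A[i2, j2] <- cc
      s1 <- as.vector(A %*% A[i1, ]); s2 <- as.vector(A %*% A[i2, ])
      S[i1, ] <- s1; S[, i1] <- s1
      S[i2, ] <- s2; S[, i2] <- s2
      cu12 <- (R[i1] - S[i1, i2]) * (R[i2] - S[i1, i2])
      cusum <- cusum + (pair_cu(i1) + pair_cu(i2) - cu12) - old
      cur <- cusum / npairs
    }
    if (t > burn_in && (t - burn_in) %% thin == 0)
      nulls[(t - burn_in) %/% thin] <- cur
  }
  null_mean <- mean(nulls)
  null_sd <- stats::sd(nulls)
  ses <- if (null_sd > 0) (c_obs - null_mean) / null_sd else NA_real_
  structure(list(c_obs = c_obs, null_mean = null_mean, null_sd = null_sd,
                 ses = ses, n_sim = n_sim, burn_in = burn_in, thin = thin,
                 null = nulls, final = A,
                 degenerate = null_sd == 0),
            class = "cscore_result")
}

#' @export
print.cscore_result <- function(x, ...) {
  cat(sprintf("C-score: observed %.4f, null %.4f +/- %.4f, SES = %s (%d sims, %d burn-in)\n",
              x$c_obs, x$null_mean, x$null_sd,
              if (is.na(x$ses)) "NA (degenerate null)" else sprintf("%.2f", x$ses),
              x$n_sim, x$burn_in))
  invisible(x)
}
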