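test_that("TMM factors are neutral for pure depth differences", {
  m <- matrix(as.integer(c(10, 20, 30, 40, 20, 40, 60, 80)), 4, 2,
              dimnames = list(paste0("t", 1:4), c("A", "B")))
  nt <- tmm_normalize(count_table(m, "bacteria"))
  expect_equal(unname(nt$tmm_factors), c(1, 1), tolerance = 1e-9)
  expect_equal(nt$cpm[, "A"], nt$cpm[, "B"], tolerance = 1e-9)
  expect_equal(nt$cpm["t1", "A"], 10 / 100 * 1e6)
})

test_that("TMM factors have geometric mean one and match a trim oracle", {
  # 50 taxa, 5 inflated in sample B: the factor should counteract them
  set.seed(7)
  base <- as.integer(rpois(50, 100))
  m <- cbind(A = base, B = base)
  m[1:5, "B"] <- m[1:5, "B"] * 20L
  rownames(m) <- sprintf("t%02d", 1:50)
  ct <- count_table(m, "bacteria")
  nt <- tmm_normalize(ct)
  expect_equal(exp(mean(log(nt$tmm_factors))), 1, tolerance = 1e-9)

  # explicit sort-trim-average oracle for B against reference A
  lib <- colSums(m)
  M <- log2((m[, "B"] / lib["B"]) / (m[, "A"] / lib["A"]))
  A <- 0.5 * log2((m[, "B"] / lib["B"]) * (m[, "A"] / lib["A"]))
  keep <- rank(M) > 0.3 * 50 & rank(M) <= 0.7 * 50 &
    rank(A) > 0.05 * 50 & rank(A) <= 0.95 * 50
  f_oracle <- 2^mean(M[keep])
  ratio <- nt$tmm_factors["B"] / nt$tmm_factors["A"]
  expect_equal(unname(ratio), f_oracle, tolerance = 0.05)
})

test_that("NB-LRT finds no effect in flat taxa and respects q >= p", {
  m <- matrix(50L, 20, 8)
  set.seed(2)
  m[11:20, ] <- matrix(as.integer(rpois(80, 30)), 10, 8)
  rownames(m) <- sprintf("t%02d", 1:20); colnames(m) <- sprintf("s%d", 1:8)
  ct <- count_table(m, "bacteria")
  meta <- two_group_meta(sample_ids(ct))
  dd <- nb_lrt_differential(ct, meta)
  flat <- dd$table[dd$table$taxon_id == "t01", ]
  expect_lt(flat$lrt, 0.5)
  expect_gt(flat$p, 0.5)
  expect_true(all(dd$table$q >= dd$table$p - 1e-12))
  ord <- order(dd$table$p)
  expect_true(all(diff(dd$table$q[ord]) >= -1e-12))
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    out <- numeric(n); out[o] <- pmin(q, 1)
    out
  }
  set.seed(10)
  for (r in 1:5) {
    p <- runif(50)^2
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("differential power on synthetic fold-change taxa is high", {
  spec <- synthetic_spec(n_taxa = 300, n_samples_per_group = 20,
                         reads_per_sample = 10000, n_differential = 20,
                         fold_change = 4, n_corr_blocks = 0, block_size = 0,
                         seed = 77)
  ds <- generate_dataset(spec)
  filt <- prevalence_filter(ds$table, 5, 2)
  dd <- nb_lrt_differential(filt, ds$metadata, tmm_normalize(filt))
  hit <- dd$table$taxon_id[dd$table$q < 0.05]
  expect_gte(mean(ds$truth$differential$taxon_id %in% hit), 0.8)
})

test_that("IndVal identifies perfect indicators and matches enumeration", {
  # perfect indicator over 12 + 12 samples: p attains 1/(n_perm + 1)
  set.seed(3)
  m <- matrix(as.integer(rpois(24 * 5, 20)), 5, 24,
              dimnames = list(paste0("t", 1:5), sprintf("s%02d", 1:24)))
  m[1, 13:24] <- 0L
  ct <- count_table(m, "bacteria")
  meta <- two_group_meta(sample_ids(ct))
  iv <- indval(ct, meta, n_perm = 199, seed = 5)
  t1 <- iv$table[iv$table$taxon_id == "t1", ]
  expect_equal(t1$indval_HL, 1)
  expect_equal(t1$best_group, "HL")
  expect_equal(t1$p, 1 / 200)

  # taxon with equal group means and occurrence: A = 0.5, high p
  flat <- iv$table[iv$table$taxon_id == "t2", ]
  expect_equal(flat$A_HL, 0.5, tolerance = 0.15)
  expect_lte(flat$stat, 1)

  # exact enumeration on a 6-sample toy equals an independent oracle
  m6 <- matrix(as.integer(rpois(18, 15)), 3, 6,
               dimnames = list(paste0("t", 1:3), paste0("s", 1:6)))
  m6[2, 4:6] <- m6[2, 4:6] + 40L
  ct6 <- count_table(m6, "bacteria")
  meta6 <- two_group_meta(sample_ids(ct6))
  iv6 <- indval(ct6, meta6, exact = TRUE)
  oracle_stat <- function(mm, g) {
    rel <- sweep(mm, 2, colSums(mm), "/")
    sapply(rownames(mm), function(tx) {
      max(sapply(c("HL", "NL"), function(lv) {
        a <- mean(rel[tx, g == lv]) /
          (mean(rel[tx, g == "HL"]) + mean(rel[tx, g == "NL"]))
        b <- mean(mm[tx, g == lv] > 0)
        sqrt(a * b)
      }))
    })
  }
  g0 <- as.character(group_vector(ct6, meta6))
  obs <- oracle_stat(m6, g0)
  splits <- utils::combn(6, 3)
  perm_stats <- apply(splits, 2, function(ix) {
    gg <- rep("NL", 6); gg[ix] <- "HL"
    oracle_stat(m6, gg)
  })
  p_oracle <- rowMeans(perm_stats >= obs - 1e-12)
  expect_equal(iv6$table$p, unname(p_oracle[iv6$table$taxon_id]),
               tolerance = 1e-12)
})

test_that("IndVal is invariant to rescaling a single sample's counts", {
  ct <- rand_count_table(15, 8, seed = 21)
  meta <- two_group_meta(sample_ids(ct))
  iv1 <- indval(ct, meta, n_perm = 99, seed = 2)
  m2 <- ct$counts
  m2[, 3] <- m2[, 3] * 7L
  iv2 <- indval(count_table(m2, "bacteria"), meta, n_perm = 99, seed = 2)
  expect_equal(iv2$table$stat, iv1$table$stat, tolerance = 1e-12)
  expect_equal(iv2$table$p, iv1$table$p)
})

test_that("hsASV intersection is exact set algebra with direction checks", {
  dtab <- data.frame(taxon_id = paste0("t", 1:4),
                     log2fc = c(2, -1.5, 3, 0.2),
                     lrt = c(30, 25, 28, 0.1),
                     p = c(1e-6, 1e-5, 1e-6, 0.9),
                     q = c(1e-5, 1e-4, 1e-5, 0.95))
  itab <- data.frame(taxon_id = paste0("t", 1:4),
                     best_group = c("NL", "HL", "HL", "NL"),
                     stat = c(0.9, 0.8, 0.85, 0.3),
                     p = c(0.001, 0.002, 0.6, 0.7))
  d <- structure(list(table = dtab, untested = character(0)),
                 class = "differential_result")
  i <- structure(list(table = itab, n_perm = 999, exact = FALSE),
                 class = "indicator_result")
  hs <- identify_hsasvs(d, i)
  expect_equal(hs$hs_flag, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(hs$assigned_group[1:2], c("NL", "HL"))
  expect_false(any(hs$discordant))
  # t2: negative fold change agrees with HL assignment; force a mismatch
  itab$best_group[2] <- "NL"
  i2 <- structure(list(table = itab, n_perm = 999, exact = FALSE),
                  class = "indicator_result")
  hs2 <- identify_hsasvs(d, i2)
  expect_true(hs2$discordant[2])
})

test_that("hsASV set equals the intersection of its component calls", {
  spec <- synthetic_spec(n_taxa = 200, n_samples_per_group = 12,
                         reads_per_sample = 8000, seed = 31)
  ds <- generate_dataset(spec)
  filt <- prevalence_filter(ds$table, 5, 2)
  dd <- nb_lrt_differential(filt, ds$metadata, tmm_normalize(filt))
  iv <- indval(filt, ds$metadata, n_perm = 199, seed = 4)
  hs <- identify_hsasvs(dd, iv)
  by_diff <- dd$table$taxon_id[dd$table$q < 0.05]
  by_ind <- iv$table$taxon_id[iv$table$p < 0.05]
  expect_setequal(hs$taxon_id[hs$hs_flag], intersect(by_diff, by_ind))
})
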