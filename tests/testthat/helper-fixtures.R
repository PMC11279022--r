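# Shared fixture builders and independent oracles used across test files.

rand_count_table <- function(n_taxa = 30, n_samples = 10, libsize = 1000,
                             seed = 1, kingdom = "bacteria") {
  set.seed(seed)
  prob <- rexp(n_taxa)
  m <- sapply(seq_len(n_samples), function(i)
    as.integer(rmultinom(1, libsize, prob)))
  rownames(m) <- sprintf("t%03d", seq_len(n_taxa))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  count_table(m, kingdom)
}

two_group_meta <- function(samples) {
  n <- length(samples)
  sample_metadata(samples, rep(c("HL", "NL"), each = n %/% 2,
                               length.out = n))
}

rand_binary <- function(n_taxa, n_samples, fill, seed) {
  set.seed(seed)
  pa <- matrix(0L, n_taxa, n_samples)
  pa[sample(length(pa), round(fill * length(pa)))] <- 1L
  pa
}

# brute-force C-score: explicit loop over taxon pairs
c_score_oracle <- function(pa) {
  nr <- nrow(pa)
  tot <- 0
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    s <- sum(pa[i, ] == 1 & pa[j, ] == 1)
    tot <- tot + (sum(pa[i, ]) - s) * (sum(pa[j, ]) - s)
  }
  tot / (nr * (nr - 1) / 2)
}

# margin-preserving greedy C-score optimization; builds checkerboard-poor
# (aggregated, minimize = TRUE) or checkerboard-rich (segregated) matrices
optimize_c_score <- function(pa, minimize = TRUE, steps = 3000, seed = 1) {
  set.seed(seed)
  cur <- c_score(pa)
  nr <- nrow(pa); nc <- ncol(pa)
  for (t in seq_len(steps)) {
    i <- sample(nr, 2); j <- sample(nc, 2)
    sub <- pa[i, j]
    if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] &&
        sub[1, 1] != sub[1, 2]) {
      cand <- pa; cand[i, j] <- sub[, 2:1]
      cnew <- c_score(cand)
      if ((minimize && cnew <= cur) || (!minimize && cnew >= cur)) {
        pa <- cand; cur <- cnew
      }
    }
  }
  pa
}

# Kruskal stress-1 of a given configuration against a dissimilarity matrix,
# monotone regression on the pooled dissimilarity order
stress1_oracle <- function(d, conf) {
  dv <- as.vector(as.dist(d))
  dc <- as.vector(dist(conf))
  ord <- order(dv)
  fit <- stats::isoreg(seq_along(ord), dc[ord])
  dhat <- numeric(length(dc))
  dhat[ord] <- fit$yf
  sqrt(sum((dc - dhat)^2) / sum(dc^2))
}

# normalized betweenness by explicit enumeration of all shortest paths
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    # BFS distances from s
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] == 1)
      for (w in nb) if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1; queue <- c(queue, w)
      }
    }
    for (t in (s + 1):n) {
      if (is.infinite(dist[t])) next
      # enumerate all shortest s-t paths by walking dist-decreasing edges
      paths <- list(t)
      repeat {
        done <- all(vapply(paths, function(p) p[1] == s, TRUE))
        if (done) break
        paths <- unlist(lapply(paths, function(p) {
          v <- p[1]
          if (v == s) return(list(p))
          preds <- which(adj[v, ] == 1 & dist == dist[v] - 1)
          lapply(preds, function(u) c(u, p))
        }), recursive = FALSE)
      }
      npath <- length(paths)
      for (p in paths) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / npath
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# wrap an igraph into the package's network container
as_co_network <- function(g) {
  structure(list(graph = g, thresholds = list(r_min = 0, p_max = 1,
                                              positive_only = TRUE,
                                              bh_adjust = FALSE),
                 modules = NULL, Q = NULL), class = "co_network")
}
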