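# Independent oracles: deliberately naive re-implementations used only to
# check the package's faster/structured code paths.  They must never share
# code with R/.

# brute-force pairwise Euclidean distances by double loop
oracle_pairwise_dist <- function(coords) {
  n <- nrow(coords)
  out <- matrix(0, n, n, dimnames = list(rownames(coords), rownames(coords)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  out
}

# naive UPGMA: at every step recompute every cross-cluster average from the
# original matrix (no Lance-Williams updates)
oracle_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d - 1e-15) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_d)
    partitions <- c(partitions, list(lapply(clusters, identity)))
  }
  list(heights = heights, partitions = partitions)
}

# Adjusted Rand Index from the contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# all nonnegative integer k-vectors summing to n
oracle_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (v in 0:n) {
    sub <- oracle_compositions(n - v, k - 1L)
    out <- rbind(out, cbind(v, sub))
  }
  unname(out)
}

# brute-force set of all tables with the given margins: cartesian product of
# per-row compositions, filtered on column sums
oracle_margin_tables <- function(row_m, col_m) {
  per_row <- lapply(row_m, oracle_compositions, k = length(col_m))
  idx <- expand.grid(lapply(per_row, function(m) seq_len(nrow(m))))
  out <- list()
  for (r in seq_len(nrow(idx))) {
    tab <- do.call(rbind, lapply(seq_along(per_row), function(i) {
      per_row[[i]][idx[r, i], ]
    }))
    if (all(colSums(tab) == col_m)) out[[length(out) + 1L]] <- tab
  }
  out
}

# exact two-sided Fisher p for a 2x2 table from the univariate hypergeometric
# closed form (probability-ordering convention)
oracle_fisher_2x2 <- function(tab, tie_tol = 1e-7) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - m2):min(m1, c1)
  probs <- dhyper(ks, m1, m2, c1)
  p_obs <- dhyper(a, m1, m2, c1)
  sum(probs[probs <= p_obs * (1 + tie_tol)])
}

oracle_table_prob <- function(tab) {
  exp(sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
        lfactorial(sum(tab)) - sum(lfactorial(tab)))
}

# sup |ECDF(p) - p| by brute force over all step points
oracle_ks_uniform <- function(p) {
  ps <- sort(p)
  n <- length(ps)
  best <- 0
  for (i in seq_len(n)) {
    best <- max(best, abs(i / n - ps[i]), abs((i - 1) / n - ps[i]))
  }
  best
}

# mean silhouette width computed straight from the definition
oracle_mean_silhouette <- function(labels, D) {
  s <- numeric(length(labels))
  for (i in seq_along(labels)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, which(labels == cl)]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# random metric matrix: distances between random points (hence a true metric)
random_metric_matrix <- function(n, seed = NULL, dim = 3) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(runif(n * dim, 0, 10), n)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(LETTERS[1:n], LETTERS[1:n])
  m
}
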