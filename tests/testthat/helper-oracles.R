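# Independent brute-force oracles used to pin expected values.
# These deliberately avoid the code paths (and where possible the library
# calls) they are checking.

# BH step-up, written directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- ranked * n / seq_len(n)
  # step-up: running minimum from the largest rank down
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Pearson correlation from explicit sums (no stats::cor).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Average ranks by hand (no rank()'s default fast path assumptions).
oracle_ranks <- function(v) {
  sapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2)
}

# Spearman correlation = Pearson of average ranks.
oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_ranks(x), oracle_ranks(y))
}

# corCor by direct enumeration of all pairwise Spearman correlations.
oracle_corcor <- function(x1, x2) {
  n <- nrow(x1)
  s <- function(m) {
    out <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      out[i, j] <- oracle_spearman(m[i, ], m[j, ])
    out
  }
  s1 <- s(x1); s2 <- s(x2)
  sapply(seq_len(n), function(g)
    oracle_pearson(s1[-g, g], s2[-g, g]))
}

# Complete-linkage agglomeration on a distance matrix, step by step.
# Returns the merge heights in order.
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq.int(i + 1L, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Small helper building a tiny validated expression matrix.
make_expr <- function(values, species = "A", tissues = NULL) {
  if (is.null(tissues)) tissues <- rep("t1", ncol(values))
  expression_matrix(values, species, tissues)
}
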