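# Independent brute-force oracles used to check the package's computations.
# These deliberately avoid the code paths (and library calls) they verify.

# O(n^3) naive UPGMA: track clusters as index sets, recompute all cross-pair
# average distances from the original matrix at every step. Returns the merge
# heights and the implied cophenetic distance matrix.
naive_upgma <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  C <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1L]]]
    b <- clusters[[best[2L]]]
    for (x in a) for (y in b) C[x, y] <- C[y, x] <- best_d
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(a, b)
    clusters[[best[2L]]] <- NULL
  }
  list(heights = heights, cophenetic = C)
}

# Pearson correlation by the direct double-loop sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# Upper-tail hypergeometric P(X >= k) by explicit enumeration over the
# support, using binomial coefficients only.
hyper_tail_oracle <- function(k, K, M, n) {
  js <- max(0, n + K - M):min(n, K)
  probs <- choose(K, js) * choose(M - K, n - js) / choose(M, n)
  sum(probs[js >= k])
}

# Welch two-sample t by the textbook formula.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# One-way fixed-effects ANOVA by explicit sums of squares.
anova_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Pearson chi-square statistic by the direct sum(O-E)^2/E loop.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# AUC as the Mann-Whitney U statistic via mean ranks (ties averaged).
auc_rank_oracle <- function(scores, is_pos) {
  r <- rank(scores)
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Subtype-level pathway deviation score by explicit double loops.
deviation_oracle <- function(mat, labels, genes, subtype) {
  total <- 0
  for (g in genes) {
    xbar <- mean(mat[g, labels == subtype])
    ybar <- mean(mat[g, ])
    total <- total + (xbar - ybar)^2
  }
  total / length(genes)
}

# Per-sample deviation feature by explicit loops.
sample_feature_oracle <- function(mat, genes, ref) {
  out <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    acc <- 0
    for (g in genes) acc <- acc + (mat[g, s] - ref[[g]])^2
    out[s] <- acc / length(genes)
  }
  names(out) <- colnames(mat)
  out
}

# Random symmetric distance matrix with zero diagonal (a valid dissimilarity,
# continuous so ties have probability zero).
random_distance <- function(n, seed) {
  set.seed(seed)
  p <- matrix(runif(n * 3), n)
  D <- as.matrix(dist(p))
  dimnames(D) <- list(sprintf("S%02d", 1:n), sprintf("S%02d", 1:n))
  D
}

small_cohort_config <- function(...) {
  args <- list(n_genes = 400L, n_candidate_genes = 120L, n_samples = 60L,
               k_subtypes = 3L, subtype_proportions = rep(1 / 3, 3),
               effect_size = 5, frac_informative = 1, noise_sd = 1,
               n_pathways = 30L, pathway_size_range = c(10L, 40L),
               clinical_shift = 8, seed = 42L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}
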