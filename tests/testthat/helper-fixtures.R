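# Shared fixtures, all built in code.

tiny_config <- function(seed = 11, ...) {
  sim_config(n_strains = 16,
             strains_per_haplotype = stats::setNames(rep(2L, 8), LETTERS[1:8]),
             n_markers = 6, n_patterns = 3, n_genes = 30,
             n_gene_sets = 4, gene_set_size = 8, n_external_genes = 10,
             seed = seed, ...)
}

# hclust tree from an explicit distance matrix on labelled items
tree_from_dist <- function(m, labels, linkage = "average") {
  dimnames(m) <- list(labels, labels)
  hcluster(m, distance = "precomputed", linkage = linkage)
}

# independent OLS oracle: normal equations solved with solve()
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  bt <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bt
  df <- length(y) - 2
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tt <- bt[2] / se
  list(beta = bt[2], se = se, t = tt, p = 2 * pt(-abs(tt), df))
}

# brute-force GSEA running sum: walk every position of the ranking
gsea_walk_oracle <- function(scores, genes, set, weight = 1) {
  N <- length(genes)
  inset <- genes %in% set
  w <- abs(scores)^weight
  W <- sum(w[inset])
  dev <- numeric(N)
  run <- 0
  for (i in seq_len(N)) {
    run <- run + if (inset[i]) w[i] / W else -1 / (N - sum(inset))
    dev[i] <- run
  }
  # extremum of the running sum, including the start at 0; on an exact
  # magnitude tie the positive extremum is reported
  cand <- c(0, dev)
  if (max(cand) >= -min(cand) - 1e-12) max(cand) else min(cand)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group assignments
wilcox_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combs <- utils::combn(n, na)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- na * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}
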