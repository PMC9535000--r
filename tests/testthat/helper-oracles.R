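# Independent oracles used to check the package's implementations.
# These deliberately share no code with the package internals.

# descendant tips of each edge by direct recursion over the edge list
oracle_edge_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_below))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) tips_below(tree$edge[e, 2]))
}

# brute-force unweighted UniFrac: per-branch membership enumeration
oracle_unifrac <- function(tree, present_a, present_b) {
  tips <- oracle_edge_tips(tree)
  len <- tree$edge.length
  in_a <- vapply(tips, function(tt) any(tt %in% present_a), TRUE)
  in_b <- vapply(tips, function(tt) any(tt %in% present_b), TRUE)
  union_len <- sum(len[in_a | in_b])
  if (union_len == 0) return(0)
  sum(len[xor(in_a, in_b)]) / union_len
}

# brute-force Kendall tau-b by O(n^2) pair counting with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(split(seq_along(x), x), function(g)
    length(g) * (length(g) - 1) / 2))
  ty <- sum(sapply(split(seq_along(y), y), function(g)
    length(g) * (length(g) - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# exhaustive two-group PERMANOVA p-value over all distinct label splits
oracle_permanova_exhaustive <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- length(groups)
  f_of <- function(g) {
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      sub <- d2[idx, idx, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    a <- length(unique(g))
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  lev <- unique(groups)
  k <- sum(groups == lev[1])
  splits <- combn(n, k)
  fs <- apply(splits, 2, function(idx) {
    g <- rep(lev[2], n); g[idx] <- lev[1]
    f_of(g)
  })
  mean(fs >= f_obs - 1e-12)
}

# small random counts table
random_counts_table <- function(ntaxa = 6, nsamp = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(ntaxa * nsamp, lambda = 20) + 1, ntaxa, nsamp,
              dimnames = list(paste0("t", seq_len(ntaxa)),
                              paste0("s", seq_len(nsamp))))
  abundance_table(m)
}
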