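# Beta diversity: unweighted UniFrac, PCoA, PERMANOVA, Mantel tests and the
# ordination-vs-environment screen.

# Logical matrix (edges x tips): does branch e lead to tip t?
edge_tip_incidence <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  desc <- matrix(FALSE, nnode, ntip)   # per tree node, descendant tips
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    desc[par, ] <- desc[par, ] | desc[chi, ]
  }
  inc <- desc[tree$edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  list(incidence = inc, lengths = tree$edge.length)
}

#' Unweighted UniFrac distance matrix
#'
#' Presence/absence phylogenetic dissimilarity: for a pair of samples, the
#' branch length leading exclusively to taxa observed in one of the two,
#' divided by the branch length leading to taxa observed in either
#' (normalisation over observed lineages, the classical formulation).
#' Presence means relative abundance strictly greater than zero.
#'
#' @param t abundance_table; taxa must all be tree leaves unless
#'   \code{prune_missing}.
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @param prune_missing drop table taxa absent from the tree (with a
#'   warning) instead of erroring.
#' @return \code{dist}-convertible symmetric matrix in [0, 1] with zero
#'   diagonal.
#' @export
unweighted_unifrac <- function(t, tree, prune_missing = FALSE) {
  tree <- validate_tree(tree)
  missing <- setdiff(taxa_ids(t), tree$tip.label)
  vals <- t$values
  if (length(missing)) {
    if (!prune_missing)
      stop_pelnet("taxa missing from tree: ",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ...")
    warning(length(missing), " taxa absent from the tree were pruned")
    vals <- vals[setdiff(rownames(vals), missing), , drop = FALSE]
  }
  et <- edge_tip_incidence(tree)
  pres <- vals > 0                                  # taxa x samples
  # branch x sample: does the branch lead to any taxon present in the sample
  lead <- (et$incidence[, rownames(vals), drop = FALSE] %*% pres) > 0
  n <- ncol(vals)
  d <- matrix(0, n, n, dimnames = list(colnames(vals), colnames(vals)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- lead[, i]; b <- lead[, j]
    union_len <- sum(et$lengths[a | b])
    d[i, j] <- d[j, i] <-
      if (union_len == 0) 0 else sum(et$lengths[xor(a, b)]) / union_len
  }
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of \eqn{-d^2/2} followed by eigendecomposition.
#' Only axes with positive eigenvalues are returned; variance fractions are
#' taken over the positive eigenvalues and negative eigenvalues (possible
#' for semimetric inputs) are reported and flagged.  Axis signs follow a
#' deterministic convention: the coordinate of largest magnitude on each
#' axis is positive.
#'
#' @param d symmetric distance matrix with sample names.
#' @return an \code{ordination}: list with \code{coordinates} (samples x
#'   axes, MDS1..), \code{eigenvalues}, \code{variance_fraction},
#'   \code{negative_eigenvalues}.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  assert_that(isSymmetric(unname(d), tol = 1e-12), "distance matrix not symmetric")
  assert_that(any(d > 0), "degenerate all-zero distance matrix")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(ev$values)) * 1e-9
  pos <- ev$values > tol
  neg <- ev$values[ev$values < -tol]
  lam <- ev$values[pos]
  coords <- ev$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), sum(pos))
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(rownames(d), paste0("MDS", seq_len(ncol(coords))))
  structure(list(coordinates = coords, eigenvalues = lam,
                 variance_fraction = lam / sum(lam),
                 negative_eigenvalues = neg),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d positive axes (MDS1 %.1f%%, MDS2 %.1f%%)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$variance_fraction[1],
              if (length(x$variance_fraction) > 1)
                100 * x$variance_fraction[2] else NA))
  if (length(x$negative_eigenvalues))
    cat(sprintf("note: %d negative eigenvalues excluded (min %.3g)\n",
                length(x$negative_eigenvalues), min(x$negative_eigenvalues)))
  invisible(x)
}

permanova_f <- function(d2, group) {
  n <- length(group)
  a <- length(unique(group))
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(group)) {
    idx <- which(group == g)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx, drop = FALSE])]) /
      length(idx)
  }
  ssa <- sst - ssw
  list(F = (ssa / (a - 1)) / (ssw / (n - a)), R2 = ssa / sst)
}

#' PERMANOVA: one-factor permutation test on a distance matrix
#'
#' Anderson's direct-from-distances pseudo-F with free permutation of the
#' sample labels; \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each n >= 2).
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list: pseudo_F, R2, p_value, n_perm, seed.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  assert_that(length(groups) == nrow(d), "one group label per sample")
  tab <- table(groups)
  assert_that(length(tab) >= 2, "need at least 2 groups")
  assert_that(all(tab >= 2), "every group needs at least 2 samples")
  d2 <- d^2
  obs <- permanova_f(d2, groups)
  set.seed(derive_seed(seed, 202L))
  ge <- 0L
  for (b in seq_len(n_perm)) {
    fp <- permanova_f(d2, sample(groups))$F
    if (fp >= obs$F - 1e-12) ge <- ge + 1L
  }
  list(pseudo_F = obs$F, R2 = obs$R2,
       p_value = (1 + ge) / (1 + n_perm), n_perm = n_perm, seed = seed)
}

#' Mantel test between two distance matrices
#'
#' Correlation of the vectorised upper triangles; significance by joint
#' row/column permutation of the second matrix.
#'
#' @param d1,d2 symmetric distance matrices over the same samples (same
#'   order).
#' @param method \code{"spearman"} (default, as used for the
#'   community-vs-biochemistry tests) or \code{"pearson"}.
#' @param n_perm permutations (default 9999).
#' @param seed RNG seed.
#' @return list: statistic r, p_value, n_perm, method, seed.
#' @export
mantel <- function(d1, d2, method = c("spearman", "pearson"),
                   n_perm = 9999, seed = 1L) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  assert_that(nrow(d1) >= 4, "need at least 4 samples")
  assert_that(all(dim(d1) == dim(d2)), "matrices must be the same size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)))
    assert_that(identical(rownames(d1), rownames(d2)),
                "sample ids of the two matrices differ")
  v1 <- upper_tri_vec(d1)
  r_obs <- cor(v1, upper_tri_vec(d2), method = method)
  set.seed(derive_seed(seed, 303L))
  n <- nrow(d1)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample(n)
    rp <- cor(v1, upper_tri_vec(d2[idx, idx]), method = method)
    if (rp >= r_obs - 1e-12) ge <- ge + 1L
  }
  list(statistic = r_obs, p_value = (1 + ge) / (1 + n_perm),
       n_perm = n_perm, method = method, seed = seed)
}

#' Screen ordination axes against environmental covariates
#'
#' For every (axis, covariate) pair: correlation coefficient with its
#' p-value (Pearson and Spearman are both reported) and the linear
#' regression R-squared, flagged when it exceeds the biological-relevance
#' threshold.
#'
#' @param ord an \code{\link{pcoa}} ordination.
#' @param covariates data.frame of numeric covariates aligned to the
#'   ordination's samples (rownames or a sample_id column).
#' @param r2_threshold relevance threshold on R-squared (default 0.25).
#' @param n_axes number of leading axes to screen (default 2).
#' @return data.frame: axis, covariate, pearson_r, pearson_p, spearman_r,
#'   spearman_p, r_squared, relevant flag; constant covariates are flagged
#'   \code{undefined}.
#' @export
axis_environment_screen <- function(ord, covariates, r2_threshold = 0.25,
                                    n_axes = 2) {
  coords <- ord$coordinates
  if ("sample_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  if (!is.null(rownames(covariates)))
    covariates <- covariates[rownames(coords), , drop = FALSE]
  assert_that(nrow(covariates) == nrow(coords),
              "covariates must align with ordination samples")
  n_axes <- min(n_axes, ncol(coords))
  rows <- list()
  for (ax in seq_len(n_axes)) for (cv in names(covariates)) {
    x <- coords[, ax]; y <- covariates[[cv]]
    ok <- complete.cases(x, y)
    if (sd(y[ok]) == 0 || sum(ok) < 3) {
      rows[[length(rows) + 1L]] <- data.frame(
        axis = colnames(coords)[ax], covariate = cv, pearson_r = NA,
        pearson_p = NA, spearman_r = NA, spearman_p = NA, r_squared = NA,
        relevant = NA, undefined = TRUE)
      next
    }
    pe <- cor.test(x[ok], y[ok], method = "pearson")
    sp <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    r2 <- summary(lm(y[ok] ~ x[ok]))$r.squared
    rows[[length(rows) + 1L]] <- data.frame(
      axis = colnames(coords)[ax], covariate = cv,
      pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
      spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
      r_squared = r2, relevant = r2 > r2_threshold, undefined = FALSE)
  }
  do.call(rbind, rows)
}
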