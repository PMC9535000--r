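make_table <- function(m) abundance_table(m)

test_that("unweighted UniFrac hand-checked cases", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix(c(1, 1, 0, 0,
                1, 0, 1, 0,
                1, 1, 0, 0), 4, 3,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2", "s3")))
  d <- unweighted_unifrac(make_table(m), tree)
  expect_equal(d["s1", "s3"], 0)            # identical presence sets
  # {A,B} vs {A,C}: unique branches B, C, (CD) = 3 of the 5 observed
  expect_equal(d["s1", "s2"], 3 / 5)
  # disjoint singleton communities share no branch
  star <- ape::read.tree(text = "(A:1,B:1);")
  m2 <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("A", "B"), c("x", "y")))
  d2 <- unweighted_unifrac(make_table(m2), star)
  expect_equal(d2["x", "y"], 1)
  # strict mode errors on missing taxa, pruning mode warns
  m3 <- rbind(m, E = c(1, 1, 1))
  expect_error(unweighted_unifrac(make_table(m3), tree), "missing from tree")
  expect_warning(d3 <- unweighted_unifrac(make_table(m3), tree,
                                          prune_missing = TRUE), "pruned")
  expect_equal(d3, d)
})

test_that("UniFrac agrees with per-branch enumeration on random trees", {
  set.seed(77)
  for (rep in 1:40) {
    tree <- ape::rtree(16)
    pres <- matrix(rbinom(16 * 2, 1, 0.5), 16, 2,
                   dimnames = list(tree$tip.label, c("u", "v")))
    pres[sample(16, 1), ] <- 1   # avoid empty communities
    d <- unweighted_unifrac(make_table(pres + 0), tree)
    expected <- oracle_unifrac(tree, rownames(pres)[pres[, 1] > 0],
                               rownames(pres)[pres[, 2] > 0])
    expect_equal(d["u", "v"], expected, tolerance = 1e-12)
  }
})

test_that("UniFrac output is a bounded semimetric", {
  set.seed(31)
  tree <- ape::rtree(12)
  m <- matrix(rbinom(12 * 6, 1, 0.6) + 0, 12, 6,
              dimnames = list(tree$tip.label, paste0("s", 1:6)))
  m[1, ] <- 1
  d <- unweighted_unifrac(make_table(m), tree)
  expect_equal(diag(d), setNames(rep(0, 6), colnames(m)))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA recovers planar configurations up to rigid motion", {
  set.seed(13)
  x <- cbind(runif(5), runif(5))
  rownames(x) <- paste0("s", 1:5)
  d <- as.matrix(dist(x))
  ord <- pcoa(d)
  expect_equal(ncol(ord$coordinates), 2)
  # centered coordinates
  expect_true(all(abs(colMeans(ord$coordinates)) < 1e-9))
  # inter-point distances reproduced
  expect_equal(as.matrix(dist(ord$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # three collinear points: a single positive axis carries all variance
  xc <- cbind(c(0, 1, 2), c(0, 1, 2))
  dc <- as.matrix(dist(xc)); dimnames(dc) <- list(letters[1:3], letters[1:3])
  oc <- pcoa(dc)
  expect_equal(ncol(oc$coordinates), 1)
  expect_equal(oc$variance_fraction, 1)
})

test_that("PCoA reports and excludes negative eigenvalues", {
  d <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 2.8,
                1, 1, 2.8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  ord <- pcoa(d)   # violates Euclidean embeddability
  expect_gt(length(ord$negative_eigenvalues), 0)
  expect_true(all(ord$eigenvalues > 0))
})

test_that("PERMANOVA p floors at 1/(n_perm+1) for separated clusters", {
  set.seed(55)
  a <- matrix(rnorm(20, 0, 0.05), 10, 2)
  b <- matrix(rnorm(20, 5, 0.05), 10, 2)
  d <- as.matrix(dist(rbind(a, b)))
  dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  res <- permanova(d, rep(c("g1", "g2"), each = 10), n_perm = 999, seed = 2)
  expect_equal(res$p_value, 0.001)
  expect_gt(res$R2, 0.9)
})

test_that("PERMANOVA permutation p matches exhaustive enumeration at n = 6", {
  set.seed(8)
  x <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  p_exh <- oracle_permanova_exhaustive(d, g)
  res <- permanova(d, g, n_perm = 9999, seed = 4)
  expect_lt(abs(res$p_value - p_exh), 0.02)
})

test_that("PERMANOVA power rises with group separation", {
  set.seed(3)
  pow <- vapply(c(0, 1, 3), function(delta) {
    mean(replicate(30, {
      x <- rbind(matrix(rnorm(12), 6, 2),
                 matrix(rnorm(12, delta), 6, 2))
      d <- as.matrix(dist(x))
      dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
      permanova(d, rep(1:2, each = 6), n_perm = 99,
                seed = sample.int(1e6, 1))$p_value <= 0.05
    }))
  }, 0)
  expect_true(all(diff(pow) >= 0))
  expect_gt(pow[3], 0.9)
})

test_that("Mantel statistic equals direct correlation of triangles", {
  set.seed(17)
  x <- matrix(rnorm(20), 10, 2)
  d1 <- as.matrix(dist(x))
  expect_equal(mantel(d1, d1, n_perm = 99, seed = 1)$statistic, 1)
  # monotone transform leaves the Spearman statistic at 1
  expect_equal(mantel(d1, d1^2, method = "spearman", n_perm = 99,
                      seed = 1)$statistic, 1)
  d2 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  r_direct <- cor(d1[upper.tri(d1)], d2[upper.tri(d2)])
  expect_equal(mantel(d1, d2, method = "pearson", n_perm = 99,
                      seed = 1)$statistic, r_direct)
})

test_that("Mantel p is roughly uniform under independence", {
  set.seed(29)
  ps <- replicate(100, {
    d1 <- as.matrix(dist(rnorm(12)))
    d2 <- as.matrix(dist(rnorm(12)))
    mantel(d1, d2, method = "pearson", n_perm = 199,
           seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps <= 0.05), 0.12)
})

test_that("axis screen flags copies and tolerates constants", {
  set.seed(41)
  x <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(x)); dimnames(d) <- list(paste0("s", 1:20),
                                               paste0("s", 1:20))
  ord <- pcoa(d)
  cov <- data.frame(copy = ord$coordinates[, 1], flat = rep(1, 20),
                    row.names = rownames(ord$coordinates))
  scr <- suppressWarnings(axis_environment_screen(ord, cov))  # perfect fit
  copy1 <- scr[scr$axis == "MDS1" & scr$covariate == "copy", ]
  expect_equal(copy1$pearson_r, 1, tolerance = 1e-9)
  expect_equal(copy1$r_squared, 1, tolerance = 1e-9)
  expect_true(copy1$relevant)
  expect_true(all(scr$undefined[scr$covariate == "flat"]))
})

test_that("distances and tests agree with the reference implementations", {
  skip_if_not_installed("vegan")
  skip_if_not_installed("picante")
  set.seed(3)
  tree <- ape::rcoal(10)
  m <- matrix(rbinom(60, 1, 0.6) + 0, 10, 6,
              dimnames = list(tree$tip.label, paste0("s", 1:6)))
  m[1, ] <- 1
  d_mine <- unweighted_unifrac(abundance_table(m), tree)
  d_ref <- as.matrix(picante::unifrac(t(m), tree))
  expect_equal(d_mine, d_ref[rownames(d_mine), colnames(d_mine)],
               tolerance = 1e-12, ignore_attr = TRUE)

  x <- matrix(rnorm(24), 12, 2)
  dd <- dist(x)
  g <- rep(c("a", "b"), each = 6)
  ref <- vegan::adonis2(dd ~ g, permutations = 99)
  dm <- as.matrix(dd); dimnames(dm) <- list(paste0("s", 1:12),
                                            paste0("s", 1:12))
  mine <- permanova(dm, g, n_perm = 99, seed = 1)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-9)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-9)

  d2 <- dist(matrix(rnorm(24), 12, 2))
  ref_m <- vegan::mantel(dd, d2, method = "pearson", permutations = 99)
  mine_m <- pelnet::mantel(as.matrix(dd), as.matrix(d2), method = "pearson",
                           n_perm = 99, seed = 1)
  expect_equal(mine_m$statistic, unname(ref_m$statistic), tolerance = 1e-12)
})
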