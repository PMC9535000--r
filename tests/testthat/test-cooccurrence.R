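test_that("CLR transform and edge sets ignore per-sample depth rescaling", {
  t0 <- random_counts_table(8, 12, seed = 41)
  scaled <- t0
  scaled$values <- sweep(t0$values, 2L, c(2, 5, 1, 3, 10, 7, 2, 4, 6, 1, 9, 3),
                         "*")
  expect_equal(clr_transform(t0), clr_transform(scaled), tolerance = 1e-12)
  n1 <- infer_network(t0, n_perm = 200, seed = 5)
  n2 <- infer_network(scaled, n_perm = 200, seed = 5)
  expect_identical(igraph::as_data_frame(n1), igraph::as_data_frame(n2))
})

test_that("planted pair is recovered with its sign", {
  set.seed(61)
  n <- 60
  z <- rnorm(n)
  m <- rbind(a = exp(z + rnorm(n, 0, 0.3)),
             b = exp(0.9 * z + rnorm(n, 0, 0.3)),
             c = exp(rnorm(n)), d = exp(rnorm(n)), e = exp(rnorm(n)),
             f = exp(rnorm(n)))
  colnames(m) <- paste0("s", 1:n)
  net <- infer_network(abundance_table(m), n_perm = 1000, seed = 3)
  ed <- igraph::as_data_frame(net)
  hit <- ed[(ed$from == "a" & ed$to == "b") | (ed$from == "b" & ed$to == "a"), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$sign, "positive")
})

test_that("order-1 pruning removes the indirect edge of a chain", {
  # A -> B -> C: with a strong chain the A-C association vanishes given B
  removed <- 0; reps <- 10
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    n <- 80
    a <- rnorm(n); b <- 0.9 * a + rnorm(n, 0, sqrt(1 - 0.81))
    cc <- 0.9 * b + rnorm(n, 0, sqrt(1 - 0.81))
    m <- rbind(A = exp(a), B = exp(b), C = exp(cc),
               D = exp(rnorm(n)), E = exp(rnorm(n)))
    colnames(m) <- paste0("s", 1:n)
    net <- infer_network(abundance_table(m), n_perm = 500, seed = r,
                         partial_threshold = 0.25)
    ed <- igraph::as_data_frame(net)
    has_ab <- any((ed$from == "A" & ed$to == "B") | (ed$from == "B" & ed$to == "A"))
    has_ac <- any((ed$from == "A" & ed$to == "C") | (ed$from == "C" & ed$to == "A"))
    if (has_ab && !has_ac) removed <- removed + 1
  }
  expect_gt(removed / reps, 0.5)
})

test_that("false-edge rate on independent taxa is controlled", {
  set.seed(71)
  edges <- replicate(20, {
    m <- matrix(exp(rnorm(8 * 40)), 8, 40,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:40)))
    igraph::ecount(infer_network(abundance_table(m), n_perm = 500,
                                 seed = sample.int(1e6, 1)))
  })
  # 28 pairs tested per replicate; essentially none should pass FDR control
  expect_lte(mean(edges) / 28, 0.05)
})

test_that("hub detection on canonical graphs", {
  star_nodes <- data.frame(taxon = c("hub", paste0("leaf", 1:5)))
  star_edges <- data.frame(from = "hub", to = paste0("leaf", 1:5), weight = 1)
  star <- association_network(star_nodes, star_edges)
  h <- find_hubs(star)
  expect_equal(h$hubs, "hub")
  expect_false(h$degenerate)
  ring_nodes <- data.frame(taxon = paste0("n", 1:6))
  ring_edges <- data.frame(from = paste0("n", 1:6),
                           to = paste0("n", c(2:6, 1)), weight = 1)
  ring <- find_hubs(association_network(ring_nodes, ring_edges))
  expect_equal(length(ring$hubs), 1)   # symmetric: tie-broken fallback
  expect_true(ring$degenerate)
  edgeless <- association_network(ring_nodes, ring_edges[0, ])
  expect_warning(h0 <- find_hubs(edgeless), "edgeless")
  expect_equal(h0$hubs, character())
})

test_that("modularity matches the disconnected-cliques closed form", {
  clique_graph <- function(k, size = 5) {
    nodes <- data.frame(taxon = paste0("n", seq_len(k * size)))
    ed <- do.call(rbind, lapply(seq_len(k), function(g) {
      ids <- paste0("n", (g - 1) * size + seq_len(size))
      t(combn(ids, 2))
    }))
    association_network(nodes, data.frame(from = ed[, 1], to = ed[, 2],
                                          weight = 1))
  }
  for (k in 2:4) {
    res <- modularity_and_modules(clique_graph(k), seed = 1)
    expect_equal(res$Q, 1 - 1 / k, tolerance = 1e-12)
    expect_equal(res$n_modules, k)
  }
  single <- modularity_and_modules(clique_graph(1), seed = 1)
  expect_equal(single$Q, 0)
  expect_equal(single$n_modules, 1)
  # determinism under a fixed seed
  g <- clique_graph(3)
  expect_identical(modularity_and_modules(g, seed = 9)$membership,
                   modularity_and_modules(g, seed = 9)$membership)
  # edgeless graph: one module per node, Q reported as 0
  nodes <- data.frame(taxon = paste0("n", 1:4))
  e0 <- modularity_and_modules(
    association_network(nodes, data.frame(from = character(),
                                          to = character(),
                                          weight = numeric())), seed = 1)
  expect_true(e0$edgeless)
  expect_equal(e0$n_modules, 4)
})

test_that("total connectivity is edges per node", {
  nodes <- data.frame(taxon = paste0("n", 1:6))
  # a tree on n nodes has (n-1)/n edges per node
  tree_edges <- data.frame(from = paste0("n", 1:5), to = paste0("n", 2:6),
                           weight = 1)
  expect_equal(total_connectivity(association_network(nodes, tree_edges)),
               5 / 6)
})

test_that("cohesion contracts: null centering and anti-correlated pairs", {
  # globally shuffled taxa: corrected connectedness and cohesion center on 0
  # (enough taxa that compositional closure contributes little)
  set.seed(83)
  m <- matrix(exp(rnorm(30 * 40)), 30, 40,
              dimnames = list(paste0("t", 1:30), paste0("s", 1:40)))
  res <- cohesion(abundance_table(m), n_null = 100, seed = 2)
  expect_lt(abs(mean(res$sample_cohesion$positive)), 0.05)
  expect_lt(abs(mean(res$sample_cohesion$negative)), 0.05)
  # two perfectly anti-correlated taxa and no positive structure
  x <- seq(0.1, 0.9, length.out = 10)
  m2 <- rbind(up = x, down = 1 - x)
  colnames(m2) <- paste0("s", 1:10)
  res2 <- cohesion(abundance_table(m2, is_relative = TRUE), n_null = 50,
                   seed = 3)
  expect_true(res2$np_infinite)
  # determinism
  expect_equal(cohesion(abundance_table(m), n_null = 50, seed = 7)$np_ratio,
               cohesion(abundance_table(m), n_null = 50, seed = 7)$np_ratio)
})

test_that("stronger negative coupling raises the N:P ratio", {
  set.seed(97)
  wins <- 0; reps <- 20
  for (r in seq_len(reps)) {
    n <- 40
    z <- rnorm(n)
    # negative-coupled community: two blocks move in opposition
    neg <- rbind(a = exp(z), b = exp(-z + rnorm(n, 0, 0.4)),
                 c = exp(-z + rnorm(n, 0, 0.4)), d = exp(rnorm(n)),
                 e = exp(rnorm(n)))
    # positive-only community
    pos <- rbind(a = exp(z), b = exp(z + rnorm(n, 0, 0.4)),
                 c = exp(z + rnorm(n, 0, 0.4)), d = exp(rnorm(n)),
                 e = exp(rnorm(n)))
    colnames(neg) <- colnames(pos) <- paste0("s", 1:n)
    rn <- cohesion(abundance_table(neg), n_null = 60, seed = r)
    rp <- cohesion(abundance_table(pos), n_null = 60, seed = r)
    npn <- if (rn$np_infinite) Inf else rn$np_ratio
    npp <- if (rp$np_infinite) 0 else rp$np_ratio
    if (npn > npp) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.9)
})

test_that("network summary assembles all reported quantities", {
  set.seed(19)
  n <- 30
  z <- rnorm(n)
  m <- rbind(a = exp(z), b = exp(0.9 * z + rnorm(n, 0, 0.3)),
             c = exp(0.9 * z + rnorm(n, 0, 0.3)),
             d = exp(rnorm(n)), e = exp(rnorm(n)), f = exp(rnorm(n)))
  colnames(m) <- paste0("s", 1:n)
  s <- network_summary(abundance_table(m), sector = "demo", seed = 11,
                       n_perm = 300, n_null = 60)
  expect_equal(s$sector, "demo")
  expect_true(all(c("np_cohesion_ratio", "modules", "modularity",
                    "total_connectivity", "hubs", "n_nodes", "n_edges")
                  %in% names(s)))
  expect_equal(s$n_nodes, 6)
  expect_gte(s$modularity, -0.5)
  expect_lte(s$modularity, 1)
})
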