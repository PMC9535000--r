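test_that("order-level collapse sums abundances and conserves totals", {
  m <- matrix(c(0.1, 0.2, 0.7, 0.3, 0.3, 0.4), 3, 2,
              dimnames = list(c("asv1", "asv2", "asv3"), c("s1", "s2")))
  tax <- data.frame(taxon = c("asv1", "asv2", "asv3"),
                    order = c("Vibrionales", "Vibrionales", NA),
                    parent = c("Gammaproteobacteria", "Gammaproteobacteria",
                               "Bacteroidia"))
  out <- collapse_to_level(abundance_table(m), tax)
  expect_equal(out$values["Vibrionales", "s1"], 0.3)
  expect_equal(rownames(out$values),
               sort(c("Vibrionales", "Unassigned-Bacteroidia")))
  expect_equal(colSums(out$values), colSums(m))
  # identity on an already-collapsed table
  tax2 <- data.frame(taxon = c("a", "b"), order = c("a", "b"))
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(collapse_to_level(abundance_table(m2), tax2)$values, m2 + 0)
  # mass conservation on random data
  t0 <- random_counts_table(12, 5, seed = 31)
  tax3 <- data.frame(taxon = taxa_ids <- rownames(t0$values),
                     order = sample(c("o1", "o2", "o3", NA), 12, TRUE),
                     parent = "p")
  out3 <- collapse_to_level(t0, tax3)
  expect_equal(colSums(out3$values), colSums(t0$values))
  expect_error(collapse_to_level(t0, tax3[-1, ]), "missing row")
})

test_that("Kendall matrix matches brute-force pair counting", {
  expect_equal(oracle_kendall(1:4, c(2, 1, 4, 3)), 1/3)
  set.seed(73)
  m <- rbind(a = 1:8, b = c(2, 1, 4, 3, 6, 5, 8, 7), c = 8:1,
             d = rpois(8, 5), e = rpois(8, 5))
  colnames(m) <- paste0("s", 1:8)
  km <- kendall_matrix(abundance_table(m))
  expect_equal(km$tau["a", "b"], oracle_kendall(1:8, m["b", ]))
  expect_equal(km$tau["a", "c"], -1)
  expect_equal(km$tau["a", "a"], 1)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(km$tau[i, j], oracle_kendall(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  expect_equal(km$tau, t(km$tau))
  # constant taxon flagged, not fatal
  m2 <- rbind(m, f = rep(3, 8))
  km2 <- kendall_matrix(abundance_table(m2))
  expect_equal(km2$constant_taxa, "f")
  expect_true(is.na(km2$tau["a", "f"]))
})

test_that("CAG clustering merges identical profiles first and honors k", {
  set.seed(51)
  base <- matrix(rexp(5 * 20), 5, 20,
                 dimnames = list(paste0("t", 1:5), paste0("s", 1:20)))
  base["t2", ] <- base["t1", ] * 2      # identical profile up to scale
  t0 <- to_relative(abundance_table(base))
  part <- cluster_cags(t0, k = 4)
  expect_equal(unname(part$membership["t1"]), unname(part$membership["t2"]))
  part1 <- cluster_cags(t0, k = 1)
  expect_equal(length(unique(part1$membership)), 1)
  expect_error(cluster_cags(t0, k = 10), "between 1")
})

test_that("CAGs are named by their most abundant member", {
  m <- matrix(c(10, 1, 1, 8,
                12, 2, 1, 9,
                 9, 1, 2, 7,
                11, 2, 2, 8), 4, 4,
              dimnames = list(c("Big1", "Small1", "Small2", "Big2"),
                              paste0("s", 1:4)))
  # Big1/Small1 covary; Small2/Big2 covary
  m["Small1", ] <- m["Big1", ] * 0.1 + 0.01 * (1:4)
  m["Small2", ] <- m["Big2", ] * 0.1 + 0.01 * (4:1)
  part <- cluster_cags(to_relative(abundance_table(m)), k = 2)
  expect_setequal(unique(part$membership), c("Big1", "Big2"))
})

test_that("over-abundance ratios, tiers and the weighted-mean identity", {
  m <- matrix(c(0.2, 0.8, 0.2, 0.8, 0.1, 0.9, 0.1, 0.9), 2, 4,
              dimnames = list(c("tA", "tB"), paste0("s", 1:4)))
  sec <- setNames(c("in", "in", "out", "out"), paste0("s", 1:4))
  prof <- over_abundance(abundance_table(m, is_relative = TRUE), sec)
  expect_equal(prof$ratio["in", "tA"], 0.2 / 0.15, tolerance = 1e-12)
  expect_equal(prof$ratio["out", "tA"], 0.1 / 0.15, tolerance = 1e-12)
  expect_equal(prof$tier["in", "tA"], "bold")     # 1.333 >= 1.3
  expect_equal(prof$tier["out", "tA"], "hidden")  # 0.667 < 1
  # single sector covering the whole study: all ratios 1
  prof1 <- over_abundance(abundance_table(m, is_relative = TRUE),
                          setNames(rep("all", 4), paste0("s", 1:4)))
  expect_equal(unname(prof1$ratio["all", ]), c(1, 1))
  # weighted-mean identity on random data with unbalanced sectors
  t0 <- to_relative(random_counts_table(10, 9, seed = 61))
  sec2 <- setNames(c(rep("a", 2), rep("b", 3), rep("c", 4)),
                   colnames(t0$values))
  prof2 <- over_abundance(t0, sec2)
  w <- prof2$n_per_sector / sum(prof2$n_per_sector)
  expect_equal(unname(colSums(prof2$ratio * w)), rep(1, 10),
               tolerance = 1e-12)
})

test_that("Wiggum networks carry significant edges and node attributes", {
  set.seed(91)
  n <- 30
  hublike <- rnorm(n)
  m <- rbind(x = exp(hublike), y = exp(hublike + rnorm(n, 0, 0.1)),
             z = exp(rnorm(n)), w = exp(rnorm(n)), v = exp(rnorm(n)))
  colnames(m) <- paste0("s", 1:n)
  t0 <- to_relative(abundance_table(m))
  corr <- kendall_matrix(t0)
  part <- cluster_cags(t0, k = 2)
  net <- build_wiggum(t0, part, corr)
  ed <- igraph::as_data_frame(net)
  expect_true(any((ed$from == "x" & ed$to == "y") |
                  (ed$from == "y" & ed$to == "x")))
  expect_true(all(ed$sign[ed$weight < 0] == "negative"))
  nd <- igraph::as_data_frame(net, "vertices")
  expect_setequal(nd$name, rownames(m))
  expect_true(all(c("mean_abundance", "cag") %in% names(nd)))
  # with an unattainable q threshold the network is edgeless but intact
  net0 <- build_wiggum(t0, part, corr, edge_q = 0)
  expect_equal(igraph::ecount(net0), 0)
  expect_equal(igraph::vcount(net0), 5)
  # sector view marks hidden-tier nodes excluded
  sec <- setNames(rep(c("p", "q"), each = 15), colnames(m))
  prof <- over_abundance(t0, sec)
  nets <- build_wiggum(t0, part, corr, profile = prof, sector = "p")
  nds <- igraph::as_data_frame(nets, "vertices")
  expect_equal(nds$excluded, unname(prof$tier["p", nds$name] == "hidden"))
})
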