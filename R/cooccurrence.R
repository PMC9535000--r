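# Sector-specific co-occurrence networks and their summaries: hub taxa,
# modules and modularity, total connectivity, and the negative-to-positive
# cohesion ratio.
#
# Network inference operates on centered-log-ratio (CLR) transformed
# relative abundances: pairwise Pearson association, permutation-tested and
# FDR-controlled, with an optional order-1 partial-correlation prune that
# removes edges explainable by a single third taxon.  This is a documented
# methodological substitute for conditional-independence tools such as
# FlashWeave: it owns its computation and does not attempt to replicate
# that tool's heterogeneous-data machinery.

#' Centered-log-ratio transform of an abundance table
#'
#' Relative abundances with a pseudocount of half the minimum positive
#' value, logged and centred per sample by the mean log abundance.
#'
#' @param t abundance_table.
#' @return taxa x samples matrix of CLR values.
#' @export
clr_transform <- function(t) {
  rel <- if (t$is_relative) t else to_relative(t)
  v <- rel$values
  pos <- v[v > 0]
  assert_that(length(pos) > 0, "all-zero table")
  pc <- min(pos) / 2
  lg <- log(v + pc)
  sweep(lg, 2L, colMeans(lg), "-")   # per-sample geometric-mean centering
}

#' Infer a sector co-occurrence network
#'
#' CLR transform (pseudocount = half the minimum positive relative
#' abundance), pairwise Pearson association, permutation p-values (one
#' seeded sample-order permutation per round, all pairs at once),
#' Benjamini-Hochberg control at \code{edge_q}, then order-1
#' partial-correlation pruning: an edge is dropped when conditioning on any
#' single other taxon sends the association below
#' \code{partial_threshold} in magnitude.
#'
#' @param t abundance_table restricted to one sector (>= 5 samples, >= 3
#'   taxa).
#' @param n_perm permutations for edge significance (default 1000).
#' @param edge_q FDR threshold (default 0.05).
#' @param partial_threshold minimum surviving |partial r| (default 0.1);
#'   set to 0 to disable pruning.
#' @param seed RNG seed.
#' @return association_network with provenance \code{"sector-inference"}.
#' @export
infer_network <- function(t, n_perm = 1000, edge_q = 0.05,
                          partial_threshold = 0.1, seed = 1L) {
  assert_that(ncol(t$values) >= 5, "need at least 5 samples in the sector")
  assert_that(nrow(t$values) >= 3, "need at least 3 taxa")
  clr <- clr_transform(t)
  x <- t(clr)                           # samples x taxa
  n <- nrow(x); p <- ncol(x)
  r_obs <- cor(x)
  set.seed(derive_seed(seed, 404L))
  exceed <- matrix(0L, p, p)
  for (b in seq_len(n_perm)) {
    rp <- cor(x, x[sample(n), , drop = FALSE])
    exceed <- exceed + (abs(rp) >= abs(r_obs) - 1e-12)
  }
  pmat <- (1 + exceed) / (1 + n_perm)
  ut <- upper.tri(pmat)
  qv <- matrix(NA_real_, p, p)
  qv[ut] <- benjamini_hochberg(pmat[ut])
  sel <- which(ut & qv <= edge_q, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(sel))
  if (partial_threshold > 0 && nrow(sel) > 0 && p >= 3) {
    for (e in seq_len(nrow(sel))) {
      i <- sel[e, 1]; j <- sel[e, 2]
      for (k in seq_len(p)) {
        if (k == i || k == j) next
        den <- (1 - r_obs[i, k]^2) * (1 - r_obs[j, k]^2)
        if (!is.finite(den) || den <= 0) next
        pr <- (r_obs[i, j] - r_obs[i, k] * r_obs[j, k]) / sqrt(den)
        if (abs(pr) < partial_threshold) { keep[e] <- FALSE; break }
      }
    }
  }
  sel <- sel[keep, , drop = FALSE]
  ids <- colnames(x)
  rel <- if (t$is_relative) t else to_relative(t)
  nodes <- data.frame(taxon = ids, mean_abundance = rowMeans(rel$values)[ids],
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
                      weight = r_obs[sel],
                      q_value = qv[sel], stringsAsFactors = FALSE)
  association_network(nodes, edges, provenance = "sector-inference")
}

#' Identify hub taxa of a network
#'
#' Hubs combine the highest degree, betweenness and closeness centralities:
#' nodes at or above the \code{q}-quantile of all three measures, computed
#' on the unsigned skeleton of the largest connected component.  When no
#' node clears all three thresholds the single best node by summed
#' centrality ranks is returned, flagged degenerate.
#'
#' @param net association_network.
#' @param q centrality quantile (default 0.90).
#' @return list: \code{hubs} (character), \code{degenerate} flag,
#'   \code{centralities} data.frame.
#' @export
find_hubs <- function(net, q = 0.90) {
  g <- net
  class(g) <- "igraph"
  if (igraph::ecount(g) == 0) {
    warning("edgeless network: no hubs")
    return(list(hubs = character(), degenerate = TRUE,
                centralities = data.frame()))
  }
  g <- igraph::delete_edge_attr(g, "weight")  # unsigned, unweighted skeleton
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == main))
  deg <- igraph::degree(sub)
  bet <- igraph::betweenness(sub)
  clo <- suppressWarnings(igraph::closeness(sub))
  cent <- data.frame(taxon = igraph::V(sub)$name, degree = deg,
                     betweenness = bet, closeness = clo,
                     stringsAsFactors = FALSE)
  cent <- cent[order(cent$taxon), ]
  thr <- vapply(cent[, c("degree", "betweenness", "closeness")],
                quantile, 0, probs = q, na.rm = TRUE)
  hit <- cent$degree >= thr[1] & cent$betweenness >= thr[2] &
    cent$closeness >= thr[3]
  # all nodes qualifying means the graph is centrality-symmetric: no hub
  # stands out, fall through to the tie-broken single candidate
  if (any(hit) && !all(hit)) {
    return(list(hubs = sort(cent$taxon[hit]), degenerate = FALSE,
                centralities = cent))
  }
  score <- rank(-cent$degree, ties.method = "min") +
    rank(-cent$betweenness, ties.method = "min") +
    rank(-cent$closeness, ties.method = "min")
  best <- cent$taxon[order(score, cent$taxon)][1L]
  list(hubs = best, degenerate = TRUE, centralities = cent)
}

#' Modules and modularity of a network
#'
#' Louvain community detection on unsigned edge weights (seeded, hence
#' deterministic), returning the modularity Q of the partition and the
#' number of communities including singletons.
#'
#' @param net association_network.
#' @param seed RNG seed.
#' @return list: \code{Q}, \code{n_modules}, \code{membership},
#'   \code{edgeless} flag.
#' @export
modularity_and_modules <- function(net, seed = 1L) {
  g <- net
  class(g) <- "igraph"
  if (igraph::ecount(g) == 0) {
    return(list(Q = 0, n_modules = igraph::vcount(g),
                membership = setNames(seq_len(igraph::vcount(g)),
                                      igraph::V(g)$name),
                edgeless = TRUE))
  }
  igraph::E(g)$weight <- abs(igraph::E(g)$weight)
  set.seed(derive_seed(seed, 505L))
  cl <- igraph::cluster_louvain(g)
  list(Q = igraph::modularity(cl),
       n_modules = length(unique(igraph::membership(cl))),
       membership = setNames(as.integer(igraph::membership(cl)),
                             igraph::V(g)$name),
       edgeless = FALSE)
}

#' Total connectivity of a network
#'
#' Edges per node, the reading used for the per-sector summary table; the
#' companion quantities (density, mean degree) are reported by
#' \code{\link{network_summary}}.
#'
#' @param net association_network.
#' @return edge count divided by node count.
#' @export
total_connectivity <- function(net) {
  igraph::ecount(net) / igraph::vcount(net)
}

#' Community cohesion and the negative:positive ratio
#'
#' Null-corrected connectedness per taxon: the positive (negative) part of
#' its Pearson correlations with all other taxa, minus the mean of the same
#' quantity under a taxon-shuffle null in which every taxon's abundances
#' are independently permuted across samples.  Per-sample cohesion is the
#' abundance-weighted sum of connectedness; the sector-level N:P ratio is
#' |mean negative cohesion| / mean positive cohesion.
#'
#' @param t abundance_table for one sector (>= 5 samples).
#' @param n_null number of null shuffles (default 200).
#' @param seed RNG seed.
#' @return list of class \code{cohesion_result}: \code{connectedness}
#'   (data.frame per taxon), \code{sample_cohesion} (data.frame per
#'   sample), \code{np_ratio}, \code{np_infinite} flag.
#' @export
cohesion <- function(t, n_null = 200, seed = 1L) {
  assert_that(ncol(t$values) >= 5, "need at least 5 samples")
  rel <- if (t$is_relative) t else to_relative(t)
  x <- t(rel$values)                       # samples x taxa
  n <- nrow(x); p <- ncol(x)
  r <- suppressWarnings(cor(x))
  r[is.na(r)] <- 0        # constant (e.g. locally absent) taxa contribute 0
  pos_part <- function(m) { diag(m) <- 0; (rowSums(pmax(m, 0))) / (p - 1) }
  neg_part <- function(m) { diag(m) <- 0; (rowSums(pmin(m, 0))) / (p - 1) }
  obs_pos <- pos_part(r); obs_neg <- neg_part(r)
  set.seed(derive_seed(seed, 606L))
  null_pos <- null_neg <- numeric(p)
  for (b in seq_len(n_null)) {
    xb <- apply(x, 2L, sample)
    rb <- suppressWarnings(cor(xb))
    rb[is.na(rb)] <- 0
    null_pos <- null_pos + pos_part(rb)
    null_neg <- null_neg + neg_part(rb)
  }
  conn_pos <- obs_pos - null_pos / n_null
  conn_neg <- obs_neg - null_neg / n_null
  coh_pos <- as.numeric(x %*% conn_pos)
  coh_neg <- as.numeric(x %*% conn_neg)
  mp <- mean(coh_pos); mn <- mean(coh_neg)
  np_inf <- mp <= 0
  structure(list(
    connectedness = data.frame(taxon = colnames(x), positive = conn_pos,
                               negative = conn_neg, stringsAsFactors = FALSE),
    sample_cohesion = data.frame(sample_id = rownames(x), positive = coh_pos,
                                 negative = coh_neg, stringsAsFactors = FALSE),
    np_ratio = if (np_inf) NA_real_ else abs(mn) / mp,
    np_infinite = np_inf, n_null = n_null, seed = seed),
    class = "cohesion_result")
}

#' One-row summary of a sector network
#'
#' The per-sector report: N:P cohesion ratio, module count, modularity,
#' total connectivity (plus density and mean degree), hub taxa and
#' node/edge counts.
#'
#' @param t sector abundance_table.
#' @param net optional precomputed \code{\link{infer_network}} result.
#' @param sector sector label for the report.
#' @param seed RNG seed propagated to all stochastic steps.
#' @param n_perm permutations for network inference.
#' @param n_null shuffles for cohesion.
#' @param hub_quantile centrality quantile for hubs.
#' @return one-row data.frame shaped like the per-sector network table.
#' @export
network_summary <- function(t, sector = "sector", net = NULL, seed = 1L,
                            n_perm = 1000, n_null = 200,
                            hub_quantile = 0.90) {
  if (is.null(net)) net <- infer_network(t, n_perm = n_perm, seed = seed)
  mods <- modularity_and_modules(net, seed = seed)
  hubs <- suppressWarnings(find_hubs(net, q = hub_quantile))
  coh <- cohesion(t, n_null = n_null, seed = seed)
  nv <- igraph::vcount(net); ne <- igraph::ecount(net)
  data.frame(sector = sector,
             np_cohesion_ratio = coh$np_ratio,
             np_infinite = coh$np_infinite,
             modules = mods$n_modules,
             modularity = mods$Q,
             total_connectivity = total_connectivity(net),
             density = if (nv > 1) ne / (nv * (nv - 1) / 2) else 0,
             mean_degree = if (nv > 0) 2 * ne / nv else 0,
             hubs = paste(hubs$hubs, collapse = ";"),
             hub_degenerate = hubs$degenerate,
             n_nodes = nv, n_edges = ne, seed = seed,
             stringsAsFactors = FALSE)
}
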