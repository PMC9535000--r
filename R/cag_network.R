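# Co-abundance groups (CAGs): order-level collapsing, Kendall co-abundance
# matrix, Ward clustering on Spearman-correlation distance, per-sector
# over-abundance profiles and Wiggum-plot network export.

#' Collapse taxa to a taxonomic level
#'
#' Abundances are summed within each group at the requested level.  Taxa
#' unassigned at that level are pooled per parent lineage into
#' \code{Unassigned-<parent>} bins, which are retained (and flagged) rather
#' than dropped, since unassigned fractions can be large in amplicon
#' surveys.
#'
#' @param t abundance_table keyed by ASV/OTU ids.
#' @param taxonomy data.frame with columns \code{taxon} (matching the table
#'   rows), the target \code{level} column (NA when unassigned) and
#'   optionally \code{parent} (fallback lineage used to label unassigned
#'   bins).
#' @param level name of the taxonomy column to collapse to (default
#'   \code{"order"}).
#' @return abundance_table at the collapsed level; per-sample totals are
#'   conserved exactly.
#' @export
collapse_to_level <- function(t, taxonomy, level = "order") {
  assert_that(level %in% names(taxonomy), "taxonomy lacks a '", level,
              "' column")
  assert_that(all(taxa_ids(t) %in% taxonomy$taxon),
              "taxonomy missing row(s) for: ",
              paste(head(setdiff(taxa_ids(t), taxonomy$taxon), 5),
                    collapse = ", "))
  taxonomy <- taxonomy[match(taxa_ids(t), taxonomy$taxon), ]
  lab <- as.character(taxonomy[[level]])
  un <- is.na(lab) | lab == ""
  if (any(un)) {
    parent <- if ("parent" %in% names(taxonomy))
      as.character(taxonomy$parent) else rep("unknown", nrow(taxonomy))
    lab[un] <- paste0("Unassigned-", parent[un])
  }
  collapsed <- rowsum(t$values, lab)
  abundance_table(collapsed, is_relative = t$is_relative, realm = t$realm)
}

#' Pairwise Kendall co-abundance matrix
#'
#' Tie-corrected Kendall tau-b between all taxon pairs across samples, with
#' asymptotic p-values and Benjamini-Hochberg q-values over the upper
#' triangle.  Constant taxa yield NA tau for their pairs and are flagged,
#' not fatal.
#'
#' @param t abundance_table with >= 5 samples.
#' @return list of class \code{correlation_matrix}: \code{tau}, \code{p},
#'   \code{q} (symmetric matrices), \code{constant_taxa}.
#' @export
kendall_matrix <- function(t) {
  assert_that(ncol(t$values) >= 5, "need at least 5 samples")
  x <- t(t$values)               # samples x taxa
  p_taxa <- ncol(x)
  ids <- colnames(x)
  tau <- p <- matrix(NA_real_, p_taxa, p_taxa, dimnames = list(ids, ids))
  diag(tau) <- 1; diag(p) <- 0
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  for (i in seq_len(p_taxa - 1)) for (j in (i + 1):p_taxa) {
    if (const[i] || const[j]) next
    ct <- suppressWarnings(cor.test(x[, i], x[, j], method = "kendall"))
    tau[i, j] <- tau[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  q <- matrix(NA_real_, p_taxa, p_taxa, dimnames = list(ids, ids))
  ut <- upper.tri(q)
  q[ut] <- benjamini_hochberg(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  structure(list(tau = tau, p = p, q = q, constant_taxa = ids[const]),
            class = "correlation_matrix")
}

#' Cluster taxa into co-abundance groups
#'
#' Taxa are clustered by Ward agglomeration (ward.D2) on a Spearman
#' correlation distance.  By default the distance is computed between the
#' taxa's abundance profiles, \eqn{d_{ij} = 1 - \rho(x_i, x_j)}; with
#' \code{cluster_input = "kendall"} the Kendall tau matrix itself is
#' converted to distances \eqn{1 - \tau}.  The number of groups is either
#' given (\code{k}) or chosen to maximise the mean silhouette width over
#' k = 2..6.  Each CAG is named after its most abundant member (unassigned
#' bins never lend their name).
#'
#' @param t abundance_table (relative abundances are used for naming).
#' @param k number of CAGs, or NULL for silhouette selection.
#' @param cluster_input \code{"profiles"} (default) or \code{"kendall"}.
#' @param corr optional precomputed \code{\link{kendall_matrix}} (required
#'   for \code{cluster_input = "kendall"}).
#' @return list of class \code{cag_partition}: \code{membership} (named CAG
#'   label per taxon), \code{k}, \code{tree} (hclust), \code{names} (CAG id
#'   -> display name).
#' @export
cluster_cags <- function(t, k = NULL, cluster_input = c("profiles", "kendall"),
                         corr = NULL) {
  cluster_input <- match.arg(cluster_input)
  ntaxa <- nrow(t$values)
  assert_that(is.null(k) || (k >= 1 && k <= ntaxa),
              "k must lie between 1 and the number of taxa")
  if (cluster_input == "profiles") {
    rho <- suppressWarnings(cor(t(t$values), method = "spearman"))
    rho[is.na(rho)] <- 0
    d <- as.dist(1 - rho)
  } else {
    assert_that(!is.null(corr), "cluster_input='kendall' needs corr")
    tau <- corr$tau
    tau[is.na(tau)] <- 0
    d <- as.dist(1 - tau)
  }
  hc <- hclust(d, method = "ward.D2")
  if (is.null(k)) {
    ks <- 2:min(6, ntaxa - 1)
    sil <- vapply(ks, function(kk) {
      mean(cluster::silhouette(cutree(hc, kk), d)[, "sil_width"])
    }, 0)
    k <- ks[which.max(sil)]
  }
  mem <- cutree(hc, k)
  rel <- if (t$is_relative) t else to_relative(t)
  mean_ab <- rowMeans(rel$values)
  cag_names <- vapply(seq_len(k), function(g) {
    members <- names(mem)[mem == g]
    named <- members[!startsWith(members, "Unassigned-")]
    pool <- if (length(named)) named else members
    pool[which.max(mean_ab[pool])]
  }, "")
  # disambiguate (two CAGs can share a dominant name only via pooled bins)
  cag_names <- make.unique(cag_names, sep = "-")
  structure(list(membership = setNames(cag_names[mem], names(mem)),
                 k = k, tree = hc,
                 names = setNames(cag_names, seq_len(k))),
            class = "cag_partition")
}

#' Per-sector over-abundance profile
#'
#' For sector s and taxon j, \code{O[s, j] = meanArea / meanTot}: the mean
#' relative abundance of j over the sector's samples divided by its mean
#' over all samples.  Display tiers follow the Wiggum-plot convention:
#' below 1 hidden, at or above 1.3 bold.  The sector-size weighted mean of
#' O over sectors is exactly 1 for every taxon.
#'
#' @param t relative abundance_table.
#' @param sectors named character vector (sample_id -> sector) or data.frame
#'   with sample_id/sector columns.
#' @param bold_threshold display threshold for the bold tier (default 1.3).
#' @return list of class \code{over_abundance_profile}: \code{ratio}
#'   (sectors x taxa), \code{tier} (hidden/normal/bold), \code{n_per_sector},
#'   \code{undefined_taxa} (zero overall mean).
#' @export
over_abundance <- function(t, sectors, bold_threshold = 1.3) {
  rel <- if (t$is_relative) t else to_relative(t)
  if (is.data.frame(sectors))
    sectors <- setNames(sectors$sector, sectors$sample_id)
  assert_that(all(sample_ids(rel) %in% names(sectors)),
              "every sample needs a sector")
  sec <- sectors[sample_ids(rel)]
  tab <- table(sec)
  assert_that(all(tab > 0), "empty sector")
  mean_tot <- rowMeans(rel$values)
  ratio <- t(vapply(names(tab), function(s) {
    rowMeans(rel$values[, sec == s, drop = FALSE]) / mean_tot
  }, numeric(nrow(rel$values))))
  undefined <- names(which(mean_tot == 0))
  tier <- matrix("normal", nrow(ratio), ncol(ratio), dimnames = dimnames(ratio))
  tier[which(ratio < 1)] <- "hidden"
  tier[which(ratio >= bold_threshold)] <- "bold"
  if (length(undefined)) tier[, undefined] <- NA_character_
  structure(list(ratio = ratio, tier = tier,
                 n_per_sector = as.integer(tab),
                 sectors = names(tab), undefined_taxa = undefined),
            class = "over_abundance_profile")
}

#' Build a Wiggum-plot association network
#'
#' Nodes are taxa sized by mean relative abundance (overall view) or by
#' over-abundance in one sector (sector view, where hidden-tier nodes are
#' marked excluded); edges are the significant Kendall co-abundances,
#' signed positive/negative.
#'
#' @param t abundance_table.
#' @param partition \code{\link{cluster_cags}} result.
#' @param corr \code{\link{kendall_matrix}} result.
#' @param profile optional \code{\link{over_abundance}} result.
#' @param sector sector name for a sector view (requires \code{profile}).
#' @param edge_q BH q-value threshold for edges (default 0.05).
#' @return association_network.
#' @export
build_wiggum <- function(t, partition, corr, profile = NULL, sector = NULL,
                         edge_q = 0.05) {
  rel <- if (t$is_relative) t else to_relative(t)
  ids <- taxa_ids(rel)
  assert_that(identical(sort(ids), sort(names(partition$membership))),
              "partition taxa do not match the table")
  nodes <- data.frame(taxon = ids,
                      mean_abundance = rowMeans(rel$values)[ids],
                      cag = unname(partition$membership[ids]),
                      stringsAsFactors = FALSE)
  if (!is.null(sector)) {
    assert_that(!is.null(profile), "sector view needs an over-abundance profile")
    assert_that(sector %in% rownames(profile$ratio), "unknown sector: ", sector)
    nodes$over_abundance <- profile$ratio[sector, ids]
    nodes$tier <- profile$tier[sector, ids]
    nodes$excluded <- !is.na(nodes$tier) & nodes$tier == "hidden"
  }
  qm <- corr$q[ids, ids]
  sel <- which(upper.tri(qm) & !is.na(qm) & qm <= edge_q, arr.ind = TRUE)
  edges <- data.frame(from = ids[sel[, 1]], to = ids[sel[, 2]],
                      weight = corr$tau[ids, ids][sel],
                      q_value = qm[sel], stringsAsFactors = FALSE)
  association_network(nodes, edges, provenance = "kendall-CAG")
}
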