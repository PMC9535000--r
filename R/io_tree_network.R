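# Newick trees and association-network serialisation.

#' Read a rooted phylogenetic tree from a Newick file
#'
#' Wraps \code{ape::read.tree} with the validation the UniFrac stage relies
#' on: unique leaf labels, finite non-negative branch lengths, rooted
#' topology.
#'
#' @param path Newick file path.
#' @param missing_lengths \code{"error"} (default) or \code{"zero"} to
#'   replace absent branch lengths with 0.
#' @return an \code{ape::phylo} tree.
#' @export
read_newick <- function(path, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  assert_that(file.exists(path), "file not found: ", path)
  txt <- paste(readLines(path), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop_pelnet("unbalanced parentheses in ", path, " (", n_open, " '(' vs ",
                n_close, " ')')", class = "pelnet_format_error")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e)
                     stop_pelnet("Newick parse error in ", path, ": ",
                                 conditionMessage(e),
                                 class = "pelnet_format_error"))
  if (is.null(tree))
    stop_pelnet("Newick parse error in ", path,
                class = "pelnet_format_error")
  validate_tree(tree, missing_lengths = missing_lengths)
}

validate_tree <- function(tree, missing_lengths = "error") {
  assert_that(inherits(tree, "phylo"), "not a phylogenetic tree")
  assert_that(!anyDuplicated(tree$tip.label), "duplicate leaf labels")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (missing_lengths == "zero") {
      if (is.null(tree$edge.length))
        tree$edge.length <- numeric(nrow(tree$edge))
      tree$edge.length[is.na(tree$edge.length)] <- 0
    } else {
      stop_pelnet("tree has missing branch lengths",
                  class = "pelnet_format_error")
    }
  }
  assert_that(all(is.finite(tree$edge.length)) && all(tree$edge.length >= 0),
              "branch lengths must be finite and non-negative")
  assert_that(ape::is.rooted(tree), "tree must be rooted")
  tree
}

#' Write a tree as Newick
#' @param tree ape::phylo.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Build an association network
#'
#' A signed, weighted graph over taxa.  Node attributes carry mean relative
#' abundance, over-abundance and CAG membership where known; edges carry a
#' weight and a sign label consistent with it.
#'
#' @param nodes data.frame with at least a \code{taxon} column; optional
#'   \code{mean_abundance}, \code{over_abundance}, \code{cag},
#'   \code{excluded} columns.
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{weight} (signed); may have zero rows.
#' @param provenance how the edges were inferred, e.g.
#'   \code{"kendall-CAG"} or \code{"sector-inference"}.
#' @return igraph object with class attribute \code{association_network}.
#' @export
association_network <- function(nodes, edges, provenance = "unspecified") {
  assert_that(is.data.frame(nodes) && "taxon" %in% names(nodes),
              "nodes needs a 'taxon' column")
  assert_that(!anyDuplicated(nodes$taxon), "duplicate node taxa")
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    assert_that(all(c("from", "to", "weight") %in% names(edges)),
                "edges need from/to/weight columns")
    assert_that(all(edges$from %in% nodes$taxon) &&
                all(edges$to %in% nodes$taxon), "edge endpoint not in nodes")
    assert_that(all(edges$from != edges$to), "self-edges not allowed")
    edges$sign <- ifelse(edges$weight >= 0, "positive", "negative")
  }
  vdf <- nodes
  names(vdf)[names(vdf) == "taxon"] <- "name"
  g <- igraph::graph_from_data_frame(
    if (nrow(edges) > 0) edges else data.frame(from = character(),
                                               to = character(),
                                               weight = numeric(),
                                               sign = character()),
    directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "provenance", provenance)
  class(g) <- c("association_network", class(g))
  g
}

network_nodes <- function(net) igraph::as_data_frame(net, what = "vertices")
network_edges <- function(net) igraph::as_data_frame(net, what = "edges")

#' Write an association network to GraphML or edge-list TSV
#'
#' The edge-TSV variant writes two files: \code{<path>} with one row per
#' edge (from, to, weight, sign) and \code{<path>.nodes.tsv} with the node
#' attribute table, so the graph round-trips losslessly including isolated
#' nodes.
#'
#' @param net association_network.
#' @param path output path.
#' @param format \code{"graphml"} or \code{"edge-tsv"}.
#' @export
write_network <- function(net, path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- network_edges(net)
    nd <- network_nodes(net)
    num <- vapply(ed, is.numeric, TRUE)
    ed[num] <- lapply(ed[num], function(v) format(v, digits = 12, trim = TRUE))
    numn <- vapply(nd, is.numeric, TRUE)
    nd[numn] <- lapply(nd[numn], function(v) format(v, digits = 12, trim = TRUE))
    write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(nd, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read an association network written by \code{write_network}
#'
#' @param path path given to \code{write_network}.
#' @param format \code{"graphml"} or \code{"edge-tsv"}.
#' @return association_network.
#' @export
read_network <- function(path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    class(g) <- c("association_network", class(g))
    return(g)
  }
  ed <- read.delim(path, stringsAsFactors = FALSE)
  nd <- read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE)
  names(nd)[names(nd) == "name"] <- "taxon"
  prov <- "unspecified"
  association_network(nd, ed, provenance = prov)
}
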