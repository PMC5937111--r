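#' Build a protein-protein interaction network
#'
#' Constructs the simple undirected graph used throughout the screening
#' pipeline: self-loops are removed, duplicate and reversed edge pairs are
#' collapsed, and every node carries a logical `seed` vertex attribute
#' recording whether it came from the differentially-expressed input list
#' (`TRUE`) or was pulled in as an interactome neighbour (`FALSE`).
#'
#' @param edges two-column character matrix or data frame of endpoints
#'   (one interaction per row); may have zero rows.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node symbols to keep in the network.
#' @param seeds character vector of symbols to flag as seed nodes.
#' @return an [igraph::igraph] object: undirected, simple, with vertex
#'   attributes `name` (gene symbol) and `seed` (logical).
#' @export
ppi_network <- function(edges = NULL, nodes = character(), seeds = character()) {
  if (is.null(edges)) {
    ep <- character()
  } else {
    edges <- as.matrix(edges)
    if (nrow(edges) > 0 && ncol(edges) < 2)
      stop("edge table must have two endpoint columns")
    ep <- if (nrow(edges) > 0) as.character(t(edges[, 1:2, drop = FALSE])) else character()
  }
  all_nodes <- unique(c(ep, as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    d = if (length(ep)) data.frame(
      from = ep[c(TRUE, FALSE)], to = ep[c(FALSE, TRUE)],
      stringsAsFactors = FALSE
    ) else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dropped <- n_before - igraph::ecount(g)
  if (n_dropped > 0)
    message(sprintf("collapsed %d self-loop/duplicate edge(s)", n_dropped))
  igraph::V(g)$seed <- igraph::V(g)$name %in% seeds
  g
}

#' @rdname ppi_network
#' @param x object to test.
#' @export
is_ppi_network <- function(x) {
  igraph::is_igraph(x) && !igraph::is_directed(x) &&
    "name" %in% igraph::vertex_attr_names(x)
}

#' Seed symbols of a network
#'
#' @param network a network built by [ppi_network()] or
#'   [expand_seed_neighborhood()].
#' @return character vector of symbols whose `seed` flag is `TRUE`
#'   (empty if the attribute is absent).
#' @export
seed_nodes <- function(network) {
  s <- igraph::vertex_attr(network, "seed")
  if (is.null(s)) return(character())
  igraph::V(network)$name[as.logical(s)]
}

#' Expand a seed list to its interactome neighbourhood
#'
#' Standard one-hop network construction: the analysed network is the
#' interactome subgraph induced on the seed proteins plus their first
#' neighbours. Every interactome edge between retained nodes is kept
#' (induced subgraph), including neighbour-neighbour edges. The hop count
#' is configurable; the conventional value used to grow a
#' differentially-expressed protein list into an analysis network is 1.
#'
#' @param seeds character vector of seed gene symbols.
#' @param interactome background interactome as an undirected igraph.
#' @param hops non-negative integer, neighbourhood radius (default 1).
#' @return induced subgraph with `seed` vertex flags set.
#' @export
expand_seed_neighborhood <- function(seeds, interactome, hops = 1L) {
  stopifnot(is_ppi_network(interactome), hops >= 0)
  seeds <- unique(as.character(seeds))
  present <- seeds[seeds %in% igraph::V(interactome)$name]
  absent <- setdiff(seeds, present)
  if (length(absent))
    warning(sprintf("%d seed(s) absent from the interactome: %s",
                    length(absent),
                    paste(head(absent, 5L), collapse = ", ")))
  if (length(present) == 0)
    stop("no seed occurs in the interactome")
  keep <- igraph::ego(interactome, order = hops, nodes = present)
  keep <- unique(unlist(lapply(keep, function(v) v$name)))
  sub <- igraph::induced_subgraph(interactome, vids = keep)
  igraph::V(sub)$seed <- igraph::V(sub)$name %in% present
  sub
}
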