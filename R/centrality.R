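#' Node degree
#'
#' Degree of every node of a simple undirected network: the number of
#' incident edges (isolated nodes score 0).
#'
#' @param network an undirected igraph.
#' @return named integer vector, one entry per node.
#' @export
compute_degree <- function(network) {
  stopifnot(is_ppi_network(network))
  d <- igraph::degree(network, loops = FALSE)
  stats::setNames(as.integer(d), igraph::V(network)$name)
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node,
#' computed by the single-sweep accumulation algorithm (one breadth-first
#' geodesic-counting pass per source followed by reverse dependency
#' accumulation; O(VE) for unweighted graphs). Disconnected graphs are
#' handled naturally — pair sums run over reachable pairs only — with one
#' global normalisation.
#'
#' @param network an undirected simple igraph.
#' @param normalized if `TRUE` (default) raw values are scaled by
#'   `2 / ((n - 1) (n - 2))` so that a node lying on every geodesic of a
#'   connected graph scores 1; graphs with fewer than 3 nodes score 0
#'   everywhere.
#' @return named numeric vector of betweenness values.
#' @export
compute_betweenness <- function(network, normalized = TRUE) {
  stopifnot(is_ppi_network(network))
  n <- igraph::vcount(network)
  nm <- igraph::V(network)$name
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  el <- igraph::as_edgelist(network, names = FALSE)
  raw <- .brandes_raw(n, as.integer(el[, 1]) - 1L, as.integer(el[, 2]) - 1L)
  if (normalized) {
    raw <- if (n >= 3) raw * 2 / ((n - 1) * (n - 2)) else rep(0, n)
  }
  stats::setNames(as.numeric(raw), nm)
}

#' Assemble a ranked centrality table
#'
#' Combines per-node degree and betweenness into the table the screening
#' stage consumes. Ranks are assigned by value descending; ties are broken
#' by symbol ascending so that the ranking is deterministic (tie groups
#' are reported via `message()`). Rows are ordered by degree rank.
#'
#' @param degree named integer vector (symbol -> degree).
#' @param bc named numeric vector (symbol -> betweenness) over the same
#'   symbols.
#' @return data frame with columns `symbol`, `degree`, `bc`,
#'   `degree_rank`, `bc_rank`.
#' @export
centrality_table <- function(degree, bc) {
  stopifnot(setequal(names(degree), names(bc)))
  sym <- names(degree)
  bc <- bc[sym]
  rank_of <- function(val) {
    ord <- order(-val, sym)
    r <- integer(length(val)); r[ord] <- seq_along(val)
    r
  }
  if (anyDuplicated(degree) || anyDuplicated(bc))
    message("centrality ties broken lexicographically by symbol")
  out <- data.frame(symbol = sym,
                    degree = as.integer(degree),
                    bc = as.numeric(bc),
                    degree_rank = rank_of(as.numeric(degree)),
                    bc_rank = rank_of(as.numeric(bc)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$degree_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname centrality_table
#' @param network an undirected simple igraph; degree and normalized
#'   betweenness are computed and tabulated.
#' @export
rank_table <- function(network) {
  stopifnot(is_ppi_network(network))
  if (igraph::vcount(network) == 0)
    return(data.frame(symbol = character(), degree = integer(), bc = numeric(),
                      degree_rank = integer(), bc_rank = integer(),
                      stringsAsFactors = FALSE))
  centrality_table(compute_degree(network), compute_betweenness(network))
}
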