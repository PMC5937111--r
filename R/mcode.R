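#' MCODE parameters
#'
#' Parameters of molecular complex detection. The defaults are the
#' conventional Cytoscape values used for PPI module screening: node
#' score cutoff 0.2, k-core 2, degree cutoff 2, max depth 100, haircut
#' on, fluff off.
#'
#' @param node_score_cutoff fraction in `[0, 1)`; a vertex joins a complex
#'   only if its weight exceeds `seed_weight * (1 - node_score_cutoff)`.
#' @param k_core integer; complexes must contain a k-core of this order.
#' @param degree_cutoff integer; vertices below this degree are weighted 0.
#' @param max_depth integer; breadth-first expansion radius from the seed.
#' @param haircut logical; iteratively trim members with fewer than 2
#'   intra-complex edges.
#' @param fluff logical; add boundary neighbours whose neighbourhood
#'   density exceeds `fluff_density` (fluffed nodes may be shared between
#'   complexes).
#' @param fluff_density density threshold for fluffing.
#' @return list of class `mcode_params`.
#' @export
mcode_params <- function(node_score_cutoff = 0.2, k_core = 2L,
                         degree_cutoff = 2L, max_depth = 100L,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.1) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff < 1,
            k_core >= 1, degree_cutoff >= 0, max_depth >= 1)
  structure(list(node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 degree_cutoff = as.integer(degree_cutoff),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density = fluff_density),
            class = "mcode_params")
}

graph_density <- function(n, m) if (n < 2) 0 else 2 * m / (n * (n - 1))

# density of the highest k-core of a vertex set's induced subgraph,
# together with its k (core-clustering coefficient ingredients)
highest_core_density <- function(network, vids) {
  sub <- igraph::induced_subgraph(network, vids)
  cor <- igraph::coreness(sub)
  k <- max(cor)
  core_v <- which(cor == k)
  core <- igraph::induced_subgraph(sub, core_v)
  list(k = k,
       density = graph_density(igraph::vcount(core), igraph::ecount(core)))
}

#' MCODE vertex weights
#'
#' Core-clustering-coefficient weighting: for every vertex of degree at
#' least `degree_cutoff`, the weight is `k * density` of the highest
#' k-core of the vertex's closed neighbourhood; lower-degree vertices are
#' weighted 0.
#'
#' @param network an undirected simple igraph.
#' @param params an [mcode_params()].
#' @return named numeric vector of weights.
#' @export
vertex_weights <- function(network, params = mcode_params()) {
  stopifnot(is_ppi_network(network), inherits(params, "mcode_params"))
  nm <- igraph::V(network)$name
  deg <- igraph::degree(network)
  w <- numeric(length(nm))
  eligible <- which(deg >= params$degree_cutoff)
  nb <- igraph::adjacent_vertices(network, eligible)
  for (i in seq_along(eligible)) {
    v <- eligible[i]
    hk <- highest_core_density(network, c(v, as.integer(nb[[i]])))
    w[v] <- hk$k * hk$density
  }
  stats::setNames(w, nm)
}

new_network_module <- function(network, members, seed) {
  members <- sort(unique(members))
  sub <- igraph::induced_subgraph(network, members)
  n <- as.integer(igraph::vcount(sub)); m <- as.integer(igraph::ecount(sub))
  structure(list(members = members, seed = seed,
                 score = graph_density(n, m) * n,
                 n_nodes = n, n_edges = m),
            class = "network_module")
}

#' @export
print.network_module <- function(x, ...) {
  cat(sprintf("MCODE module: seed %s, score %.3f, %d nodes, %d edges\n",
              x$seed, x$score, x$n_nodes, x$n_edges))
  invisible(x)
}

has_k_core <- function(network, members, k) {
  sub <- igraph::induced_subgraph(network, members)
  igraph::vcount(sub) > 0 && max(igraph::coreness(sub)) >= k
}

# iterative removal of members with < 2 intra-complex edges
haircut_members <- function(network, members) {
  repeat {
    if (length(members) == 0) return(members)
    sub <- igraph::induced_subgraph(network, members)
    deg <- igraph::degree(sub)
    drop <- igraph::V(sub)$name[deg < 2]
    if (length(drop) == 0) return(members)
    members <- setdiff(members, drop)
  }
}

#' Predict molecular complexes (MCODE)
#'
#' Canonical seeded greedy complex detection. Vertices are weighted by
#' [vertex_weights()]; complexes are grown breadth-first from the
#' highest-weighted unassigned vertex, admitting a neighbour iff its
#' weight strictly exceeds `seed_weight * (1 - node_score_cutoff)` and it
#' is not yet part of any complex, to a depth of at most `max_depth`.
#' Post-processing: complexes lacking a `k_core`-core are discarded;
#' haircut iteratively trims singly-connected members; fluff optionally
#' adds dense boundary neighbours. Every iteration order is tie-broken by
#' symbol so the output is deterministic. Complexes are scored as
#' `density * n_nodes` and returned sorted by score descending (ties by
#' member count descending, then seed symbol).
#'
#' @param network an undirected simple igraph.
#' @param params an [mcode_params()].
#' @return list of `network_module` objects.
#' @export
predict_complexes <- function(network, params = mcode_params()) {
  stopifnot(is_ppi_network(network), inherits(params, "mcode_params"))
  nm <- igraph::V(network)$name
  w <- vertex_weights(network, params)
  assigned <- stats::setNames(rep(FALSE, length(nm)), nm)
  # seed order: weight descending, symbol ascending
  seed_order <- nm[order(-w, nm)]
  complexes <- list()
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  adj <- lapply(adj, function(v) nm[as.integer(v)])
  names(adj) <- nm
  for (seed in seed_order) {
    if (assigned[seed]) next
    thr <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0 && depth < params$max_depth) {
      nxt <- character()
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!assigned[u] && w[u] > thr) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- sort(unique(nxt))
      depth <- depth + 1L
    }
    if (length(members) >= 2 && has_k_core(network, members, params$k_core)) {
      if (params$haircut) members <- haircut_members(network, members)
      if (params$fluff && length(members) > 0) {
        boundary <- sort(setdiff(unique(unlist(adj[members], use.names = FALSE)),
                                 members))
        keep <- vapply(boundary, function(u) {
          nb <- c(u, adj[[u]])
          sub <- igraph::induced_subgraph(network, nb)
          graph_density(igraph::vcount(sub), igraph::ecount(sub)) >
            params$fluff_density
        }, logical(1))
        members <- c(members, boundary[keep])
      }
      if (length(members) >= 2)
        complexes[[length(complexes) + 1L]] <- new_network_module(network, members, seed)
    }
  }
  ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
               -vapply(complexes, `[[`, numeric(1), "n_nodes"),
               vapply(complexes, `[[`, character(1), "seed"))
  complexes[ord]
}

#' Retain high-scoring modules
#'
#' The module-retention rule applied before functional analysis: keep
#' modules with `score > min_score` and `n_nodes > min_nodes`, both
#' strict.
#'
#' @param modules list of `network_module` objects.
#' @param min_score score threshold (default 3).
#' @param min_nodes node-count threshold (default 6).
#' @return filtered list, original order preserved.
#' @export
filter_modules <- function(modules, min_score = 3, min_nodes = 6L) {
  Filter(function(m) m$score > min_score && m$n_nodes > min_nodes, modules)
}

#' Tabulate modules
#'
#' @param modules list of `network_module` objects.
#' @return data frame with one row per module (rank, seed, score, n_nodes,
#'   n_edges, comma-joined members).
#' @export
module_table <- function(modules) {
  data.frame(rank = seq_along(modules),
             seed = vapply(modules, `[[`, character(1), "seed"),
             score = vapply(modules, `[[`, numeric(1), "score"),
             n_nodes = vapply(modules, `[[`, integer(1), "n_nodes"),
             n_edges = vapply(modules, `[[`, integer(1), "n_edges"),
             members = vapply(modules, function(m)
               paste(m$members, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}
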