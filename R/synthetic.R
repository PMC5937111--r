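#' Specification of a synthetic interactome experiment
#'
#' Bundles every knob of the synthetic data generator. The defaults are the
#' study conditions used throughout the test suite and the analysis
#' scripts: a 2000-node scale-free (preferential attachment, 2 edges per
#' arriving node) backbone, 140 seed proteins — the order of a typical
#' differentially-expressed protein list — three planted dense modules of
#' 10 nodes at internal density 0.9 emulating molecular complexes, and a
#' 50-term GO-like catalog in which each planted module has one matching
#' term covering 80% of its members.
#'
#' @param n_nodes number of backbone nodes.
#' @param attach_m preferential-attachment edges per arriving node.
#' @param n_seeds size of the seed (differentially-expressed) list.
#' @param n_planted_modules number of planted dense modules.
#' @param planted_size nodes per planted module (>= 4).
#' @param planted_density target internal edge density of each planted
#'   module, in (0.5, 1].
#' @param n_terms number of annotation terms.
#' @param enriched_fraction fraction of each planted module carrying its
#'   matched term, in (0, 1].
#' @param rng_seed integer seed; every generator output is deterministic
#'   given this value.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 2000L, attach_m = 2L, n_seeds = 140L,
                           n_planted_modules = 3L, planted_size = 10L,
                           planted_density = 0.9, n_terms = 50L,
                           enriched_fraction = 0.8, rng_seed = 1L) {
  spec <- list(n_nodes = as.integer(n_nodes), attach_m = as.integer(attach_m),
               n_seeds = as.integer(n_seeds),
               n_planted_modules = as.integer(n_planted_modules),
               planted_size = as.integer(planted_size),
               planted_density = planted_density,
               n_terms = as.integer(n_terms),
               enriched_fraction = enriched_fraction,
               rng_seed = as.integer(rng_seed))
  stopifnot(spec$n_nodes > 0, spec$attach_m > 0, spec$attach_m < spec$n_nodes,
            spec$n_seeds > 0, spec$n_seeds <= spec$n_nodes,
            spec$n_planted_modules >= 0,
            spec$planted_size >= 4, spec$planted_size <= spec$n_nodes,
            spec$planted_density > 0.5,
            spec$n_terms > 0, spec$n_terms >= spec$n_planted_modules,
            spec$enriched_fraction > 0, spec$enriched_fraction <= 1)
  if (spec$planted_density > 1)
    stop("planted_density > 1 is unreachable without multi-edges")
  if (spec$n_planted_modules * spec$planted_size > spec$n_nodes)
    stop("planted modules (kept disjoint) do not fit in n_nodes")
  class(spec) <- "synthetic_spec"
  spec
}

synthetic_labels <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a synthetic interactome
#'
#' Scale-free backbone by linear preferential attachment (`attach_m` edges
#' per arriving node, no multi-edges), relabelled to synthetic symbols
#' `G000001...` so fixture networks stay disjoint from real gene
#' namespaces. Each planted module is a random disjoint subset of
#' `planted_size` nodes whose missing internal edges are added (in random
#' order) until the internal density reaches `planted_density`. The result
#' is deterministic given `rng_seed`; planted memberships are recorded in
#' the graph attribute `planted_modules`.
#'
#' @param spec a [synthetic_spec()].
#' @return an undirected simple igraph with `planted_modules` graph
#'   attribute (list of character vectors, possibly empty).
#' @export
generate_interactome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$rng_seed, {
    g <- igraph::sample_pa(spec$n_nodes, power = 1, m = spec$attach_m,
                           directed = FALSE, algorithm = "psumtree")
    igraph::V(g)$name <- synthetic_labels(spec$n_nodes)
    planted <- list()
    if (spec$n_planted_modules > 0) {
      # planted modules emulate distinct molecular complexes: memberships
      # are disjoint AND mutually non-adjacent in the backbone, so one
      # complex cannot bleed into another through a bridge edge
      for (try in seq_len(200L)) {
        pool <- sample(igraph::V(g)$name,
                       spec$n_planted_modules * spec$planted_size)
        planted <- split(pool, rep(seq_len(spec$n_planted_modules),
                                   each = spec$planted_size))
        grp <- rep(seq_along(planted), each = spec$planted_size)
        sub <- igraph::induced_subgraph(g, pool)
        el <- igraph::as_edgelist(sub)
        cross <- nrow(el) > 0 &&
          any(grp[match(el[, 1], pool)] != grp[match(el[, 2], pool)])
        if (!cross) break
        if (try == 200L)
          stop("could not place mutually non-adjacent planted modules; ",
               "reduce n_planted_modules or planted_size")
      }
      planted <- lapply(planted, sort)
      names(planted) <- sprintf("M%02d", seq_along(planted))
      n_pairs <- spec$planted_size * (spec$planted_size - 1) / 2
      need <- ceiling(spec$planted_density * n_pairs)
      for (members in planted) {
        pairs <- t(utils::combn(members, 2))
        have <- vapply(seq_len(nrow(pairs)), function(i)
          igraph::are_adjacent(g, pairs[i, 1], pairs[i, 2]), logical(1))
        missing <- which(!have)
        add <- need - (n_pairs - length(missing))
        if (add > 0) {
          pick <- missing[sample.int(length(missing), min(add, length(missing)))]
          g <- igraph::add_edges(g, as.vector(t(pairs[pick, , drop = FALSE])))
        }
      }
    }
    g$planted_modules <- planted
    igraph::V(g)$seed <- FALSE
    g
  })
}

#' Draw a synthetic seed list
#'
#' Uniform sample of `n_seeds` nodes without replacement, adjusted so that
#' every planted module contributes at least one seed (a non-planted
#' sampled node is swapped out for a random module member when needed).
#' Deterministic given `rng_seed`.
#'
#' @param network interactome from [generate_interactome()].
#' @param spec the matching [synthetic_spec()].
#' @return character vector of seed symbols, sorted.
#' @export
draw_seed_list <- function(network, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), is_ppi_network(network))
  nodes <- igraph::V(network)$name
  stopifnot(spec$n_seeds <= length(nodes))
  planted <- network$planted_modules
  withr::with_seed(spec$rng_seed + 1L, {
    seeds <- sample(nodes, spec$n_seeds)
    for (members in planted) {
      if (!any(members %in% seeds)) {
        in_any <- seeds %in% unlist(planted, use.names = FALSE)
        drop <- rev(which(!in_any))[1]
        if (is.na(drop)) drop <- length(seeds)
        seeds[drop] <- sample(members, 1)
      }
    }
    sort(seeds)
  })
}

#' Generate a planted-enrichment annotation catalog
#'
#' GO-like synthetic catalog over the network's node set: the first
#' `n_planted_modules` terms are each matched to one planted module and
#' contain `enriched_fraction` of that module's members plus random
#' background genes; the remaining terms are uniform random gene sets.
#' Term sizes are drawn uniformly between 10 and 50 genes, the typical
#' size range of informative GO biological-process terms. Deterministic
#' given `rng_seed`. The matched term ids are `TERM0001`,... in planted
#' module order, recorded in the catalog's `planted_terms` attribute.
#'
#' @param network interactome from [generate_interactome()].
#' @param spec the matching [synthetic_spec()].
#' @return an [annotation_catalog()] with universe = all network nodes and
#'   attribute `planted_terms` (named character vector, module id ->
#'   term id).
#' @export
generate_annotations <- function(network, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), is_ppi_network(network))
  nodes <- igraph::V(network)$name
  planted <- network$planted_modules
  stopifnot(spec$n_terms >= length(planted))
  withr::with_seed(spec$rng_seed + 2L, {
    sizes <- sample(10:50, spec$n_terms, replace = TRUE)
    ids <- sprintf("TERM%04d", seq_len(spec$n_terms))
    terms <- vector("list", spec$n_terms)
    names(terms) <- ids
    for (i in seq_len(spec$n_terms)) {
      if (i <= length(planted)) {
        members <- planted[[i]]
        core <- sample(members, max(1L, round(spec$enriched_fraction * length(members))))
        if (spec$enriched_fraction >= 1) core <- members
        fill <- max(0L, sizes[i] - length(core))
        bg <- sample(setdiff(nodes, members), fill)
        terms[[i]] <- sort(c(core, bg))
      } else {
        terms[[i]] <- sort(sample(nodes, sizes[i]))
      }
    }
    desc <- stats::setNames(sprintf("synthetic process %d", seq_len(spec$n_terms)), ids)
    cat <- annotation_catalog(terms, descriptions = desc, universe = nodes)
    attr(cat, "planted_terms") <-
      if (length(planted)) stats::setNames(ids[seq_along(planted)], names(planted))
      else stats::setNames(character(), character())
    cat
  })
}
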