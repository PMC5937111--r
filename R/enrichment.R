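#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P[X >= overlap]` for `X` hypergeometric: the
#' chance of drawing at least `overlap` term members when `module_size`
#' genes are drawn without replacement from a universe of `universe_size`
#' genes of which `term_size` carry the term.
#'
#' @param overlap observed overlap between module and term.
#' @param term_size number of term members in the universe.
#' @param module_size number of genes in the module.
#' @param universe_size size of the gene universe.
#' @return p-value in `[0, 1]`.
#' @export
hypergeometric_p <- function(overlap, term_size, module_size, universe_size) {
  if (overlap < 0 || term_size < 0 || module_size < 0 ||
      overlap > term_size || overlap > module_size ||
      term_size > universe_size || module_size > universe_size)
    stop("inconsistent hypergeometric arguments")
  stats::phyper(overlap - 1, term_size, universe_size - term_size,
                module_size, lower.tail = FALSE)
}

#' Bonferroni step-down (Holm) correction
#'
#' Sequentially-rejective multiple-testing correction: p-values are sorted
#' ascending, the i-th smallest is multiplied by `m - i + 1`, capped at 1,
#' and running maxima enforce monotonicity; results are returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return corrected p-values, same length and order.
#' @export
bonferroni_step_down <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}

#' Pairwise Cohen's kappa between annotation terms
#'
#' Chance-corrected agreement of the membership indicator vectors of every
#' term pair over a fixed gene scope: `kappa = (p_o - p_e) / (1 - p_e)`.
#' Identical indicator vectors score 1 by convention (even when expected
#' agreement is 1); non-identical vectors with `p_e = 1` score 0.
#'
#' @param catalog an [annotation_catalog()] (terms are restricted to the
#'   scope before comparison).
#' @param gene_scope character vector of genes over which agreement is
#'   measured.
#' @return symmetric numeric matrix with term ids as dimnames; diagonal 1.
#' @export
kappa_matrix <- function(catalog, gene_scope) {
  stopifnot(inherits(catalog, "annotation_catalog"), length(gene_scope) > 0)
  gene_scope <- unique(as.character(gene_scope))
  ids <- names(catalog$terms)
  ind <- vapply(catalog$terms, function(m) gene_scope %in% m,
                logical(length(gene_scope)))
  ind <- matrix(ind, nrow = length(gene_scope),
                dimnames = list(gene_scope, ids))
  k <- length(ids)
  km <- matrix(1, k, k, dimnames = list(ids, ids))
  if (k < 2) return(km)
  n <- length(gene_scope)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      km[i, j] <- km[j, i] <- cohen_kappa(ind[, i], ind[, j], n)
    }
  }
  km
}

cohen_kappa <- function(x, y, n) {
  if (identical(x, y)) return(1)
  a <- sum(x & y); b <- sum(x & !y); cc <- sum(!x & y); d <- n - a - b - cc
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Group annotation terms by kappa agreement
#'
#' Single-linkage grouping: terms are nodes, pairs with
#' `kappa >= threshold` are edges, and groups are the connected
#' components. The group id is the position of the component's
#' lexicographically smallest term in the sorted term list, so ids are
#' stable under input reordering.
#'
#' @param kappa symmetric kappa matrix with term-id dimnames.
#' @param threshold agreement threshold (default 0.4).
#' @return named integer vector, term id -> group id.
#' @export
group_terms <- function(kappa, threshold = 0.4) {
  stopifnot(is.matrix(kappa), nrow(kappa) == ncol(kappa))
  ids <- rownames(kappa)
  adj <- (kappa >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  sorted_ids <- sort(ids)
  rep_of <- vapply(split(ids, comp), function(mem) min(mem), character(1))
  gid <- match(rep_of[as.character(comp)], sorted_ids)
  stats::setNames(as.integer(gid), ids)
}

#' Over-representation analysis of one module
#'
#' Tests every catalog term overlapping the module with the one-sided
#' hypergeometric test against the catalog universe, corrects across the
#' module's tested terms by the Bonferroni step-down (Holm) procedure,
#' annotates kappa groups (agreement measured over the catalog universe),
#' and returns the `top_n` terms by corrected p-value (ties broken by
#' term id).
#'
#' @param module a `network_module`, or a character vector of member
#'   symbols.
#' @param catalog an [annotation_catalog()].
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05).
#' @param top_n number of top terms to report (default 3; all tested
#'   terms if fewer).
#' @param kappa_threshold term-grouping threshold (default 0.4).
#' @param module_id optional identifier copied into the result.
#' @return data frame with one row per reported term: `module_id`,
#'   `term_id`, `description`, `overlap`, `term_size`, `module_size`,
#'   `universe_size`, `p_value`, `p_corrected`, `significant`,
#'   `kappa_group`.
#' @export
enrich_module <- function(module, catalog, alpha = 0.05, top_n = 3L,
                          kappa_threshold = 0.4, module_id = NA_character_) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  members <- if (inherits(module, "network_module")) module$members
             else unique(as.character(module))
  if (length(members) == 0) stop("empty module")
  outside <- setdiff(members, catalog$universe)
  if (length(outside)) {
    warning(sprintf("%d module member(s) outside the annotation universe dropped",
                    length(outside)))
    members <- setdiff(members, outside)
  }
  if (length(members) == 0) stop("no module member in the annotation universe")
  uni_n <- length(catalog$universe)
  overlaps <- vapply(catalog$terms, function(m) length(intersect(m, members)),
                     integer(1))
  tested <- names(overlaps)[overlaps >= 1]
  if (length(tested) == 0)
    return(empty_enrichment())
  p <- vapply(tested, function(id)
    hypergeometric_p(overlaps[[id]], length(catalog$terms[[id]]),
                     length(members), uni_n), numeric(1))
  p_adj <- bonferroni_step_down(p)
  km <- kappa_matrix(
    annotation_catalog(catalog$terms[tested],
                       descriptions = catalog$descriptions[tested],
                       universe = catalog$universe),
    gene_scope = catalog$universe)
  groups <- group_terms(km, threshold = kappa_threshold)
  out <- data.frame(module_id = module_id,
                    term_id = tested,
                    description = as.character(catalog$descriptions[tested]),
                    overlap = as.integer(overlaps[tested]),
                    term_size = lengths(catalog$terms[tested]),
                    module_size = length(members),
                    universe_size = uni_n,
                    p_value = as.numeric(p),
                    p_corrected = as.numeric(p_adj),
                    significant = as.numeric(p_adj) <= alpha,
                    kappa_group = as.integer(groups[tested]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_corrected, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}

empty_enrichment <- function() {
  data.frame(module_id = character(), term_id = character(),
             description = character(), overlap = integer(),
             term_size = integer(), module_size = integer(),
             universe_size = integer(), p_value = numeric(),
             p_corrected = numeric(), significant = logical(),
             kappa_group = integer(), stringsAsFactors = FALSE)
}
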