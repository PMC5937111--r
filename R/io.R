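#' Read a differentially-expressed gene list
#'
#' One gene symbol per row (first column of a TSV). Duplicated symbols are
#' dropped, keeping first occurrence and original order, with a warning.
#'
#' @param path TSV file, one symbol per row (extra columns ignored).
#' @param direction `"up"` or `"down"`, the regulation direction tag
#'   attached to every record.
#' @param header `"auto"` (default) detects a `symbol` header row;
#'   `TRUE`/`FALSE` force the choice.
#' @return data frame with columns `symbol` (character) and `direction`
#'   (factor with levels up/down), one row per distinct symbol.
#' @export
read_gene_list <- function(path, direction = c("up", "down"), header = "auto") {
  direction <- match.arg(direction)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty gene list file: ", path)
  if (identical(header, "auto"))
    header <- tolower(trimws(strsplit(lines[1], "\t")[[1]][1])) %in%
      c("symbol", "gene", "gene_name", "id")
  if (isTRUE(header)) lines <- lines[-1]
  if (length(lines) == 0) stop("gene list file has a header but no rows: ", path)
  sym <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  sym <- trimws(sym)
  bad <- grep("\\s", sym)
  if (length(bad))
    stop(sprintf("symbol containing whitespace at row %d: '%s'", bad[1], sym[bad[1]]))
  dup <- duplicated(sym)
  if (any(dup))
    warning(sprintf("dropped %d duplicate symbol(s): %s", sum(dup),
                    paste(unique(sym[dup]), collapse = ", ")))
  data.frame(symbol = sym[!dup],
             direction = factor(direction, levels = c("up", "down")),
             stringsAsFactors = FALSE)
}

#' Read an interaction edge list
#'
#' Supports plain two-column TSV (`a<TAB>b` per row) and Cytoscape SIF
#' (`node relation target1 target2 ...`; a line with a single node declares
#' an isolated node). The result is a simple undirected graph: self-loops
#' and repeated pairs are collapsed (counts reported via `message()`).
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"sif"`.
#' @return network as built by [ppi_network()] (no seed flags set).
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  from <- character(); to <- character(); isolated <- character()
  if (dialect == "tsv") {
    for (i in seq_along(lines)) {
      tok <- strsplit(lines[i], "\t")[[1]]
      tok <- tok[nzchar(tok)]
      if (length(tok) < 2)
        stop(sprintf("line %d has fewer than 2 tokens: '%s'", i, lines[i]))
      from <- c(from, tok[1]); to <- c(to, tok[2])
    }
  } else {
    for (i in seq_along(lines)) {
      tok <- strsplit(lines[i], "[\t ]+")[[1]]
      tok <- tok[nzchar(tok)]
      if (length(tok) == 1) {
        isolated <- c(isolated, tok[1])
      } else if (length(tok) == 2) {
        stop(sprintf("SIF line %d has a relation but no target: '%s'", i, lines[i]))
      } else {
        tg <- tok[-(1:2)]
        from <- c(from, rep(tok[1], length(tg))); to <- c(to, tg)
      }
    }
  }
  ppi_network(edges = cbind(from, to), nodes = isolated)
}

#' Write an interaction edge list
#'
#' Canonical form: every edge written once as `min(a,b)<TAB>max(a,b)` (or
#' `a pp b` for SIF), edges sorted lexicographically, isolated nodes as
#' single-token lines (SIF) or omitted (TSV cannot represent them; a
#' warning is raised if any exist).
#'
#' @param network an undirected igraph.
#' @param path output file.
#' @param dialect `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  el <- igraph::as_edgelist(network)
  if (nrow(el)) {
    el <- t(apply(el, 1, sort))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  iso <- igraph::V(network)$name[igraph::degree(network) == 0]
  if (dialect == "tsv") {
    if (length(iso))
      warning(sprintf("%d isolated node(s) not representable in TSV edge list", length(iso)))
    writeLines(if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t") else character(), path)
  } else {
    writeLines(c(if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(),
                 sort(iso)), path)
  }
  invisible(path)
}

#' Construct an annotation catalog
#'
#' Container for GO-style gene-set annotations: named list of member sets,
#' matching descriptions, and the gene universe against which enrichment
#' is tested.
#'
#' @param terms named list of character vectors (term id -> member symbols).
#' @param descriptions named character vector of term descriptions
#'   (defaults to the term ids).
#' @param universe gene universe; defaults to the union of all members.
#' @return object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(terms, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  if (anyDuplicated(names(terms)))
    stop("duplicate term id: ", names(terms)[duplicated(names(terms))][1])
  sizes <- lengths(terms)
  if (any(sizes == 0))
    stop("empty term: ", names(terms)[sizes == 0][1])
  terms <- lapply(terms, function(m) unique(as.character(m)))
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  universe <- unique(as.character(universe))
  outside <- setdiff(unlist(terms, use.names = FALSE), universe)
  if (length(outside))
    stop("term member(s) outside the universe: ",
         paste(head(outside, 5L), collapse = ", "))
  if (is.null(descriptions)) descriptions <- stats::setNames(names(terms), names(terms))
  structure(list(terms = terms,
                 descriptions = descriptions[names(terms)],
                 universe = universe),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf("annotation catalog: %d terms over a universe of %d genes\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: `term-id<TAB>description<TAB>gene1<TAB>gene2...` per line.
#'
#' @param path GMT file.
#' @param universe optional explicit gene universe; default is the union
#'   of all term members.
#' @return an [annotation_catalog()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  terms <- list(); desc <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t")[[1]]
    if (length(tok) < 3)
      stop(sprintf("GMT line %d has no gene members: '%s'", i, lines[i]))
    id <- tok[1]
    if (id %in% names(terms)) stop("duplicate term id: ", id)
    terms[[id]] <- unique(tok[-(1:2)])
    desc[id] <- tok[2]
  }
  annotation_catalog(terms, descriptions = desc, universe = universe)
}

#' Write gene sets in GMT format
#'
#' @param catalog an [annotation_catalog()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  writeLines(vapply(names(catalog$terms), function(id) {
    paste(c(id, catalog$descriptions[[id]], catalog$terms[[id]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Load a screening configuration
#'
#' Reads a YAML file holding any subset of the pipeline's tunables and
#' merges it with the package defaults (which are the conventional
#' screening values): `hops` for neighbourhood expansion, an `mcode`
#' section (see [mcode_params()]), a `screen` section (see
#' [screen_params()]), a `module_filter` section (`min_score`,
#' `min_nodes`), and an `enrichment` section (`alpha`, `top_n`,
#' `kappa_threshold`).
#'
#' @param path YAML file; missing sections fall back to defaults.
#' @return list with elements `hops`, `mcode` (`mcode_params`), `screen`
#'   (`screen_params`), `module_filter`, `enrichment`.
#' @export
read_screen_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  pick <- function(section, fun, defaults) {
    args <- cfg[[section]]
    stopifnot(is.null(args) || is.list(args))
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
      stop(sprintf("unknown %s option(s): %s", section,
                   paste(unknown, collapse = ", ")))
    do.call(fun, utils::modifyList(defaults, args %||% list()))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  list(
    hops = as.integer(cfg$hops %||% 1L),
    mcode = pick("mcode", mcode_params,
                 list(node_score_cutoff = 0.2, k_core = 2L, degree_cutoff = 2L,
                      max_depth = 100L, haircut = TRUE, fluff = FALSE,
                      fluff_density = 0.1)),
    screen = pick("screen", screen_params,
                  list(top_k = 20L, degree_panel_cutoff = 1200)),
    module_filter = pick("module_filter", list,
                         list(min_score = 3, min_nodes = 6L)),
    enrichment = pick("enrichment", list,
                      list(alpha = 0.05, top_n = 3L, kappa_threshold = 0.4))
  )
}
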