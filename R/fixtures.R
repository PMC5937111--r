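#' Packaged laryngeal carcinoma screening tables
#'
#' Accessors for the plain-text fixtures shipped under
#' `inst/extdata/laryngeal/`: the 136 up- and 139 down-regulated protein
#' symbols of a tissue proteomics screen of laryngeal squamous cell
#' carcinoma, the printed top-20 hub (degree) and bottleneck (betweenness)
#' blocks of the up- and down-regulated PPI networks, and the detected
#' network modules with their printed hub proteins (hub-bottleneck
#' members are marked with an asterisk in the source table and carried
#' here as a flag). Identifiers are kept exactly as printed — no alias
#' unification — because the screening counts are only reproducible under
#' literal case-sensitive matching.
#'
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @return `laryngeal_gene_list()`: data frame of `symbol`, `direction`.
#' @name laryngeal_fixtures
NULL

laryngeal_path <- function(file) {
  system.file("extdata", "laryngeal", file, package = "ppiscreen",
              mustWork = TRUE)
}

#' @rdname laryngeal_fixtures
#' @export
laryngeal_gene_list <- function(direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  up <- read_gene_list(laryngeal_path("up_genes.tsv"), "up")
  down <- read_gene_list(laryngeal_path("down_genes.tsv"), "down")
  switch(direction, up = up, down = down, both = rbind(up, down))
}

#' @rdname laryngeal_fixtures
#' @return `laryngeal_centrality()`: a centrality table merging the
#'   printed hub-degree and bottleneck-BC blocks of one network. Symbols
#'   present in only one block get 0 for the missing quantity (they are
#'   outside that block's printed top 20, so any value below the block
#'   minimum preserves the printed ranking).
#' @export
laryngeal_centrality <- function(direction = c("up", "down")) {
  direction <- match.arg(direction)
  deg <- read.delim(laryngeal_path("hub_degree.tsv"), stringsAsFactors = FALSE)
  bcv <- read.delim(laryngeal_path("bottleneck_bc.tsv"), stringsAsFactors = FALSE)
  deg <- deg[deg$direction == direction, ]
  bcv <- bcv[bcv$direction == direction, ]
  sym <- union(deg$symbol, bcv$symbol)
  d <- stats::setNames(rep(0L, length(sym)), sym)
  d[deg$symbol] <- as.integer(deg$degree)
  b <- stats::setNames(rep(0, length(sym)), sym)
  b[bcv$symbol] <- bcv$bc
  suppressMessages(centrality_table(d, b))
}

#' @rdname laryngeal_fixtures
#' @return `laryngeal_degrees()`: named integer vector of every printed
#'   hub degree (both networks).
#' @export
laryngeal_degrees <- function() {
  deg <- read.delim(laryngeal_path("hub_degree.tsv"), stringsAsFactors = FALSE)
  stats::setNames(as.integer(deg$degree), deg$symbol)
}

#' @rdname laryngeal_fixtures
#' @return `laryngeal_modules()`: data frame of the printed module table
#'   (`direction`, `module_id`, `score`, `n_nodes`, `n_edges`, `seed`,
#'   `hubs` comma-joined, `hub_bottlenecks` comma-joined subset flagged
#'   in the source).
#' @export
laryngeal_modules <- function(direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  mod <- read.delim(laryngeal_path("modules.tsv"), stringsAsFactors = FALSE)
  if (direction != "both") mod <- mod[mod$direction == direction, ]
  parse_hubs <- function(s) {
    if (is.na(s) || s == "NA") return(character())
    strsplit(s, ",")[[1]]
  }
  raw <- lapply(mod$hubs, parse_hubs)
  mod$hubs <- vapply(raw, function(h) paste(sub("\\*$", "", h), collapse = ","),
                     character(1))
  mod$hub_bottlenecks <- vapply(raw, function(h)
    paste(sub("\\*$", "", h[grepl("\\*$", h)]), collapse = ","), character(1))
  rownames(mod) <- NULL
  mod
}

split_csv <- function(s) {
  out <- strsplit(s, ",")
  lapply(out, function(x) x[nzchar(x)])
}

#' Screening cascade over the printed tables
#'
#' Runs the full hub/bottleneck/module/panel cascade on the packaged
#' laryngeal fixtures: top-20 hubs and bottlenecks per network from the
#' printed centrality blocks, hub-bottleneck intersection per network,
#' module-membership filtering against the module table's flagged
#' hub-bottleneck proteins (the printed module table lists each module's
#' hub proteins, not full membership, so the flagged proteins are the
#' only printed anchor for module residency), and the inclusive
#' degree-1200 panel cutoff.
#'
#' @param params a [screen_params()].
#' @return list with per-direction hub/bottleneck/hub-bottleneck lists
#'   and the combined `hub_bottlenecks`, `module_resident`, `panel` sets.
#' @export
laryngeal_screen <- function(params = screen_params()) {
  per_dir <- lapply(c(up = "up", down = "down"), function(dir) {
    tab <- laryngeal_centrality(dir)
    hubs <- select_hubs(tab, params)
    bottlenecks <- select_bottlenecks(tab, params)
    list(hubs = hubs, bottlenecks = bottlenecks,
         hub_bottlenecks = intersect_hub_bottleneck(hubs, bottlenecks))
  })
  hb <- sort(c(per_dir$up$hub_bottlenecks, per_dir$down$hub_bottlenecks))
  mod <- laryngeal_modules()
  module_sets <- split_csv(mod$hub_bottlenecks)
  resident <- filter_by_module_membership(hb, module_sets)
  panel <- select_panel(resident, laryngeal_degrees(), params)
  list(up = per_dir$up, down = per_dir$down,
       hub_bottlenecks = hb, module_resident = resident, panel = panel)
}
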