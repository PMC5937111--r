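#' Screening parameters
#'
#' @param top_k number of hubs and of bottlenecks to select (default 20).
#' @param degree_panel_cutoff inclusive degree threshold of the final
#'   biomarker-panel selection (default 1200).
#' @return list of class `screen_params`.
#' @export
screen_params <- function(top_k = 20L, degree_panel_cutoff = 1200) {
  stopifnot(top_k >= 1)
  structure(list(top_k = as.integer(top_k),
                 degree_panel_cutoff = degree_panel_cutoff),
            class = "screen_params")
}

take_top <- function(table, rank_col, k) {
  tab <- table[order(table[[rank_col]]), , drop = FALSE]
  if (nrow(tab) < k) {
    warning(sprintf("table has only %d rows; returning all (top_k = %d)",
                    nrow(tab), k))
    k <- nrow(tab)
  }
  tab$symbol[seq_len(k)]
}

#' Select hub proteins
#'
#' The `top_k` symbols with highest degree (ties already broken
#' lexicographically in the centrality table's ranks).
#'
#' @param table a centrality table from [centrality_table()]/[rank_table()].
#' @param params a [screen_params()].
#' @return ordered character vector of hub symbols.
#' @export
select_hubs <- function(table, params = screen_params()) {
  stopifnot(nrow(table) > 0)
  take_top(table, "degree_rank", params$top_k)
}

#' Select bottleneck proteins
#'
#' The `top_k` symbols with highest betweenness centrality.
#'
#' @inheritParams select_hubs
#' @return ordered character vector of bottleneck symbols.
#' @export
select_bottlenecks <- function(table, params = screen_params()) {
  stopifnot(nrow(table) > 0)
  take_top(table, "bc_rank", params$top_k)
}

#' Hub-bottleneck intersection
#'
#' Literal case-sensitive set intersection of hub and bottleneck lists:
#' the key-protein criterion.
#'
#' @param hubs,bottlenecks character vectors of symbols.
#' @return character vector (sorted set).
#' @export
intersect_hub_bottleneck <- function(hubs, bottlenecks) {
  sort(intersect(hubs, bottlenecks))
}

#' Restrict candidates to module residents
#'
#' Keeps the hub-bottleneck candidates that belong to at least one
#' detected network module.
#'
#' @param hub_bottlenecks character vector of candidate symbols.
#' @param modules list of `network_module` objects (or of character
#'   member vectors).
#' @return character vector (sorted set).
#' @export
filter_by_module_membership <- function(hub_bottlenecks, modules) {
  members <- unlist(lapply(modules, function(m)
    if (inherits(m, "network_module")) m$members else as.character(m)),
    use.names = FALSE)
  sort(intersect(hub_bottlenecks, unique(members)))
}

#' Degree-cutoff biomarker panel selection
#'
#' Final screening step: keep candidates whose degree is at least
#' `degree_panel_cutoff` (inclusive).
#'
#' @param candidates character vector of symbols.
#' @param degrees named integer vector covering every candidate.
#' @param params a [screen_params()].
#' @return character vector (sorted set).
#' @export
select_panel <- function(candidates, degrees, params = screen_params()) {
  candidates <- unique(as.character(candidates))
  missing <- setdiff(candidates, names(degrees))
  if (length(missing))
    stop("no degree entry for candidate(s): ", paste(missing, collapse = ", "))
  sort(candidates[degrees[candidates] >= params$degree_panel_cutoff])
}

#' Run the full screening cascade
#'
#' Hub selection, bottleneck selection, hub-bottleneck intersection,
#' module-membership filtering, and degree-cutoff panel selection, with
#' the monotone-cascade invariant (panel within module residents within
#' hub-bottlenecks within hubs-or-bottlenecks) asserted on every run.
#'
#' @param table centrality table of the analysed network.
#' @param modules list of `network_module` objects (or member vectors).
#' @param params a [screen_params()].
#' @param degrees optional named degree vector; defaults to the table's
#'   `degree` column.
#' @return list of class `screen_result` with elements `hubs`,
#'   `bottlenecks`, `hub_bottlenecks`, `module_resident`, `panel`.
#' @export
screen_cascade <- function(table, modules, params = screen_params(),
                           degrees = NULL) {
  if (is.null(degrees))
    degrees <- stats::setNames(table$degree, table$symbol)
  hubs <- select_hubs(table, params)
  bottlenecks <- select_bottlenecks(table, params)
  hb <- intersect_hub_bottleneck(hubs, bottlenecks)
  resident <- filter_by_module_membership(hb, modules)
  panel <- select_panel(resident, degrees, params)
  stopifnot(all(panel %in% resident), all(resident %in% hb),
            all(hb %in% union(hubs, bottlenecks)))
  structure(list(hubs = hubs, bottlenecks = bottlenecks,
                 hub_bottlenecks = hb, module_resident = resident,
                 panel = panel),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0("screening cascade: %d hubs, %d bottlenecks -> %d ",
                     "hub-bottlenecks -> %d module-resident -> panel of %d\n"),
              length(x$hubs), length(x$bottlenecks),
              length(x$hub_bottlenecks), length(x$module_resident),
              length(x$panel)))
  if (length(x$panel))
    cat("panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}
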