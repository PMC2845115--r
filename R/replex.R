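#' Conflict graph over a set of assays
#'
#' Nodes are assays; an edge joins two assays whose analytes (optionally
#' including adduct-shifted satellites) come closer than `min_gap` Da, i.e.
#' whose peaks could not be told apart if the two assays shared a pool.
#'
#' @param assays List of [sbe_assay()] objects.
#' @param mass_table A [mass_table()].
#' @param min_gap Minimum tolerated cross-assay mass gap (Da).
#' @param include_adducts Compare adduct-shifted masses too (default FALSE).
#' @return An object of class `conflict_graph`: list with `nodes` (assay
#'   ids) and `edges` (two-column character matrix of unordered pairs).
#' @export
build_conflict_graph <- function(assays, mass_table = default_mass_table(),
                                 min_gap = 16, include_adducts = FALSE) {
  stopifnot(min_gap > 0)
  ids <- vapply(assays, `[[`, character(1), "assay_id")
  names(assays) <- ids
  edges <- list()
  n <- length(assays)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      cf <- pool_conflicts(assays[c(i, j)], mass_table, min_gap = min_gap,
                           include_adducts = include_adducts)
      if (nrow(cf))
        edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
    }
  }
  structure(
    list(nodes = ids,
         edges = if (length(edges)) do.call(rbind, edges) else
           matrix(character(), ncol = 2)),
    class = "conflict_graph")
}

#' @export
print.conflict_graph <- function(x, ...) {
  cat(sprintf("<conflict_graph> %d assays, %d conflict edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

conflict_matrix <- function(graph) {
  n <- length(graph$nodes)
  m <- matrix(FALSE, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges))
    for (r in seq_len(nrow(graph$edges))) {
      m[graph$edges[r, 1], graph$edges[r, 2]] <- TRUE
      m[graph$edges[r, 2], graph$edges[r, 1]] <- TRUE
    }
  m
}

#' Re-plex assays into mass-resolvable pools
#'
#' Greedy first-fit-decreasing pooling over the conflict graph: assays are
#' sorted by descending conflict degree (ties by ascending assay id) and
#' each is placed into the first existing pool that contains no conflicting
#' assay and has fewer than `max_plex` members, opening a new pool
#' otherwise. The output always validates conflict-free at the stated
#' `min_gap`; singleton pools make any instance feasible.
#'
#' @param assays List of [sbe_assay()] objects to pool.
#' @param mass_table A [mass_table()].
#' @param max_plex Maximum assays per pool (>= 1, default 9).
#' @param min_gap Minimum cross-assay analyte gap in Da (default 16).
#' @param include_adducts Include adduct-shifted masses in the conflict
#'   predicate (default FALSE).
#' @param name Name of the produced panel.
#' @return An [sbe_panel()] with pools named `"plex1"`, `"plex2"`, ....
#' @export
replex <- function(assays, mass_table = default_mass_table(), max_plex = 9,
                   min_gap = 16, include_adducts = FALSE,
                   name = "replexed") {
  stopifnot(max_plex >= 1)
  graph <- build_conflict_graph(assays, mass_table, min_gap = min_gap,
                                include_adducts = include_adducts)
  conf <- conflict_matrix(graph)
  ids <- graph$nodes
  deg <- rowSums(conf)
  order_ids <- ids[order(-deg, ids)]
  pools <- list()
  for (id in order_ids) {
    placed <- FALSE
    for (p in seq_along(pools)) {
      if (length(pools[[p]]) < max_plex &&
          !any(conf[id, pools[[p]]])) {
        pools[[p]] <- c(pools[[p]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) pools[[length(pools) + 1L]] <- id
  }
  names(pools) <- sprintf("plex%d", seq_along(pools))
  names(assays) <- vapply(assays, `[[`, character(1), "assay_id")
  panel <- sbe_panel(name, assays, pools, mass_table, max_plex = max_plex)
  leftover <- panel_conflicts(panel, min_gap = min_gap,
                              include_adducts = include_adducts)
  stopifnot(nrow(leftover) == 0L)
  panel
}

#' Provably minimal pooling for small instances
#'
#' Exhaustive branch-and-bound over pool assignments: tries pool counts from
#' the trivial lower bound `ceiling(n / max_plex)` upward, searching assays
#' in ascending id order with symmetry breaking (an assay may only open the
#' next unopened pool), so the first feasible assignment found is the
#' lexicographically least partition at the minimal pool count.
#'
#' @inheritParams replex
#' @param max_n Refuse instances larger than this (default 12).
#' @return An [sbe_panel()] with the provably minimal number of pools.
#' @export
replex_optimal <- function(assays, mass_table = default_mass_table(),
                           max_plex = 9, min_gap = 16,
                           include_adducts = FALSE, name = "optimal",
                           max_n = 12) {
  n <- length(assays)
  if (n > max_n)
    stop(sprintf("instance too large for exhaustive search (n = %d > %d)",
                 n, max_n), call. = FALSE)
  stopifnot(max_plex >= 1, n >= 1)
  graph <- build_conflict_graph(assays, mass_table, min_gap = min_gap,
                                include_adducts = include_adducts)
  conf <- conflict_matrix(graph)
  ids <- sort(graph$nodes)
  assign_pools <- function(k) {
    pool_of <- integer(n)
    search <- function(i, n_open) {
      if (i > n) return(TRUE)
      for (p in seq_len(min(n_open + 1L, k))) {
        members <- ids[which(pool_of[seq_len(i - 1L)] == p)]
        if (length(members) >= max_plex) next
        if (any(conf[ids[i], members])) next
        pool_of[i] <<- p
        if (search(i + 1L, max(n_open, p))) return(TRUE)
      }
      pool_of[i] <<- 0L
      FALSE
    }
    if (search(1L, 0L)) pool_of else NULL
  }
  k <- ceiling(n / max_plex)
  repeat {
    sol <- assign_pools(k)
    if (!is.null(sol)) break
    k <- k + 1L
  }
  pools <- split(ids, sol)
  names(pools) <- sprintf("plex%d", seq_along(pools))
  names(assays) <- vapply(assays, `[[`, character(1), "assay_id")
  panel <- sbe_panel(name, assays, pools, mass_table, max_plex = max_plex)
  attr(panel, "optimal_pool_count") <- length(pools)
  panel
}
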