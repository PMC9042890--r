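#' Signed shortest paths from one element
#'
#' Breadth-first search over the signed graph. The sign (type) of a path is
#' the product of its edge signs; a target first reached at the minimal
#' depth with both signs has no unambiguous type and is flagged
#' inconsistent. The search runs over states `(node, sign)`, so a node can
#' be reached once per sign; the minimal depth per sign is recorded and the
#' two are reconciled into one record per reachable target.
#'
#' @param graph A [mim_graph].
#' @param from Source element id.
#' @param max_depth Maximum path length in edges (`Inf` for unlimited).
#' @return A tibble with one row per distinct reachable target: `source`,
#'   `target`, `length` (edge count of the shortest path), `sign` (`-1`,
#'   `+1`, or `0` when inconsistent), `consistent` (logical). Unreachable
#'   pairs and the self pair are absent — no sentinel rows.
#' @export
shortest_paths_from <- function(graph, from, max_depth = Inf) {
  check_element(graph, from)
  if (!is.infinite(max_depth) && max_depth < 1) {
    stop_twodea("`max_depth` must be >= 1.", class = "twodea_usage_error")
  }
  dist <- signed_bfs(graph, from, max_depth = max_depth)
  dist_to_records(graph, from, dist)
}

# BFS over (node, sign) states; returns an n x 2 integer matrix of minimal
# depths (col 1: cumulative sign +1, col 2: -1), NA where unreached.
# reverse = TRUE walks in-edges, yielding SP(u -> src) lengths for all u.
signed_bfs <- function(graph, src, max_depth = Inf, reverse = FALSE) {
  n <- nrow(graph$elements)
  s <- graph$idx[[src]]
  adj <- if (reverse) graph$in_adj else graph$out_adj
  other_end <- if (reverse) graph$edge_from else graph$edge_to
  esign <- graph$edge_sign
  dist <- matrix(NA_integer_, n, 2L)
  dist[s, 1L] <- 0L
  fr_nodes <- s
  fr_signs <- 1L # 1 encodes cumulative sign +1, 2 encodes -1
  d <- 0L
  while (length(fr_nodes) && d < max_depth) {
    d <- d + 1L
    eidx <- unlist(adj[fr_nodes], use.names = FALSE)
    if (!length(eidx)) break
    reps <- lengths(adj[fr_nodes])
    from_sign <- rep(fr_signs, reps)
    ys <- other_end[eidx]
    flip <- esign[eidx] == -1L
    new_sign <- ifelse(xor(from_sign == 2L, flip), 2L, 1L)
    first <- !duplicated(ys + n * (new_sign - 1L))
    ys <- ys[first]
    new_sign <- new_sign[first]
    unvis <- is.na(dist[cbind(ys, new_sign)])
    ys <- ys[unvis]
    new_sign <- new_sign[unvis]
    if (!length(ys)) break
    dist[cbind(ys, new_sign)] <- d
    fr_nodes <- ys
    fr_signs <- new_sign
  }
  dist
}

dist_to_records <- function(graph, from, dist, reverse = FALSE) {
  ids <- graph$elements$id
  s <- graph$idx[[from]]
  dp <- dist[, 1L]
  dn <- dist[, 2L]
  reached <- (!is.na(dp) | !is.na(dn)) & seq_along(ids) != s
  v <- which(reached)
  if (!length(v)) {
    return(tibble(source = character(), target = character(),
                  length = integer(), sign = integer(),
                  consistent = logical()))
  }
  L <- pmin(dp[v], dn[v], na.rm = TRUE)
  both <- !is.na(dp[v]) & !is.na(dn[v]) & dp[v] == dn[v]
  sgn <- ifelse(both, 0L, ifelse(!is.na(dp[v]) & (is.na(dn[v]) | dp[v] < dn[v]),
                                 1L, -1L))
  out <- tibble(
    source = if (reverse) ids[v] else rep(ids[s], length(v)),
    target = if (reverse) rep(ids[s], length(v)) else ids[v],
    length = as.integer(L),
    sign = as.integer(sgn),
    consistent = !both
  )
  arrange(out, .data$source, .data$target)
}

#' All-pairs signed shortest-path table
#'
#' Runs [shortest_paths_from()] from every source (or a subset) and binds
#' the records. This is the precomputation step: the influence recursions
#' only ever consult path lengths up to 2 edges, so `max_depth = 2` is a
#' fast path when the table is built solely to feed influence scoring.
#'
#' @inheritParams shortest_paths_from
#' @param sources Character vector of source ids, or `NULL` for all.
#' @return Tibble as in [shortest_paths_from()].
#' @export
path_table <- function(graph, sources = NULL, max_depth = Inf) {
  sources <- sources %||% graph$elements$id
  purrr::map_dfr(sources, shortest_paths_from, graph = graph,
                 max_depth = max_depth)
}

#' Write / read a path table as TSV
#'
#' Columns `u`, `v`, `L`, `T`, `consistent`; supports precomputing path
#' analytics once and reusing them across analyses.
#' @param paths Tibble from [path_table()].
#' @param path Output file.
#' @return `write_path_table()` the path, invisibly; `read_path_table()` the
#'   tibble.
#' @export
write_path_table <- function(paths, path) {
  out <- data.frame(u = paths$source, v = paths$target, L = paths$length,
                    T = paths$sign, consistent = paths$consistent)
  write_tsv_plain(out, path)
  invisible(path)
}

#' @rdname write_path_table
#' @export
read_path_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tibble(source = as.character(tab$u), target = as.character(tab$v),
         length = as.integer(tab$L), sign = as.integer(tab$T),
         consistent = as.logical(tab$consistent))
}

# --- submap path census (feeds the phenotype influence base case) ---------

# Enumerates simple paths (vertex sequences, parallel edges collapsed) from
# each submap member u to the phenotype v inside the submap-induced
# subgraph, capped at max_path_len edges. "Number of paths to v" is
# ill-defined on cyclic subgraphs, so the cap is a declared, documented
# parameter of the method rather than an internal constant.
path_census <- function(graph, v, max_path_len = 8) {
  check_element(graph, v, "phenotype")
  if (element_type(graph, v) != "phenotype") {
    stop_twodea(sprintf("'%s' is not a phenotype.", v),
                class = "twodea_usage_error")
  }
  vs <- regulator_sets(graph, v)$submap
  empty <- list(n_paths = 0L, n_paths_u = integer(0), n_elements = 0L,
                n_elements_u = integer(0), on_path = list())
  if (!length(vs)) {
    return(empty)
  }
  nodes <- c(vs, v)
  ia <- graph$interactions
  sub <- ia[ia$source %in% nodes & ia$target %in% nodes, , drop = FALSE]
  if (!nrow(sub)) {
    return(empty)
  }
  ig <- igraph::graph_from_data_frame(
    sub[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = nodes))
  ig <- igraph::simplify(ig, remove.multiple = TRUE, remove.loops = TRUE)
  on_path <- list()
  path_sets <- list()
  for (u in vs) {
    ps <- igraph::all_simple_paths(ig, from = u, to = v, mode = "out",
                                   cutoff = max_path_len)
    if (!length(ps)) next
    seqs <- purrr::map(ps, ~ names(.x))
    path_sets[[u]] <- seqs
    on_path[[u]] <- sort(setdiff(unique(unlist(seqs)), v))
  }
  all_paths <- unlist(path_sets, recursive = FALSE, use.names = FALSE)
  n_paths <- length(all_paths)
  connected <- names(on_path) %||% character()
  n_paths_u <- vapply(connected, function(u) {
    sum(vapply(all_paths, function(p) u %in% p, logical(1)))
  }, integer(1))
  n_elements_u <- setNames(lengths(on_path), connected)
  list(
    n_paths = n_paths,
    n_paths_u = n_paths_u,
    n_elements = length(connected),
    n_elements_u = n_elements_u,
    on_path = on_path
  )
}

#' Elements on submap paths to a phenotype
#'
#' For each element `u` sharing a submap with phenotype `v`, the set of
#' elements lying on simple paths from `u` to `v` within the submap-induced
#' subgraph (paths capped at `max_path_len` edges), including `u` and
#' excluding `v`. Elements with no such path are absent from the result.
#'
#' @param graph A [mim_graph].
#' @param v A phenotype id with submap membership.
#' @param max_path_len Cap on counted path length, in edges.
#' @return Named list: element id -> character vector of on-path elements.
#' @export
on_path_elements <- function(graph, v, max_path_len = 8) {
  path_census(graph, v, max_path_len)$on_path
}

#' Submap path counts for a phenotype
#'
#' The count statistics behind the phenotype-influence base case: the total
#' number of counted (simple, capped) submap paths into `v`, the number
#' passing through each element, the number of submap elements connected to
#' `v`, and the per-element on-path element counts.
#'
#' @inheritParams on_path_elements
#' @return List with `n_paths`, `n_paths_u` (named), `n_elements`,
#'   `n_elements_u` (named). Degenerate submaps yield zero counts and empty
#'   maps.
#' @export
count_paths <- function(graph, v, max_path_len = 8) {
  cen <- path_census(graph, v, max_path_len)
  cen[c("n_paths", "n_paths_u", "n_elements", "n_elements_u")]
}
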