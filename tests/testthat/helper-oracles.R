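# Independent literal-formula oracles. These deliberately share no code
# with the package internals: paths by recursive depth-first enumeration
# of simple paths, influence and enrichment statistics by direct
# transcription of their defining formulas.

# every simple path from each source, as (target, length, sign product);
# reduced to minimal length and the set of signs attained at it
oracle_path_records <- function(graph, max_len = Inf) {
  ia <- graph$interactions
  ids <- graph$elements$id
  out <- list()
  for (u in ids) {
    hits <- new.env(parent = emptyenv()) # v -> matrix of (L, sign)
    walk <- function(node, sign, depth, visited) {
      if (depth >= max_len) return(invisible())
      rows <- which(ia$source == node)
      for (r in rows) {
        v <- ia$target[r]
        if (v %in% visited) next
        s2 <- sign * ia$sign[r]
        hits[[v]] <- rbind(hits[[v]], c(depth + 1L, s2))
        walk(v, s2, depth + 1L, c(visited, v))
      }
    }
    walk(u, 1L, 0L, u)
    for (v in ls(hits)) {
      m <- hits[[v]]
      L <- min(m[, 1])
      signs <- unique(m[m[, 1] == L, 2])
      out[[paste(u, v, sep = "|")]] <-
        list(source = u, target = v, length = L,
             sign = if (length(signs) == 1) signs else 0L,
             consistent = length(signs) == 1)
    }
  }
  out
}

oracle_records_tbl <- function(records) {
  tab <- dplyr::bind_rows(lapply(records, function(r) {
    tibble::tibble(source = r$source, target = r$target,
                   length = as.integer(r$length), sign = as.integer(r$sign),
                   consistent = r$consistent)
  }))
  dplyr::arrange(tab, source, target)
}

# lookup helper over the oracle records
orc_sp <- function(records, u, v) records[[paste(u, v, sep = "|")]]

# literal class-influence (transcriptional / catalytic) evaluation
oracle_class_influence <- function(graph, v, iclass, records) {
  ia <- graph$interactions
  base_rows <- ia[ia$target == v & ia$iclass == iclass, , drop = FALSE]
  members <- unique(base_rows$source)
  base <- vapply(members, function(k) sum(base_rows$sign[base_rows$source == k]),
                 numeric(1))
  scores <- base[base != 0]
  for (u in setdiff(graph$elements$id, c(members, v))) {
    s <- 0
    for (k in members) {
      sp <- orc_sp(records, u, k)
      if (is.null(sp) || sp$length > 2 || !sp$consistent) next
      s <- s + base[[k]] * sp$sign / 2^sp$length
    }
    s <- max(-1, min(1, s))
    if (s != 0) scores[[u]] <- s
  }
  scores
}

# independent simple-path enumeration on the submap-induced subgraph
oracle_submap_census <- function(graph, v, max_path_len = 8) {
  el <- graph$elements
  sm <- el$submaps[[match(v, el$id)]]
  vs <- setdiff(unique(unlist(
    lapply(seq_len(nrow(el)),
           function(i) if (length(intersect(el$submaps[[i]], sm))) el$id[i]))),
    v)
  nodes <- c(vs, v)
  ia <- graph$interactions
  pairs <- unique(ia[ia$source %in% nodes & ia$target %in% nodes,
                     c("source", "target")])
  paths <- list()
  for (u in vs) {
    walk <- function(node, depth, visited) {
      if (node == v) {
        paths[[length(paths) + 1L]] <<- visited[visited != v]
        return(invisible())
      }
      if (depth >= max_path_len) return(invisible())
      nxt <- pairs$target[pairs$source == node]
      for (w in nxt) {
        if (w %in% visited) next
        walk(w, depth + 1L, c(visited, w))
      }
    }
    walk(u, 0L, u)
  }
  # paths end without v appended; visited excludes v by construction
  starts <- vapply(paths, `[`, "", 1)
  connected <- sort(unique(starts))
  list(
    n_paths = length(paths),
    n_paths_u = vapply(connected, function(u)
      sum(vapply(paths, function(p) u %in% p, logical(1))), integer(1)),
    n_elements = length(connected),
    n_elements_u = vapply(connected, function(u)
      length(unique(unlist(paths[starts == u]))), integer(1)),
    on_path = setNames(lapply(connected, function(u)
      sort(unique(unlist(paths[starts == u])))), connected)
  )
}

oracle_phenotype_influence <- function(graph, v, records, max_path_len = 8) {
  el <- graph$elements
  sm <- el$submaps[[match(v, el$id)]]
  vs <- setdiff(unique(unlist(
    lapply(seq_len(nrow(el)),
           function(i) if (length(intersect(el$submaps[[i]], sm))) el$id[i]))),
    v)
  if (!length(vs)) return(numeric(0))
  cen <- oracle_submap_census(graph, v, max_path_len)
  base <- setNames(numeric(length(vs)), vs)
  for (u in names(cen$n_paths_u)) {
    sp <- orc_sp(records, u, v)
    if (is.null(sp) || !sp$consistent) next
    base[[u]] <- sp$sign * (cen$n_paths_u[[u]] / cen$n_paths +
                              cen$n_elements_u[[u]] / cen$n_elements)
  }
  cap <- max(abs(base), 0)
  scores <- base
  for (u in setdiff(el$id, c(vs, v))) {
    s <- 0
    for (k in vs) {
      sp <- orc_sp(records, u, k)
      if (is.null(sp) || sp$length > 2 || !sp$consistent) next
      s <- s + base[[k]] * sp$sign / 2^sp$length
    }
    if (s != 0 && cap > 0) scores[[u]] <- sign(s) * min(abs(s), cap)
  }
  scores <- scores[scores != 0]
  m <- if (length(scores)) max(abs(scores)) else 0
  if (m > 0) scores <- scores / m
  scores
}

# enrichment statistics by direct formula transcription
oracle_level <- function(i, fc) sum(i * fc)
oracle_saturation <- function(i_dce, i_all) sum(abs(i_dce)) / sum(abs(i_all))
oracle_es <- function(i, fc, k) {
  sum(abs(i * fc) * i * fc) / (k + sum(i^2 * fc^2))
}
# regression-through-origin construction: project points onto the
# diagonals, append the two baseline points (+-sqrt(k/2), 0)
oracle_es_regression <- function(i, fc, k) {
  x <- c(fc * abs(i), sqrt(k / 2), -sqrt(k / 2))
  y <- c(abs(fc) * i, 0, 0)
  sum(x * y) / sum(x^2)
}
oracle_sensitivity <- function(i, fc) sum(i * fc) / sum(abs(fc))
oracle_specificity <- function(i_nondce) {
  sum(1 - abs(i_nondce)) / length(i_nondce)
}
oracle_upstream_es <- function(i, fc) {
  sum(abs(i * fc) * i * fc) / (sum(abs(fc[i == 0])) + sum(i^2 * fc^2))
}

# influence columns as named vectors for comparison
col_to_vec <- function(tbl, v) {
  sel <- tbl$target == v
  setNames(tbl$score[sel], tbl$source[sel])
}

expect_named_equal <- function(got, want, tol = 1e-10) {
  got <- got[order(names(got))]
  want <- want[order(names(want))]
  testthat::expect_equal(names(got), names(want))
  testthat::expect_equal(unname(got), unname(want), tolerance = tol)
}
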