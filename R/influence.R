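#' Influence scores
#'
#' Influence scores quantify the directed effect of one element on another
#' in the signed interaction graph, as a number in `[-1, 1]`. Three contexts
#' are defined, each anchored in a base set of direct regulators and
#' propagated upstream by signed shortest paths:
#'
#' * **transcriptional** — influence of `u` on a gene `v`, anchored in `v`'s
#'   transcription factors. A TF's influence equals its edge sign (`+1`
#'   induction, `-1` suppression). A non-TF element aggregates, over every
#'   TF `k` it reaches within two edges, the TF's influence times the sign
#'   of the shortest `u -> k` path, halved per path edge
#'   (`/ 2^L`); the aggregate is clamped to `[-1, 1]`.
#' * **catalytic** — identical structure with `v`'s enzymes as the base set
#'   (`+1` synthesis, `-1` consumption).
#' * **phenotype** — influence of `u` on a phenotype `v`, anchored in `v`'s
#'   submap neighbourhood. For a submap member the base score is the signed
#'   shortest-path type times its share of counted submap paths and on-path
#'   elements; outside elements aggregate as above with the aggregate's
#'   magnitude capped at the largest base magnitude. The finished column is
#'   divided by its maximum absolute value, so it spans `[-1, 1]` with at
#'   least one entry of magnitude 1.
#'
#' Pairs whose shortest path is inconsistent (equal-length paths of opposite
#' sign) contribute nothing. Self-influence is never computed. Zero scores
#' are not stored: absent means "no effect".
#'
#' @param graph A [mim_graph].
#' @param v Target element id (a gene/transcriptional target, metabolite, or
#'   phenotype depending on context).
#' @param paths Optional precomputed path table from [path_table()]; when
#'   `NULL` the two-edge reverse searches are run on demand.
#' @param quiet Suppress log messages about skipped pairs (net-zero parallel
#'   edges, inconsistent paths).
#' @return A tibble with columns `source`, `target`, `context`, `score`,
#'   `provenance` (`"base"` or `"aggregated"`).
#' @name influence
NULL

clamp1 <- function(x) {
  out <- pmax(pmin(x, 1), -1)
  names(out) <- names(x)
  out
}

# net sign of the direct class-edges from each base-set member to v;
# parallel +1/-1 edges cancel to 0 (the pair is then skipped and logged)
base_signs <- function(graph, v, members, iclass, quiet = FALSE) {
  ia <- graph$interactions
  sel <- ia$target == v & ia$iclass == iclass & ia$source %in% members
  sgn <- tapply(ia$sign[sel], ia$source[sel], sum)
  sgn <- setNames(as.numeric(sgn), names(sgn))
  zero <- names(sgn)[sgn == 0]
  if (length(zero) && !quiet) {
    inform(sprintf(
      "net-zero parallel edges: %s -> %s dropped from the base set value.",
      paste(zero, collapse = ", "), v))
  }
  sgn[match(members, names(sgn))]
}

# all u with a consistent shortest path into `to` of <= 2 edges,
# as a tibble (source, length, sign); served from `paths` when supplied
reach_within2 <- function(graph, to, paths = NULL, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[to]])) {
    return(cache[[to]])
  }
  rec <- if (!is.null(paths)) {
    paths[paths$target == to & paths$length <= 2L, , drop = FALSE]
  } else {
    dist_to_records(graph, to,
                    signed_bfs(graph, to, max_depth = 2, reverse = TRUE),
                    reverse = TRUE)
  }
  rec <- rec[, c("source", "length", "sign")]
  if (!is.null(cache)) cache[[to]] <- rec
  rec
}

# shared aggregation step of all three recursions: for u outside the base
# set, I(u, v) = sum over base members k reached within two edges of
# I(k, v) * T(SP_{u,k}) / 2^L(SP_{u,k}); inconsistent paths carry sign 0
aggregate_upstream <- function(graph, v, base_vals, paths = NULL,
                               cache = NULL) {
  acc <- new.env(parent = emptyenv())
  for (k in names(base_vals)) {
    bk <- base_vals[[k]]
    if (is.na(bk) || bk == 0) next
    rec <- reach_within2(graph, k, paths = paths, cache = cache)
    if (!nrow(rec)) next
    contrib <- bk * rec$sign / 2^rec$length
    for (j in seq_len(nrow(rec))) {
      u <- rec$source[j]
      if (u == v || u %in% names(base_vals)) next
      acc[[u]] <- (acc[[u]] %||% 0) + contrib[j]
    }
  }
  vals <- unlist(as.list(acc), use.names = TRUE)
  if (is.null(vals)) setNames(numeric(0), character(0)) else vals
}

influence_tbl <- function(v, context, base_vals, agg_vals) {
  out <- tibble(
    source = c(names(base_vals), names(agg_vals)),
    target = v,
    context = context,
    score = c(unname(base_vals), unname(agg_vals)),
    provenance = c(rep("base", length(base_vals)),
                   rep("aggregated", length(agg_vals)))
  )
  out <- out[!is.na(out$score) & out$score != 0, , drop = FALSE]
  arrange(out, .data$source)
}

#' @rdname influence
#' @export
transcriptional_influence <- function(graph, v, paths = NULL, quiet = FALSE) {
  check_element(graph, v)
  class_influence(graph, v, "transcriptional", paths, quiet)
}

#' @rdname influence
#' @export
catalytic_influence <- function(graph, v, paths = NULL, quiet = FALSE) {
  check_element(graph, v)
  class_influence(graph, v, "catalytic", paths, quiet)
}

class_influence <- function(graph, v, context, paths = NULL, quiet = FALSE,
                            cache = NULL) {
  members <- if (context == "transcriptional") {
    unique(graph$tf[[v]] %||% character())
  } else {
    unique(graph$enzymes[[v]] %||% character())
  }
  iclass <- context
  if (!length(members)) {
    return(influence_tbl(v, context, setNames(numeric(0), character(0)),
                         setNames(numeric(0), character(0))))
  }
  base_vals <- base_signs(graph, v, members, iclass, quiet = quiet)
  names(base_vals) <- members
  agg <- aggregate_upstream(graph, v, base_vals, paths = paths, cache = cache)
  agg <- clamp1(agg)
  influence_tbl(v, context, base_vals, agg)
}

#' @rdname influence
#' @param max_path_len Cap (in edges) on counted simple submap paths feeding
#'   the phenotype base case.
#' @export
phenotype_influence <- function(graph, v, paths = NULL, max_path_len = 8,
                                quiet = FALSE) {
  check_element(graph, v)
  phenotype_influence_impl(graph, v, paths, max_path_len, quiet)
}

phenotype_influence_impl <- function(graph, v, paths = NULL, max_path_len = 8,
                                     quiet = FALSE, cache = NULL) {
  vs <- regulator_sets(graph, v)$submap
  if (!length(vs)) {
    if (!quiet) {
      warn(sprintf("phenotype '%s' has no submap regulators; empty column.",
                   v))
    }
    return(influence_tbl(v, "phenotype", setNames(numeric(0), character(0)),
                         setNames(numeric(0), character(0))))
  }
  cen <- path_census(graph, v, max_path_len)
  sp_to_v <- if (!is.null(paths)) {
    paths[paths$target == v, , drop = FALSE]
  } else {
    dist_to_records(graph, v, signed_bfs(graph, v, reverse = TRUE),
                    reverse = TRUE)
  }
  tsp <- setNames(sp_to_v$sign, sp_to_v$source)

  base_vals <- setNames(numeric(length(vs)), vs)
  for (u in names(cen$n_paths_u)) {
    tu <- unname(tsp[u])
    if (is.na(tu) || tu == 0L) {
      if (!quiet && !is.na(tu)) {
        inform(sprintf("inconsistent shortest path %s -> %s skipped.", u, v))
      }
      next
    }
    base_vals[[u]] <- tu * (cen$n_paths_u[[u]] / cen$n_paths +
                              cen$n_elements_u[[u]] / cen$n_elements)
  }

  cap <- max(abs(base_vals), 0)
  agg <- aggregate_upstream(graph, v, base_vals, paths = paths, cache = cache)
  if (length(agg) && cap > 0) {
    agg <- sign(agg) * pmin(abs(agg), cap)
  }
  col <- influence_tbl(v, "phenotype", base_vals, agg)
  # normalization happens once the full column (base + aggregated) exists
  m <- if (nrow(col)) max(abs(col$score)) else 0
  if (m > 0) col$score <- col$score / m
  col
}

#' Build an influence table
#'
#' Batch driver over [transcriptional_influence()], [catalytic_influence()]
#' or [phenotype_influence()]: one sparse column per target, bound into a
#' single tibble. Deterministic: recomputing, or saving with
#' [write_influence()] and reloading, reproduces the table exactly. Two-edge
#' reverse reachability around shared regulators is cached across columns.
#'
#' @param graph A [mim_graph].
#' @param context `"transcriptional"`, `"catalytic"` or `"phenotype"`.
#' @param targets Character vector of target ids, or `"all"`: every element
#'   with at least one in-edge of the context's class (every phenotype for
#'   the phenotype context).
#' @inheritParams influence
#' @return Tibble with columns `source`, `target`, `context`, `score`,
#'   `provenance`.
#' @export
build_influence <- function(graph, context = c("transcriptional", "catalytic",
                                               "phenotype"),
                            targets = "all", paths = NULL, max_path_len = 8,
                            quiet = TRUE) {
  context <- match.arg(context)
  if (identical(targets, "all")) {
    targets <- switch(
      context,
      transcriptional = sort(unique(names(graph$tf))),
      catalytic = sort(unique(names(graph$enzymes))),
      phenotype = sort(graph$elements$id[graph$elements$bio_type ==
                                           "phenotype"])
    )
  } else {
    for (v in targets) check_element(graph, v)
    targets <- sort(unique(targets))
  }
  cache <- new.env(parent = emptyenv())
  purrr::map_dfr(targets, function(v) {
    if (context == "phenotype") {
      phenotype_influence_impl(graph, v, paths, max_path_len, quiet = quiet,
                               cache = cache)
    } else {
      class_influence(graph, v, context, paths, quiet = quiet, cache = cache)
    }
  })
}

#' Extract one influence column or row as a named vector
#'
#' `influence_on()` returns the scores of all elements on target `v`
#' (a column, used by downstream enrichment); `influence_from()` returns
#' the scores of source `v` on all its targets (a row, used by upstream
#' enrichment, where the candidate target's effect on the data elements is
#' what matters).
#'
#' @param influence Tibble from [build_influence()].
#' @param v Element id.
#' @return Named numeric vector (names are the other endpoint's ids).
#' @export
influence_on <- function(influence, v) {
  sel <- influence$target == v
  setNames(influence$score[sel], influence$source[sel])
}

#' @rdname influence_on
#' @export
influence_from <- function(influence, v) {
  sel <- influence$source == v
  setNames(influence$score[sel], influence$target[sel])
}

#' Persist influence tables
#'
#' TSV (`u`, `v`, `context`, `score`) or sparse-triplet JSON. Scores are
#' written with 17 significant digits, so save/load round-trips are exact
#' and reloaded tables are bit-identical to freshly computed ones.
#'
#' @param influence Tibble from [build_influence()].
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `write_influence()` the path invisibly; `read_influence()` the
#'   tibble.
#' @export
write_influence <- function(influence, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(u = influence$source, v = influence$target,
                     context = influence$context,
                     score = sprintf("%.17g", influence$score),
                     provenance = influence$provenance)
    write_tsv_plain(df, path)
  } else {
    obj <- list(u = influence$source, v = influence$target,
                context = influence$context, score = influence$score,
                provenance = influence$provenance)
    writeLines(jsonlite::toJSON(obj, digits = I(17), pretty = TRUE), path,
               useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_influence
#' @export
read_influence <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    out <- tibble(source = tab$u, target = tab$v, context = tab$context,
                  score = as.numeric(tab$score), provenance = tab$provenance)
  } else {
    obj <- jsonlite::fromJSON(path)
    out <- tibble(source = obj$u, target = obj$v, context = obj$context,
                  score = obj$score, provenance = obj$provenance)
  }
  out
}
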