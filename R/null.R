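#' Type-stratified permutation null
#'
#' Builds the randomized reference distribution for an enrichment
#' statistic. Each of the `n` randomized DCE lists keeps the original list's
#' cardinality and exact multiset of fold-change values; only the element
#' identities are redrawn, uniformly without replacement among all map
#' elements of the same biological type as the entry being replaced. The
#' generator is seeded and the seed recorded, so a null model is exactly
#' reproducible.
#'
#' @param graph A [mim_graph].
#' @param dces A `dce_set`.
#' @param statistic Function `(element_ids, fc) -> numeric(1)` evaluated on
#'   each randomized list (e.g. a closure around [enrichment_score()]).
#' @param n Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `null_model`: list with `n`, `values` (the n statistic values),
#'   `perm_ids` (element-id matrix, one column per permutation), `fc`,
#'   `seed`.
#' @export
permutation_null <- function(graph, dces, statistic, n = 1000, seed = 1) {
  if (n < 2) stop_twodea("`n` must be >= 2.", class = "twodea_usage_error")
  ids <- permute_dce_ids(graph, dces, n = n, seed = seed)
  values <- vapply(seq_len(n), function(j) statistic(ids[, j], dces$fc),
                   numeric(1))
  structure(list(n = n, values = values, perm_ids = ids, fc = dces$fc,
                 seed = seed),
            class = "null_model")
}

# identity matrix of randomized DCE lists: |DCE| rows, n columns; row i is
# always an element of the same bio_type as dces$element[i]
permute_dce_ids <- function(graph, dces, n, seed) {
  m <- nrow(dces)
  out <- matrix(NA_character_, m, n)
  if (m == 0) {
    return(out)
  }
  types <- element_type(graph, dces$element)
  if (anyNA(types)) {
    stop_twodea(sprintf("DCE element(s) not in the graph: %s",
                        paste(dces$element[is.na(types)], collapse = ", ")),
                class = "twodea_data_error")
  }
  with_seed(seed, {
    for (t in unique(types)) {
      rows <- which(types == t)
      pool <- graph$elements$id[graph$elements$bio_type == t]
      if (length(pool) < length(rows)) {
        stop_twodea(sprintf(
          "cannot permute %d DCE(s) of type '%s': only %d map element(s) of that type.",
          length(rows), t, length(pool)),
          class = "twodea_data_error")
      }
      for (j in seq_len(n)) {
        out[rows, j] <- sample(pool, length(rows), replace = FALSE)
      }
    }
  })
  out
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> n = %d, seed = %s, mean = %.4g, sd = %.4g\n",
              x$n, format(x$seed), mean(x$values), stats::sd(x$values)))
  invisible(x)
}
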