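# Small graphs built in code; no fixture files.

toy_elements <- function(ids, types, submaps = NULL) {
  tibble::tibble(id = ids, bio_type = types,
                 submaps = submaps %||% vector("list", length(ids)))
}

toy_edges <- function(...) {
  # each argument: c(source, sign, target, class)
  rows <- list(...)
  tibble::tibble(
    source = vapply(rows, `[`, "", 1),
    sign = as.integer(vapply(rows, `[`, "", 2)),
    target = vapply(rows, `[`, "", 3),
    iclass = vapply(rows, `[`, "", 4)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A -> G (+, transcriptional), B -> G (-, transcriptional)
toy_tf_graph <- function() {
  mim_graph(
    toy_elements(c("A", "B", "G"), c("protein", "protein", "gene")),
    toy_edges(c("A", "1", "G", "transcriptional"),
              c("B", "-1", "G", "transcriptional")),
    quiet = TRUE
  )
}

# linear submap a -> b -> v (generic, all positive)
toy_linear_submap <- function() {
  mim_graph(
    toy_elements(c("a", "b", "v"), c("protein", "protein", "phenotype"),
                 submaps = list("s", "s", "s")),
    toy_edges(c("a", "1", "b", "generic"),
              c("b", "1", "v", "generic")),
    quiet = TRUE
  )
}

# random signed typed digraph; sparse enough for exhaustive path oracles
random_mim <- function(seed, n = NULL, p_neg = 0.4, with_phenotype = TRUE) {
  set.seed(seed)
  n <- n %||% sample(6:25, 1)
  ids <- sprintf("n%02d", seq_len(n))
  types <- sample(c("gene", "protein", "metabolite"), n, replace = TRUE)
  m <- max(4L, round(1.6 * n))
  src <- sample(ids, m, replace = TRUE)
  tgt <- sample(ids, m, replace = TRUE)
  keep <- src != tgt
  src <- src[keep]
  tgt <- tgt[keep]
  sgn <- sample(c(-1L, 1L), length(src), replace = TRUE,
                prob = c(p_neg, 1 - p_neg))
  cls <- sample(c("transcriptional", "catalytic", "generic"), length(src),
                replace = TRUE)
  submaps <- vector("list", n)
  if (with_phenotype) {
    pi <- sample(n, 1)
    types[pi] <- "phenotype"
    members <- sample(setdiff(seq_len(n), pi), min(n - 1L, 6L))
    for (i in c(pi, members)) submaps[[i]] <- "sm1"
  }
  mim_graph(tibble::tibble(id = ids, bio_type = types, submaps = submaps),
            tibble::tibble(source = src, sign = sgn, target = tgt,
                           iclass = cls),
            quiet = TRUE)
}

random_dces <- function(graph, n_dce, seed, bio_type = NULL) {
  set.seed(seed)
  pool <- graph$elements$id
  if (!is.null(bio_type)) {
    pool <- graph$elements$id[graph$elements$bio_type %in% bio_type]
  }
  n_dce <- min(n_dce, length(pool))
  dce_set(sample(pool, n_dce), fc = rnorm(n_dce, 0, 2))
}
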