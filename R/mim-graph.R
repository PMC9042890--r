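#' Build a molecular interaction map graph
#'
#' Constructs the signed, typed, directed interaction graph that all analyses
#' in this package operate on. Elements (vertices) carry a biological type and
#' optional submap memberships; interactions (edges) are triples
#' `(source, sign, target)` with `sign` in `{-1, +1}`, annotated with an
#' interaction class (`transcriptional`, `catalytic` or `generic`) that
#' determines how regulator sets are populated.
#'
#' The constructor validates the tables, canonicalises row order (elements by
#' id, interactions by source/target/sign/class, so the graph is independent
#' of input row order), collapses duplicate `(source, sign, target)` triples,
#' and builds adjacency and regulator caches:
#' * `tf[[v]]` — sources of transcriptional in-edges of `v`,
#' * `enzymes[[v]]` — sources of catalytic in-edges of `v` (a `+1` edge is
#'   synthesis, a `-1` edge is consumption),
#' * `submap_members[[s]]` — element ids belonging to submap `s`.
#'
#' @param elements Data frame with columns `id` (unique, non-missing), `name`
#'   (defaults to `id`), `bio_type` (one of gene, protein, metabolite,
#'   phenotype, complex, miRNA, lncRNA, other; unknown values are mapped to
#'   `other` with a warning), and optionally `submaps` (list column of
#'   character vectors, or a `;`-separated string column).
#' @param interactions Data frame with columns `source`, `sign` (`-1` or
#'   `+1`), `target`, and optionally `iclass` (defaults to `generic`, with a
#'   warning when the column is absent).
#' @param quiet Suppress informational messages about collapsed duplicate
#'   edges and coerced biological types.
#'
#' @return An object of class `mim_graph`.
#' @examples
#' g <- mim_graph(
#'   elements = data.frame(id = c("A", "B", "G"),
#'                         bio_type = c("protein", "protein", "gene")),
#'   interactions = data.frame(source = c("A", "B"), sign = c(1, -1),
#'                             target = c("G", "G"),
#'                             iclass = "transcriptional")
#' )
#' regulator_sets(g, "G")$tf
#' @export
mim_graph <- function(elements, interactions, quiet = FALSE) {
  elements <- normalise_elements(elements, quiet = quiet)
  interactions <- normalise_interactions(interactions, elements$id,
                                         quiet = quiet)

  n_input <- attr(interactions, "n_input_rows")
  n_collapsed <- attr(interactions, "n_collapsed")

  g <- structure(
    list(
      elements = elements,
      interactions = interactions,
      n_input_rows = n_input,
      n_collapsed = n_collapsed
    ),
    class = "mim_graph"
  )
  g <- build_caches(g)
  g
}

normalise_elements <- function(elements, quiet = FALSE) {
  elements <- as_tibble(elements)
  if (!all(c("id") %in% names(elements))) {
    stop_twodea("element table must have an `id` column.",
                class = "twodea_load_error")
  }
  elements$id <- as.character(elements$id)
  if (anyNA(elements$id) || any(elements$id == "")) {
    stop_twodea("element ids must be non-missing, non-empty strings.",
                class = "twodea_load_error")
  }
  dup <- unique(elements$id[duplicated(elements$id)])
  if (length(dup) > 0) {
    stop_twodea(sprintf("duplicate element id(s): %s",
                        paste(dup, collapse = ", ")),
                class = "twodea_load_error")
  }
  if (!"name" %in% names(elements)) elements$name <- elements$id
  elements$name <- as.character(elements$name)
  if (!"bio_type" %in% names(elements)) elements$bio_type <- "other"
  elements$bio_type <- as.character(elements$bio_type)
  unknown <- !(elements$bio_type %in% BIO_TYPES) | is.na(elements$bio_type)
  if (any(unknown)) {
    if (!quiet) {
      warn(sprintf("%d element(s) with unknown bio_type mapped to 'other': %s",
                   sum(unknown),
                   paste(head(unique(elements$bio_type[unknown]), 5),
                         collapse = ", ")))
    }
    elements$bio_type[unknown] <- "other"
  }
  if (!"submaps" %in% names(elements)) {
    elements$submaps <- vector("list", nrow(elements))
  } else if (!is.list(elements$submaps)) {
    elements$submaps <- strsplit(
      ifelse(is.na(elements$submaps), "", as.character(elements$submaps)), ";",
      fixed = TRUE)
  }
  elements$submaps <- lapply(elements$submaps, function(s) {
    s <- as.character(s)
    sort(unique(s[!is.na(s) & s != ""]))
  })
  if (!"xrefs" %in% names(elements)) elements$xrefs <- vector("list", nrow(elements))
  elements <- elements[, c("id", "name", "bio_type", "submaps", "xrefs")]
  arrange(elements, .data$id)
}

normalise_interactions <- function(interactions, ids, quiet = FALSE) {
  interactions <- as_tibble(interactions)
  needed <- c("source", "sign", "target")
  if (!all(needed %in% names(interactions))) {
    stop_twodea("interaction table must have columns source, sign, target.",
                class = "twodea_load_error")
  }
  n_input <- nrow(interactions)
  interactions$source <- as.character(interactions$source)
  interactions$target <- as.character(interactions$target)
  sign_num <- suppressWarnings(as.integer(as.character(interactions$sign)))
  bad_sign <- is.na(sign_num) | !(sign_num %in% c(-1L, 1L))
  if (any(bad_sign)) {
    stop_twodea(sprintf(
      "interaction sign must be -1 or +1; offending row(s): %s",
      paste(head(which(bad_sign), 5), collapse = ", ")),
      class = "twodea_load_error")
  }
  interactions$sign <- sign_num
  if (!"iclass" %in% names(interactions)) {
    if (!quiet) {
      warn("no interaction `iclass` column; all interactions set to 'generic'.")
    }
    interactions$iclass <- "generic"
  }
  interactions$iclass <- as.character(interactions$iclass)
  interactions$iclass[is.na(interactions$iclass) |
                        interactions$iclass == ""] <- "generic"
  bad_class <- !(interactions$iclass %in% INTERACTION_CLASSES)
  if (any(bad_class)) {
    stop_twodea(sprintf(
      "unknown interaction class(es): %s",
      paste(unique(interactions$iclass[bad_class]), collapse = ", ")),
      class = "twodea_load_error")
  }
  dangling <- setdiff(c(interactions$source, interactions$target), ids)
  if (length(dangling) > 0) {
    stop_twodea(sprintf("interaction endpoint(s) not in element table: %s",
                        paste(head(dangling, 10), collapse = ", ")),
                class = "twodea_load_error")
  }
  selfloop <- interactions$source == interactions$target
  if (any(selfloop)) {
    stop_twodea(sprintf("self-loop interaction(s) are not allowed: %s",
                        paste(head(unique(interactions$source[selfloop]), 5),
                              collapse = ", ")),
                class = "twodea_load_error")
  }

  # set semantics over (source, sign, target); class conflicts resolved by a
  # fixed priority so the result is row-order independent
  interactions$iclass <- factor(interactions$iclass,
                                levels = INTERACTION_CLASSES)
  interactions <- interactions[, c("source", "sign", "target", "iclass")]
  interactions <- arrange(interactions, .data$source, .data$target,
                          .data$sign, .data$iclass)
  key <- paste(interactions$source, interactions$sign, interactions$target,
               sep = "\r")
  dups <- duplicated(key)
  n_collapsed <- sum(dups)
  if (n_collapsed > 0 && !quiet) {
    inform(sprintf("collapsed %d duplicate interaction triple(s).",
                   n_collapsed))
  }
  interactions <- interactions[!dups, ]
  interactions$iclass <- as.character(interactions$iclass)
  attr(interactions, "n_input_rows") <- n_input
  attr(interactions, "n_collapsed") <- n_collapsed
  interactions
}

build_caches <- function(g) {
  ids <- g$elements$id
  idx <- setNames(seq_along(ids), ids)
  si <- idx[g$interactions$source]
  ti <- idx[g$interactions$target]
  n <- length(ids)
  g$idx <- idx
  g$edge_from <- unname(si)
  g$edge_to <- unname(ti)
  g$edge_sign <- g$interactions$sign
  g$out_adj <- split(seq_len(nrow(g$interactions)), factor(si, levels = seq_len(n)))
  g$in_adj <- split(seq_len(nrow(g$interactions)), factor(ti, levels = seq_len(n)))
  names(g$out_adj) <- ids
  names(g$in_adj) <- ids

  is_tr <- g$interactions$iclass == "transcriptional"
  is_cat <- g$interactions$iclass == "catalytic"
  g$tf <- split(g$interactions$source[is_tr], g$interactions$target[is_tr])
  g$enzymes <- split(g$interactions$source[is_cat],
                     g$interactions$target[is_cat])

  memb <- tidyr::unnest(
    tibble(id = g$elements$id, submap = g$elements$submaps),
    "submap")
  g$submap_members <- if (nrow(memb) > 0) {
    split(memb$id, memb$submap)
  } else {
    list()
  }
  g
}

#' @export
print.mim_graph <- function(x, ...) {
  tt <- table(x$elements$bio_type)
  cat(sprintf("<mim_graph> %d elements, %d interactions, %d submap(s)\n",
              nrow(x$elements), nrow(x$interactions),
              length(x$submap_members)))
  cat("  bio types:",
      paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", "),
      "\n")
  invisible(x)
}

has_element <- function(graph, id) id %in% graph$elements$id

check_element <- function(graph, id, what = "element") {
  assert_scalar_chr(id, what)
  if (!has_element(graph, id)) {
    stop_twodea(sprintf("%s '%s' not found in the graph.", what, id),
                class = "twodea_lookup_error")
  }
  invisible(id)
}

element_type <- function(graph, id) {
  graph$elements$bio_type[match(id, graph$elements$id)]
}

#' Regulator sets of an element
#'
#' Returns the three regulator sets that parameterise the influence-score
#' recursions: the transcription factors of `v` (sources of transcriptional
#' in-edges), the synthesizing/consuming enzymes of `v` (sources of catalytic
#' in-edges, where the edge sign distinguishes synthesis `+1` from
#' consumption `-1`), and the submap neighbourhood of `v` (all elements
#' sharing a submap with `v`, excluding `v` itself).
#'
#' @param graph A [mim_graph].
#' @param v Element id.
#' @return A list with character-vector components `tf`, `enzymes`, `submap`.
#' @export
regulator_sets <- function(graph, v) {
  check_element(graph, v)
  submaps_v <- graph$elements$submaps[[match(v, graph$elements$id)]]
  vs <- unique(unlist(graph$submap_members[submaps_v], use.names = FALSE))
  list(
    tf = sort(unique(graph$tf[[v]] %||% character())),
    enzymes = sort(unique(graph$enzymes[[v]] %||% character())),
    submap = sort(setdiff(vs %||% character(), v))
  )
}

#' Validate a molecular interaction map
#'
#' Reporting operation: censuses the graph (elements per biological type,
#' interactions per sign and class) and lists structural violations. On a
#' graph built by [mim_graph()] the hard violations (dangling endpoints,
#' illegal signs, duplicate ids) cannot occur — they are load errors — so the
#' violation list flags the soft conditions: phenotypes without submap
#' membership or without any in-edge (isolated phenotypes cannot be enriched).
#'
#' @param graph A [mim_graph].
#' @return A list with `n_elements`, `n_interactions`, `bio_type_counts`,
#'   `sign_counts`, `class_counts` and a tibble `violations`
#'   (columns `kind`, `id`, `detail`).
#' @export
mim_validate <- function(graph) {
  el <- graph$elements
  ia <- graph$interactions
  viol <- list()

  dangling <- setdiff(c(ia$source, ia$target), el$id)
  for (d in dangling) {
    viol[[length(viol) + 1L]] <- tibble(kind = "dangling_id", id = d,
                                        detail = "endpoint not in element table")
  }
  bad_sign <- which(!(ia$sign %in% c(-1L, 1L)))
  for (i in bad_sign) {
    viol[[length(viol) + 1L]] <- tibble(
      kind = "illegal_sign", id = paste0(ia$source[i], "->", ia$target[i]),
      detail = sprintf("sign = %s", ia$sign[i]))
  }
  phen <- el$id[el$bio_type == "phenotype"]
  for (p in phen) {
    if (length(graph$in_adj[[p]]) == 0L) {
      viol[[length(viol) + 1L]] <- tibble(kind = "isolated_phenotype", id = p,
                                          detail = "phenotype has no in-edges")
    }
    if (length(regulator_sets(graph, p)$submap) == 0L) {
      viol[[length(viol) + 1L]] <- tibble(kind = "phenotype_no_submap", id = p,
                                          detail = "phenotype has empty submap neighbourhood")
    }
  }

  list(
    n_elements = nrow(el),
    n_interactions = nrow(ia),
    n_input_rows = graph$n_input_rows,
    n_collapsed = graph$n_collapsed,
    bio_type_counts = table(factor(el$bio_type, levels = BIO_TYPES)),
    sign_counts = table(factor(ia$sign, levels = c(-1L, 1L))),
    class_counts = table(factor(ia$iclass, levels = INTERACTION_CLASSES)),
    violations = if (length(viol)) bind_rows(viol) else
      tibble(kind = character(), id = character(), detail = character())
  )
}
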