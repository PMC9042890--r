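#' Specify a synthetic molecular interaction map
#'
#' Parameters of the layered synthetic map built by [make_network()]. The
#' defaults draw a ~50-element map that mirrors, at reduced scale, the
#' composition of a curated disease map: a protein signalling layer feeding
#' transcription factors, a transcriptional layer (TF -> gene), a metabolic
#' layer (enzyme -> metabolite), and phenotypes anchored in submaps of
#' connected regulators.
#'
#' @param n_tfs,n_genes,n_enzymes,n_metabolites,n_signal,n_phenotypes Layer
#'   sizes.
#' @param tf_per_gene Range (min, max) of transcriptional in-edges per gene.
#' @param enz_per_metabolite Range of catalytic in-edges per metabolite.
#' @param sig_per_tf Range of generic signalling in-edges per TF.
#' @param submap_size Elements per phenotype submap (drawn from genes and
#'   signalling proteins).
#' @param neg_fraction Fraction of negative edges, exactly realized up to
#'   rounding.
#' @param seed Integer seed; generation is a pure function of spec + seed.
#' @return A `network_spec` list.
#' @export
network_spec <- function(n_tfs = 8, n_genes = 20, n_enzymes = 5,
                         n_metabolites = 6, n_signal = 8, n_phenotypes = 3,
                         tf_per_gene = c(1, 3), enz_per_metabolite = c(1, 2),
                         sig_per_tf = c(1, 2), submap_size = 6,
                         neg_fraction = 0.3, seed = 1) {
  spec <- list(n_tfs = n_tfs, n_genes = n_genes, n_enzymes = n_enzymes,
               n_metabolites = n_metabolites, n_signal = n_signal,
               n_phenotypes = n_phenotypes, tf_per_gene = tf_per_gene,
               enz_per_metabolite = enz_per_metabolite,
               sig_per_tf = sig_per_tf, submap_size = submap_size,
               neg_fraction = neg_fraction, seed = seed)
  counts <- unlist(spec[c("n_tfs", "n_genes", "n_enzymes", "n_metabolites",
                          "n_signal", "n_phenotypes")])
  if (any(counts < 1)) {
    stop_twodea("all layer sizes must be positive.",
                class = "twodea_generation_error")
  }
  if (neg_fraction < 0 || neg_fraction > 1) {
    stop_twodea("`neg_fraction` must be in [0, 1].",
                class = "twodea_generation_error")
  }
  if (submap_size < 1 || submap_size > n_genes + n_signal) {
    stop_twodea("`submap_size` must fit inside the gene + signalling layers.",
                class = "twodea_generation_error")
  }
  structure(spec, class = "network_spec")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic interaction map
#'
#' Builds the layered signed digraph described by a [network_spec()]:
#' signalling proteins regulate TFs and each other (generic edges), TFs
#' regulate genes (transcriptional), enzymes synthesize or consume
#' metabolites (catalytic), and each phenotype owns a submap whose members
#' (genes and signalling proteins) form a connected regulator subgraph
#' ending in the phenotype. Edge signs are assigned so the requested
#' negative fraction is realized exactly up to rounding. The result always
#' passes [mim_validate()] with zero violations, and identical specs give
#' byte-identical canonical serializations.
#'
#' @param spec A `network_spec`.
#' @return A [mim_graph].
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(spec$seed, {
    tfs <- sprintf("TF%02d", seq_len(spec$n_tfs))
    genes <- sprintf("G%03d", seq_len(spec$n_genes))
    enzymes <- sprintf("ENZ%02d", seq_len(spec$n_enzymes))
    mets <- sprintf("MET%02d", seq_len(spec$n_metabolites))
    sigs <- sprintf("SIG%02d", seq_len(spec$n_signal))
    phens <- sprintf("PHEN%02d", seq_len(spec$n_phenotypes))

    edges <- list()
    add_edges <- function(src, tgt, iclass) {
      tibble(source = src, target = tgt, iclass = iclass)
    }
    # transcriptional layer
    edges$tr <- purrr::map_dfr(genes, function(g) {
      add_edges(sample(tfs, min(rint(1, spec$tf_per_gene), spec$n_tfs)),
                g, "transcriptional")
    })
    # catalytic layer
    edges$cat <- purrr::map_dfr(mets, function(m) {
      add_edges(sample(enzymes,
                       min(rint(1, spec$enz_per_metabolite), spec$n_enzymes)),
                m, "catalytic")
    })
    # signalling layer: signal -> TF, signal -> signal, signal -> enzyme
    edges$sig_tf <- purrr::map_dfr(tfs, function(tf) {
      add_edges(sample(sigs, min(rint(1, spec$sig_per_tf), spec$n_signal)),
                tf, "generic")
    })
    if (spec$n_signal >= 2) {
      pairs <- t(replicate(max(2, spec$n_signal %/% 2),
                           sample(sigs, 2, replace = FALSE)))
      edges$sig_sig <- add_edges(pairs[, 1], pairs[, 2], "generic")
    }
    edges$sig_enz <- add_edges(sample(sigs, spec$n_enzymes, replace = TRUE),
                               enzymes, "generic")

    # phenotype submaps: a shuffled member chain ending at the phenotype,
    # plus direct shortcut edges, so every member reaches the phenotype
    submaps <- setNames(vector("list", spec$n_phenotypes), phens)
    edges$sub <- purrr::map_dfr(seq_along(phens), function(i) {
      v <- phens[i]
      members <- sample(c(genes, sigs), spec$submap_size)
      submaps[[v]] <<- members
      chain <- add_edges(members[-length(members)], members[-1], "generic")
      tail_edge <- add_edges(members[length(members)], v, "generic")
      n_short <- max(1L, spec$submap_size %/% 3L)
      shortcuts <- add_edges(sample(members[-length(members)],
                                    min(n_short, length(members) - 1L)),
                             v, "generic")
      bind_rows(chain, tail_edge, shortcuts)
    })

    all_edges <- distinct(bind_rows(edges),
                          .data$source, .data$target, .data$iclass)
    ne <- nrow(all_edges)
    sign_vec <- rep(1L, ne)
    n_neg <- round(spec$neg_fraction * ne)
    if (n_neg > 0) sign_vec[sample(ne, n_neg)] <- -1L
    all_edges$sign <- sign_vec

    bio <- c(setNames(rep("protein", length(tfs)), tfs),
             setNames(rep("gene", length(genes)), genes),
             setNames(rep("protein", length(enzymes)), enzymes),
             setNames(rep("metabolite", length(mets)), mets),
             setNames(rep("protein", length(sigs)), sigs),
             setNames(rep("phenotype", length(phens)), phens))
    submap_of <- lapply(names(bio), function(id) {
      hits <- names(submaps)[purrr::map_lgl(submaps, ~ id %in% .x)]
      if (id %in% phens) hits <- c(hits, id)
      if (length(hits)) paste0("sm_", hits) else character()
    })
    elements <- tibble(id = names(bio), name = names(bio),
                       bio_type = unname(bio), submaps = submap_of)
    mim_graph(elements, all_edges, quiet = TRUE)
  })
}

#' Generate topology-independent null differential data
#'
#' Draws `n_dce` element identities of one biological type uniformly at
#' random (independently of the network topology), with fold changes from
#' `Normal(0, fc_sd)` and adjusted p-values uniform below the significance
#' threshold, so every row passes the default filters. This is the
#' calibration input: analyses run on it should show uniform p-values.
#'
#' @param graph A [mim_graph].
#' @param n_dce Number of rows.
#' @param fc_sd Standard deviation of the log2 fold changes.
#' @param bio_type Element type to sample.
#' @param p_threshold Significance threshold the adjusted p-values fall
#'   under.
#' @param sample Sample label used in the column names.
#' @param seed Integer seed.
#' @return A wide data table (`symbol`, `FC_<sample>`, `padj_<sample>`)
#'   accepted by [filter_dces()].
#' @export
make_null_dces <- function(graph, n_dce = 30, fc_sd = 2, bio_type = "gene",
                           p_threshold = 0.05, sample = "s1", seed = 1) {
  pool <- graph$elements$id[graph$elements$bio_type == bio_type]
  if (n_dce > length(pool)) {
    stop_twodea(sprintf("n_dce = %d exceeds the %d element(s) of type '%s'.",
                        n_dce, length(pool), bio_type),
                class = "twodea_data_error")
  }
  with_seed(seed, {
    ids <- base::sample(pool, n_dce)
    out <- tibble(symbol = ids,
                  fc = rnorm(n_dce, 0, fc_sd),
                  padj = runif(n_dce, 0, p_threshold))
  })
  names(out) <- c("symbol", paste0("FC_", sample), paste0("padj_", sample))
  out
}

#' Generate differential data with a planted regulator signal
#'
#' Emulates an experiment in which one map entity truly drives the
#' measured changes. Elements under the planted entity's influence
#' ("responders", a fraction of its regulon) receive
#' `FC = effect * sign(I) + noise` and significant adjusted p-values;
#' all other elements of the data type receive pure noise and
#' non-significant p-values, so default filtering recovers exactly the
#' responders. The p-value construction is synthetic — uniform below/above
#' the threshold — not a model of real differential testing.
#'
#' @param graph A [mim_graph].
#' @param influence Influence table: target-to-data rows for an upstream
#'   planting (e.g. transcriptional context), or a phenotype context table
#'   when `target` is a phenotype.
#' @param target Planted element id (regulator or phenotype).
#' @param effect Mean absolute log2 fold change of responders.
#' @param responder_fraction Fraction of the planted entity's nonzero-
#'   influence regulon that responds.
#' @param noise_sd Standard deviation of the Gaussian noise on every FC.
#' @param p_threshold Filter threshold the p-values are generated around.
#' @param sample Sample label.
#' @param seed Integer seed.
#' @return A wide data table as in [make_null_dces()].
#' @export
make_planted_dces <- function(graph, influence, target, effect = 2,
                              responder_fraction = 0.5, noise_sd = 0.5,
                              p_threshold = 0.05, sample = "s1", seed = 1) {
  check_element(graph, target)
  iv <- if (element_type(graph, target) == "phenotype") {
    influence_on(influence, target)
  } else {
    influence_from(influence, target)
  }
  iv <- iv[iv != 0]
  if (length(iv) < 5) {
    stop_twodea(sprintf(
      "planted target '%s' influences only %d element(s); need >= 5.",
      target, length(iv)),
      class = "twodea_generation_error")
  }
  with_seed(seed, {
    n_resp <- max(1L, round(responder_fraction * length(iv)))
    responders <- base::sample(names(iv), n_resp)
    types <- unique(element_type(graph, names(iv)))
    universe <- graph$elements$id[graph$elements$bio_type %in% types]
    non_resp <- setdiff(universe, responders)
    fc <- c(effect * sign(iv[responders]) + rnorm(n_resp, 0, noise_sd),
            rnorm(length(non_resp), 0, noise_sd))
    padj <- c(runif(n_resp, 0, p_threshold),
              runif(length(non_resp), p_threshold, 1))
    out <- tibble(symbol = c(responders, non_resp), fc = unname(fc),
                  padj = padj)
  })
  out <- arrange(out, .data$symbol)
  names(out) <- c("symbol", paste0("FC_", sample), paste0("padj_", sample))
  out
}
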