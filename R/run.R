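#' Downstream phenotype enrichment
#'
#' Full downstream analysis: for every phenotype with an influence column
#' and every sample's DCE set, computes the level (influence-weighted
#' fold-change sum), saturation, and enrichment score; builds a
#' type-stratified permutation null (shared across phenotypes within a
#' sample), fits direction-specific half-Gaussians, standardises the
#' observed statistic(s) to z-scores and two-sided p-values, and applies
#' Benjamini-Hochberg correction across all phenotypes of each sample.
#' Levels are finally normalized per phenotype across samples.
#'
#' The `statistic_mode` selects which null drives the reported p-value:
#' the enrichment-score null (`"es"`), the level null (`"level"`), or the
#' more conservative/liberal of the two per row (`"max_p"` / `"min_p"`).
#' Both component p-values are always reported (`p_es`, `p_level`).
#'
#' With `k_mode = "adaptive"` the baseline mass is set to `2 * max(FC)^2`
#' of the evaluated fold-change set — the baseline points move out to
#' `(±max|FC|, 0)` — for the observed and each permuted set alike (the
#' permutation scheme preserves the fold-change multiset, so the two
#' coincide; the flag matters when custom statistics alter that).
#'
#' Phenotypes whose permutation null is degenerate (e.g. no regulator of
#' the DCE's biological type, so every randomized statistic is zero) get
#' `NA` statistics rather than aborting the run.
#'
#' @param graph A [mim_graph].
#' @param influence Phenotype-context influence table from
#'   [build_influence()].
#' @param dce_sets A `dce_set` or list of them (one per sample).
#' @param statistic_mode One of `"es"`, `"level"`, `"max_p"`, `"min_p"`.
#' @param n Permutations per sample (default 1000).
#' @param seed Integer seed; sample `i` uses `seed + i - 1`.
#' @param k Baseline mass when `k_mode = "fixed"`.
#' @param k_mode `"fixed"` or `"adaptive"`.
#' @param z_cap z-score cutoff for p-values.
#' @return A `downstream_enrichment` object; `tidy()` it for the result
#'   table (one row per phenotype per sample).
#' @export
run_downstream <- function(graph, influence, dce_sets,
                           statistic_mode = c("es", "level", "max_p", "min_p"),
                           n = 1000, seed = 1, k = 2,
                           k_mode = c("fixed", "adaptive"), z_cap = 14) {
  statistic_mode <- match.arg(statistic_mode)
  k_mode <- match.arg(k_mode)
  dce_sets <- as_dce_list(dce_sets)
  phenotypes <- sort(unique(influence$target))

  rows <- purrr::imap_dfr(dce_sets, function(dces, s_idx) {
    s_seed <- seed + s_idx - 1L
    sample_label <- attr(dces, "sample") %||% paste0("sample", s_idx)
    perm <- permute_dce_ids(graph, dces, n = n, seed = s_seed)
    fc <- dces$fc
    k_use <- if (k_mode == "adaptive" && length(fc)) 2 * max(fc^2) else k
    purrr::map_dfr(phenotypes, function(v) {
      iv <- influence_on(influence, v)
      obs_level <- phenotype_level(dces, iv)
      obs_es <- enrichment_score(dces, iv, k = k_use)
      sat <- saturation(dces, iv)
      nm <- null_matrices(iv, fc, perm)
      k_perm <- if (k_mode == "adaptive" && length(fc)) {
        2 * max(fc^2)
      } else {
        k
      }
      es_null <- nm$sq_signed / (k_perm + nm$sq)
      stats_row(sample_label, v, obs_level, obs_es, sat,
                es_null = es_null, level_null = nm$level, z_cap = z_cap)
    })
  })

  rows <- split_mode_p(rows, statistic_mode)
  per_sample <- group_by(rows, .data$sample)
  rows <- ungroup(mutate(per_sample, adj_p = bh_adjust(.data$p)))
  rows <- normalize_levels(rename(rows, phenotype = "phenotype"))
  rows <- select(rows, "sample", "phenotype", "level", "level_norm",
                 "saturation", "es", "z", "p_es", "p_level", "p", "adj_p")

  structure(list(
    table = rows,
    options = list(statistic_mode = statistic_mode, n = n, seed = seed,
                   k = k, k_mode = k_mode, z_cap = z_cap),
    kind = "downstream"
  ), class = c("downstream_enrichment", "twodea_enrichment"))
}

as_dce_list <- function(dce_sets) {
  if (inherits(dce_sets, "dce_set")) {
    dce_sets <- list(dce_sets)
  }
  if (!is.list(dce_sets) || !all(purrr::map_lgl(dce_sets, inherits,
                                                "dce_set"))) {
    stop_twodea("`dce_sets` must be a dce_set or a list of dce_set objects.",
                class = "twodea_usage_error")
  }
  dce_sets
}

# vectorized permutation statistics: influence looked up for the whole
# identity matrix at once, absent elements scoring 0
null_matrices <- function(iv, fc, perm) {
  if (!nrow(perm)) {
    z <- rep(0, ncol(perm))
    return(list(level = z, sq = z, sq_signed = z, zero_fc = z,
                zero_fc_signed = z))
  }
  m <- matrix(unname(iv[perm]), nrow = nrow(perm))
  m[is.na(m)] <- 0
  p <- m * fc
  list(level = colSums(p),
       sq = colSums(p^2),
       sq_signed = colSums(abs(p) * p),
       zero_fc = colSums(abs(fc) * (m == 0)),
       zero_fc_signed = colSums(fc * (m == 0)))
}

stats_row <- function(sample_label, v, obs_level, obs_es, sat, es_null,
                      level_null, z_cap) {
  zp_es <- safe_zp(obs_es, es_null, z_cap)
  zp_lv <- safe_zp(obs_level, level_null, z_cap)
  tibble(sample = sample_label, phenotype = v, level = obs_level,
         saturation = sat, es = obs_es,
         z_es = zp_es$z, p_es = zp_es$p,
         z_level = zp_lv$z, p_level = zp_lv$p)
}

safe_zp <- function(stat, null_values, z_cap) {
  tryCatch({
    fits <- gaussian_half_fit(null_values[!is.na(null_values)])
    z_and_p(stat, fits, z_cap = z_cap)
  }, twodea_degenerate_error = function(e) list(z = NA_real_, p = NA_real_))
}

split_mode_p <- function(rows, statistic_mode) {
  pick <- switch(statistic_mode,
                 es = list(p = rows$p_es, z = rows$z_es),
                 level = list(p = rows$p_level, z = rows$z_level),
                 max_p = {
                   use_es <- !is.na(rows$p_es) &
                     (is.na(rows$p_level) | rows$p_es >= rows$p_level)
                   list(p = pmax(rows$p_es, rows$p_level, na.rm = TRUE),
                        z = ifelse(use_es, rows$z_es, rows$z_level))
                 },
                 min_p = {
                   use_es <- !is.na(rows$p_es) &
                     (is.na(rows$p_level) | rows$p_es <= rows$p_level)
                   list(p = pmin(rows$p_es, rows$p_level, na.rm = TRUE),
                        z = ifelse(use_es, rows$z_es, rows$z_level))
                 })
  rows$p <- pick$p
  rows$z <- pick$z
  rows$p[is.nan(rows$p)] <- NA_real_
  rows$z_es <- NULL
  rows$z_level <- NULL
  rows
}

#' Upstream target enrichment
#'
#' Ranks candidate upstream regulators (targets) by how specifically their
#' influence pattern accounts for the observed differential changes. For
#' each candidate `v` and each sample: sensitivity (`sum(I * FC)/sum|FC|`
#' over DCEs), specificity (`mean(1 - |I|)` over the non-DCE universe), and
#' the adapted enrichment score whose baseline is the fold-change mass of
#' DCEs that `v` does not regulate. Significance comes from the same
#' type-stratified permutation null, half-Gaussian fits and BH correction
#' as the downstream analysis. Candidates are ranked by sensitivity
#' magnitude, then specificity, then id (deterministic ties).
#'
#' @param graph A [mim_graph].
#' @param influence Influence table whose rows run target -> data element
#'   (typically `build_influence(graph, "transcriptional")`).
#' @param dce_sets A `dce_set` or list of them.
#' @param target_filter `NULL` (all sources in the influence table), the
#'   string `"tf"` (restrict to elements with at least one transcriptional
#'   out-edge), or a character vector of biological types.
#' @param n,seed,z_cap As in [run_downstream()].
#' @param strict_k Signed (as-printed) unregulated-FC baseline; see
#'   [upstream_es()].
#' @param specificity_universe `"same_type"` restricts the non-DCE universe
#'   to map elements of the same biological type(s) as the DCE data (so a
#'   transcriptomics run is judged against genes only); `"all"` uses every
#'   map element.
#' @return An `upstream_enrichment` object; `tidy()` for the table (one
#'   row per candidate per sample, ranked).
#' @export
run_upstream <- function(graph, influence, dce_sets, target_filter = NULL,
                         n = 1000, seed = 1, strict_k = FALSE,
                         specificity_universe = c("same_type", "all"),
                         z_cap = 14) {
  specificity_universe <- match.arg(specificity_universe)
  dce_sets <- as_dce_list(dce_sets)

  candidates <- sort(unique(influence$source))
  if (!is.null(target_filter)) {
    if (identical(target_filter, "tf")) {
      tfs <- unique(graph$interactions$source[
        graph$interactions$iclass == "transcriptional"])
      candidates <- intersect(candidates, tfs)
    } else {
      candidates <- candidates[element_type(graph, candidates) %in%
                                 target_filter]
    }
  }
  if (!length(candidates)) {
    stop_twodea("no candidate targets left after filtering.",
                class = "twodea_usage_error")
  }

  rows <- purrr::imap_dfr(dce_sets, function(dces, s_idx) {
    s_seed <- seed + s_idx - 1L
    sample_label <- attr(dces, "sample") %||% paste0("sample", s_idx)
    perm <- permute_dce_ids(graph, dces, n = n, seed = s_seed)
    fc <- dces$fc
    universe <- if (specificity_universe == "all") {
      graph$elements$id
    } else {
      types <- unique(element_type(graph, dces$element))
      graph$elements$id[graph$elements$bio_type %in% types]
    }
    purrr::map_dfr(candidates, function(v) {
      ifrom <- influence_from(influence, v)
      sens <- sensitivity(dces, ifrom)
      spc <- specificity(dces, ifrom, universe)
      es_obs <- upstream_es(dces, ifrom, strict_k = strict_k)
      nm <- null_matrices(ifrom, fc, perm)
      k_null <- if (strict_k) nm$zero_fc_signed else nm$zero_fc
      es_null <- (nm$sq_signed) / (k_null + nm$sq)
      zp <- safe_zp(es_obs, es_null[is.finite(es_null)], z_cap)
      tibble(sample = sample_label, target = v, sensitivity = sens,
             specificity = spc, es = es_obs, z = zp$z, p = zp$p)
    })
  })

  per_sample <- group_by(rows, .data$sample)
  rows <- ungroup(mutate(per_sample, adj_p = bh_adjust(.data$p)))
  rows <- mutate(rows, polarity = dplyr::case_when(
    is.na(.data$sensitivity) ~ NA_character_,
    .data$sensitivity > 0 ~ "positive",
    .data$sensitivity < 0 ~ "negative",
    TRUE ~ "neutral"))
  rows <- group_by(rows, .data$sample)
  rows <- mutate(rows, rank = order(order(-abs(dplyr::coalesce(.data$sensitivity, 0)),
                                          -dplyr::coalesce(.data$specificity, 0),
                                          .data$target)))
  rows <- arrange(ungroup(rows), .data$sample, .data$rank)

  structure(list(
    table = rows,
    options = list(target_filter = target_filter, n = n, seed = seed,
                   strict_k = strict_k,
                   specificity_universe = specificity_universe,
                   z_cap = z_cap),
    kind = "upstream"
  ), class = c("upstream_enrichment", "twodea_enrichment"))
}

#' Data-independent in silico perturbation
#'
#' Exploration mode: instead of measured fold changes, the user asserts
#' changes for chosen elements (conventionally `+1` activation, `-1`
#' inhibition, or any value) and the influence-weighted levels of all
#' phenotypes are computed by the same linear aggregation as the downstream
#' analysis. No statistics are attached — the result is additive in the
#' perturbations and sign-symmetric by construction.
#'
#' @param graph A [mim_graph].
#' @param influence Phenotype-context influence table.
#' @param perturbations Named numeric vector (names are element ids, values
#'   assumed fold changes), or a two-column data frame `element`, `fc`.
#' @return Tibble with columns `phenotype`, `level`.
#' @export
in_silico_perturbation <- function(graph, influence, perturbations) {
  if (is.numeric(perturbations) && !is.null(names(perturbations))) {
    perturbations <- tibble(element = names(perturbations),
                            fc = unname(perturbations))
  }
  perturbations <- as_tibble(perturbations)
  missing <- setdiff(perturbations$element, graph$elements$id)
  if (length(missing)) {
    stop_twodea(sprintf("unknown element(s): %s",
                        paste(missing, collapse = ", ")),
                class = "twodea_lookup_error")
  }
  dces <- dce_set(perturbations$element, perturbations$fc,
                  sample = "perturbation")
  phenotypes <- sort(unique(influence$target))
  tibble(
    phenotype = phenotypes,
    level = vapply(phenotypes, function(v) {
      phenotype_level(dces, influence_on(influence, v))
    }, numeric(1))
  )
}
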