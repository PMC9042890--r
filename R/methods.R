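#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_hline
#'   geom_vline geom_abline scale_fill_gradient2 labs theme_minimal facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy enrichment results
#'
#' `tidy()` returns the result table (one row per enriched element per
#' sample); `glance()` a one-row summary per analysis.
#' @param x A `downstream_enrichment` or `upstream_enrichment` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.twodea_enrichment <- function(x, ...) {
  x$table
}

#' @rdname tidy.twodea_enrichment
#' @export
glance.twodea_enrichment <- function(x, ...) {
  tab <- x$table
  tibble(
    kind = x$kind,
    n_samples = length(unique(tab$sample)),
    n_elements = length(unique(tab[[if (x$kind == "downstream") "phenotype"
                                    else "target"]])),
    n_significant = sum(tab$adj_p < 0.05, na.rm = TRUE),
    n_permutations = x$options$n,
    seed = x$options$seed
  )
}

#' @export
print.twodea_enrichment <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<%s enrichment> %d sample(s) x %d element(s); %d significant (adj p < 0.05); n = %d permutations, seed = %s\n",
    x$kind, g$n_samples, g$n_elements, g$n_significant, g$n_permutations,
    format(g$seed)))
  print(x$table, n = 10)
  invisible(x)
}

#' Plot downstream enrichment as a phenotype-by-sample heatmap
#'
#' Tiles are the per-phenotype normalized levels; significant entries
#' (adjusted p below `alpha`) are marked.
#' @param object A `downstream_enrichment`.
#' @param alpha Significance threshold for the markers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.downstream_enrichment <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  sig <- tab[!is.na(tab$adj_p) & tab$adj_p < alpha, , drop = FALSE]
  ggplot(tab, aes(x = .data$sample, y = .data$phenotype,
                  fill = .data$level_norm)) +
    geom_tile() +
    geom_point(data = sig, shape = 8, size = 1.5, colour = "black") +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "level",
         title = "Downstream phenotype enrichment",
         subtitle = sprintf("* adj p < %.2g", alpha)) +
    theme_minimal()
}

#' Plot upstream targets in the specificity-sensitivity plane
#'
#' One point per candidate target per sample, the plane used to rank
#' targets: the best positive targets sit top-right, the best negative
#' targets bottom-right.
#' @param object An `upstream_enrichment`.
#' @param alpha Highlight targets with adjusted p below this.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.upstream_enrichment <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  tab$significant <- !is.na(tab$adj_p) & tab$adj_p < alpha
  ggplot(tab, aes(x = .data$specificity, y = .data$sensitivity,
                  colour = .data$significant)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_point() +
    facet_wrap(~sample) +
    labs(title = "Upstream target enrichment",
         x = "specificity", y = "sensitivity") +
    theme_minimal()
}

#' Regulation plot: fold change against influence score
#'
#' The two-dimensional plane the enrichment score summarises: each DCE is
#' a point at (FC, influence of/on the element of interest); the dashed
#' diagonals are the projection axes of the score.
#' @param dces A `dce_set`.
#' @param influence Named influence vector ([influence_on()] or
#'   [influence_from()]).
#' @param label Title annotation, e.g. the element of interest.
#' @return A ggplot object.
#' @export
plot_regulation <- function(dces, influence, label = NULL) {
  df <- tibble(fc = dces$fc,
               influence = aligned_influence(dces, influence),
               element = dces$element)
  ggplot(df, aes(x = .data$fc, y = .data$influence)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_vline(xintercept = 0, colour = "grey70") +
    geom_abline(slope = c(1, -1) / max(abs(df$fc), 1), intercept = 0,
                linetype = 2, colour = "grey80") +
    geom_point() +
    labs(x = "log2 fold change", y = "influence score", title = label) +
    theme_minimal()
}
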