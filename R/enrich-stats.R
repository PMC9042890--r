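#' Downstream enrichment statistics
#'
#' The elementary statistics of the two-dimensional enrichment analysis.
#' All take a DCE set (element ids with signed log2 fold changes) and an
#' influence column — a named numeric vector `influence[u] = I(u, v)` as
#' returned by [influence_on()] — and reduce the paired `(I, FC)` values:
#'
#' * `phenotype_level()` — the estimated activity change of `v`:
#'   `sum(I * FC)` over the DCEs. Linear, unclamped.
#' * `saturation()` — the influence-weighted fraction of `v`'s regulators
#'   present in the DCE list: `sum(|I|, DCEs) / sum(|I|, all regulators)`,
#'   in `[0, 1]`; `NA` when `v` has no regulators at all.
#' * `enrichment_score()` — the bounded two-dimensional statistic: each DCE
#'   contributes `|I * FC| * I * FC` to the numerator and `I^2 * FC^2` to
#'   the denominator, which additionally carries the baseline mass `k`
#'   (default 2). Geometrically this is the slope of a least-squares
#'   regression through the origin after projecting points onto the
#'   diagonals — x: `FC * |I|`, y: `|FC| * I` — with two baseline points
#'   `(±sqrt(k/2), 0)` appended (for `k = 2`: `(1, 0)` and `(-1, 0)`), so
#'   `|ES| <= 1` always.
#'
#' @param dces A `dce_set` (or tibble with `element`, `fc`).
#' @param influence Named numeric vector of influence scores on the target.
#' @param k Baseline mass (non-negative); `k = 2` corresponds to baseline
#'   points `(1, 0)` and `(-1, 0)`.
#' @return A single numeric value.
#' @name downstream-statistics
NULL

aligned_influence <- function(dces, influence) {
  iv <- unname(influence[match(dces$element, names(influence))])
  iv[is.na(iv)] <- 0
  iv
}

#' @rdname downstream-statistics
#' @export
phenotype_level <- function(dces, influence) {
  iv <- aligned_influence(dces, influence)
  sum(iv * dces$fc)
}

#' @rdname downstream-statistics
#' @export
saturation <- function(dces, influence) {
  denom <- sum(abs(influence))
  if (!length(influence) || denom == 0) {
    return(NA_real_)
  }
  sum(abs(influence[names(influence) %in% dces$element])) / denom
}

# shared ES kernel: products p_u = I_u * FC_u, baseline mass k
es_kernel <- function(prod, k) {
  denom <- k + sum(prod^2)
  if (denom == 0) {
    return(NA_real_)
  }
  sum(abs(prod) * prod) / denom
}

#' @rdname downstream-statistics
#' @export
enrichment_score <- function(dces, influence, k = 2) {
  if (k < 0) stop_twodea("`k` must be >= 0.", class = "twodea_usage_error")
  iv <- aligned_influence(dces, influence)
  es_kernel(iv * dces$fc, k)
}

#' Normalize phenotype levels across samples
#'
#' Phenotype levels are aggregate quantities whose scale depends on the DCE
#' list, so they are only comparable within a phenotype: each phenotype's
#' levels are divided by their maximum absolute value across samples
#' (all-zero phenotypes are left untouched). Signs are preserved.
#'
#' @param levels Tibble with columns `phenotype`, `sample`, `level`.
#' @return The tibble with an added/overwritten `level_norm` column.
#' @export
normalize_levels <- function(levels) {
  levels <- as_tibble(levels)
  grouped <- group_by(levels, .data$phenotype)
  out <- mutate(grouped,
                level_norm = if (max(abs(.data$level)) > 0) {
                  .data$level / max(abs(.data$level))
                } else {
                  .data$level
                })
  ungroup(out)
}

#' Upstream target statistics
#'
#' Statistics ranking a candidate upstream target `v` by how well its
#' influence pattern explains the observed differential changes. Here the
#' influence column runs from the target to the data:
#' `influence[u] = I(v, u)`, as returned by [influence_from()].
#'
#' * `sensitivity()` — true-positive-rate analogue,
#'   `sum(I * FC) / sum(|FC|)` over DCEs, in `[-1, 1]`. It reaches `+1`
#'   exactly when `I * FC = |FC|` for every DCE (a *positive* target that
#'   induces everything up and represses everything down) and `-1` for the
#'   mirror-image *negative* target. `NA` for an empty DCE set.
#' * `specificity()` — true-negative-rate analogue,
#'   `sum(1 - |I|) / count` over the non-DCE universe, in `[0, 1]`; `1`
#'   when `v` has no influence on any non-DCE. `NA` for an empty universe.
#' * `upstream_es()` — the enrichment score with the fixed baseline
#'   replaced by the fold-change mass of DCEs the target does **not**
#'   regulate: `k = sum(|FC_u|)` over DCEs with `I(v, u) = 0` (the
#'   absolute value keeps the denominator positive; `strict_k = TRUE`
#'   reproduces the signed sum as printed in the original formulation).
#'
#' @param dces A `dce_set`.
#' @param influence Named numeric vector `I(v, u)` over targets `u` of `v`.
#' @param universe Character vector of candidate data elements defining the
#'   non-DCE universe for `specificity()`.
#' @param strict_k Use the signed fold-change sum in the `upstream_es()`
#'   denominator instead of the absolute sum.
#' @return A single numeric value.
#' @name upstream-statistics
NULL

#' @rdname upstream-statistics
#' @export
sensitivity <- function(dces, influence) {
  if (!nrow(dces)) {
    return(NA_real_)
  }
  iv <- aligned_influence(dces, influence)
  sum(iv * dces$fc) / sum(abs(dces$fc))
}

#' @rdname upstream-statistics
#' @export
specificity <- function(dces, influence, universe) {
  non_dce <- setdiff(universe, dces$element)
  if (!length(non_dce)) {
    return(NA_real_)
  }
  iv <- unname(influence[match(non_dce, names(influence))])
  iv[is.na(iv)] <- 0
  sum(1 - abs(iv)) / length(non_dce)
}

#' @rdname upstream-statistics
#' @export
upstream_es <- function(dces, influence, strict_k = FALSE) {
  iv <- aligned_influence(dces, influence)
  prod <- iv * dces$fc
  unreg <- dces$fc[iv == 0]
  k <- if (strict_k) sum(unreg) else sum(abs(unreg))
  es_kernel(prod, k)
}

# ---------------------------------------------------------------------------
# Normal-tail machinery: series p-value with the documented z cutoff

#' Two-sided normal tail probability by series expansion
#'
#' Computes `p = 2 * (1 - Phi(|z|))` without relying on a CDF
#' implementation: a Maclaurin series of the normal integral accumulated
#' term-wise until the next term falls below `tol` for moderate `z`, and a
#' Laplace continued fraction for the Mills ratio in the far tail
#' (`|z| > 6`) where the series suffers catastrophic cancellation. `|z|` is
#' capped at `z_cap` (default 14), flooring the attainable p-value at
#' about 1.56e-44.
#'
#' @param z z-score (vectorised).
#' @param tol Series truncation tolerance.
#' @param z_cap Cutoff on `|z|`.
#' @return Two-sided tail probabilities in `(0, 1]`.
#' @export
normal_tail_p <- function(z, tol = 1e-18, z_cap = 14) {
  vapply(z, function(zi) {
    zi <- min(abs(zi), z_cap)
    if (zi == 0) {
      return(1)
    }
    phi <- exp(-zi^2 / 2) / sqrt(2 * pi)
    if (zi > 6) {
      # Laplace continued fraction for Q(z) = phi(z)/(z + 1/(z + 2/(z + ...)))
      cf <- 0
      for (a in 80:1) cf <- a / (zi + cf)
      q <- phi / (zi + cf)
    } else {
      # Phi(z) = 1/2 + phi(z) * sum_{j>=0} z^(2j+1) / (1 * 3 * ... * (2j+1))
      term <- zi
      acc <- zi
      j <- 0
      while (abs(term) >= tol && j < 1000) {
        j <- j + 1
        term <- term * zi^2 / (2 * j + 1)
        acc <- acc + term
      }
      q <- 0.5 - phi * acc
    }
    min(1, max(2 * q, 0))
  }, numeric(1))
}

#' Direction-specific half-Gaussian fit of a permutation null
#'
#' Influence scores and fold changes need not be symmetrically distributed,
#' so the null distribution of a statistic may have different spread above
#' and below zero. Each direction is fitted separately with a zero-centred
#' half-normal: the positive-side scale is the root mean square of the
#' positive null values, likewise for the negative side. A direction with
#' fewer than two same-signed values falls back to the other direction's
#' fit (flagged in the result); an entirely degenerate null is an error.
#'
#' @param null A `null_model` from [permutation_null()] or a numeric vector
#'   of null statistic values.
#' @return List with components `pos` and `neg`, each `(mu = 0, sigma)`,
#'   plus logical fallback flags `pos_fallback`, `neg_fallback`.
#' @export
gaussian_half_fit <- function(null) {
  x <- if (inherits(null, "null_model")) null$values else as.numeric(null)
  x <- x[!is.na(x)]
  if (!length(x)) {
    stop_twodea("empty null distribution.", class = "twodea_degenerate_error")
  }
  xp <- x[x > 0]
  xn <- x[x < 0]
  sp <- if (length(xp) >= 2) sqrt(mean(xp^2)) else NA_real_
  sn <- if (length(xn) >= 2) sqrt(mean(xn^2)) else NA_real_
  pos_fb <- is.na(sp)
  neg_fb <- is.na(sn)
  if (pos_fb && neg_fb) {
    # all-zero or near-constant null: no direction has two same-signed values
    stop_twodea("degenerate null: fewer than two same-signed values in both directions.",
                class = "twodea_degenerate_error")
  }
  if (pos_fb) sp <- sn
  if (neg_fb) sn <- sp
  list(pos = list(mu = 0, sigma = sp), neg = list(mu = 0, sigma = sn),
       pos_fallback = pos_fb, neg_fallback = neg_fb)
}

#' z-score and p-value for an observed statistic
#'
#' Standardises the observed statistic against the direction-matched
#' half-Gaussian fit (positive statistics against the positive-side scale,
#' negative against the negative side) and converts to a two-sided p-value
#' with [normal_tail_p()]. `|z|` is capped at `z_cap` for the p-value, so p
#' never falls below about 1.56e-44; the reported `z` itself is uncapped.
#'
#' @param stat Observed statistic value.
#' @param fits Fit list from [gaussian_half_fit()].
#' @param z_cap Cutoff on `|z|` used for the p-value.
#' @return List with `z` and `p`.
#' @export
z_and_p <- function(stat, fits, z_cap = 14) {
  if (is.na(stat)) {
    return(list(z = NA_real_, p = NA_real_))
  }
  fit <- if (stat >= 0) fits$pos else fits$neg
  if (is.na(fit$sigma) || fit$sigma <= 0) {
    stop_twodea("degenerate null: sigma = 0.",
                class = "twodea_degenerate_error")
  }
  z <- (stat - fit$mu) / fit$sigma
  list(z = z, p = normal_tail_p(z, z_cap = z_cap))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control over all enriched elements of one
#' sample. Applied before any user-side filtering of the result table, so
#' filtering cannot bias the correction.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the same order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
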