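test_that("phenotype level is the influence-weighted fold-change sum", {
  d <- dce_set(c("a", "b"), fc = c(2, 2))
  expect_equal(phenotype_level(d[1, ], c(a = 1)), 2)
  expect_equal(phenotype_level(d, c(a = 1, b = -0.5)), 1)
  # dot-product oracle on random vectors
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    iv <- setNames(runif(n, -1, 1), paste0("e", 1:n))
    fc <- rnorm(n, 0, 2)
    d2 <- dce_set(paste0("e", 1:n), fc)
    expect_equal(phenotype_level(d2, iv), oracle_level(iv, fc))
  }
})

test_that("level normalization divides by the per-phenotype absolute maximum", {
  tab <- tibble::tibble(phenotype = c("p", "p"), sample = c("s1", "s2"),
                        level = c(2, -4))
  expect_equal(normalize_levels(tab)$level_norm, c(0.5, -1))
  one <- tibble::tibble(phenotype = "p", sample = "s1", level = -3)
  expect_equal(normalize_levels(one)$level_norm, -1)
  zero <- tibble::tibble(phenotype = c("p", "p"), sample = c("s1", "s2"),
                         level = c(0, 0))
  expect_equal(normalize_levels(zero)$level_norm, c(0, 0))
})

test_that("saturation is the influence-weighted DCE share of regulators", {
  iv <- c(a = 0.5, b = -0.5, c = 1)
  expect_equal(saturation(dce_set(c("a", "b", "c"), c(1, 1, 1)), iv), 1)
  expect_equal(saturation(dce_set(c("c"), 1), iv), 0.5) # half the |I| mass
  expect_equal(saturation(dce_set("zz", 1), iv), 0)
  expect_true(is.na(saturation(dce_set("a", 1), numeric(0))))
})

test_that("enrichment score matches hand values and stays bounded", {
  expect_equal(enrichment_score(dce_set("a", 1), c(a = 1), k = 2), 1 / 3)
  d <- dce_set(c("a", "b"), c(1, 1))
  expect_equal(enrichment_score(d, c(a = 1, b = -1), k = 2), 0)
  expect_equal(enrichment_score(dce_set("zz", 2), c(a = 1), k = 2), 0)
  expect_error(enrichment_score(d, c(a = 1), k = -1),
               class = "twodea_usage_error")
})

test_that("enrichment score equals the regression-through-origin construction", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    iv <- setNames(runif(n, -1, 1), paste0("e", 1:n))
    fc <- rnorm(n, 0, 2)
    k <- sample(c(0.5, 2, 5), 1)
    d <- dce_set(paste0("e", 1:n), fc)
    es <- enrichment_score(d, iv, k = k)
    expect_equal(es, oracle_es_regression(iv, fc, k), tolerance = 1e-12)
    expect_lte(abs(es), 1)
  }
})

test_that("sensitivity reaches +-1 exactly for perfectly aligned targets", {
  d <- dce_set(c("a", "b"), c(2, -1))
  expect_equal(sensitivity(d, c(a = 1, b = -1)), 1)   # positive target
  expect_equal(sensitivity(d, c(a = -1, b = 1)), -1)  # negative target
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:25, 1)
    iv <- setNames(runif(n, -1, 1), paste0("e", 1:n))
    fc <- rnorm(n)
    d2 <- dce_set(paste0("e", 1:n), fc)
    expect_equal(sensitivity(d2, iv), oracle_sensitivity(iv, fc))
  }
  expect_true(is.na(sensitivity(dce_set(character(), numeric()), c(a = 1))))
})

test_that("specificity measures absence of influence on non-DCEs", {
  d <- dce_set("a", 2)
  uni <- c("a", "b", "c")
  expect_equal(specificity(d, c(a = 1), uni), 1)          # only DCEs touched
  expect_equal(specificity(d, c(b = 1, c = -1), uni), 0)  # all non-DCEs at |I|=1
  expect_equal(specificity(d, c(b = 0.5), uni), 0.75)
  expect_true(is.na(specificity(d, c(a = 1), "a")))       # empty universe
})

test_that("upstream ES uses unregulated fold-change mass as its baseline", {
  d <- dce_set(c("a", "b"), c(1, 1))
  expect_equal(upstream_es(d, c(a = 1, b = 1)), 1)  # fully regulated, aligned
  expect_equal(upstream_es(d, c(x = 1)), 0)         # regulates nothing
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:25, 1)
    iv <- setNames(sample(c(0, runif(2, -1, 1)), n, replace = TRUE),
                   paste0("e", 1:n))
    fc <- rnorm(n)
    d2 <- dce_set(paste0("e", 1:n), fc)
    expect_equal(upstream_es(d2, iv), oracle_upstream_es(iv, fc))
  }
  # strict as-printed mode keeps the signed sum
  d3 <- dce_set(c("a", "b"), c(-2, 1))
  iv3 <- c(b = 1)
  expect_equal(upstream_es(d3, iv3, strict_k = TRUE),
               1 / (-2 + 1))
})

test_that("series tail probability agrees with the normal CDF and floors at z = 14", {
  expect_equal(normal_tail_p(0), 1)
  expect_equal(normal_tail_p(1.959964), 0.05, tolerance = 1e-6)
  grid <- seq(0.1, 13.9, by = 0.2)
  expect_equal(normal_tail_p(grid), 2 * stats::pnorm(grid, lower.tail = FALSE),
               tolerance = 1e-12)
  floor_p <- normal_tail_p(14)
  expect_equal(floor_p, 1.56e-44, tolerance = 0.01)
  expect_equal(normal_tail_p(20), floor_p) # capped
  expect_equal(normal_tail_p(-2), normal_tail_p(2)) # two-sided symmetry
})

test_that("half-Gaussian fit recovers known scales per direction", {
  set.seed(5)
  x <- rnorm(20000)
  fits <- gaussian_half_fit(x)
  expect_equal(fits$pos$sigma, 1, tolerance = 0.03)
  expect_equal(fits$neg$sigma, 1, tolerance = 0.03)
  expect_false(fits$pos_fallback || fits$neg_fallback)
  # scale equivariance
  fits3 <- gaussian_half_fit(3 * x)
  expect_equal(fits3$pos$sigma, 3 * fits$pos$sigma)
  # one-sided null falls back to the other direction, flagged
  fb <- gaussian_half_fit(abs(x))
  expect_true(fb$neg_fallback)
  expect_equal(fb$neg$sigma, fb$pos$sigma)
  expect_error(gaussian_half_fit(numeric(0)),
               class = "twodea_degenerate_error")
  expect_error(gaussian_half_fit(c(0, 0, 0)),
               class = "twodea_degenerate_error")
})

test_that("z-scores use the direction-matched fit and cap the p-value", {
  fits <- list(pos = list(mu = 0, sigma = 2), neg = list(mu = 0, sigma = 0.5))
  zp <- z_and_p(1, fits)
  expect_equal(zp$z, 0.5)
  zp_neg <- z_and_p(-1, fits)
  expect_equal(zp_neg$z, -2)
  expect_equal(zp_neg$p, normal_tail_p(2))
  # z beyond the cutoff reports the uncapped z but the floored p
  big <- z_and_p(100, fits)
  expect_equal(big$z, 50)
  expect_equal(big$p, normal_tail_p(14))
  expect_error(z_and_p(1, list(pos = list(mu = 0, sigma = 0))),
               class = "twodea_degenerate_error")
})

test_that("BH adjustment is the standard step-up and order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(a = 0.04, b = 0.001, c = 0.3, d = 0.02)
  perm <- sample(names(p))
  expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p)[order(names(p))],
               ignore_attr = TRUE)
})
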