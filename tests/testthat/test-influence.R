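test_that("transcriptional base case and one-step aggregation", {
  # u is a direct inducing TF -> +1; w activates the TF at distance 1 -> +0.5
  el <- toy_elements(c("w", "u", "v"), c("protein", "protein", "gene"))
  ia <- toy_edges(c("u", "1", "v", "transcriptional"),
                  c("w", "1", "u", "generic"))
  g <- mim_graph(el, ia, quiet = TRUE)
  col <- influence_on(transcriptional_influence(g, "v"), "v")
  expect_equal(col[["u"]], 1)
  expect_equal(col[["w"]], 0.5)
})

test_that("aggregated transcriptional influence clamps at 1", {
  # one upstream activator of two (then three) inducing TFs at distance 1
  make <- function(n_tf) {
    tfs <- paste0("k", seq_len(n_tf))
    el <- toy_elements(c("u", tfs, "v"),
                       c("protein", rep("protein", n_tf), "gene"))
    ia <- dplyr::bind_rows(
      tibble::tibble(source = tfs, sign = 1L, target = "v",
                     iclass = "transcriptional"),
      tibble::tibble(source = "u", sign = 1L, target = tfs,
                     iclass = "generic"))
    mim_graph(el, ia, quiet = TRUE)
  }
  col2 <- influence_on(transcriptional_influence(make(2), "v"), "v")
  expect_equal(col2[["u"]], 1) # raw 1.0, clamp inactive
  col3 <- influence_on(transcriptional_influence(make(3), "v"), "v")
  expect_equal(col3[["u"]], 1) # raw 1.5, clamped
})

test_that("catalytic influence handles synthesis, consumption and relief of consumption", {
  el <- toy_elements(c("u", "e", "m"), c("protein", "protein", "metabolite"))
  # u inhibits the sole consuming enzyme: (-1) * (-1) / 2 = +0.5
  ia <- toy_edges(c("e", "-1", "m", "catalytic"),
                  c("u", "-1", "e", "generic"))
  g <- mim_graph(el, ia, quiet = TRUE)
  col <- influence_on(catalytic_influence(g, "m"), "m")
  expect_equal(col[["e"]], -1)
  expect_equal(col[["u"]], 0.5)
})

test_that("phenotype influence base case, sign propagation and normalization", {
  # sole direct positive regulator: raw 1 * (1/1 + 1/1) = 2 -> normalized 1
  el <- toy_elements(c("a", "v"), c("protein", "phenotype"),
                     submaps = list("s", "s"))
  g <- mim_graph(el, toy_edges(c("a", "1", "v", "generic")), quiet = TRUE)
  col <- influence_on(phenotype_influence(g, "v"), "v")
  expect_equal(col[["a"]], 1)

  # negative single-edge regulator flips the sign
  g2 <- mim_graph(el, toy_edges(c("a", "-1", "v", "generic")), quiet = TRUE)
  expect_equal(influence_on(phenotype_influence(g2, "v"), "v")[["a"]], -1)

  # empty submap -> warning and empty column
  el3 <- toy_elements(c("a", "v"), c("protein", "phenotype"),
                      submaps = list(NULL, "s"))
  g3 <- mim_graph(el3, toy_edges(c("a", "1", "v", "generic")), quiet = TRUE)
  expect_warning(col3 <- phenotype_influence(g3, "v"), "submap")
  expect_equal(nrow(col3), 0L)
})

test_that("net-zero parallel direct edges leave no stored entry", {
  el <- toy_elements(c("a", "v"), c("protein", "gene"))
  ia <- toy_edges(c("a", "1", "v", "transcriptional"),
                  c("a", "-1", "v", "transcriptional"))
  g <- mim_graph(el, ia, quiet = TRUE)
  expect_message(col <- transcriptional_influence(g, "v"), "net-zero")
  expect_equal(nrow(col), 0L)
})

test_that("influence decays by half per edge up to the two-edge horizon", {
  # chain u3 -> u2 -> u1 -> TF -> v, all +1
  el <- toy_elements(c("u3", "u2", "u1", "tf", "v"),
                     c(rep("protein", 4), "gene"))
  ia <- toy_edges(c("tf", "1", "v", "transcriptional"),
                  c("u1", "1", "tf", "generic"),
                  c("u2", "1", "u1", "generic"),
                  c("u3", "1", "u2", "generic"))
  g <- mim_graph(el, ia, quiet = TRUE)
  col <- influence_on(transcriptional_influence(g, "v"), "v")
  expect_equal(col[["tf"]], 1)
  expect_equal(col[["u1"]], 0.5)
  expect_equal(col[["u2"]], 0.25)
  expect_false("u3" %in% names(col)) # beyond L <= 2 of any base TF
})

test_that("negating the path edge flips the influence sign on tree fixtures", {
  el <- toy_elements(c("w", "u", "v"), c("protein", "protein", "gene"))
  pos <- mim_graph(el, toy_edges(c("u", "1", "v", "transcriptional"),
                                 c("w", "1", "u", "generic")), quiet = TRUE)
  neg <- mim_graph(el, toy_edges(c("u", "1", "v", "transcriptional"),
                                 c("w", "-1", "u", "generic")), quiet = TRUE)
  expect_equal(influence_on(transcriptional_influence(pos, "v"), "v")[["w"]],
               -influence_on(transcriptional_influence(neg, "v"), "v")[["w"]])
})

test_that("all three contexts match literal-formula oracles on random fixtures", {
  n_checked <- 0
  for (seed in 1:50) {
    g <- random_mim(seed)
    records <- oracle_path_records(g)
    for (ctx in c("transcriptional", "catalytic")) {
      regs <- if (ctx == "transcriptional") g$tf else g$enzymes
      for (v in head(sort(names(regs)), 3)) {
        got <- suppressMessages(influence_on(
          if (ctx == "transcriptional") transcriptional_influence(g, v)
          else catalytic_influence(g, v), v))
        want <- oracle_class_influence(g, v, ctx, records)
        want <- want[order(names(want))]
        expect_named_equal(got, want, tol = 1e-12)
        n_checked <- n_checked + 1
      }
    }
    v <- g$elements$id[g$elements$bio_type == "phenotype"][1]
    got <- suppressWarnings(suppressMessages(
      influence_on(phenotype_influence(g, v), v)))
    want <- oracle_phenotype_influence(g, v, records)
    expect_named_equal(got, want, tol = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("influence magnitudes never exceed one in any context", {
  for (seed in c(8, 30)) {
    g <- make_network(network_spec(seed = seed, neg_fraction = 0.4))
    for (ctx in c("transcriptional", "catalytic", "phenotype")) {
      tab <- build_influence(g, ctx)
      expect_true(all(abs(tab$score) <= 1 + 1e-15),
                  info = sprintf("%s seed %d", ctx, seed))
    }
  }
})

test_that("phenotype columns are normalized to unit maximum magnitude", {
  g <- make_network(network_spec(seed = 15))
  tab <- build_influence(g, "phenotype")
  per_max <- tapply(abs(tab$score), tab$target, max)
  expect_true(all(abs(per_max - 1) < 1e-12))
})

test_that("build_influence restricted to one target yields only that column", {
  g <- make_network(network_spec(seed = 15))
  tgt <- sort(unique(names(g$tf)))[1]
  tab <- build_influence(g, "transcriptional", targets = tgt)
  expect_equal(unique(tab$target), tgt)
  expect_error(build_influence(g, "transcriptional", targets = "nope"),
               class = "twodea_lookup_error")
})

test_that("influence tables persist and reload exactly in both formats", {
  g <- make_network(network_spec(seed = 12))
  tab <- build_influence(g, "phenotype")
  for (fmt in c("tsv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_influence(tab, f, fmt)
    back <- read_influence(f, fmt)
    expect_identical(back$score, tab$score)
    expect_equal(as.data.frame(back), as.data.frame(tab))
  }
})

test_that("precomputed path tables give identical influence results", {
  g <- make_network(network_spec(seed = 19))
  pt <- path_table(g)
  expect_equal(build_influence(g, "transcriptional", paths = pt),
               build_influence(g, "transcriptional"))
  expect_equal(build_influence(g, "phenotype", paths = pt),
               build_influence(g, "phenotype"))
})
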