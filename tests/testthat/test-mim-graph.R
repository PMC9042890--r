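test_that("toy map construction populates regulator caches", {
  g <- toy_tf_graph()
  expect_s3_class(g, "mim_graph")
  expect_equal(regulator_sets(g, "G")$tf, c("A", "B"))
  expect_equal(regulator_sets(g, "G")$enzymes, character())
})

test_that("loading is independent of input row order", {
  el <- toy_elements(c("A", "B", "G", "P"),
                     c("protein", "protein", "gene", "phenotype"),
                     submaps = list("s", "s", NULL, "s"))
  ia <- toy_edges(c("A", "1", "G", "transcriptional"),
                  c("B", "-1", "G", "transcriptional"),
                  c("A", "1", "B", "generic"),
                  c("B", "1", "P", "generic"))
  g1 <- mim_graph(el, ia, quiet = TRUE)
  set.seed(1)
  g2 <- mim_graph(el[sample(nrow(el)), ], ia[sample(nrow(ia)), ],
                  quiet = TRUE)
  d1 <- withr::local_tempdir()
  write_mim(g1, file.path(d1, "e1.json"), file.path(d1, "i1.json"), "json")
  write_mim(g2, file.path(d1, "e2.json"), file.path(d1, "i2.json"), "json")
  expect_identical(readLines(file.path(d1, "e1.json")),
                   readLines(file.path(d1, "e2.json")))
  expect_identical(readLines(file.path(d1, "i1.json")),
                   readLines(file.path(d1, "i2.json")))
})

test_that("round-trip through both dialects reproduces the graph", {
  g <- make_network(network_spec(seed = 11))
  d <- withr::local_tempdir()
  for (fmt in c("json", "tsv")) {
    ep <- file.path(d, paste0("e.", fmt))
    ip <- file.path(d, paste0("i.", fmt))
    write_mim(g, ep, ip, fmt)
    g2 <- read_mim(ep, ip, fmt, quiet = TRUE)
    expect_equal(g2$elements, g$elements)
    expect_equal(g2$interactions, g$interactions, ignore_attr = TRUE)
    expect_equal(g2$tf, g$tf)
    expect_equal(g2$enzymes, g$enzymes)
    expect_equal(g2$submap_members, g$submap_members)
    # serialize -> load -> serialize is byte-stable
    ep2 <- file.path(d, paste0("e2.", fmt))
    ip2 <- file.path(d, paste0("i2.", fmt))
    write_mim(g2, ep2, ip2, fmt)
    expect_identical(readLines(ep2), readLines(ep))
  }
})

test_that("loader rejects structural defects, naming the offender", {
  el <- toy_elements(c("A", "G"), c("protein", "gene"))
  expect_error(
    mim_graph(el, toy_edges(c("A", "1", "Z", "generic")), quiet = TRUE),
    "Z", class = "twodea_load_error")
  expect_error(
    mim_graph(el, toy_edges(c("A", "0", "G", "generic")), quiet = TRUE),
    "sign", class = "twodea_load_error")
  expect_error(
    mim_graph(el, toy_edges(c("A", "1", "A", "generic")), quiet = TRUE),
    "self-loop", class = "twodea_load_error")
  expect_error(
    mim_graph(toy_elements(c("A", "A"), c("protein", "protein")),
              toy_edges(c("A", "1", "A", "generic")), quiet = TRUE),
    "duplicate", class = "twodea_load_error")
})

test_that("duplicate triples collapse with set semantics, opposite signs coexist", {
  el <- toy_elements(c("A", "G"), c("protein", "gene"))
  ia <- toy_edges(c("A", "1", "G", "transcriptional"),
                  c("A", "1", "G", "transcriptional"),
                  c("A", "-1", "G", "transcriptional"))
  g <- mim_graph(el, ia, quiet = TRUE)
  expect_equal(nrow(g$interactions), 2L)
  expect_setequal(g$interactions$sign, c(-1L, 1L))
  # no row silently dropped: input rows = kept edges + collapsed duplicates
  expect_equal(g$n_input_rows, nrow(g$interactions) + g$n_collapsed)
})

test_that("validator censuses the map and reports violations", {
  el <- toy_elements(c("A", "M", "P", "R"),
                     c("protein", "metabolite", "phenotype", "miRNA"),
                     submaps = list("s", NULL, "s", NULL))
  ia <- toy_edges(c("A", "1", "M", "catalytic"),
                  c("A", "-1", "P", "generic"),
                  c("R", "-1", "A", "generic"),
                  c("R", "1", "M", "generic"),
                  c("A", "1", "R", "generic"),
                  c("M", "1", "P", "generic"))
  g <- mim_graph(el, ia, quiet = TRUE)
  rep <- mim_validate(g)
  expect_equal(rep$n_elements, 4L)
  expect_equal(rep$n_interactions, 6L)
  expect_equal(as.integer(rep$bio_type_counts[["phenotype"]]), 1L)
  expect_equal(as.integer(rep$sign_counts[["1"]]), 4L)
  expect_equal(as.integer(rep$sign_counts[["-1"]]), 2L)
  expect_equal(nrow(rep$violations), 0L)

  # an isolated phenotype is a reported violation, not an error
  el2 <- toy_elements(c("A", "P"), c("protein", "phenotype"),
                      submaps = list(NULL, "s"))
  g2 <- mim_graph(el2, toy_edges(c("P", "1", "A", "generic")), quiet = TRUE)
  rep2 <- mim_validate(g2)
  expect_true("isolated_phenotype" %in% rep2$violations$kind)
  expect_true("P" %in% rep2$violations$id)
})

test_that("regulator caches match a brute-force scan of the interaction table", {
  for (seed in c(2, 5, 9)) {
    g <- random_mim(seed)
    ia <- g$interactions
    for (v in g$elements$id) {
      rs <- regulator_sets(g, v)
      expect_equal(rs$tf, sort(unique(
        ia$source[ia$target == v & ia$iclass == "transcriptional"])))
      expect_equal(rs$enzymes, sort(unique(
        ia$source[ia$target == v & ia$iclass == "catalytic"])))
    }
  }
})

test_that("enzyme regulator set includes both synthesizing and consuming enzymes", {
  el <- toy_elements(c("E1", "E2", "M"), c("protein", "protein", "metabolite"))
  ia <- toy_edges(c("E1", "1", "M", "catalytic"),
                  c("E2", "-1", "M", "catalytic"))
  g <- mim_graph(el, ia, quiet = TRUE)
  expect_equal(regulator_sets(g, "M")$enzymes, c("E1", "E2"))
})

test_that("submap neighbourhood excludes the element itself", {
  g <- toy_linear_submap()
  expect_equal(regulator_sets(g, "v")$submap, c("a", "b"))
  expect_error(regulator_sets(g, "zz"), "not found",
               class = "twodea_lookup_error")
})

test_that("symbol matching prefers exact ids, then case-insensitive names", {
  el <- tibble::tibble(id = c("g1", "g2"), name = c("Actb", "ACTB"),
                       bio_type = "gene")
  g <- mim_graph(el, toy_edges(c("g1", "1", "g2", "generic")), quiet = TRUE)
  expect_equal(match_symbols(g, "g1"), "g1")
  # ambiguous case-insensitive name -> unmatched
  expect_true(is.na(match_symbols(g, "actb")))
  el2 <- tibble::tibble(id = c("g1", "g2"), name = c("Actb", "Gapdh"),
                        bio_type = "gene")
  g2 <- mim_graph(el2, toy_edges(c("g1", "1", "g2", "generic")), quiet = TRUE)
  expect_equal(match_symbols(g2, c("ACTB", "gapdh", "nope")),
               c("g1", "g2", NA))
})
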