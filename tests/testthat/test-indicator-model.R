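test_that("label normalization canonicalizes case, whitespace and punctuation", {
  expect_identical(normalize_label("  Dysphagia "), "dysphagia")
  expect_identical(normalize_label("Forced   Vital\tCapacity"),
                   "forced vital capacity")
  syn <- synonym_map(c("quality of life" = "qol"))
  expect_identical(normalize_label("Quality-of-Life", syn), "qol")
  expect_error(normalize_label("   "), class = "neutrality_invalid_label")
  expect_error(normalize_label("!!!"), class = "neutrality_invalid_label")
})

test_that("normalization is idempotent on a fuzz corpus", {
  set.seed(101)
  syn <- synonym_map(c("pain score" = "pain", "qol" = "quality of life"))
  for (i in 1:200) {
    raw <- random_label()
    once <- normalize_label(raw, syn)
    expect_identical(normalize_label(once, syn), once)
  }
})

test_that("synonym chains resolve and cycles are rejected", {
  syn <- synonym_map(c(a = "b", b = "c"))
  expect_identical(normalize_label("a", syn), "c")
  expect_error(synonym_map(c(a = "b", b = "a")),
               class = "neutrality_invalid_synonyms")
})

test_that("domain constructors enforce their invariants", {
  expect_error(severity_scale("d", "s", 2000, character(0)),
               class = "neutrality_empty_scale")
  expect_error(study_endpoints("d", "s1", "x", sample_size = 0),
               class = "neutrality_invalid_sample_size")
  # duplicate labels collapse within a scale
  sc <- make_scale(c("Pain", "pain ", "fatigue"))
  expect_length(sc$indicators, 2L)
  # a study with no endpoints is valid
  expect_length(make_study(character(0))$endpoints, 0L)
  # dataset members must share the disease and scales sort by year then name
  s1 <- make_scale("x", name = "b", year = 2010)
  s2 <- make_scale("y", name = "a", year = 2001)
  s3 <- make_scale("z", name = "a", year = 2010)
  ds <- disease_dataset(list(s1, s2, s3))
  expect_identical(vapply(ds$scales, `[[`, character(1), "name"),
                   c("a", "a", "b"))
  expect_error(
    disease_dataset(list(s1), list(make_study("x", disease = "other"))),
    class = "neutrality_cross_disease")
  expect_error(
    disease_dataset(list(s1), list(make_study("x"), make_study("y"))),
    class = "neutrality_duplicate_study")
})

test_that("the observation universe unions studies, reference and extras", {
  ds <- disease_dataset(
    list(make_scale(c("x1", "x2"))),
    list(make_study(c("x1", "y1"), "S1"), make_study("y2", "S2"))
  )
  u <- observation_universe(ds, ds$scales[[1]])
  expect_setequal(u, c("x1", "x2", "y1", "y2"))
  extra <- make_scale("z1", name = "later", year = 2010)
  expect_setequal(observation_universe(ds, ds$scales[[1]], extra),
                  c("x1", "x2", "y1", "y2", "z1"))
  foreign <- make_scale("w", disease = "other")
  expect_error(observation_universe(ds, foreign),
               class = "neutrality_cross_disease")
})

test_that("universe size matches a brute-force pairwise-dedup oracle", {
  set.seed(202)
  for (i in 1:100) {
    pool <- toks("i", 20)
    ref <- make_scale(sample(pool, sample(1:8, 1)))
    studies <- lapply(seq_len(sample(1:4, 1)), function(j) {
      make_study(sample(pool, sample(0:10, 1)), id = paste0("s", j))
    })
    ds <- disease_dataset(list(ref), studies)
    u <- observation_universe(ds, ref)
    oracle <- brute_union(c(lapply(studies, `[[`, "endpoints"),
                            list(ref$indicators)))
    expect_setequal(u, oracle)
    expect_length(u, length(oracle))
  }
})

test_that("endpoint classification reproduces the four-cell definitions", {
  u <- c("x1", "x2", "y1", "y2")
  tab <- classify_endpoints(c("x1", "y1"), c("x1", "x2"), u)
  expect_identical(unclass(tab)[c("a", "b", "c", "d")],
                   list(a = 1L, b = 1L, c = 1L, d = 1L))
  # perfect match: all reference found, nothing redundant
  ref <- toks("r", 5)
  tab2 <- classify_endpoints(ref, ref, c(ref, toks("e", 3)))
  expect_identical(c(tab2$a, tab2$b, tab2$c, tab2$d), c(5L, 0L, 0L, 3L))
  # total miss
  tab3 <- classify_endpoints(character(0), ref, c(ref, toks("e", 4)))
  expect_identical(c(tab3$a, tab3$b, tab3$c, tab3$d), c(0L, 0L, 5L, 4L))
  expect_error(classify_endpoints("zz", ref, c(ref, "e1")),
               class = "neutrality_universe_incomplete")
  expect_error(classify_endpoints("e1", c(ref, "outside"), c(ref, "e1")),
               class = "neutrality_universe_incomplete")
})

test_that("cells agree with a double-loop oracle and conserve the margins", {
  set.seed(303)
  for (i in 1:100) {
    pool <- toks("i", sample(5:20, 1))
    ref <- sample(pool, sample(1:length(pool), 1))
    study <- sample(pool, sample(0:length(pool), 1))
    tab <- classify_endpoints(study, ref, pool)
    oracle <- brute_cells(study, ref, pool)
    expect_identical(unclass(tab)[c("a", "b", "c", "d")], oracle)
    expect_identical(tab$a + tab$b + tab$c + tab$d, length(pool))
    expect_identical(tab$a + tab$c, length(ref))
    expect_identical(tab$b + tab$d, length(pool) - length(ref))
  }
})

test_that("re-ingesting an already-normalized dataset changes no counts", {
  sc <- make_scale(c("Pain Score", "Fatigue!", "  QoL"))
  again <- make_scale(sc$indicators)
  expect_identical(again$indicators, sc$indicators)
})
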