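test_that("the Neutrality score follows the cell definitions", {
  # perfect: every scale item overlapped, every outside item irrelevant
  res <- neutrality_score(classification_table(4, 0, 0, 6))
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$neutrality, 2)
  expect_true(res$acceptable)
  # total mismatch: nothing overlaps and every outside item was used
  worst <- neutrality_score(classification_table(0, 5, 3, 0))
  expect_equal(worst$neutrality, 0)
  expect_false(worst$acceptable)
  # hand arithmetic on mixed cells
  mid <- neutrality_score(classification_table(10, 5, 1, 40))
  expect_equal(mid$sensitivity, 10 / 11)
  expect_equal(mid$specificity, 40 / 45)
  expect_equal(mid$neutrality, 10 / 11 + 40 / 45)
  expect_true(mid$acceptable)
})

test_that("acceptability is strict: a score of exactly 1.50 is not acceptable", {
  res <- neutrality_score(classification_table(3, 1, 1, 3))
  expect_equal(res$neutrality, 1.5)
  expect_false(res$acceptable)
})

test_that("degenerate tables are refused rather than given a convention", {
  expect_error(neutrality_score(classification_table(0, 2, 0, 3)),
               class = "neutrality_empty_reference")
  expect_error(neutrality_score(classification_table(2, 0, 1, 0)),
               class = "neutrality_empty_complement")
})

test_that("scores stay in range over random classification tables", {
  set.seed(42)
  for (i in 1:200) {
    tab <- classification_table(sample(0:20, 1), sample(0:20, 1),
                                sample(0:20, 1), sample(0:20, 1))
    if (tab$a + tab$c == 0 || tab$b + tab$d == 0) next
    res <- neutrality_score(tab)
    expect_gte(res$sensitivity, 0); expect_lte(res$sensitivity, 1)
    expect_gte(res$specificity, 0); expect_lte(res$specificity, 1)
    expect_gte(res$neutrality, 0); expect_lte(res$neutrality, 2)
    expect_equal(res$neutrality, res$sensitivity + res$specificity)
  }
})

test_that("composites deduplicate by label and keep the bookkeeping identity", {
  s1 <- make_scale(c("p", "q", "r"), name = "first", year = 2001)
  s2 <- make_scale(c("q", "s"), name = "second", year = 2005)
  comp <- build_composite(list(s2, s1)) # order given doesn't matter
  expect_setequal(comp$indicators, c("p", "q", "r", "s"))
  expect_identical(comp$duplicates_excluded, 1L)
  expect_identical(comp$member_scales, c("first", "second")) # year order
  # disjoint scales of sizes 25 and 12 pool to 37 with nothing excluded
  big <- build_composite(list(make_scale(toks("a", 25), name = "a"),
                              make_scale(toks("b", 12), name = "b", year = 2009)))
  expect_length(big$indicators, 37L)
  expect_identical(big$duplicates_excluded, 0L)
  expect_error(build_composite(list()), class = "neutrality_empty_composite")
  expect_error(
    build_composite(list(s1, make_scale("x", disease = "other"))),
    class = "neutrality_cross_disease")
})

test_that("composite union size matches a brute-force oracle on random scales", {
  set.seed(7)
  for (i in 1:100) {
    pool <- toks("i", 30)
    scales <- lapply(seq_len(sample(1:4, 1)), function(j) {
      make_scale(sample(pool, sample(1:12, 1)), name = paste0("s", j),
                 year = 2000L + j)
    })
    comp <- build_composite(scales)
    oracle <- brute_union(lapply(scales, `[[`, "indicators"))
    expect_length(comp$indicators, length(oracle))
    sizes <- vapply(scales, function(s) length(s$indicators), integer(1))
    expect_identical(length(comp$indicators) + comp$duplicates_excluded,
                     as.integer(sum(sizes)))
  }
})

test_that("a study matching its scale exactly scores N = 2", {
  ref <- make_scale(toks("r", 6), name = "first")
  perfect <- make_study(ref$indicators, "perfect")
  other <- make_study(toks("e", 4), "other")
  ds <- disease_dataset(list(ref), list(perfect, other))
  res <- score_study(perfect, ref, ds)
  expect_equal(res$neutrality, 2)
  expect_true(res$acceptable)
})

test_that("folding a disjoint composite into the universe moves only d and Sp", {
  ref <- make_scale(toks("r", 5), name = "first", year = 2000)
  later <- make_scale(toks("z", 4), name = "later", year = 2008)
  st <- make_study(c(toks("r", 3), "e1"), "s1")
  other <- make_study(c("e1", "e2"), "s2")
  ds <- disease_dataset(list(ref, later), list(st, other))
  plain <- score_study(st, ref, ds)
  folded <- score_study(st, ref, ds, fold_in = build_composite(list(later)))
  expect_identical(folded$table$a, plain$table$a)
  expect_identical(folded$table$c, plain$table$c)
  expect_identical(folded$table$b, plain$table$b)
  expect_identical(folded$table$d, plain$table$d + 4L)
  expect_equal(folded$sensitivity, plain$sensitivity)
  expect_gt(folded$specificity, plain$specificity)
})

test_that("adding an overlapping endpoint never lowers Se; a redundant one never raises Sp", {
  set.seed(11)
  for (i in 1:50) {
    pool <- toks("i", 15)
    extras <- toks("e", 6)
    ref <- sample(pool, sample(2:10, 1))
    study <- c(sample(ref, sample(0:(length(ref) - 1), 1)),
               sample(extras, sample(0:4, 1)))
    universe <- c(pool, extras)
    base <- neutrality_score(classify_endpoints(study, ref, universe))
    missing <- setdiff(ref, study)
    if (length(missing) > 0) {
      plus_overlap <- neutrality_score(
        classify_endpoints(c(study, missing[1]), ref, universe))
      expect_gte(plus_overlap$sensitivity, base$sensitivity)
    }
    unused <- setdiff(extras, study)
    if (length(unused) > 0) {
      plus_redundant <- neutrality_score(
        classify_endpoints(c(study, unused[1]), ref, universe))
      expect_lte(plus_redundant$specificity, base$specificity)
    }
  }
})

test_that("score_studies returns one tidy row per study", {
  ref <- make_scale(toks("r", 4), name = "first")
  ds <- disease_dataset(
    list(ref),
    list(make_study(ref$indicators, "good", sample_size = 40),
         make_study("e1", "bad"))
  )
  res <- score_studies(ds)
  expect_identical(nrow(res), 2L)
  expect_identical(res$study_id, c("good", "bad"))
  expect_equal(res$neutrality, res$sensitivity + res$specificity)
  expect_identical(res$sample_size, c(40L, NA_integer_))
  expect_identical(res$a + res$b + res$c + res$d, rep(5L, 2))
})
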