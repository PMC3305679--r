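# Synthetic-corpus generator: determinism, terminology validity, and
# end-to-end ground-truth consistency.

test_that("generation is a pure function of the spec", {
  spec <- fixture_spec(seed = 1, n_monographs = 10, n_forms = 8)
  a <- generate_terminology(spec)
  b <- generate_terminology(spec)
  expect_identical(a, b)
  ca <- generate_monographs(spec, a)
  cb <- generate_monographs(spec, b)
  expect_identical(ca, cb)
  # and byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_corpus(spec, d1)
  write_fixture_corpus(spec, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
})

test_that("the generated terminology loads and keeps the backbone", {
  spec <- fixture_spec(seed = 2, n_forms = 26)
  term <- generate_terminology(spec)
  tree <- load_terminology(term$concepts, term$tree)
  expect_true(all(c("Solid", "Tablet", "Oral Tablet", "Vaginal Tablet",
                    "Extended Release Tablet", "Oral Capsule",
                    "Extended Release Capsule", "Oral Solution") %in%
                  term$concepts$name))
  # multi-parent concept has exactly two tree numbers
  erect <- term$tree$tree_number[term$tree$concept_id == "ERECT"]
  expect_length(erect, 2)
  expect_true(is_ancestor(tree, "ECT", "ERECT") && is_ancestor(tree, "ERT", "ERECT"))
  # branded records reference existing concepts
  expect_true(all(term$branded$dosage_form_concept_id %in% term$concepts$concept_id))
  expect_false(any(duplicated(term$branded$brand_name)))
  expect_error(fixture_spec(n_forms = 3))
})

test_that("gold is the projection of the manifest and sentences carry their patterns", {
  spec <- fixture_spec(seed = 3, n_monographs = 25)
  term <- generate_terminology(spec)
  corpus <- generate_monographs(spec, term)
  tree <- load_terminology(term$concepts, term$tree)

  for (entry in corpus$manifest) {
    gold_ids <- corpus$gold$concept_id[corpus$gold$monograph_id == entry$monograph_id]
    expect_setequal(gold_ids, entry$planted)
    # planted sets are antichains
    for (a in entry$planted) for (b in entry$planted) {
      expect_false(is_ancestor(tree, a, b))
    }
    # extracted evidence recovers exactly the planted sentences and patterns
    m <- corpus$monographs[[entry$monograph_id]]
    ev <- extract_evidence(m)
    expect_setequal(ev$sentence, unname(entry$sentences))
    expect_identical(
      sort(ev$pattern),
      sort(names(entry$sentences))
    )
  }
})

test_that("a noise-free corpus is recovered perfectly end to end", {
  spec <- fixture_spec(seed = 4, n_monographs = 40, route_noise = 0,
                       distractor_rate = 0.5, brand_dropout = 0)
  term <- generate_terminology(spec)
  corpus <- generate_monographs(spec, term)
  tree <- load_terminology(term$concepts, term$tree)
  res <- identify_corpus(corpus$monographs, tree)
  ev <- macro_evaluate(res, load_gold(corpus$gold, tree))
  expect_true(all(ev$summary$mean == 1))
  expect_true(all(ev$summary$sd == 0))
})

test_that("silver built from the generated brand tables equals the planted sets", {
  spec <- fixture_spec(seed = 6, n_monographs = 30, brand_dropout = 0)
  term <- generate_terminology(spec)
  corpus <- generate_monographs(spec, term)
  tree <- load_terminology(term$concepts, term$tree)
  silver <- build_silver(corpus$monographs, term$branded, tree)
  expect_length(silver$excluded, 0)
  for (id in names(silver$entries)) {
    expect_setequal(silver$entries[[id]], corpus$manifest[[id]]$planted)
  }
})

test_that("full brand dropout excludes every monograph", {
  spec <- fixture_spec(seed = 7, n_monographs = 12, brand_dropout = 1)
  term <- generate_terminology(spec)
  corpus <- generate_monographs(spec, term)
  tree <- load_terminology(term$concepts, term$tree)
  silver <- build_silver(corpus$monographs, term$branded, tree)
  expect_length(silver$entries, 0)
  expect_true(all(silver$excluded == "NO_BRAND_SECTION"))
})

test_that("planted dosage-form counts follow the 1/2/3 mixture", {
  spec <- fixture_spec(seed = 8, n_monographs = 300)
  corpus <- generate_monographs(spec, generate_terminology(spec))
  counts <- table(corpus$gold$monograph_id)
  expect_true(all(counts %in% 1:3))
  # mean 1.6 by design; loose band for a 300-draw sample
  expect_gt(mean(counts), 1.35)
  expect_lt(mean(counts), 1.85)
})
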