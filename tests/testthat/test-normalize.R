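# Route translation, title-route enrichment, stem-bag matching, the full
# identification pipeline, and the baseline lookup.

test_that("lay route expressions translate to concept-name route terms", {
  expect_identical(
    translate_routes("Moxifloxacin comes as tablet to take by mouth."),
    "Moxifloxacin comes as tablet to take oral."
  )
  expect_match(
    translate_routes("It is an ointment to apply to the eyes."),
    "ophthalmic"
  )
  expect_identical(translate_routes("No route words here."),
                   "No route words here.")
})

test_that("translation is case-insensitive, word-bounded, longest-first", {
  expect_identical(translate_routes("Take BY MOUTH daily."), "Take oral daily.")
  # "into the ears" must not be half-replaced by a shorter overlapping rule
  expect_identical(translate_routes("Drop it into the ears gently."),
                   "Drop it otic gently.")
  # no replacement inside words
  expect_identical(translate_routes("The bymouth token stays."),
                   "The bymouth token stays.")
})

test_that("enrichment appends the title routes; empty route is identity", {
  seg <- segment_title("Propranolol Oral")
  expect_identical(
    enrich_with_routes("It also comes as a solution or concentrate.", seg),
    "It also comes as a solution or concentrate. oral"
  )
  seg0 <- segment_title("Acetaminophen")
  expect_identical(enrich_with_routes("Unchanged.", seg0), "Unchanged.")
  seg2 <- segment_title("Drug Ophthalmic Topical")
  expect_identical(enrich_with_routes("S.", seg2), "S. ophthalmic topical")
})

test_that("stem bags are unique stems of the tokenized sentence", {
  bag <- to_stem_bag("It also comes as a solution or concentrate. oral")
  expect_true(all(c("solut", "oral") %in% bag))
  expect_identical(to_stem_bag(""), character(0))
  s <- "Tablets and tablets, more TABLETS."
  expect_identical(to_stem_bag(s),
                   unique(porter_stem(tokenize_words(s)[[1]])))
})

test_that("a concept matches when all of its stems are in the bag", {
  tree <- make_worked_example_tree()
  bag <- to_stem_bag("Moxifloxacin comes as tablet to take oral.")
  expect_identical(match_dosage_forms(bag, tree), "ORAL_TAB")
  expect_identical(match_dosage_forms(character(0), tree), character(0))
})

test_that("match_dosage_forms equals the exhaustive subset-test oracle", {
  tree <- make_tablet_tree()
  universe <- unique(unlist(tree$concepts$stems))
  extra <- c("take", "use", "appli", "daili", "water")
  set.seed(11)
  for (i in 1:300) {
    bag <- unique(sample(c(universe, extra), sample(0:8, 1)))
    want <- tree$concepts$concept_id[
      vapply(tree$concepts$stems, function(st) all(st %in% bag), logical(1))]
    expect_setequal(match_dosage_forms(bag, tree), want)
  }
})

test_that("matching is monotone in the bag", {
  tree <- make_tablet_tree()
  set.seed(3)
  universe <- unique(unlist(tree$concepts$stems))
  for (i in 1:50) {
    bag <- unique(sample(universe, sample(1:5, 1)))
    bigger <- unique(c(bag, sample(universe, 2)))
    expect_true(all(match_dosage_forms(bag, tree) %in%
                    match_dosage_forms(bigger, tree)))
  }
})

test_that("the bag-of-words pipeline reproduces the cyclobenzaprine cross-match", {
  tree <- make_worked_example_tree()
  m <- usage_monograph("cyclobenzaprine", "Cyclobenzaprine",
    "Cyclobenzaprine comes as a tablet and an extended release capsule to take by mouth.")
  res <- identify_dosage_forms(m, tree)
  # shared modifiers cross-match: the extended-release tablet is a known
  # false positive of the representation; the oral tablet is filtered out
  expect_setequal(res$dosage_forms, c("ERT", "ERC"))
})

test_that("the specificity filter keeps only the most specific candidate", {
  tree <- make_worked_example_tree()
  m <- usage_monograph("darifenacin", "Darifenacin",
    "Darifenacin comes as an extended-release (long-acting) tablet to take by mouth.")
  res <- identify_dosage_forms(m, tree)
  expect_identical(res$dosage_forms, "ERT")
  # the oral tablet is matched pre-filter and then removed
  expect_true("ORAL_TAB" %in% res$evidence$concept_id)
})

test_that("title enrichment and route translation each unlock a match", {
  tree <- load_terminology(
    data.frame(concept_id = c("ORAL_SOLN", "SOLN", "ORAL_TAB"),
               name = c("Oral Solution", "Solution", "Oral Tablet")),
    data.frame(concept_id = c("ORAL_SOLN", "SOLN", "ORAL_TAB"),
               tree_number = c("F2.1.1", "F2.1", "F4.23.1"))
  )
  prop <- usage_monograph("propranolol", "Propranolol Oral",
                          "It also comes as a solution or concentrate.")
  expect_true("ORAL_SOLN" %in% identify_dosage_forms(prop, tree)$dosage_forms)
  expect_false("ORAL_SOLN" %in%
               identify_dosage_forms(prop, tree, enrich = FALSE)$dosage_forms)

  moxi <- usage_monograph("moxifloxacin", "Moxifloxacin",
                          "Moxifloxacin comes as tablet to take by mouth.")
  expect_true("ORAL_TAB" %in% identify_dosage_forms(moxi, tree)$dosage_forms)
  expect_false("ORAL_TAB" %in%
               identify_dosage_forms(moxi, tree, translate = FALSE)$dosage_forms)
})

test_that("enrichment never shrinks the pre-filter candidate set", {
  tree <- make_tablet_tree()
  m <- usage_monograph("d", "Drug Oral",
                       "Drug comes as a tablet. It comes in capsule form.")
  with_e <- identify_dosage_forms(m, tree)
  without_e <- identify_dosage_forms(m, tree, enrich = FALSE)
  expect_true(all(without_e$evidence$concept_id %in% with_e$evidence$concept_id))
})

test_that("identification is deterministic", {
  tree <- make_tablet_tree()
  m <- usage_monograph("d", "Drug",
                       "Drug comes as a tablet to take by mouth.")
  expect_identical(identify_dosage_forms(m, tree), identify_dosage_forms(m, tree))
})

test_that("baseline matches unstemmed terms in the usage section only", {
  tree <- load_terminology(
    data.frame(concept_id = c("TAB", "ORAL_TAB"),
               name = c("Tablet", "Oral Tablet")),
    data.frame(concept_id = c("TAB", "ORAL_TAB"),
               tree_number = c("F4.23", "F4.23.1"))
  )
  m <- usage_monograph("d", "Drug",
                       "It comes as a tablet to take by mouth.")
  expect_identical(baseline_identify(m, tree)$dosage_forms, "TAB")
  # literal "oral tablet" in prose matches both; no specificity filter
  m2 <- usage_monograph("d2", "Drug", "Take the oral tablet daily.")
  expect_setequal(baseline_identify(m2, tree)$dosage_forms, c("TAB", "ORAL_TAB"))
  # unstemmed: plural "tablets" does not match the singular term
  m3 <- usage_monograph("d3", "Drug", "It comes as tablets.")
  expect_identical(baseline_identify(m3, tree)$dosage_forms, character(0))
  # empty / absent usage section
  m4 <- monograph("d4", "Drug", list("About your treatment" = "A tablet."))
  expect_identical(baseline_identify(m4, tree)$dosage_forms, character(0))
})

test_that("rule files round-trip through the TSV readers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(default_translation_rules(), tmp)
  expect_identical(read_translation_rules(tmp), default_translation_rules())
})

test_that("the shipped config files match the built-in defaults", {
  rules <- system.file("extdata", "translation_rules.tsv", package = "dfid")
  expect_identical(read_translation_rules(rules), default_translation_rules())
  markers <- system.file("extdata", "route_markers.txt", package = "dfid")
  expect_identical(read_route_markers(markers), default_route_markers())
})
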