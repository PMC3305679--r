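# Silver-standard construction from brand names and gold-standard loading.

branded_fixture <- function() {
  data.frame(
    branded_drug_name = c("Fluoxetine 4 MG/ML Oral Solution [Prozac]",
                          "Chlordiazepoxide 100 MG Injectable Solution [Librium]",
                          "Chlordiazepoxide 5 MG Oral Capsule [Librium]",
                          "Nolink 1 MG Oral Tablet [Nolink]"),
    brand_name = c("Prozac", "Librium", "Librium", "Nolink"),
    dosage_form_concept_id = c("ORAL_SOLN", "INJ_SOLN", "ORAL_CAP", NA)
  )
}

silver_tree <- function() {
  load_terminology(
    data.frame(concept_id = c("ORAL_SOLN", "INJ_SOLN", "ORAL_CAP"),
               name = c("Oral Solution", "Injectable Solution", "Oral Capsule")),
    data.frame(concept_id = c("ORAL_SOLN", "INJ_SOLN", "ORAL_CAP"),
               tree_number = c("F2.1.1", "F2.1.2", "F4.24.1"))
  )
}

test_that("a brand maps through its branded-drug record to its dosage form", {
  ms <- list(monograph("fluoxetine", "Fluoxetine", brand_names = "Prozac"))
  std <- build_silver(ms, branded_fixture(), silver_tree())
  expect_identical(std$entries$fluoxetine, "ORAL_SOLN")
  expect_length(std$excluded, 0)
})

test_that("all dosage forms of a multi-product brand are unioned", {
  ms <- list(monograph("chlordiazepoxide", "Chlordiazepoxide",
                       brand_names = "Librium"))
  std <- build_silver(ms, branded_fixture(), silver_tree())
  expect_setequal(std$entries$chlordiazepoxide, c("INJ_SOLN", "ORAL_CAP"))
})

test_that("failure modes are recorded with their reasons", {
  ms <- list(
    monograph("dicloxacillin", "Dicloxacillin"),                      # no brands
    monograph("strontium", "Strontium-89 Chloride",
              brand_names = "Metastron"),                             # unmapped
    monograph("nolink", "Nolinkine", brand_names = "Nolink")          # no DF link
  )
  std <- build_silver(ms, branded_fixture(), silver_tree())
  expect_length(std$entries, 0)
  expect_identical(std$excluded[["dicloxacillin"]], "NO_BRAND_SECTION")
  expect_identical(std$excluded[["strontium"]], "BRAND_UNMAPPED")
  expect_identical(std$excluded[["nolink"]], "NO_DF_LINK")
})

test_that("brand matching strips trademark glyphs and ignores case", {
  ms <- list(monograph("m", "M", brand_names = "PROZAC®"))
  std <- build_silver(ms, branded_fixture(), silver_tree())
  expect_identical(std$entries$m, "ORAL_SOLN")
})

test_that("one mapped brand suffices; failed brands contribute nothing", {
  ms <- list(monograph("m", "M", brand_names = c("Unknownil", "Prozac")))
  std <- build_silver(ms, branded_fixture(), silver_tree())
  expect_identical(std$entries$m, "ORAL_SOLN")
})

test_that("every monograph lands in exactly one of entries or excluded", {
  spec <- fixture_spec(seed = 5, n_monographs = 30, brand_dropout = 0.3)
  term <- generate_terminology(spec)
  corpus <- generate_monographs(spec, term)
  tree <- load_terminology(term$concepts, term$tree)
  std <- build_silver(corpus$monographs, term$branded, tree)
  ids <- vapply(corpus$monographs, `[[`, character(1), "monograph_id")
  expect_setequal(c(names(std$entries), names(std$excluded)), ids)
  expect_length(intersect(names(std$entries), names(std$excluded)), 0)
  # silver is independent of monograph order
  std_rev <- build_silver(rev(corpus$monographs), term$branded, tree)
  expect_setequal(names(std_rev$entries), names(std$entries))
  expect_identical(std_rev$entries[names(std$entries)], std$entries)
  # silver entries are never empty
  expect_true(all(lengths(std$entries) > 0))
})

test_that("gold standards load and round-trip through TSV", {
  tree <- silver_tree()
  gold <- load_gold(data.frame(monograph_id = c("m1", "m1", "m2"),
                               concept_id = c("ORAL_SOLN", "ORAL_CAP", "INJ_SOLN")),
                    tree)
  expect_identical(gold$kind, "gold")
  expect_setequal(gold$entries$m1, c("ORAL_SOLN", "ORAL_CAP"))
  expect_length(gold$entries$m2, 1)

  empty <- load_gold(data.frame(monograph_id = character(0),
                                concept_id = character(0)), tree)
  expect_length(empty$entries, 0)

  expect_error(
    load_gold(data.frame(monograph_id = "m1", concept_id = "BOGUS"), tree),
    "BOGUS", class = "dfid_load_error"
  )

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_standard(gold, tmp)
  gold2 <- load_gold(tmp, tree)
  expect_identical(gold2$entries[sort(names(gold2$entries))],
                   gold$entries[sort(names(gold$entries))])
})
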