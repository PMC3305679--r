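# Shared in-code fixtures: small dosage-form trees and worked-example
# monographs used across the test files.

# eight-concept tree mirroring the tablet branch of the hierarchy, with a
# multi-parent leaf (two tree numbers) for exhaustive antichain checks
make_tablet_tree <- function() {
  concepts <- data.frame(
    concept_id = c("SOLID", "TAB", "ORAL_TAB", "VAG_TAB", "ECT", "ERT", "ERECT", "ORAL_CAP"),
    name = c("Solid", "Tablet", "Oral Tablet", "Vaginal Tablet",
             "Enteric Coated Tablet", "Extended Release Tablet",
             "Extended Release Enteric Coated Tablet", "Oral Capsule")
  )
  numbers <- data.frame(
    concept_id = c("SOLID", "TAB", "ORAL_TAB", "VAG_TAB", "ECT", "ERT",
                   "ERECT", "ERECT", "ORAL_CAP"),
    tree_number = c("F4", "F4.23", "F4.23.1", "F4.23.2", "F4.23.1.4",
                    "F4.23.1.5", "F4.23.1.4.1", "F4.23.1.5.1", "F4.24.1")
  )
  load_terminology(concepts, numbers)
}

# tablet + capsule tree for the error-analysis worked example
make_worked_example_tree <- function() {
  load_terminology(
    data.frame(
      concept_id = c("ORAL_TAB", "ERT", "ORAL_CAP", "ERC"),
      name = c("Oral Tablet", "Extended Release Tablet",
               "Oral Capsule", "Extended Release Capsule")
    ),
    data.frame(
      concept_id = c("ORAL_TAB", "ERT", "ORAL_CAP", "ERC"),
      tree_number = c("F4.23.1", "F4.23.1.5", "F4.24.1", "F4.24.1.1")
    )
  )
}

usage_monograph <- function(id, title, text,
                            section = "How should this medicine be used?",
                            brands = character(0)) {
  monograph(id, title, sections = stats::setNames(list(text), section),
            brand_names = brands)
}

# independent O(n^2) specificity filter: drop every candidate that is an
# ancestor of another candidate, checking all ordered pairs
brute_force_most_specific <- function(tree, candidates) {
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    is_anc <- FALSE
    for (j in seq_along(candidates)) {
      if (i != j && is_ancestor(tree, candidates[i], candidates[j])) is_anc <- TRUE
    }
    keep[i] <- !is_anc
  }
  candidates[keep]
}
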