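# Dosage-form terminology: concepts, dotted tree numbers, and the ancestor
# partial order they induce (the DFtree). Specificity is encoded purely in
# the tree numbers: "F4.23" (Tablet) is an ancestor of "F4.23.1" (Oral
# Tablet) because its dotted segments are a proper prefix. A concept may own
# several tree numbers (multi-parent membership), e.g. an extended-release
# enteric-coated tablet sits under both the enteric-coated and the
# extended-release branches.

#' Load a dosage-form terminology into a DFtree
#'
#' Reads the concept table and tree-number table and builds the hierarchy
#' used for specificity filtering. Concept-name stems are precomputed with
#' the configured stemmer so sentence stem-bags can be matched directly.
#'
#' @param concept_table Path to a TSV with header `concept_id<TAB>name`, or a
#'   data frame with those columns.
#' @param tree_table Path to a TSV with header `concept_id<TAB>tree_number`
#'   (one row per concept/number pair), or a data frame with those columns.
#' @param stemmer Word-stemming function; defaults to [porter_stem()].
#' @return An object of class `df_tree` with elements `concepts` (tibble:
#'   `concept_id`, `name`, list-column `stems`), `tree_numbers` (tibble:
#'   `concept_id`, `tree_number`), and `index` (named character mapping
#'   tree number to concept_id).
#' @examples
#' concepts <- data.frame(
#'   concept_id = c("C1", "C2"),
#'   name = c("Tablet", "Oral Tablet")
#' )
#' numbers <- data.frame(
#'   concept_id = c("C1", "C2"),
#'   tree_number = c("F4.23", "F4.23.1")
#' )
#' tree <- load_terminology(concepts, numbers)
#' is_ancestor(tree, "C1", "C2")
#' @export
load_terminology <- function(concept_table, tree_table, stemmer = porter_stem) {
  concepts <- .read_tsv_or_df(concept_table, c("concept_id", "name"))
  numbers <- .read_tsv_or_df(tree_table, c("concept_id", "tree_number"))

  if (nrow(concepts) == 0L) {
    rlang::abort("concept table is empty", class = "dfid_load_error")
  }
  dup_c <- concepts$concept_id[duplicated(concepts$concept_id)]
  if (length(dup_c)) {
    rlang::abort(
      paste0("duplicate concept_id in concept table: ", paste(unique(dup_c), collapse = ", ")),
      class = "dfid_load_error"
    )
  }
  dup_n <- numbers$tree_number[duplicated(numbers$tree_number)]
  if (length(dup_n)) {
    rlang::abort(
      paste0("tree number assigned to more than one concept: ", paste(unique(dup_n), collapse = ", ")),
      class = "dfid_load_error"
    )
  }
  unknown <- setdiff(numbers$concept_id, concepts$concept_id)
  if (length(unknown)) {
    rlang::abort(
      paste0("tree table references unknown concept_id: ", paste(unknown, collapse = ", ")),
      class = "dfid_load_error"
    )
  }
  bad_num <- numbers$tree_number[!grepl("^F[^.\\s]*(\\.[^.\\s]+)*$", numbers$tree_number)]
  if (length(bad_num)) {
    rlang::abort(
      paste0("malformed tree number: ", paste(bad_num, collapse = ", ")),
      class = "dfid_load_error"
    )
  }
  no_number <- setdiff(concepts$concept_id, numbers$concept_id)
  if (length(no_number)) {
    rlang::abort(
      paste0("concept without tree number: ", paste(no_number, collapse = ", ")),
      class = "dfid_load_error"
    )
  }

  concepts <- tibble::as_tibble(concepts[c("concept_id", "name")])
  concepts$stems <- lapply(concepts$name, stem_concept_name, stemmer = stemmer)

  index <- stats::setNames(numbers$concept_id, numbers$tree_number)

  structure(
    list(
      concepts = concepts,
      tree_numbers = tibble::as_tibble(numbers[c("concept_id", "tree_number")]),
      index = index
    ),
    class = "df_tree"
  )
}

#' @export
print.df_tree <- function(x, ...) {
  cat("<df_tree> ", nrow(x$concepts), " dosage-form concepts, ",
      nrow(x$tree_numbers), " tree numbers\n", sep = "")
  invisible(x)
}

.read_tsv_or_df <- function(x, cols) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_tsv(x, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  }
  if (!is.data.frame(x)) {
    rlang::abort("expected a file path or a data frame", class = "dfid_load_error")
  }
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    rlang::abort(
      paste0("missing column(s): ", paste(missing, collapse = ", ")),
      class = "dfid_load_error"
    )
  }
  as.data.frame(lapply(x[cols], as.character), stringsAsFactors = FALSE)
}

.tree_numbers_of <- function(tree, id) {
  tree$tree_numbers$tree_number[tree$tree_numbers$concept_id == id]
}

.check_concepts <- function(tree, ids) {
  unknown <- setdiff(ids, tree$concepts$concept_id)
  if (length(unknown)) {
    rlang::abort(
      paste0("unknown concept_id: ", paste(unknown, collapse = ", ")),
      class = "dfid_lookup_error"
    )
  }
  invisible(TRUE)
}

# proper dotted-segment prefix: "F4.2" is NOT a prefix of "F4.23"
.segment_prefix <- function(a, b) {
  sa <- strsplit(a, ".", fixed = TRUE)[[1]]
  sb <- strsplit(b, ".", fixed = TRUE)[[1]]
  length(sa) < length(sb) && all(sa == sb[seq_along(sa)])
}

#' Test the ancestor relation between two dosage-form concepts
#'
#' `a` is an ancestor of `b` when some tree number of `a` is a proper
#' dotted-segment prefix of some tree number of `b`. The relation is a strict
#' partial order: irreflexive (`is_ancestor(tree, x, x)` is `FALSE`) and
#' transitive. Comparison is by whole segments, so "F4.2" is not an ancestor
#' of "F4.23".
#'
#' @param tree A `df_tree` from [load_terminology()].
#' @param a,b Concept identifiers present in `tree`.
#' @return `TRUE` or `FALSE`.
#' @export
is_ancestor <- function(tree, a, b) {
  stopifnot(inherits(tree, "df_tree"))
  .check_concepts(tree, c(a, b))
  if (identical(a, b)) return(FALSE)
  na <- .tree_numbers_of(tree, a)
  nb <- .tree_numbers_of(tree, b)
  for (x in na) for (y in nb) if (.segment_prefix(x, y)) return(TRUE)
  FALSE
}

#' Keep only the most specific dosage-form concepts
#'
#' Removes from `candidates` every concept that is an ancestor of another
#' candidate, leaving an antichain under [is_ancestor()]. This is the
#' specificity filter applied to the per-monograph candidate union: when both
#' "Oral Tablet" and its child "Extended Release Tablet" are matched, only
#' the child is kept.
#'
#' @param tree A `df_tree`.
#' @param candidates Character vector of concept identifiers.
#' @return Character vector (subset of `candidates`, original order kept).
#' @export
most_specific <- function(tree, candidates) {
  stopifnot(inherits(tree, "df_tree"))
  candidates <- unique(candidates)
  .check_concepts(tree, candidates)
  if (length(candidates) <= 1L) return(candidates)
  drop <- vapply(candidates, function(a) {
    any(vapply(candidates, function(b) !identical(a, b) && is_ancestor(tree, a, b),
               logical(1)))
  }, logical(1))
  candidates[!drop]
}

#' Stem a dosage-form concept name
#'
#' Lowercases the name, splits on whitespace and hyphens, strips punctuation,
#' stems each token separately, and deduplicates — so "Oral Solution" yields
#' the stems "oral" and "solut".
#'
#' @param name Nonempty dosage-form name.
#' @param stemmer Word-stemming function; defaults to [porter_stem()].
#' @return Character vector of unique stems.
#' @export
stem_concept_name <- function(name, stemmer = porter_stem) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  unique(stemmer(tokenize_words(name)[[1]]))
}

#' Look up concept names for concept identifiers
#'
#' @param tree A `df_tree`.
#' @param ids Character vector of concept identifiers.
#' @return Character vector of names, same order as `ids`.
#' @export
concept_name <- function(tree, ids) {
  stopifnot(inherits(tree, "df_tree"))
  .check_concepts(tree, ids)
  tree$concepts$name[match(ids, tree$concepts$concept_id)]
}
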