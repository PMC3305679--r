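# Reference standards. The gold standard is a hand-annotated table of
# (monograph, dosage form) pairs. The silver standard is derived
# automatically: each brand name listed in a monograph is matched to
# branded-drug records (brand -> dosage form links, as in "Fluoxetine
# 4 MG/ML Oral Solution [Prozac]"), and the union of the linked dosage
# forms becomes the monograph's reference set. Monographs for which the
# derivation fails are excluded with a reason rather than scored.

FAILURE_REASONS <- c("NO_BRAND_SECTION", "BRAND_UNMAPPED", "NO_DF_LINK")

.strip_trademark <- function(x) {
  tolower(stringr::str_squish(stringr::str_replace_all(x, "[®™]", "")))
}

#' Read a branded-drug table
#'
#' TSV with header
#' `branded_drug_name<TAB>brand_name<TAB>dosage_form_concept_id`.
#'
#' @param path Path to the TSV, or a data frame with those columns.
#' @param tree Optional `df_tree`; when given, dosage-form ids are validated
#'   against it.
#' @return Tibble with the three columns.
#' @export
read_branded_drugs <- function(path, tree = NULL) {
  branded <- .read_tsv_or_df(path, c("branded_drug_name", "brand_name",
                                     "dosage_form_concept_id"))
  branded <- tibble::as_tibble(branded)
  if (!is.null(tree)) {
    unknown <- setdiff(stats::na.omit(branded$dosage_form_concept_id),
                       tree$concepts$concept_id)
    if (length(unknown)) {
      rlang::abort(paste0("branded-drug table references unknown dosage form: ",
                          paste(unknown, collapse = ", ")),
                   class = "dfid_load_error")
    }
  }
  branded
}

#' Build the silver standard from brand names
#'
#' For each monograph: brands are matched case-insensitively against the
#' branded-drug records after stripping trademark glyphs; the dosage forms
#' of all matched records are unioned. A monograph is excluded (with a
#' reason) when it lists no brands (`NO_BRAND_SECTION`), none of its brands
#' matches a record (`BRAND_UNMAPPED`), or matched records carry no
#' dosage-form link (`NO_DF_LINK`). Partial brand coverage still yields an
#' entry.
#'
#' @param monographs List of `monograph` objects.
#' @param branded Branded-drug table ([read_branded_drugs()] output or a
#'   path/data frame accepted by it). A missing dosage-form link is an empty
#'   or `NA` `dosage_form_concept_id`.
#' @param tree A `df_tree`; all linked dosage forms must exist in it.
#' @return A `reference_standard`: list with `kind = "silver"`, `entries`
#'   (named list monograph_id -> character vector of concept ids), and
#'   `excluded` (named character vector monograph_id -> failure reason).
#' @export
build_silver <- function(monographs, branded, tree) {
  stopifnot(inherits(tree, "df_tree"))
  branded <- read_branded_drugs(branded, tree)
  brand_key <- .strip_trademark(branded$brand_name)

  entries <- list()
  excluded <- character(0)
  for (m in monographs) {
    stopifnot(inherits(m, "monograph"))
    id <- m$monograph_id
    if (!length(m$brand_names)) {
      excluded[[id]] <- "NO_BRAND_SECTION"
      next
    }
    matched <- brand_key %in% .strip_trademark(m$brand_names)
    if (!any(matched)) {
      excluded[[id]] <- "BRAND_UNMAPPED"
      next
    }
    dfs <- branded$dosage_form_concept_id[matched]
    dfs <- unique(dfs[!is.na(dfs) & nzchar(dfs)])
    if (!length(dfs)) {
      excluded[[id]] <- "NO_DF_LINK"
      next
    }
    entries[[id]] <- dfs
  }
  structure(list(kind = "silver", entries = entries, excluded = excluded),
            class = "reference_standard")
}

#' Load a gold standard from a label file
#'
#' TSV with header `monograph_id<TAB>concept_id`, one row per annotated
#' (monograph, dosage form) pair.
#'
#' @param gold_file Path to the TSV or a data frame with those columns.
#' @param tree A `df_tree`; every concept id must exist in it.
#' @return A `reference_standard` with `kind = "gold"` and empty `excluded`.
#' @export
load_gold <- function(gold_file, tree) {
  stopifnot(inherits(tree, "df_tree"))
  gold <- .read_tsv_or_df(gold_file, c("monograph_id", "concept_id"))
  bad <- which(!gold$concept_id %in% tree$concepts$concept_id)
  if (length(bad)) {
    rlang::abort(paste0("gold row ", bad[1], " references unknown concept '",
                        gold$concept_id[bad[1]], "' (monograph '",
                        gold$monograph_id[bad[1]], "')"),
                 class = "dfid_load_error")
  }
  entries <- lapply(split(gold$concept_id, gold$monograph_id), unique)
  structure(list(kind = "gold", entries = entries, excluded = character(0)),
            class = "reference_standard")
}

#' @export
print.reference_standard <- function(x, ...) {
  cat("<reference_standard> kind = ", x$kind, ", ", length(x$entries),
      " entries, ", length(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Write a reference standard to TSV files
#'
#' Entries go to `monograph_id<TAB>concept_id`; exclusions (if any) to a
#' companion `monograph_id<TAB>reason` file.
#'
#' @param standard A `reference_standard`.
#' @param entries_path Output TSV for entries.
#' @param excluded_path Output TSV for exclusions; skipped when `NULL`.
#' @return `entries_path` invisibly.
#' @export
write_standard <- function(standard, entries_path, excluded_path = NULL) {
  stopifnot(inherits(standard, "reference_standard"))
  entries <- tibble::tibble(
    monograph_id = rep(names(standard$entries), lengths(standard$entries)),
    concept_id = unlist(standard$entries, use.names = FALSE) %||% character(0)
  )
  readr::write_tsv(entries, entries_path)
  if (!is.null(excluded_path)) {
    readr::write_tsv(tibble::tibble(monograph_id = names(standard$excluded),
                                    reason = unname(standard$excluded)),
                     excluded_path)
  }
  invisible(entries_path)
}
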