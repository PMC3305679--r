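# Normalization of evidence sentences to dosage-form concepts.
#
# Per sentence: (1) translate lay route expressions to the route vocabulary
# used in concept names ("by mouth" -> "oral"); (2) append the title's route
# terms (a sentence "It also comes as a solution." in a monograph titled
# "Propranolol Oral" becomes matchable against "Oral Solution"); (3) reduce
# the sentence to a bag of unique word stems; (4) a concept is matched when
# ALL of its name stems occur in the bag. Candidates are pooled across all
# evidence sentences of the monograph and the most-specific filter keeps
# only concepts that are not ancestors of other candidates.

#' Default lay-route translation rules
#'
#' Maps popular route expressions found in monograph prose to the route
#' terms used in dosage-form concept names. Ships with the common phrases
#' ("by mouth" -> "oral", "into the nose" -> "nasal", "into the ear" ->
#' "otic", "on the skin" -> "topical", "in the eye" -> "ophthalmic") and
#' their surface variants; the rule set is data, replaceable via
#' [read_translation_rules()].
#'
#' @return Tibble with columns `phrase`, `replacement`.
#' @export
default_translation_rules <- function() {
  tibble::tribble(
    ~phrase,            ~replacement,
    "by mouth",         "oral",
    "into nose",        "nasal",
    "into the nose",    "nasal",
    "in the nose",      "nasal",
    "into ear",         "otic",
    "into the ear",     "otic",
    "into the ears",    "otic",
    "in the ear",       "otic",
    "in the ears",      "otic",
    "on skin",          "topical",
    "on the skin",      "topical",
    "to the skin",      "topical",
    "in eye",           "ophthalmic",
    "in the eye",       "ophthalmic",
    "in the eyes",      "ophthalmic",
    "to the eye",       "ophthalmic",
    "to the eyes",      "ophthalmic",
    "into the vagina",  "vaginal",
    "into the rectum",  "rectal",
    "by injection",     "injectable",
  )
}

#' Read a translation-rule file
#'
#' TSV with header `phrase<TAB>replacement`, one rule per line.
#'
#' @param path Path to the rules TSV.
#' @return Tibble with columns `phrase`, `replacement`.
#' @export
read_translation_rules <- function(path) {
  rules <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  missing <- setdiff(c("phrase", "replacement"), names(rules))
  if (length(missing)) {
    rlang::abort(paste0("rules file missing column(s): ", paste(missing, collapse = ", ")),
                 class = "dfid_load_error")
  }
  tibble::tibble(phrase = tolower(rules$phrase), replacement = rules$replacement)
}

#' Translate lay route expressions in a sentence
#'
#' Replaces every rule phrase occurring in the sentence (case-insensitive,
#' word-boundary match) with its replacement token. Rules are applied
#' longest-phrase-first so "into the ear" wins over any shorter overlapping
#' phrase. Text without route expressions is returned unchanged.
#'
#' @param sentence Sentence string.
#' @param rules Tibble with columns `phrase`, `replacement`
#'   (default [default_translation_rules()]).
#' @return Translated sentence string.
#' @examples
#' translate_routes("Moxifloxacin comes as tablet to take by mouth.")
#' @export
translate_routes <- function(sentence, rules = default_translation_rules()) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  rules <- rules[order(-nchar(rules$phrase)), ]
  out <- sentence
  for (i in seq_len(nrow(rules))) {
    pat <- stringr::regex(paste0("\\b", stringr::str_replace_all(rules$phrase[i],
                                                                 "\\s+", "\\\\s+"), "\\b"),
                          ignore_case = TRUE)
    out <- stringr::str_replace_all(out, pat, rules$replacement[i])
  }
  out
}

#' Enrich a sentence with the title's route terms
#'
#' Appends the segmented route terms R from the monograph title to the
#' sentence (lowercased, space-separated). Matching is bag-of-stems, so the
#' appended position is immaterial; a sentence is unchanged when R is empty.
#'
#' @param sentence Sentence string.
#' @param seg A [segment_title()] result.
#' @return Enriched sentence string.
#' @export
enrich_with_routes <- function(sentence, seg) {
  stopifnot(inherits(seg, "title_segmentation"))
  if (!length(seg$route_terms)) return(sentence)
  paste(c(sentence, tolower(seg$route_terms)), collapse = " ")
}

#' Reduce a sentence to a bag of unique word stems
#'
#' @param sentence Sentence string (applied after translation and
#'   enrichment in the pipeline).
#' @param stemmer Word-stemming function; defaults to [porter_stem()].
#' @return Character vector of unique stems (empty for empty input).
#' @export
to_stem_bag <- function(sentence, stemmer = porter_stem) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  unique(stemmer(tokenize_words(sentence)[[1]]))
}

#' Match a stem bag against the dosage-form concepts
#'
#' A concept is identified when every stem of its name occurs in the bag.
#'
#' @param bag Character vector of stems ([to_stem_bag()] output).
#' @param tree A `df_tree`.
#' @return Character vector of matched concept identifiers.
#' @export
match_dosage_forms <- function(bag, tree) {
  stopifnot(inherits(tree, "df_tree"))
  hit <- vapply(tree$concepts$stems, function(st) all(st %in% bag), logical(1))
  tree$concepts$concept_id[hit]
}

#' Identify the dosage forms of a monograph
#'
#' Runs the full pipeline: title segmentation, evidence-sentence extraction
#' (patterns P1-P5), per-sentence route translation and title-route
#' enrichment, stem-bag matching against the terminology, union of
#' candidates across sentences, and the most-specific filter. A monograph
#' without evidence sections yields an empty result, never an error.
#'
#' @param m A `monograph`.
#' @param tree A `df_tree`.
#' @param markers Route-marker lexicon (default [default_route_markers()]).
#' @param rules Translation rules (default [default_translation_rules()]).
#' @param stemmer Word-stemming function (default [porter_stem()]).
#' @param enrich Append title routes to sentences (default `TRUE`; exposed
#'   for ablation).
#' @param translate Apply route translation rules (default `TRUE`; exposed
#'   for ablation).
#' @return An `identification_result`: list with `monograph_id`,
#'   `dosage_forms` (character vector of concept ids, an antichain under the
#'   tree's ancestor relation), and `evidence` (tibble `concept_id`,
#'   `pattern`, `section_name`, `sentence` recording which sentence produced
#'   each pre-filter candidate).
#' @examples
#' tree <- load_terminology(
#'   data.frame(concept_id = c("C1", "C2"),
#'              name = c("Oral Tablet", "Extended Release Tablet")),
#'   data.frame(concept_id = c("C1", "C2"),
#'              tree_number = c("F4.23.1", "F4.23.1.5"))
#' )
#' m <- monograph("darifenacin", "Darifenacin", sections = list(
#'   "How should this medicine be used?" =
#'     "Darifenacin comes as an extended-release (long-acting) tablet to take by mouth."
#' ))
#' identify_dosage_forms(m, tree)$dosage_forms
#' @export
identify_dosage_forms <- function(m, tree,
                                  markers = default_route_markers(),
                                  rules = default_translation_rules(),
                                  stemmer = porter_stem,
                                  enrich = TRUE, translate = TRUE) {
  stopifnot(inherits(m, "monograph"), inherits(tree, "df_tree"))
  seg <- segment_title(m$title, markers)
  ev <- extract_evidence(m, seg)

  evidence_rows <- list()
  candidates <- character(0)
  for (i in seq_len(nrow(ev))) {
    s <- ev$sentence[i]
    if (translate) s <- translate_routes(s, rules)
    if (enrich) s <- enrich_with_routes(s, seg)
    bag <- to_stem_bag(s, stemmer)
    hits <- match_dosage_forms(bag, tree)
    candidates <- union(candidates, hits)
    if (length(hits)) {
      evidence_rows[[length(evidence_rows) + 1L]] <- tibble::tibble(
        concept_id = hits,
        pattern = ev$pattern[i],
        section_name = ev$section_name[i],
        sentence = ev$sentence[i]
      )
    }
  }
  evidence <- if (length(evidence_rows)) {
    dplyr::bind_rows(evidence_rows)
  } else {
    tibble::tibble(concept_id = character(0), pattern = character(0),
                   section_name = character(0), sentence = character(0))
  }

  structure(
    list(
      monograph_id = m$monograph_id,
      dosage_forms = most_specific(tree, candidates),
      evidence = evidence
    ),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  cat("<identification_result> ", x$monograph_id, ": {",
      paste(x$dosage_forms, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Baseline dosage-form lookup
#'
#' Whole-section lookup used as the comparison method: a concept is
#' identified when all of its UNSTEMMED name terms occur (case-insensitive,
#' whole-word) in the usage section. No title segmentation, no route
#' translation, no enrichment, and no specificity filter — so "tablet" in
#' prose matches "Tablet" but not "Oral Tablet" unless "oral" is also
#' literally present, and ancestors are retained.
#'
#' @param m A `monograph`.
#' @param tree A `df_tree`.
#' @return An `identification_result` (with empty `evidence` provenance).
#' @export
baseline_identify <- function(m, tree) {
  stopifnot(inherits(m, "monograph"), inherits(tree, "df_tree"))
  keys <- vapply(names(m$sections), .canonical_section, character(1))
  usage <- unlist(m$sections[keys == "usage"], use.names = FALSE)
  words <- if (length(usage)) unique(unlist(tokenize_words(paste(usage, collapse = " ")))) else character(0)
  hit <- vapply(tree$concepts$name, function(nm) {
    terms <- tokenize_words(nm)[[1]]
    length(words) > 0L && all(terms %in% words)
  }, logical(1))
  structure(
    list(
      monograph_id = m$monograph_id,
      dosage_forms = tree$concepts$concept_id[hit],
      evidence = tibble::tibble(concept_id = character(0), pattern = character(0),
                                section_name = character(0), sentence = character(0))
    ),
    class = "identification_result"
  )
}

#' Identify dosage forms for a whole corpus
#'
#' @param monographs List of `monograph` objects.
#' @param tree A `df_tree`.
#' @param baseline Use [baseline_identify()] instead of the full pipeline.
#' @param ... Passed to [identify_dosage_forms()].
#' @return Named list of `identification_result`, keyed by monograph_id.
#' @export
identify_corpus <- function(monographs, tree, baseline = FALSE, ...) {
  res <- lapply(monographs, function(m) {
    if (baseline) baseline_identify(m, tree) else identify_dosage_forms(m, tree, ...)
  })
  stats::setNames(res, vapply(res, `[[`, character(1), "monograph_id"))
}
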