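# Synthetic fixture generation. Emits a mini dosage-form terminology whose
# backbone mirrors the hand-encoded hierarchy (Solid > Tablet > Oral
# Tablet / Vaginal Tablet, a multi-parent extended-release enteric-coated
# tablet, capsule and solution branches), a branded-drug table linking
# generated brand names to leaf forms, and a monograph corpus with planted
# dosage forms, evidence sentences instantiated from the P1-P5 templates,
# lay-route phrasing sampled at a configurable rate, distractor prose, and
# brand sections — everything recorded in a ground-truth manifest so
# end-to-end recovery is checkable.
#
# Planted dosage-form sets are antichains in the mini tree: the pipeline's
# most-specific filter would necessarily delete a planted ancestor of
# another planted form, so a non-antichain target set is unrecoverable by
# design, not by defect. Each planted form gets its own evidence sentence;
# the per-monograph count is 1/2/3 with probability 0.5/0.4/0.1 (mean 1.6,
# near the 1.55 forms per monograph of manually annotated consumer
# monographs).

#' Specification for a synthetic fixture corpus
#'
#' @param seed Integer random seed; all outputs are pure functions of the
#'   spec including the seed.
#' @param n_monographs Number of monographs to generate.
#' @param n_forms Requested number of dosage-form concepts (>= 4). The
#'   backbone hierarchy (19 concepts) is always present; larger values add
#'   extra leaf forms, up to the built-in inventory.
#' @param route_noise Probability that a planted evidence sentence expresses
#'   its route as a lay phrase needing translation ("by mouth") rather than
#'   the concept-name route term ("oral").
#' @param brand_dropout Probability that a monograph omits its "Brand names"
#'   section.
#' @param distractor_rate Probability of inserting each of the candidate
#'   non-evidence distractor sentences into a monograph.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_monographs = 50L, n_forms = 19L,
                         route_noise = 0.5, brand_dropout = 0,
                         distractor_rate = 0.5) {
  stopifnot(n_monographs >= 1L, n_forms >= 4L,
            route_noise >= 0, route_noise <= 1,
            brand_dropout >= 0, brand_dropout <= 1,
            distractor_rate >= 0, distractor_rate <= 1)
  structure(
    list(seed = as.integer(seed), n_monographs = as.integer(n_monographs),
         n_forms = as.integer(n_forms), route_noise = route_noise,
         brand_dropout = brand_dropout, distractor_rate = distractor_rate),
    class = "fixture_spec"
  )
}

# run expr with a private RNG stream; leaves the session RNG untouched
.with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.backbone_concepts <- function() {
  tibble::tribble(
    ~concept_id, ~name,                                      ~numbers,
    "SOLID",     "Solid",                                    "F4",
    "TAB",       "Tablet",                                   "F4.23",
    "ORAL_TAB",  "Oral Tablet",                              "F4.23.1",
    "VAG_TAB",   "Vaginal Tablet",                           "F4.23.2",
    "CHEW_TAB",  "Chewable Tablet",                          "F4.23.1.2",
    "ECT",       "Enteric Coated Tablet",                    "F4.23.1.4",
    "ERT",       "Extended Release Tablet",                  "F4.23.1.5",
    "ERECT",     "Extended Release Enteric Coated Tablet",   "F4.23.1.4.1|F4.23.1.5.1",
    "CAP",       "Capsule",                                  "F4.24",
    "ORAL_CAP",  "Oral Capsule",                             "F4.24.1",
    "ERC",       "Extended Release Capsule",                 "F4.24.1.1",
    "LIQUID",    "Liquid",                                   "F2",
    "SOLN",      "Solution",                                 "F2.1",
    "ORAL_SOLN", "Oral Solution",                            "F2.1.1",
    "INJ_SOLN",  "Injectable Solution",                      "F2.1.2",
    "OPH_SOLN",  "Ophthalmic Solution",                      "F2.1.3",
    "SEMI",      "Semisolid",                                "F3",
    "OINT",      "Ointment",                                 "F3.1",
    "OPH_OINT",  "Ophthalmic Ointment",                      "F3.1.1",
  )
}

.extra_concepts <- function() {
  tibble::tribble(
    ~concept_id,   ~name,                  ~numbers,
    "OTIC_SOLN",   "Otic Solution",        "F2.1.4",
    "NASAL_SPRAY", "Nasal Spray",          "F2.2.1",
    "ORAL_SUSP",   "Oral Suspension",      "F2.3.1",
    "TOP_CREAM",   "Topical Cream",        "F3.2.1",
    "RECT_SUPP",   "Rectal Suppository",   "F4.25.1",
    "TD_PATCH",    "Transdermal Patch",    "F4.26.1",
    "INH_POWDER",  "Inhalation Powder",    "F4.27.1",
  )
}

# leaf forms the sentence templates can express, with their route term, a
# lay route phrase needing translation, the in-sentence form wording, the
# administration verb, and the title token used in title-route mode
.plantable_forms <- function() {
  tibble::tribble(
    ~concept_id, ~route,       ~lay,               ~form,                                    ~verb,    ~title_route,
    "ORAL_TAB",  "oral",       "by mouth",         "tablet",                                 "take",   "Oral",
    "VAG_TAB",   "vaginal",    "into the vagina",  "tablet",                                 "insert", "Vaginal",
    "CHEW_TAB",  "oral",       "by mouth",         "chewable tablet",                        "take",   "Oral",
    "ECT",       "oral",       "by mouth",         "enteric coated tablet",                  "take",   "Oral",
    "ERT",       "oral",       "by mouth",         "extended-release tablet",                "take",   "Oral",
    "ERECT",     "oral",       "by mouth",         "extended-release enteric coated tablet", "take",   "Oral",
    "ORAL_CAP",  "oral",       "by mouth",         "capsule",                                "take",   "Oral",
    "ERC",       "oral",       "by mouth",         "extended-release capsule",               "take",   "Oral",
    "ORAL_SOLN", "oral",       "by mouth",         "solution",                               "take",   "Oral",
    "INJ_SOLN",  "injectable", "by injection",     "solution",                               "use",    "Injection",
    "OPH_SOLN",  "ophthalmic", "in the eyes",      "solution",                               "apply",  "Ophthalmic",
    "OPH_OINT",  "ophthalmic", "in the eyes",      "ointment",                               "apply",  "Ophthalmic",
    "OTIC_SOLN", "otic",       "into the ears",    "solution",                               "place",  "Otic",
    "NASAL_SPRAY", "nasal",    "into the nose",    "spray",                                  "spray",  "Nasal",
    "ORAL_SUSP", "oral",       "by mouth",         "suspension",                             "take",   "Oral",
    "TOP_CREAM", "topical",    "on the skin",      "cream",                                  "apply",  "Topical",
    "RECT_SUPP", "rectal",     "into the rectum",  "suppository",                            "insert", "Rectal",
  )
}

#' Generate a mini dosage-form terminology with a branded-drug table
#'
#' The emitted tree always contains the 19-concept backbone (Solid, Tablet,
#' Oral/Vaginal/Chewable/Enteric-Coated/Extended-Release Tablet, the
#' multi-parent Extended Release Enteric Coated Tablet with its two tree
#' numbers, the capsule, solution, and ointment branches); `n_forms` beyond
#' the backbone adds extra leaf forms. Every expressible leaf form is linked
#' to two generated brand names via the branded-drug table.
#'
#' @param spec A [fixture_spec()].
#' @return List with tibbles `concepts` (`concept_id`, `name`), `tree`
#'   (`concept_id`, `tree_number`), `branded` (`branded_drug_name`,
#'   `brand_name`, `dosage_form_concept_id`), and `plantable` (template
#'   metadata for the generator).
#' @export
generate_terminology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_forms < 4L) {
    rlang::abort("n_forms must be at least 4", class = "dfid_argument_error")
  }
  base <- .backbone_concepts()
  extra <- .extra_concepts()
  n_extra <- min(max(spec$n_forms - nrow(base), 0L), nrow(extra))
  all <- rbind(base, extra[seq_len(n_extra), ])

  tree <- tibble::tibble(
    concept_id = rep(all$concept_id, lengths(strsplit(all$numbers, "|", fixed = TRUE))),
    tree_number = unlist(strsplit(all$numbers, "|", fixed = TRUE))
  )
  concepts <- tibble::tibble(concept_id = all$concept_id, name = all$name)
  plantable <- .plantable_forms()
  plantable <- plantable[plantable$concept_id %in% concepts$concept_id, ]

  branded <- .with_local_seed(spec$seed, {
    syllables <- c("zor", "vel", "tri", "max", "lun", "ceb", "dor", "fex",
                   "gal", "hep", "mir", "nol", "pex", "quo", "rin", "sel",
                   "tav", "ulo", "wix", "yat")
    rows <- lapply(seq_len(nrow(plantable)), function(i) {
      id <- plantable$concept_id[i]
      brands <- vapply(1:2, function(k) {
        nm <- paste0(toupper(substr(sample(syllables, 1), 1, 1)),
                     substr(sample(syllables, 1), 2, 3),
                     sample(syllables, 1), sample(syllables, 1))
        paste0(nm, i, k)  # uniqueness guard
      }, character(1))
      tibble::tibble(
        branded_drug_name = paste0("Ingredient", i, " 10 MG ",
                                   concepts$name[concepts$concept_id == id],
                                   " [", brands, "]"),
        brand_name = brands,
        dosage_form_concept_id = id
      )
    })
    dplyr::bind_rows(rows)
  })

  list(concepts = concepts, tree = tree, branded = branded, plantable = plantable)
}

.distractor_pool <- c(
  "Store it at room temperature away from excess heat and moisture.",
  "Follow the directions on your prescription label carefully.",
  "Ask your pharmacist any questions you have about refilling your prescription.",
  "Do not stop using it without talking to your doctor."
)

.sentence_templates <- function(drug, form, tail) {
  c(P1 = paste0(drug, " comes as a ", form, tail, "."),
    P2 = paste0("It comes in ", form, " form", tail, "."),
    P3 = paste0(drug, " is supplied as a ", form, tail, "."),
    P4 = paste0("This medication is supplied as a ", form, tail, "."),
    P5 = paste0("The drug is supplied as a ", form, tail, "."))
}

# sample an antichain of k plantable forms (rejection sampling; planted
# sets must be antichains to be recoverable through the specificity filter)
.sample_antichain <- function(ids, k, tree_obj) {
  for (attempt in 1:100) {
    s <- sample(ids, k)
    ok <- TRUE
    for (a in s) for (b in s) {
      if (!identical(a, b) && is_ancestor(tree_obj, a, b)) ok <- FALSE
    }
    if (ok) return(s)
  }
  sample(ids, 1)  # k-sized antichain not found; fall back to a singleton
}

#' Generate a monograph corpus with known ground truth
#'
#' Each monograph receives 1-3 planted leaf dosage forms (an antichain; see
#' [fixture_spec()] for the count distribution), one evidence sentence per
#' planted form instantiated from a P1-P5 template, route wording sampled
#' between the direct route term and a lay phrase per `route_noise`,
#' distractor sentences per `distractor_rate`, and a "Brand names" section
#' listing brands of the planted forms unless dropped per `brand_dropout`.
#' With probability 0.3, a monograph whose planted forms share one route
#' moves the route to the title ("Drug007 Ophthalmic") and omits it from the
#' sentences, exercising title-route enrichment. With probability 0.25 the
#' last evidence sentence is housed in an "About your treatment" section.
#'
#' @param spec A [fixture_spec()].
#' @param terminology A [generate_terminology()] result.
#' @return List with `monographs` (named list of `monograph`), `gold`
#'   (tibble `monograph_id`, `concept_id`), and `manifest` (per-monograph
#'   ground truth: planted forms, evidence sentences with their pattern ids,
#'   title-route flag, listed brands).
#' @export
generate_monographs <- function(spec, terminology) {
  stopifnot(inherits(spec, "fixture_spec"))
  tree_obj <- load_terminology(terminology$concepts, terminology$tree)
  pl <- terminology$plantable
  branded <- terminology$branded

  .with_local_seed(spec$seed + 1L, {
    monographs <- list()
    manifest <- list()
    gold_rows <- list()

    for (i in seq_len(spec$n_monographs)) {
      id <- sprintf("drug%03d", i)
      drug <- sprintf("Drug%03d", i)
      k <- sample(1:3, 1, prob = c(0.5, 0.4, 0.1))
      planted <- .sample_antichain(pl$concept_id, min(k, nrow(pl)), tree_obj)
      rows <- pl[match(planted, pl$concept_id), ]

      shared_route <- length(unique(rows$route)) == 1L
      title_route <- shared_route && stats::runif(1) < 0.3
      title <- if (title_route) paste(drug, rows$title_route[1]) else drug

      sentences <- character(0)
      patterns <- character(0)
      for (j in seq_len(nrow(rows))) {
        tail <- if (title_route) {
          ""
        } else {
          expr <- if (stats::runif(1) < spec$route_noise) rows$lay[j] else rows$route[j]
          paste0(" to ", rows$verb[j], " ", expr)
        }
        tpl <- .sentence_templates(drug, rows$form[j], tail)
        pick <- sample(PATTERN_IDS, 1)
        sentences <- c(sentences, tpl[[pick]])
        patterns <- c(patterns, pick)
      }

      distractors <- .distractor_pool[stats::runif(length(.distractor_pool)) < spec$distractor_rate]
      usage_sentences <- sentences
      treatment_text <- NULL
      if (length(sentences) > 1L && stats::runif(1) < 0.25) {
        treatment_text <- sentences[length(sentences)]
        usage_sentences <- sentences[-length(sentences)]
      }
      body <- c(usage_sentences, distractors)
      body <- body[sample(length(body))]

      sections <- list("How should this medicine be used?" = paste(body, collapse = " "))
      if (!is.null(treatment_text)) {
        sections[["About your treatment"]] <- treatment_text
      }

      dropped_brands <- stats::runif(1) < spec$brand_dropout
      brands <- if (dropped_brands) {
        character(0)
      } else {
        vapply(planted, function(cid) {
          cand <- branded$brand_name[branded$dosage_form_concept_id == cid]
          sample(cand, 1)
        }, character(1))
      }

      monographs[[id]] <- monograph(id, title, sections, brands)
      manifest[[id]] <- list(
        monograph_id = id, title = title, planted = planted,
        sentences = stats::setNames(sentences, patterns),
        title_route = title_route, brands = brands
      )
      gold_rows[[id]] <- tibble::tibble(monograph_id = id, concept_id = planted)
    }

    list(monographs = monographs, gold = dplyr::bind_rows(gold_rows),
         manifest = manifest)
  })
}

#' Write a complete fixture corpus to disk
#'
#' Produces `monographs/*.xml`, `terminology/{concepts,tree,branded}.tsv`,
#' `gold.tsv`, and `manifest.json` under `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_fixture_corpus <- function(spec, dir) {
  term <- generate_terminology(spec)
  corpus <- generate_monographs(spec, term)

  dir.create(file.path(dir, "monographs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "terminology"), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(term$concepts, file.path(dir, "terminology", "concepts.tsv"))
  readr::write_tsv(term$tree, file.path(dir, "terminology", "tree.tsv"))
  readr::write_tsv(term$branded, file.path(dir, "terminology", "branded.tsv"))
  readr::write_tsv(corpus$gold, file.path(dir, "gold.tsv"))
  for (m in corpus$monographs) {
    write_monograph(m, file.path(dir, "monographs", paste0(m$monograph_id, ".xml")))
  }
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
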