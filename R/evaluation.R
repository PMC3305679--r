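# Evaluation. Per monograph, precision is |D ∩ F| / |D| and recall is
# |D ∩ F| / |F|, where D is the identified dosage-form set and F the
# reference set; F-measure is their harmonic mean. Matching is exact set
# identity on concept ids (a hierarchical-credit mode, where predicting an
# ancestor or descendant of a reference concept earns credit, is available
# behind a flag). The corpus summary is the macro average: the mean of the
# per-monograph metrics, reported with SD, median, and IQR.

#' Per-monograph precision, recall, and F-measure
#'
#' Conventions: an empty prediction scores P = R = F = 0 (a monograph where
#' the method returns nothing counts as a failure, not a skip); F = 0
#' whenever P + R = 0. The reference must be nonempty — monographs without
#' reference dosage forms are excluded upstream, so an empty reference here
#' signals a standards bug.
#'
#' @param predicted Character vector of predicted concept ids (set D).
#' @param reference Nonempty character vector of reference concept ids (F).
#' @param monograph_id Optional id recorded in the output.
#' @param hierarchical_credit If `TRUE`, a predicted concept also counts as
#'   correct when it is an ancestor or descendant of a reference concept in
#'   `tree` (and symmetrically for recall).
#' @param tree Required when `hierarchical_credit = TRUE`.
#' @return One-row tibble: `monograph_id`, `precision`, `recall`,
#'   `f_measure`, `n_predicted`, `n_reference`, `n_correct`.
#' @export
prf <- function(predicted, reference, monograph_id = NA_character_,
                hierarchical_credit = FALSE, tree = NULL) {
  predicted <- unique(as.character(predicted))
  reference <- unique(as.character(reference))
  if (!length(reference)) {
    rlang::abort("reference dosage-form set is empty", class = "dfid_argument_error")
  }

  if (hierarchical_credit) {
    stopifnot(inherits(tree, "df_tree"))
    related <- function(a, b) identical(a, b) || is_ancestor(tree, a, b) || is_ancestor(tree, b, a)
    pred_ok <- vapply(predicted, function(p) any(vapply(reference, related, logical(1), a = p)),
                      logical(1))
    ref_ok <- vapply(reference, function(r) any(vapply(predicted, related, logical(1), a = r)),
                     logical(1))
    n_correct_p <- sum(pred_ok)
    n_correct_r <- sum(ref_ok)
  } else {
    n_correct_p <- n_correct_r <- length(intersect(predicted, reference))
  }

  p <- if (length(predicted)) n_correct_p / length(predicted) else 0
  r <- n_correct_r / length(reference)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0

  tibble::new_tibble(
    list(
      monograph_id = monograph_id,
      precision = p, recall = r, f_measure = f,
      n_predicted = length(predicted), n_reference = length(reference),
      n_correct = n_correct_p
    ),
    nrow = 1L
  )
}

#' Macro-averaged evaluation of identification results
#'
#' Computes [prf()] for every entry of the reference standard (a monograph
#' with no prediction contributes an empty set, i.e. zeros) and summarizes
#' each metric with mean, sample standard deviation, median, and
#' interquartile range (Q3 - Q1, linear-interpolation quantiles).
#' Monographs listed in `standard$excluded` are skipped.
#'
#' @param results Named list of `identification_result` (from
#'   [identify_corpus()]), or a data frame with columns `monograph_id`,
#'   `concept_id`.
#' @param standard A `reference_standard` with at least one entry.
#' @param hierarchical_credit,tree Passed to [prf()].
#' @return An `evaluation_summary`: list with `per_monograph` (tibble of
#'   per-monograph metrics) and `summary` (tibble: `metric`, `mean`, `sd`,
#'   `median`, `iqr`), plus `n_monographs`.
#' @export
macro_evaluate <- function(results, standard, hierarchical_credit = FALSE, tree = NULL) {
  stopifnot(inherits(standard, "reference_standard"))
  if (!length(standard$entries)) {
    rlang::abort("reference standard has no entries", class = "dfid_argument_error")
  }
  pred_sets <- .prediction_sets(results)

  per <- dplyr::bind_rows(lapply(names(standard$entries), function(id) {
    prf(pred_sets[[id]] %||% character(0), standard$entries[[id]],
        monograph_id = id, hierarchical_credit = hierarchical_credit, tree = tree)
  }))

  summarize_metric <- function(x, name) {
    tibble::tibble(
      metric = name,
      mean = mean(x),
      sd = if (length(x) > 1L) stats::sd(x) else 0,
      median = stats::median(x),
      iqr = unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
    )
  }
  summary <- dplyr::bind_rows(
    summarize_metric(per$precision, "precision"),
    summarize_metric(per$recall, "recall"),
    summarize_metric(per$f_measure, "f_measure")
  )

  structure(
    list(per_monograph = per, summary = summary, n_monographs = nrow(per)),
    class = "evaluation_summary"
  )
}

.prediction_sets <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("monograph_id", "concept_id") %in% names(results)))
    return(lapply(split(results$concept_id, results$monograph_id), unique))
  }
  stopifnot(is.list(results))
  sets <- lapply(results, function(r) {
    stopifnot(inherits(r, "identification_result"))
    r$dosage_forms
  })
  stats::setNames(sets, vapply(results, `[[`, character(1), "monograph_id"))
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary> over", x$n_monographs, "monographs\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}
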