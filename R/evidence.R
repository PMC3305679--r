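# Evidence-sentence extraction. The usage sections are split into sentences
# and each sentence is tested against five surface patterns that signal a
# dosage-form statement:
#   P1  sentence contains "come as" (or a variant of "come")
#   P2  sentence contains "come in" (variants likewise)
#   P3  the first token is an ingredient term from the title
#   P4  the sentence starts with a determiner + "medication(s)"
#   P5  the sentence starts with a determiner + "drug(s)"
# Precedence is P1 > P2 > P3 > P4 > P5, first match wins; downstream
# normalization is identical for all patterns, so precedence only affects
# provenance reporting.

PATTERN_IDS <- c("P1", "P2", "P3", "P4", "P5")

.default_variants <- list(
  come = c("come", "comes", "came", "coming"),
  medication = c("medication", "medications"),
  drug = c("drug", "drugs"),
  determiner = c("the", "this", "these", "your")
)

# sentence splitter: break at . ? or ! followed by whitespace and an
# upper-case/digit sentence opener, protecting common abbreviations
.abbreviations <- c("e.g", "i.e", "etc", "dr", "mr", "mrs", "ms", "vs",
                    "fig", "no", "st", "approx")

#' Split section text into sentences
#'
#' Rule-based splitter: a sentence boundary is a run of `.?!` followed by
#' whitespace and a capital letter or digit, unless the period closes a
#' known abbreviation. The concatenation of the output (modulo whitespace)
#' equals the input.
#'
#' @param text Section text (length-1 character).
#' @return Character vector of sentences; empty for empty input.
#' @export
split_sentences <- function(text) {
  if (is.null(text) || !length(text)) return(character(0))
  stopifnot(is.character(text), length(text) == 1L)
  text <- stringr::str_squish(text)
  if (!nzchar(text)) return(character(0))

  candidates <- stringr::str_locate_all(text, "[.?!]+(?=\\s+[A-Z0-9])")[[1]]
  if (!nrow(candidates)) return(text)
  ends <- candidates[, "end"]
  keep <- vapply(seq_along(ends), function(i) {
    prefix <- substr(text, 1L, ends[i])
    last_word <- stringr::str_extract(prefix, "[A-Za-z.]+$")
    last_word <- tolower(sub("[.?!]+$", "", last_word %||% ""))
    !(last_word %in% .abbreviations)
  }, logical(1))
  ends <- ends[keep]
  if (!length(ends)) return(text)

  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(text))
  out <- stringr::str_trim(substring(text, starts, stops))
  out[nzchar(out)]
}

#' Match a sentence against the evidence patterns
#'
#' Returns the lowest-numbered matching pattern id ("P1".."P5") or `NA` when
#' none matches. Verb/noun variants are allowed ("comes as", "came in",
#' "medications"); P4/P5 require the determiner + keyword to open the
#' sentence (an anchored approximation of "subject of the sentence"); P3
#' compares the sentence's first token case-insensitively against the
#' title's ingredient terms.
#'
#' @param sentence Nonempty sentence string.
#' @param ingredient_terms Character vector of title ingredient tokens
#'   (for P3); may be empty.
#' @param variants Named list overriding the variant sets `come`,
#'   `medication`, `drug`, `determiner`.
#' @return `"P1".."P5"` or `NA_character_`.
#' @export
match_pattern <- function(sentence, ingredient_terms = character(0),
                          variants = list()) {
  stopifnot(is.character(sentence), length(sentence) == 1L, nzchar(sentence))
  v <- utils::modifyList(.default_variants, variants)
  s <- tolower(sentence)

  come_alt <- paste(v$come, collapse = "|")
  if (stringr::str_detect(s, paste0("\\b(", come_alt, ")\\s+as\\b"))) return("P1")
  if (stringr::str_detect(s, paste0("\\b(", come_alt, ")\\s+in\\b"))) return("P2")

  first_token <- tokenize_words(sentence)[[1]][1]
  if (length(ingredient_terms) && !is.na(first_token) &&
      first_token %in% tolower(ingredient_terms)) {
    return("P3")
  }

  det_alt <- paste(v$determiner, collapse = "|")
  if (stringr::str_detect(s, paste0("^\\s*(", det_alt, ")\\s+(",
                                    paste(v$medication, collapse = "|"), ")\\b"))) {
    return("P4")
  }
  if (stringr::str_detect(s, paste0("^\\s*(", det_alt, ")\\s+(",
                                    paste(v$drug, collapse = "|"), ")\\b"))) {
    return("P5")
  }
  NA_character_
}

#' Extract dosage-form evidence sentences from a monograph
#'
#' Splits every evidence section into sentences and keeps those matching one
#' of the patterns P1-P5, in document order, with provenance.
#'
#' @param m A `monograph`.
#' @param seg The monograph's [segment_title()] result; defaults to
#'   segmenting `m$title` with the default marker lexicon.
#' @param variants Pattern-variant overrides passed to [match_pattern()].
#' @return Tibble with columns `monograph_id`, `section_name`, `pattern`,
#'   `sentence` (zero rows when nothing matches or no evidence section
#'   exists).
#' @export
extract_evidence <- function(m, seg = segment_title(m$title), variants = list()) {
  stopifnot(inherits(m, "monograph"))
  sections <- .evidence_sections_named(m)
  rows <- list()
  for (i in seq_along(sections)) {
    for (s in split_sentences(sections[[i]])) {
      p <- match_pattern(s, seg$ingredient_terms, variants)
      if (!is.na(p)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          monograph_id = m$monograph_id,
          section_name = names(sections)[i],
          pattern = p,
          sentence = s
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(monograph_id = character(0), section_name = character(0),
                          pattern = character(0), sentence = character(0)))
  }
  dplyr::bind_rows(rows)
}
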