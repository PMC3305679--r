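# Porter stemming algorithm (Porter 1980), the classic suffix-stripping
# stemmer for English. Dosage-form matching is stem-based so that surface
# variants in monograph prose ("tablets", "capsules", "solution") meet the
# stemmed tokens of concept names ("Tablet" -> "tablet", "Oral Solution" ->
# {"oral", "solut"}).
#
# The measure conditions (m > 0, m = 1, m > 1) are encoded as regular
# expressions over the C/V skeleton of the word, with "y" a vowel when it
# follows a consonant.

.porter_re <- local({
  cns <- "[^aeiou]"          # consonant, y excluded below where it acts as vowel
  vwl <- "[aeiouy]"
  C <- paste0(cns, "[^aeiouy]*")   # one or more consonants
  V <- paste0(vwl, "[aeiou]*")     # one or more vowels
  list(
    mgr0 = paste0("^(", C, ")?", V, C),                       # m > 0
    meq1 = paste0("^(", C, ")?", V, C, "(", V, ")?$"),        # m = 1
    mgr1 = paste0("^(", C, ")?", V, C, V, C),                 # m > 1
    has_v = paste0("^(", C, ")?", vwl)                        # stem contains a vowel
  )
})

.step2_map <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", bli = "ble", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble", logi = "log"
)

.step3_map <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic",
  ical = "ic", ful = "", ness = ""
)

.step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.porter_one <- function(w) {
  if (nchar(w) < 3L) return(w)
  re <- .porter_re

  # initial y is a consonant; protect it through vowel-sensitive checks
  first_y <- substr(w, 1L, 1L) == "y"
  if (first_y) w <- paste0("Y", substr(w, 2L, nchar(w)))

  # Step 1a: plurals
  if (grepl("(ss|i)es$", w)) {
    w <- sub("es$", "", w)
  } else if (grepl("[^s]s$", w)) {
    w <- sub("s$", "", w)
  }

  # Step 1b: -ed / -ing
  if (grepl("eed$", w)) {
    stem <- sub("eed$", "", w)
    if (grepl(re$mgr0, stem)) w <- paste0(stem, "ee")
  } else {
    m <- regmatches(w, regexec("^(.+?)(ed|ing)$", w))[[1]]
    if (length(m) && grepl(re$has_v, m[2])) {
      w <- m[2]
      if (grepl("(at|bl|iz)$", w)) {
        w <- paste0(w, "e")
      } else if (grepl("([^aeiouylsz])\\1$", w)) {
        w <- substr(w, 1L, nchar(w) - 1L)
      } else if (grepl(re$meq1, w) && grepl("[^aeiouwxy][aeiouy][^aeiou]$", w)) {
        w <- paste0(w, "e")  # cvc with short stem -> restore e (hop-ing vs hop-e)
      }
    }
  }

  # Step 1c: terminal y -> i when the stem has a vowel
  if (grepl("y$", w)) {
    stem <- sub("y$", "", w)
    if (grepl(re$has_v, stem)) w <- paste0(stem, "i")
  }

  # Step 2: double suffixes, m > 0
  for (suf in names(.step2_map)) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (grepl(re$mgr0, stem)) w <- paste0(stem, .step2_map[[suf]])
      break
    }
  }

  # Step 3: -ic-, -full, -ness etc., m > 0
  for (suf in names(.step3_map)) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (grepl(re$mgr0, stem)) w <- paste0(stem, .step3_map[[suf]])
      break
    }
  }

  # Step 4: strip residual suffix when m > 1; -ion only after s or t
  for (suf in .step4_suffixes) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (suf == "ion" && !grepl("[st]$", stem)) break
      if (grepl(re$mgr1, stem)) w <- stem
      break
    }
  }

  # Step 5a: drop terminal e when m > 1, or m = 1 without a short cvc ending
  if (grepl("e$", w)) {
    stem <- sub("e$", "", w)
    if (grepl(re$mgr1, stem) ||
        (grepl(re$meq1, stem) && !grepl("[^aeiouwxy][aeiouy][^aeiou]$", stem))) {
      w <- stem
    }
  }

  # Step 5b: -ll -> -l when m > 1
  if (grepl("ll$", w) && grepl(re$mgr1, w)) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }

  if (first_y) w <- paste0("y", substr(w, 2L, nchar(w)))
  w
}

#' Stem English words with the Porter algorithm
#'
#' Vectorized Porter (1980) suffix stripping. Words are lowercased before
#' stemming; tokens shorter than three characters are returned unchanged, as
#' in the original algorithm.
#'
#' @param words Character vector of single words (no internal whitespace).
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("solution", "tablets", "extended", "release"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(tolower(words), .porter_one, character(1), USE.NAMES = FALSE)
}

#' Tokenize free text for stem-bag construction
#'
#' Lowercases, treats hyphens and slashes as token separators (so
#' "extended-release" contributes "extended" and "release"), strips all other
#' punctuation, and splits on whitespace.
#'
#' @param text Character vector of text.
#' @return List of character vectors, one per input element.
#' @export
tokenize_words <- function(text) {
  x <- tolower(text)
  x <- stringr::str_replace_all(x, "[-/]", " ")
  x <- stringr::str_replace_all(x, "[^a-z0-9\\s]", " ")
  toks <- stringr::str_split(stringr::str_squish(x), stringr::fixed(" "))
  lapply(toks, function(t) t[nzchar(t)])
}
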