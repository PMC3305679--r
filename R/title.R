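# Title segmentation. Monograph titles follow "ingredient(s) + optional
# route": "Diclofenac Ophthalmic" discusses the ophthalmic products of
# diclofenac. Splitting the title at the leftmost route-indicating marker
# gives the ingredient terms I (used by evidence pattern P3) and the route
# terms R (appended to evidence sentences during enrichment).

#' Default route-marker lexicon
#'
#' Route-indicating terms that mark where a monograph title switches from
#' ingredient to administration route. The list ships with the common
#' consumer-monograph routes and can be replaced or extended via a plain-text
#' lexicon file ([read_route_markers()]).
#'
#' @return Lowercase character vector of marker terms.
#' @export
default_route_markers <- function() {
  c("nasal", "ophthalmic", "otic", "oral", "rectal", "vaginal",
    "topical", "transdermal", "injection", "inhalation")
}

#' Read a route-marker lexicon file
#'
#' One term per line; blank lines and `#` comments are ignored; terms are
#' lowercased.
#'
#' @param path Path to the lexicon file.
#' @return Lowercase character vector of marker terms.
#' @export
read_route_markers <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_squish(sub("#.*$", "", lines))
  markers <- tolower(lines[nzchar(lines)])
  if (!length(markers)) {
    rlang::abort("route-marker lexicon is empty", class = "dfid_load_error")
  }
  markers
}

#' Segment a monograph title into ingredient and route terms
#'
#' Tokenizes the title on whitespace (commas stripped) and finds the
#' leftmost token that is a route marker (whole-token, case-insensitive).
#' Tokens from that position onward are the route terms R; everything before
#' is the ingredient I. With no marker, the whole title is ingredient and R
#' is empty. A title never segments to an empty ingredient: a marker in
#' first position is treated as part of the ingredient name.
#'
#' @param title Nonempty title string.
#' @param markers Character vector of route markers
#'   (default [default_route_markers()]).
#' @return A list of class `title_segmentation` with `ingredient_terms`,
#'   `route_terms`, and `marker_position` (1-based token index of the
#'   leftmost marker, or `NA` when none).
#' @examples
#' segment_title("Diclofenac Ophthalmic")
#' segment_title("Propranolol Oral")
#' @export
segment_title <- function(title, markers = default_route_markers()) {
  if (!is.character(title) || length(title) != 1L || !nzchar(stringr::str_squish(title))) {
    rlang::abort("title must be a nonempty string", class = "dfid_argument_error")
  }
  tokens <- stringr::str_split(stringr::str_squish(stringr::str_replace_all(title, ",", " ")),
                               stringr::fixed(" "))[[1]]
  hits <- which(tolower(tokens) %in% tolower(markers))
  hits <- hits[hits > 1L]  # ingredient_terms must be nonempty
  q <- if (length(hits)) min(hits) else NA_integer_
  if (is.na(q)) {
    ingredient <- tokens
    route <- character(0)
  } else {
    ingredient <- tokens[seq_len(q - 1L)]
    route <- tokens[q:length(tokens)]
  }
  structure(
    list(ingredient_terms = ingredient, route_terms = route, marker_position = q),
    class = "title_segmentation"
  )
}

#' @export
print.title_segmentation <- function(x, ...) {
  cat("<title_segmentation> I = [", paste(x$ingredient_terms, collapse = ", "),
      "], R = [", paste(x$route_terms, collapse = ", "), "]\n", sep = "")
  invisible(x)
}
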