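# Monograph XML reading and writing. Each monograph is a consumer-level
# full-text drug document whose subject is a generic ingredient; its title
# and two usage sections ("How should this medicine be used?", "About your
# treatment") carry the dosage-form evidence, and the "Brand names" section
# lists marketed products used for silver-standard construction.
#
# Dialect:
#   <monograph id="...">
#     <title>Acetaminophen</title>
#     <section name="How should this medicine be used?">free text</section>
#     <section name="Brand names"><brand>Tylenol</brand>...</section>
#   </monograph>

.canonical_section <- function(name) {
  x <- tolower(stringr::str_squish(stringr::str_replace_all(name, "[^A-Za-z0-9 ]", "")))
  # the usage section appears with both "medicine" and "medication" spellings
  if (x %in% c("how should this medicine be used", "how should this medication be used")) {
    return("usage")
  }
  if (x == "about your treatment") return("treatment")
  if (x == "brand names") return("brands")
  x
}

EVIDENCE_SECTION_KEYS <- c("usage", "treatment")

#' Parse a drug monograph from XML
#'
#' @param xml_source Path to a monograph XML file, an XML string, or an
#'   `xml2` document.
#' @param monograph_id Identifier to use; defaults to the file stem when
#'   `xml_source` is a path, else the document's `id` attribute.
#' @return An object of class `monograph`: a list with `monograph_id`,
#'   `title`, `sections` (named list of section texts, keys verbatim from the
#'   file), and `brand_names` (character vector, empty when the monograph has
#'   no "Brand names" section).
#' @export
parse_monograph <- function(xml_source, monograph_id = NULL) {
  is_path <- is.character(xml_source) && length(xml_source) == 1L &&
    !grepl("<", xml_source, fixed = TRUE) && file.exists(xml_source)
  doc <- tryCatch(
    if (inherits(xml_source, "xml_document")) xml_source else xml2::read_xml(xml_source),
    error = function(e) {
      src <- if (is_path) xml_source else "<inline xml>"
      rlang::abort(paste0("malformed XML in ", src, ": ", conditionMessage(e)),
                   class = "dfid_parse_error")
    }
  )
  root <- xml2::xml_root(doc)
  title_node <- xml2::xml_find_first(root, "./title")
  if (inherits(title_node, "xml_missing")) {
    rlang::abort("monograph has no <title> element", class = "dfid_schema_error")
  }
  title <- stringr::str_squish(xml2::xml_text(title_node))
  if (!nzchar(title)) {
    rlang::abort("monograph <title> is empty", class = "dfid_schema_error")
  }

  if (is.null(monograph_id)) {
    monograph_id <- if (is_path) {
      tools::file_path_sans_ext(basename(xml_source))
    } else {
      id_attr <- xml2::xml_attr(root, "id")
      if (is.na(id_attr)) title else id_attr
    }
  }

  section_nodes <- xml2::xml_find_all(root, "./section")
  sections <- list()
  brand_names <- character(0)
  for (node in section_nodes) {
    name <- xml2::xml_attr(node, "name")
    if (is.na(name)) next
    if (.canonical_section(name) == "brands") {
      brand_names <- stringr::str_squish(xml2::xml_text(xml2::xml_find_all(node, "./brand")))
      brand_names <- brand_names[nzchar(brand_names)]
      sections[[name]] <- ""
    } else {
      # flatten inner markup to plain text
      sections[[name]] <- stringr::str_squish(xml2::xml_text(node))
    }
  }

  structure(
    list(
      monograph_id = monograph_id,
      title = title,
      sections = sections,
      brand_names = brand_names
    ),
    class = "monograph"
  )
}

#' @export
print.monograph <- function(x, ...) {
  cat("<monograph> ", x$monograph_id, ": \"", x$title, "\", ",
      length(x$sections), " section(s), ", length(x$brand_names),
      " brand name(s)\n", sep = "")
  invisible(x)
}

#' Construct a monograph in memory
#'
#' Convenience constructor mirroring what [parse_monograph()] returns, for
#' building test and fixture documents without touching disk.
#'
#' @param monograph_id Identifier.
#' @param title Title string (nonempty).
#' @param sections Named list/character of section texts.
#' @param brand_names Character vector of brand names.
#' @return A `monograph` object.
#' @export
monograph <- function(monograph_id, title, sections = list(), brand_names = character(0)) {
  stopifnot(nzchar(title))
  structure(
    list(
      monograph_id = monograph_id,
      title = title,
      sections = as.list(sections),
      brand_names = as.character(brand_names)
    ),
    class = "monograph"
  )
}

#' Serialize a monograph back to the XML dialect
#'
#' Writing then re-parsing yields an equal monograph (round-trip property).
#'
#' @param m A `monograph`.
#' @param path Output file path; when `NULL` the XML string is returned.
#' @return `path` invisibly, or the XML string when `path` is `NULL`.
#' @export
write_monograph <- function(m, path = NULL) {
  stopifnot(inherits(m, "monograph"))
  doc <- xml2::xml_new_root("monograph", id = m$monograph_id)
  xml2::xml_add_child(doc, "title", m$title)
  for (name in names(m$sections)) {
    if (.canonical_section(name) == "brands") next
    xml2::xml_add_child(doc, "section", m$sections[[name]], name = name)
  }
  if (length(m$brand_names)) {
    brands <- xml2::xml_add_child(doc, "section", name = "Brand names")
    for (b in m$brand_names) xml2::xml_add_child(brands, "brand", b)
  }
  if (is.null(path)) {
    return(as.character(doc))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read all monographs from a directory
#'
#' @param dir Directory containing `*.xml` monograph files.
#' @return Named list of `monograph` objects keyed by monograph_id, in
#'   lexicographic file order.
#' @export
read_monograph_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  ms <- lapply(files, parse_monograph)
  stats::setNames(ms, vapply(ms, `[[`, character(1), "monograph_id"))
}

#' Get the texts of the dosage-form evidence sections
#'
#' Returns the usage section ("How should this medicine be used?", either
#' spelling) and the "About your treatment" section, whichever exist, in
#' document order. Section-name lookup is case- and punctuation-insensitive.
#' A monograph with neither section (e.g. a vaccine monograph) yields an
#' empty list, which propagates to an empty identification result downstream.
#'
#' @param m A `monograph`.
#' @return Character vector of section texts (possibly empty).
#' @export
get_evidence_sections <- function(m) {
  stopifnot(inherits(m, "monograph"))
  keys <- vapply(names(m$sections), .canonical_section, character(1))
  out <- unlist(m$sections[keys %in% EVIDENCE_SECTION_KEYS], use.names = FALSE)
  if (is.null(out)) character(0) else out
}

# named evidence sections with their canonical keys, for provenance
.evidence_sections_named <- function(m) {
  keys <- vapply(names(m$sections), .canonical_section, character(1))
  keep <- keys %in% EVIDENCE_SECTION_KEYS
  stats::setNames(unlist(m$sections[keep], use.names = FALSE) %||% character(0),
                  names(m$sections)[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
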