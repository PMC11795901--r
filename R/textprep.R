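# Term definition for free text, and decomposition of keyword strings
# into MeSH descriptors and qualifiers.

# hyphen inventory: ASCII hyphen-minus, the Unicode hyphen/dash block
# U+2010..U+2015, and the minus sign U+2212
.split_re  <- "[\\s\\u002d\\u2010-\\u2015\\u2212]+"
.strip_re  <- "[\\p{S}\\p{P}]"
.number_re <- "^\\p{Nd}+$"

#' Tokenize free text into searchable terms
#'
#' A term is a word without hyphens, without characters of the Unicode
#' Symbol or Punctuation categories, and that is not a number. Text is
#' split on whitespace and on hyphens/dashes (so `"self-aware"` yields
#' the two terms `"self"` and `"aware"`, matching how major search
#' platforms treat hyphenated words), symbol and punctuation characters
#' are stripped, purely numeric pieces are dropped, and the survivors
#' are lower-cased. Letters outside ASCII (Greek letters, letters with
#' diacritics) are ordinary letters and are kept; alphanumeric mixes
#' such as `"p53"` are kept because they are not numbers.
#'
#' @param text A character vector; elements are tokenized independently.
#' @return For a single string, a character vector of tokens in text
#'   order; for a longer vector, a list of such vectors.
#' @examples
#' tokenize_freetext("self-aware")
#' tokenize_freetext("Beta-Blockers reduce risk (2022).")
#' @export
tokenize_freetext <- function(text) {
  one <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    pieces <- stringr::str_split_1(x, .split_re)
    pieces <- stringr::str_replace_all(pieces, .strip_re, "")
    pieces <- pieces[nzchar(pieces)]
    pieces <- pieces[!stringr::str_detect(pieces, .number_re)]
    stringr::str_to_lower(pieces)
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Parse a raw keyword string into descriptor, qualifier and major flag
#'
#' PubMed keyword exports use `descriptor/qualifier` for MeSH headings
#' with subheadings ("Neoplasms/diagnosis") and a leading `*` for major
#' topics. The raw string is split at the first `/`; no dictionary
#' validation happens here.
#'
#' @param raw A single non-empty keyword string.
#' @return A list with `raw`, `descriptor`, `qualifier` (`NA` when
#'   absent) and `major_topic`.
#' @export
parse_keyword <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- trimws(raw)
  if (!nzchar(s)) stop("malformed keyword: empty", call. = FALSE)
  major <- startsWith(s, "*")
  body <- if (major) substring(s, 2L) else s
  slash <- regexpr("/", body, fixed = TRUE)
  if (slash == 1L || !nzchar(body)) {
    stop(sprintf("malformed keyword: '%s'", raw), call. = FALSE)
  }
  if (slash > 0L) {
    descriptor <- substring(body, 1L, slash - 1L)
    qualifier <- substring(body, slash + 1L)
    if (!nzchar(qualifier)) {
      stop(sprintf("malformed keyword: '%s'", raw), call. = FALSE)
    }
  } else {
    descriptor <- body
    qualifier <- NA_character_
  }
  list(raw = s, descriptor = descriptor, qualifier = qualifier,
       major_topic = major)
}

#' Construct a MeSH dictionary
#'
#' @param descriptors Character vector of descriptor names.
#' @param qualifiers Character vector of qualifier (subheading) names.
#' @param version_label Provenance label, e.g. the MeSH year.
#' @return A `mesh_dictionary` with case-insensitive lookup that
#'   reports names in the dictionary's own casing.
#' @export
mesh_dictionary <- function(descriptors, qualifiers,
                            version_label = "custom") {
  descriptors <- unique(trimws(descriptors))
  qualifiers <- unique(trimws(qualifiers))
  descriptors <- descriptors[nzchar(descriptors)]
  qualifiers <- qualifiers[nzchar(qualifiers)]
  structure(
    list(descriptors = descriptors, qualifiers = qualifiers,
         descriptor_lookup = stats::setNames(descriptors,
                                             tolower(descriptors)),
         qualifier_lookup = stats::setNames(qualifiers,
                                            tolower(qualifiers)),
         version_label = version_label),
    class = "mesh_dictionary"
  )
}

#' @export
print.mesh_dictionary <- function(x, ...) {
  cat(sprintf("<mesh_dictionary '%s'> %d descriptors, %d qualifiers\n",
              x$version_label, length(x$descriptors),
              length(x$qualifiers)))
  invisible(x)
}

# case-insensitive membership; returns canonical name or NA
mesh_canonical <- function(dict, name, what = c("descriptor", "qualifier")) {
  what <- match.arg(what)
  lk <- if (what == "descriptor") dict$descriptor_lookup else dict$qualifier_lookup
  out <- unname(lk[tolower(name)])
  out
}

#' Classify a parsed keyword against a MeSH dictionary
#'
#' Only dictionary-listed names reach the MeSH and qualifier frequency
#' tables; everything else appears only in the all-keywords table. A
#' qualifier counts whenever its name is in the dictionary, regardless
#' of the descriptor's validity.
#'
#' @param entry A parsed keyword from [parse_keyword()].
#' @param dict A `mesh_dictionary`.
#' @return One of `"mesh_descriptor"`, `"mesh_qualifier_bearing"`
#'   (the qualifier is dictionary-listed and feeds the qualifier
#'   table), or `"non_mesh"`.
#' @export
classify_keyword <- function(entry, dict) {
  stopifnot(inherits(dict, "mesh_dictionary"))
  desc_ok <- !is.na(mesh_canonical(dict, entry$descriptor, "descriptor"))
  qual_ok <- !is.na(entry$qualifier) &&
    !is.na(mesh_canonical(dict, entry$qualifier, "qualifier"))
  if (qual_ok) return("mesh_qualifier_bearing")
  if (desc_ok) return("mesh_descriptor")
  "non_mesh"
}

#' Read a MeSH dictionary from plain-text name lists
#'
#' One name per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param descriptor_path,qualifier_path Paths to the two name lists.
#' @param version_label Provenance label stored on the dictionary.
#' @return A `mesh_dictionary`.
#' @export
read_mesh_dictionary <- function(descriptor_path, qualifier_path,
                                 version_label = basename(descriptor_path)) {
  read_list <- function(path) {
    x <- readLines(path, encoding = "UTF-8", warn = FALSE)
    x <- trimws(x)
    x[nzchar(x) & !startsWith(x, "#")]
  }
  mesh_dictionary(read_list(descriptor_path), read_list(qualifier_path),
                  version_label = version_label)
}

#' Read a MeSH dictionary from a MeSH descriptor XML file
#'
#' Extracts `DescriptorName` and `QualifierName` elements from an NLM
#' MeSH XML export. Optional: the plain-text loader is the default
#' route and has no extra dependency.
#'
#' @param path Path to the XML file.
#' @param version_label Provenance label.
#' @return A `mesh_dictionary`.
#' @export
read_mesh_xml <- function(path, version_label = basename(path)) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("the xml2 package is required to read MeSH XML", call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  desc <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//DescriptorName/String"))
  qual <- xml2::xml_text(
    xml2::xml_find_all(doc, ".//QualifierName/String"))
  mesh_dictionary(desc, qual, version_label = version_label)
}
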