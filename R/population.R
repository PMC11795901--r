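# Population model: document frequencies in a background corpus of
# records, used as the binomial null for term overrepresentation.
# Counts are document frequencies (records containing the term at
# least once), not occurrence counts: the z-score compares the share of
# records containing a term, which is also the per-document sampling
# model behind the classical text-analysis implementations of the
# objective approach.

new_population_model <- function(n_pop, doc_freq = integer(),
                                 mesh_doc_freq = integer(),
                                 qualifier_doc_freq = integer(),
                                 label = "") {
  check_map <- function(m, what) {
    if (length(m)) {
      if (any(m < 1L) || any(m > n_pop)) {
        stop(sprintf("%s counts must lie in [1, n_pop]", what),
             call. = FALSE)
      }
    }
    m
  }
  structure(
    list(n_pop = as.integer(n_pop),
         doc_freq = check_map(doc_freq, "freetext"),
         mesh_doc_freq = check_map(mesh_doc_freq, "mesh"),
         qualifier_doc_freq = check_map(qualifier_doc_freq, "qualifier"),
         label = label),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "<population_model '%s'> %d documents; %d free-text terms, %d MeSH descriptors, %d qualifiers\n",
    x$label, x$n_pop, length(x$doc_freq), length(x$mesh_doc_freq),
    length(x$qualifier_doc_freq)))
  invisible(x)
}

# per-record presence counts of tokens / descriptors / qualifiers
count_document_frequencies <- function(records, dict = NULL) {
  tok_tab <- table(unlist(lapply(records$records, function(r) {
    unique(c(tokenize_freetext(r$title), tokenize_freetext(r$abstract)))
  })))
  mesh_tab <- qual_tab <- integer()
  if (!is.null(dict)) {
    per_record <- lapply(records$records, function(r) {
      if (!length(r$keywords)) {
        return(list(desc = character(), qual = character()))
      }
      entries <- lapply(r$keywords, parse_keyword)
      desc <- vapply(entries, function(e) {
        nm <- mesh_canonical(dict, e$descriptor, "descriptor")
        if (is.na(nm)) NA_character_ else nm
      }, character(1))
      qual <- vapply(entries, function(e) {
        if (is.na(e$qualifier)) return(NA_character_)
        nm <- mesh_canonical(dict, e$qualifier, "qualifier")
        if (is.na(nm)) NA_character_ else nm
      }, character(1))
      list(desc = unique(desc[!is.na(desc)]),
           qual = unique(qual[!is.na(qual)]))
    })
    mesh_tab <- table(unlist(lapply(per_record, `[[`, "desc")))
    qual_tab <- table(unlist(lapply(per_record, `[[`, "qual")))
  }
  to_map <- function(tab) {
    if (!length(tab)) return(stats::setNames(integer(), character()))
    stats::setNames(as.integer(tab), names(tab))
  }
  list(freetext = to_map(tok_tab), mesh = to_map(mesh_tab),
       qualifier = to_map(qual_tab))
}

#' Build a population model from a record set
#'
#' Tokenizes every record's title and abstract with the same term
#' definition used for the analysis tables and counts, for each term,
#' the number of records containing it at least once. Keywords are
#' decomposed into MeSH descriptors and qualifiers against `dict`, with
#' per-record presence counted the same way.
#'
#' @param records A `record_set` representing the background corpus
#'   (e.g. a random sample of PubMed records).
#' @param dict A `mesh_dictionary`; only dictionary-listed names enter
#'   the MeSH and qualifier maps.
#' @param label Provenance label (e.g. a build date).
#' @return A `population_model`.
#' @export
build_population_model <- function(records, dict = NULL, label = "") {
  stopifnot(inherits(records, "record_set"))
  if (!n_records(records)) stop("empty record set", call. = FALSE)
  maps <- count_document_frequencies(records, dict)
  new_population_model(n_records(records),
                       doc_freq = maps$freetext,
                       mesh_doc_freq = maps$mesh,
                       qualifier_doc_freq = maps$qualifier,
                       label = label)
}

#' Null probability of a term under the population model
#'
#' @param model A `population_model`.
#' @param term Term (free text), descriptor, or qualifier name.
#' @param vocabulary Which map to consult.
#' @return Document frequency divided by population size, or `NA` when
#'   the term is absent from the population (the caller then assigns
#'   the z = 10000 sentinel).
#' @export
lookup_p0 <- function(model, term,
                      vocabulary = c("freetext", "mesh", "qualifier")) {
  stopifnot(inherits(model, "population_model"))
  vocabulary <- match.arg(vocabulary)
  map <- switch(vocabulary, freetext = model$doc_freq,
                mesh = model$mesh_doc_freq,
                qualifier = model$qualifier_doc_freq)
  cnt <- map[term]
  unname(ifelse(is.na(cnt), NA_real_, cnt / model$n_pop))
}

.popmodel_magic <- "#population-model\tv1"

#' Save a population model to a TSV file
#'
#' The persisted format is a diff-able three-section UTF-8 TSV: header
#' lines `#n_pop` and `#label`, then `#section` markers for the
#' freetext, mesh and qualifier maps with `term<TAB>count` rows.
#'
#' @param model A `population_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_population_model <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  section <- function(name, map) {
    c(sprintf("#section\t%s", name),
      if (length(map)) sprintf("%s\t%d", names(map), map))
  }
  lines <- c(.popmodel_magic,
             sprintf("#n_pop\t%d", model$n_pop),
             sprintf("#label\t%s", model$label),
             section("freetext", model$doc_freq),
             section("mesh", model$mesh_doc_freq),
             section("qualifier", model$qualifier_doc_freq))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Load a population model from its TSV file
#'
#' A file missing one of the mesh/qualifier sections loads with an
#' empty map for it and a warning (terms scored against an empty map
#' all receive the z = 10000 sentinel). Counts outside `[1, n_pop]` are
#' a load error.
#'
#' @param path Path written by [save_population_model()].
#' @return A `population_model`.
#' @export
load_population_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines) || lines[[1]] != .popmodel_magic) {
    stop("not a population model file (bad or missing version header)",
         call. = FALSE)
  }
  n_pop <- NA_integer_
  label <- ""
  maps <- list(freetext = integer(), mesh = integer(),
               qualifier = integer())
  seen <- character()
  cur <- NA_character_
  for (line in lines[-1]) {
    if (!nzchar(line)) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (startsWith(line, "#")) {
      key <- parts[[1]]
      val <- if (length(parts) > 1L) parts[[2]] else ""
      if (key == "#n_pop") n_pop <- as.integer(val)
      if (key == "#label") label <- val
      if (key == "#section") {
        if (!val %in% names(maps)) {
          stop(sprintf("unknown section '%s'", val), call. = FALSE)
        }
        cur <- val
        seen <- c(seen, val)
      }
      next
    }
    if (is.na(cur) || length(parts) != 2L) {
      stop(sprintf("malformed population model row: %s", line),
           call. = FALSE)
    }
    cnt <- suppressWarnings(as.integer(parts[[2]]))
    if (is.na(cnt)) {
      stop(sprintf("non-integer count in row: %s", line), call. = FALSE)
    }
    maps[[cur]][parts[[1]]] <- cnt
  }
  if (is.na(n_pop) || n_pop < 1L) {
    stop("population model file lacks a valid #n_pop", call. = FALSE)
  }
  absent <- setdiff(names(maps), seen)
  if (length(absent)) {
    warning(sprintf("population model file lacks section(s): %s",
                    paste(absent, collapse = ", ")), call. = FALSE)
  }
  new_population_model(n_pop, doc_freq = maps$freetext,
                       mesh_doc_freq = maps$mesh,
                       qualifier_doc_freq = maps$qualifier,
                       label = label)
}
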