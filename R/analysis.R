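# Frequency tables with overrepresentation z-scores: free text, MeSH
# descriptors, qualifiers, and the raw all-keywords table.

#' Analysis configuration
#'
#' @param z_cutoff Candidate cut-off on the z-score; terms at or above
#'   it are flagged as candidate search terms. Default 20, the
#'   empirically established threshold for the objective approach.
#' @param rare_min_documents Terms in fewer records than this are
#'   hidden by the rare-term filter (default 2, i.e. hide terms found
#'   in only one record).
#' @param rare_min_pct Terms in less than this percentage of records
#'   are hidden by the rare-term filter (default 10).
#' @param kwic_window Number of context words shown on each side of a
#'   keyword-in-context match (default 2).
#' @param max_skip Maximum number of skipped words in the 2-word
#'   skip-gram table (default 2, i.e. skip distances 0, 1, 2).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(z_cutoff = 20, rare_min_documents = 2L,
                            rare_min_pct = 10, kwic_window = 2L,
                            max_skip = 2L) {
  stopifnot(z_cutoff >= 0, rare_min_documents >= 0, rare_min_pct >= 0,
            kwic_window >= 1, max_skip >= 0)
  structure(list(z_cutoff = z_cutoff,
                 rare_min_documents = as.integer(rare_min_documents),
                 rare_min_pct = rare_min_pct,
                 kwic_window = as.integer(kwic_window),
                 max_skip = as.integer(max_skip)),
            class = "analysis_config")
}

# sentinels: a term absent from the population set cannot be tested and
# is maximally interesting; a term present in every population record
# with x < n is maximally uninteresting
.z_absent <- 10000
.z_floor  <- -10000

#' One-sample proportion z-score against a binomial null
#'
#' The normal approximation of the binomial test, without continuity
#' correction: `z = (x - n * p0) / sqrt(n * p0 * (1 - p0))`, where `x`
#' of `n` development-set records contain the term and `p0` is the
#' term's document probability in the population set.
#'
#' @param x Number of records containing the term, `0 <= x <= n`.
#' @param n Number of records in the analysed set.
#' @param p0 Null probability from the population model, in `(0, 1]`.
#'   `p0 = 1` is a degenerate edge: the score is 0 when `x = n` and is
#'   clamped to the -10000 sentinel otherwise.
#' @return The z-score.
#' @examples
#' z_score(30, 100, 0.3) # 0: observed equals expectation
#' z_score(30, 100, 0.1) # ~6.67: strong overrepresentation
#' @export
z_score <- function(x, n, p0) {
  stopifnot(n >= 1, all(x >= 0), all(x <= n))
  if (any(p0 <= 0) || any(p0 > 1)) {
    stop("p0 must lie in (0, 1]", call. = FALSE)
  }
  z <- (x - n * p0) / sqrt(n * p0 * (1 - p0))
  degenerate <- p0 == 1
  if (any(degenerate)) {
    z[degenerate] <- ifelse(x[degenerate] == n, 0, .z_floor)
  }
  z
}

# z per row given population counts (NA count = absent -> 10000)
z_from_counts <- function(x, n, pop_count, n_pop) {
  vapply(seq_along(x), function(i) {
    if (is.na(pop_count[[i]])) return(.z_absent)
    z_score(x[[i]], n, pop_count[[i]] / n_pop)
  }, numeric(1))
}

# shared assembly: given doc counts, optional term freq and population
# counts, build the sorted stats tibble
build_term_stats <- function(term, documents, term_frequency = NULL,
                             pop_count, n, n_pop, cfg) {
  z <- z_from_counts(documents, n, pop_count, n_pop)
  out <- tibble::tibble(
    term = term,
    documents = as.integer(documents),
    documents_pct = 100 * documents / n,
    z = z
  )
  if (!is.null(term_frequency)) {
    out$term_frequency <- as.integer(term_frequency)
  }
  out$is_candidate <- out$z >= cfg$z_cutoff
  # z descending, alphabetical (locale-independent) tie-break
  ord <- order(-out$z, out$term, method = "radix")
  out[ord, ]
}

# tokens of one record's title+abstract, with per-record unique and
# total views
record_tokens <- function(r) c(tokenize_freetext(r$title),
                               tokenize_freetext(r$abstract))

#' Free-text frequency table with z-scores
#'
#' One row per unique term across the titles and abstracts of the
#' analysed set. `documents` counts records containing the term at
#' least once, `term_frequency` counts total occurrences, and `z` is
#' the binomial-test z-score against the population model. Terms absent
#' from the population set receive the sentinel z = 10000. All
#' identified terms are returned; use [filter_rare()] to hide rare
#' ones. Rows are sorted by z descending, ties alphabetical.
#'
#' @param dev A `record_set` (typically the development set).
#' @param pop A `population_model`.
#' @param cfg An [analysis_config()].
#' @return A tibble with columns `term`, `documents`, `documents_pct`,
#'   `z`, `term_frequency`, `is_candidate`.
#' @export
freetext_table <- function(dev, pop, cfg = analysis_config()) {
  stopifnot(inherits(dev, "record_set"),
            inherits(pop, "population_model"))
  n <- n_records(dev)
  if (!n) stop("empty record set", call. = FALSE)
  toks <- lapply(dev$records, record_tokens)
  if (!length(unlist(toks))) {
    warning("no searchable tokens in any record; empty table",
            call. = FALSE)
    return(build_term_stats(character(), integer(), integer(),
                            integer(), n, pop$n_pop, cfg))
  }
  doc_tab <- table(unlist(lapply(toks, unique)))
  tf_tab <- table(unlist(toks))
  terms <- names(doc_tab)
  build_term_stats(
    term = terms,
    documents = as.integer(doc_tab),
    term_frequency = as.integer(tf_tab[terms]),
    pop_count = unname(pop$doc_freq[terms]),
    n = n, n_pop = pop$n_pop, cfg = cfg
  )
}

# parsed keyword entries for every record, with canonical names
record_keyword_entries <- function(records, dict) {
  lapply(records$records, function(r) {
    if (!length(r$keywords)) return(list())
    lapply(r$keywords, function(kw) {
      e <- parse_keyword(kw)
      e$descriptor_canonical <- mesh_canonical(dict, e$descriptor,
                                               "descriptor")
      e$qualifier_canonical <- if (is.na(e$qualifier)) {
        NA_character_
      } else {
        mesh_canonical(dict, e$qualifier, "qualifier")
      }
      e
    })
  })
}

#' MeSH descriptor frequency table with z-scores
#'
#' Only descriptors listed in the dictionary appear. Descriptors are
#' counted once per record, so the document frequency equals the term
#' frequency and no `term_frequency` column is reported.
#'
#' @inheritParams freetext_table
#' @param dict A `mesh_dictionary`.
#' @return A tibble with columns `term`, `documents`, `documents_pct`,
#'   `z`, `is_candidate`.
#' @export
mesh_table <- function(dev, pop, dict, cfg = analysis_config()) {
  stopifnot(inherits(dev, "record_set"),
            inherits(pop, "population_model"),
            inherits(dict, "mesh_dictionary"))
  n <- n_records(dev)
  if (!n) stop("empty record set", call. = FALSE)
  if (!length(pop$mesh_doc_freq)) {
    warning(paste("population model has no MeSH section;",
                  "every descriptor receives the z = 10000 sentinel"),
            call. = FALSE)
  }
  entries <- record_keyword_entries(dev, dict)
  per_record <- lapply(entries, function(es) {
    unique(stats::na.omit(vapply(es, `[[`, character(1),
                                 "descriptor_canonical")))
  })
  doc_tab <- table(unlist(per_record))
  terms <- names(doc_tab)
  build_term_stats(
    term = terms,
    documents = as.integer(doc_tab),
    pop_count = unname(pop$mesh_doc_freq[terms]),
    n = n, n_pop = pop$n_pop, cfg = cfg
  )
}

#' Qualifier (subheading) frequency table with z-scores
#'
#' Qualifiers may occur more than once per record (attached to
#' different descriptors), so both `documents` and `term_frequency`
#' are reported. Only dictionary-listed qualifier names appear.
#'
#' @inheritParams mesh_table
#' @return A tibble like [freetext_table()]'s.
#' @export
qualifier_table <- function(dev, pop, dict, cfg = analysis_config()) {
  stopifnot(inherits(dev, "record_set"),
            inherits(pop, "population_model"),
            inherits(dict, "mesh_dictionary"))
  n <- n_records(dev)
  if (!n) stop("empty record set", call. = FALSE)
  if (!length(pop$qualifier_doc_freq)) {
    warning(paste("population model has no qualifier section;",
                  "every qualifier receives the z = 10000 sentinel"),
            call. = FALSE)
  }
  entries <- record_keyword_entries(dev, dict)
  per_record <- lapply(entries, function(es) {
    stats::na.omit(vapply(es, `[[`, character(1),
                          "qualifier_canonical"))
  })
  doc_tab <- table(unlist(lapply(per_record, unique)))
  tf_tab <- table(unlist(per_record))
  terms <- names(doc_tab)
  build_term_stats(
    term = terms,
    documents = as.integer(doc_tab),
    term_frequency = as.integer(tf_tab[terms]),
    pop_count = unname(pop$qualifier_doc_freq[terms]),
    n = n, n_pop = pop$n_pop, cfg = cfg
  )
}

#' Raw keyword frequency table
#'
#' Counts keyword strings verbatim, so MeSH/qualifier combinations such
#' as "Neoplasms/diagnosis" and "Neoplasms/therapy" are distinct rows.
#' Non-MeSH keywords appear here too. No z-scores are calculated.
#'
#' @param dev A `record_set`.
#' @return A tibble with columns `keyword` and `frequency`, sorted by
#'   frequency descending, ties alphabetical.
#' @export
all_keywords_table <- function(dev) {
  stopifnot(inherits(dev, "record_set"))
  if (!n_records(dev)) stop("empty record set", call. = FALSE)
  kws <- unlist(lapply(dev$records, `[[`, "keywords"))
  if (!length(kws)) {
    return(tibble::tibble(keyword = character(), frequency = integer()))
  }
  tab <- table(kws)
  out <- tibble::tibble(keyword = names(tab),
                        frequency = as.integer(tab))
  ord <- order(-out$frequency, out$keyword, method = "radix")
  out[ord, ]
}

#' Hide rare terms from a frequency table
#'
#' A pure view filter reproducing the "hide rare terms" checkbox: a row
#' is hidden when its term appears in fewer than `rare_min_documents`
#' records or in less than `rare_min_pct` percent of the records.
#'
#' @param rows A frequency table from [freetext_table()] and friends.
#' @param n Number of records behind the table.
#' @param cfg An [analysis_config()].
#' @return The filtered tibble.
#' @export
filter_rare <- function(rows, n, cfg = analysis_config()) {
  keep <- rows$documents >= cfg$rare_min_documents &
    rows$documents_pct >= cfg$rare_min_pct
  rows[keep, ]
}

#' Relative recall of a single term
#'
#' The share of the analysed record set a single term retrieves, i.e.
#' its `documents_pct`. Recall of Boolean combinations of terms is out
#' of scope.
#'
#' @param term_row One row of a frequency table.
#' @return A percentage in `(0, 100]`.
#' @export
relative_recall <- function(term_row) {
  term_row$documents_pct
}
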