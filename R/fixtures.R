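# Synthetic record sets with known, planted term statistics, and a
# miniature MeSH dictionary. These stand in for real PubMed test sets
# so that every analysis is testable offline; the generated "text" is
# a bag of vocabulary terms, not realistic English prose.

#' Specification for a synthetic record set
#'
#' @param n_records Number of records to generate.
#' @param vocabulary A data frame with columns `term` (a valid
#'   free-text token), `p` (per-record inclusion probability in
#'   `[0, 1]`), and optionally `mean_repeats` (mean occurrences per
#'   record when present, >= 1; default 1).
#' @param mesh_pool Optional data frame with columns `keyword` (a raw
#'   keyword string such as `"Neoplasms/therapy"`) and `p` (per-record
#'   inclusion probability).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_records, vocabulary,
                         mesh_pool = NULL, seed = 1L) {
  vocabulary <- as.data.frame(vocabulary)
  stopifnot(n_records >= 1, all(c("term", "p") %in% names(vocabulary)),
            all(vocabulary$p >= 0), all(vocabulary$p <= 1))
  if (is.null(vocabulary$mean_repeats)) vocabulary$mean_repeats <- 1
  stopifnot(all(vocabulary$mean_repeats >= 1))
  if (!is.null(mesh_pool)) {
    mesh_pool <- as.data.frame(mesh_pool)
    stopifnot(all(c("keyword", "p") %in% names(mesh_pool)),
              all(mesh_pool$p >= 0), all(mesh_pool$p <= 1))
  }
  structure(list(n_records = as.integer(n_records),
                 vocabulary = vocabulary, mesh_pool = mesh_pool,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic record set with realized planted truth
#'
#' Each record's title and abstract are space-joined samples from the
#' vocabulary: each term is present with its inclusion probability,
#' repeated `1 + Poisson(mean_repeats - 1)` times, and each included
#' term block lands in the title or the abstract. Keywords are drawn
#' from the `mesh_pool`. Alongside the records, the realized — not
#' expected — per-term document and occurrence counts are returned, so
#' analysis tables can be asserted exactly rather than statistically.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `records` (a `record_set`) and `truth`, a list
#'   holding `doc_freq`, `term_freq`, and `keyword_freq` named integer
#'   vectors (terms with zero realized count are absent).
#' @export
generate_records <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(
    spec$seed,
    {
      voc <- spec$vocabulary
      records <- vector("list", spec$n_records)
      doc_freq <- term_freq <- stats::setNames(
        integer(length(voc$term)), voc$term)
      keyword_freq <- integer()
      for (i in seq_len(spec$n_records)) {
        present <- stats::runif(nrow(voc)) < voc$p
        title_toks <- character()
        abstract_toks <- character()
        for (j in which(present)) {
          reps <- 1L + stats::rpois(1L, voc$mean_repeats[[j]] - 1)
          block <- rep(voc$term[[j]], reps)
          if (stats::runif(1) < 0.3) {
            title_toks <- c(title_toks, block)
          } else {
            abstract_toks <- c(abstract_toks, block)
          }
          doc_freq[[voc$term[[j]]]] <- doc_freq[[voc$term[[j]]]] + 1L
          term_freq[[voc$term[[j]]]] <- term_freq[[voc$term[[j]]]] + reps
        }
        kws <- character()
        if (!is.null(spec$mesh_pool)) {
          kw_present <- stats::runif(nrow(spec$mesh_pool)) <
            spec$mesh_pool$p
          kws <- spec$mesh_pool$keyword[kw_present]
          for (kw in kws) {
            keyword_freq[kw] <- (if (is.na(keyword_freq[kw])) 0L
                                 else keyword_freq[[kw]]) + 1L
          }
        }
        records[[i]] <- new_ris_record(
          record_id = as.character(100000L + i),
          ref_type = "JOUR",
          authors = sprintf("Author %d", i),
          title = paste(title_toks, collapse = " "),
          abstract = paste(abstract_toks, collapse = " "),
          year = "2022",
          keywords = kws
        )
      }
      list(
        records = new_record_set(records, source_dialect = "pubmed"),
        truth = list(doc_freq = doc_freq[doc_freq > 0L],
                     term_freq = term_freq[term_freq > 0L],
                     keyword_freq = keyword_freq)
      )
    },
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

#' Miniature MeSH dictionary for tests and examples
#'
#' About 30 descriptors (including "Neoplasms" and "Humans") and 10
#' qualifiers (including "diagnosis" and "therapy"), loaded from the
#' plain-text name lists bundled with the package. A stand-in for a
#' full MeSH year dictionary; real analyses should load one with
#' [read_mesh_dictionary()] or [read_mesh_xml()].
#'
#' @return A `mesh_dictionary`.
#' @export
mini_mesh_dictionary <- function() {
  read_mesh_dictionary(
    system.file("extdata", "mesh_mini_descriptors.txt",
                package = "termscout", mustWork = TRUE),
    system.file("extdata", "mesh_mini_qualifiers.txt",
                package = "termscout", mustWork = TRUE),
    version_label = "mini-synthetic"
  )
}
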