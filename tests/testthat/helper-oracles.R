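# Independent brute-force oracles: naive per-record scans kept separate
# from the table-building code paths they check.

# document and occurrence counts by a plain double loop over records
zero_if_null <- function(a) if (is.null(a)) 0L else a

naive_freetext_counts <- function(records) {
  doc <- list()
  tf <- list()
  for (r in records$records) {
    toks <- c(tokenize_freetext(r$title), tokenize_freetext(r$abstract))
    for (t in unique(toks)) {
      doc[[t]] <- zero_if_null(doc[[t]]) + 1L
    }
    for (t in toks) {
      tf[[t]] <- zero_if_null(tf[[t]]) + 1L
    }
  }
  list(doc = unlist(doc), tf = unlist(tf))
}

# enumerate every ordered index pair with gap <= max_skip
naive_skipgrams <- function(records, max_skip) {
  counts <- new.env(parent = emptyenv())
  for (r in records$records) {
    for (field in c("title", "abstract")) {
      toks <- tokenize_freetext(r[[field]])
      L <- length(toks)
      if (L < 2) next
      for (i in seq_len(L - 1)) {
        for (j in (i + 1):L) {
          k <- j - i - 1
          if (k > max_skip) next
          key <- paste(toks[i], toks[j], k, sep = "\x1f")
          counts[[key]] <- (if (is.null(counts[[key]])) 0L
                            else counts[[key]]) + 1L
        }
      }
    }
  }
  out <- as.list(counts)
  unlist(out)
}

# a small random fixture spec drawn from a pool of plausible terms
random_fixture_spec <- function(seed, n_records = 8L) {
  pool <- c("tumour", "cancer", "cells", "screening", "therapy",
            "breast", "risk", "cohort", "biopsy", "survival")
  withr::with_seed(seed, {
    k <- sample(4:8, 1)
    terms <- sample(pool, k)
    fixture_spec(
      n_records = n_records,
      vocabulary = data.frame(
        term = terms,
        p = stats::runif(k, 0.1, 0.95),
        mean_repeats = 1 + stats::rexp(k, 1)
      ),
      mesh_pool = data.frame(
        keyword = c("Neoplasms/therapy", "Neoplasms/diagnosis",
                    "Humans", "my lab keyword"),
        p = c(0.5, 0.3, 0.8, 0.2)
      ),
      seed = seed
    )
  })
}

# a tiny population model written and loaded through the TSV format,
# with hand-chosen counts
make_population_tsv <- function(n_pop, freetext = integer(),
                                mesh = integer(),
                                qualifier = integer()) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  rows <- function(name, map) {
    c(sprintf("#section\t%s", name),
      if (length(map)) sprintf("%s\t%d", names(map), map))
  }
  writeLines(c("#population-model\tv1",
               sprintf("#n_pop\t%d", n_pop),
               "#label\ttest",
               rows("freetext", freetext),
               rows("mesh", mesh),
               rows("qualifier", qualifier)),
             path)
  load_population_model(path)
}
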