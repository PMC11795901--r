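# record-set construction helper shared with test-population.R lives
# there; rebuild minimal sets here where needed
mini_set <- function(texts, keywords = NULL) {
  recs <- lapply(seq_along(texts), function(i) {
    termscout:::new_ris_record(
      record_id = as.character(i), ref_type = "JOUR",
      title = texts[[i]],
      keywords = if (is.null(keywords)) character() else keywords[[i]])
  })
  termscout:::new_record_set(recs)
}

test_that("z_score reproduces the uncorrected proportion statistic", {
  expect_equal(z_score(30, 100, 0.3), 0)
  expect_equal(z_score(30, 100, 0.1), 20 / sqrt(9))
  expect_equal(z_score(0, 50, 0.2), -10 / sqrt(8))
})

test_that("z_score agrees with the phat-based form and is monotone in x", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(5:500, 1)
      x <- sample(0:n, 1)
      p0 <- stats::runif(1, 0.001, 0.999)
      phat_form <- (x / n - p0) / sqrt(p0 * (1 - p0) / n)
      expect_equal(z_score(x, n, p0), phat_form, tolerance = 1e-12)
    }
  })
  z_seq <- z_score(0:20, 20, 0.4)
  expect_true(all(diff(z_seq) > 0))
})

test_that("z_score rejects invalid p0 and clamps the p0 = 1 edge", {
  expect_error(z_score(1, 10, 0), "p0")
  expect_error(z_score(1, 10, 1.2), "p0")
  expect_equal(z_score(10, 10, 1), 0)
  expect_equal(z_score(9, 10, 1), -10000)
})

test_that("the free-text table reproduces a hand-worked example", {
  # 10 records, 6 containing "tumour" with 9 occurrences in total
  texts <- c("tumour growth", "tumour tumour spread", "tumour",
             "tumour tumour response", "tumour", "tumour tumour cells",
             "cells", "growth", "spread", "response")
  dev <- mini_set(texts)
  pop <- make_population_tsv(100, freetext = c(
    tumour = 5L, growth = 40L, spread = 30L, response = 50L,
    cells = 60L))
  tab <- freetext_table(dev, pop)
  row <- tab[tab$term == "tumour", ]
  expect_equal(row$documents, 6L)
  expect_equal(row$documents_pct, 60)
  expect_equal(row$term_frequency, 9L)
  expect_equal(row$z, (6 - 10 * 0.05) / sqrt(10 * 0.05 * 0.95),
               tolerance = 1e-12)
  expect_equal(round(row$z, 4), 7.9802)
})

test_that("terms absent from the population get the 10000 sentinel", {
  dev <- mini_set(c("zebrafish stripes", "zebrafish"))
  pop <- make_population_tsv(50, freetext = c(stripes = 2L))
  tab <- freetext_table(dev, pop)
  expect_equal(tab$z[tab$term == "zebrafish"], 10000)
  expect_true(tab$is_candidate[tab$term == "zebrafish"])
  expect_lt(abs(tab$z[tab$term == "stripes"]), 10000)
})

test_that("rows sort by z descending with alphabetical tie-break", {
  dev <- mini_set(c("alpha beta gamma", "alpha beta gamma"))
  pop <- make_population_tsv(100, freetext = c(
    alpha = 10L, beta = 10L, gamma = 50L))
  tab <- freetext_table(dev, pop)
  expect_equal(tab$term, c("alpha", "beta", "gamma"))
  expect_true(all(diff(tab$z) <= 0))
})

test_that("a dev set with no text yields an empty table and a warning", {
  dev <- mini_set(c("", ""))
  pop <- make_population_tsv(10, freetext = c(x = 1L))
  expect_warning(tab <- freetext_table(dev, pop), "no searchable")
  expect_equal(nrow(tab), 0L)
})

test_that("MeSH and qualifier tables split the vocabulary correctly", {
  dev <- mini_set(
    c("t one", "t two"),
    keywords = list(
      c("Neoplasms/diagnosis", "Neoplasms/therapy", "Humans",
        "my lab keyword"),
      c("Humans", "Breast Neoplasms/therapy")))
  pop <- make_population_tsv(
    100,
    mesh = c(Neoplasms = 10L, Humans = 80L, `Breast Neoplasms` = 5L),
    qualifier = c(diagnosis = 20L, therapy = 30L))
  dict <- mini_mesh_dictionary()

  mt <- mesh_table(dev, pop, dict)
  # descriptor counted once per record despite two qualifier combos
  expect_equal(mt$documents[mt$term == "Neoplasms"], 1L)
  expect_equal(mt$documents[mt$term == "Humans"], 2L)
  expect_equal(mt$documents_pct[mt$term == "Humans"], 100)
  expect_false("term_frequency" %in% names(mt))
  expect_false("my lab keyword" %in% mt$term)

  qt <- qualifier_table(dev, pop, dict)
  expect_equal(qt$documents[qt$term == "therapy"], 2L)
  expect_equal(qt$term_frequency[qt$term == "therapy"], 2L)
  expect_equal(qt$documents[qt$term == "diagnosis"], 1L)
  expect_true("term_frequency" %in% names(qt))
})

test_that("qualifier term frequency can exceed document frequency", {
  dev <- mini_set("t", keywords = list(
    c("Neoplasms/therapy", "Breast Neoplasms/therapy")))
  pop <- make_population_tsv(100, qualifier = c(therapy = 30L),
                             mesh = c(Neoplasms = 1L))
  qt <- qualifier_table(dev, pop, mini_mesh_dictionary())
  expect_equal(qt$documents[qt$term == "therapy"], 1L)
  expect_equal(qt$term_frequency[qt$term == "therapy"], 2L)
})

test_that("a population model without MeSH sections sentinels loudly", {
  dev <- mini_set("t", keywords = list("Humans"))
  pop <- make_population_tsv(100, freetext = c(t = 1L))
  expect_warning(mt <- mesh_table(dev, pop, mini_mesh_dictionary()),
                 "sentinel")
  expect_equal(mt$z, 10000)
})

test_that("the all-keywords table counts raw strings verbatim", {
  dev <- mini_set(
    c("a", "b", "c"),
    keywords = list(
      c("Neoplasms/diagnosis", "Neoplasms/therapy"),
      c("Humans"), c("Humans")))
  tab <- all_keywords_table(dev)
  expect_equal(tab$frequency[tab$keyword == "Humans"], 2L)
  expect_equal(tab$frequency[tab$keyword == "Neoplasms/diagnosis"], 1L)
  expect_equal(tab$frequency[tab$keyword == "Neoplasms/therapy"], 1L)
  expect_equal(tab$keyword[[1]], "Humans")  # frequency-desc order
})

test_that("filter_rare hides singletons and sub-10% terms", {
  rows <- tibble::tibble(
    term = c("once", "four", "six"),
    documents = c(1L, 4L, 6L),
    documents_pct = 100 * c(1, 4, 6) / 50,
    z = c(5, 5, 5), is_candidate = FALSE)
  kept <- filter_rare(rows, 50)
  expect_equal(kept$term, "six")   # 12% and >1 record
  # four is in 8% of records: hidden by the percentage clause alone
  expect_false("four" %in% kept$term)
})

test_that("relative recall is the documents percentage", {
  expect_equal(relative_recall(list(documents_pct = 60)), 60)
  expect_equal(relative_recall(tibble::tibble(documents_pct = 100)),
               100)
  expect_equal(relative_recall(list(documents_pct = 100 / 3)),
               33.33333, tolerance = 1e-5)
})

test_that("every table row matches a naive per-record recount", {
  for (seed in c(61, 62, 63, 64, 65)) {
    g <- generate_records(random_fixture_spec(seed))
    pop <- make_population_tsv(200, freetext = c(
      tumour = 10L, cancer = 20L, cells = 150L, screening = 5L,
      therapy = 40L, breast = 12L, risk = 90L, cohort = 30L))
    tab <- freetext_table(g$records, pop)
    oracle <- naive_freetext_counts(g$records)
    n <- n_records(g$records)
    expect_setequal(tab$term, names(oracle$doc))
    for (i in seq_len(nrow(tab))) {
      t <- tab$term[[i]]
      expect_identical(tab$documents[[i]], oracle$doc[[t]])
      expect_identical(tab$term_frequency[[i]], oracle$tf[[t]])
      expect_equal(tab$documents_pct[[i]], 100 * oracle$doc[[t]] / n)
      p0 <- lookup_p0(pop, t, "freetext")
      expected_z <- if (is.na(p0)) {
        10000
      } else {
        (oracle$doc[[t]] - n * p0) / sqrt(n * p0 * (1 - p0))
      }
      expect_equal(tab$z[[i]], expected_z, tolerance = 1e-12)
    }
  }
})

test_that("free-text and keyword vocabularies do not leak into each other", {
  g <- generate_records(random_fixture_spec(71))
  pop <- make_population_tsv(100, freetext = c(tumour = 5L))
  ft <- freetext_table(g$records, pop)
  akw <- all_keywords_table(g$records)
  # keywords never appear as free-text rows and vice versa
  expect_length(intersect(ft$term, akw$keyword), 0)
  dict <- mini_mesh_dictionary()
  mt <- suppressWarnings(mesh_table(g$records, pop, dict))
  expect_length(intersect(ft$term, mt$term), 0)
  expect_true(all(mt$term %in% dict$descriptors))
})
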