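# Development/validation split and OVID id-list output.

# fixed PRNG so splits reproduce bit-identically across platforms:
# Mersenne-Twister with Inversion and Rejection sampling (the R >=
# 3.6.0 sampling algorithm), pinned explicitly rather than relying on
# the session default
.split_rng <- function(seed, expr) {
  withr::with_seed(seed, expr,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

round_half_up <- function(x) floor(x + 0.5)

#' Split a test set into development and validation sets (2:1)
#'
#' Draws a random 2:1 partition of the records; the development set
#' receives `round_half_up(2n/3)` records. The applied seed is returned
#' so the pseudo-random split can be reproduced later (e.g. for peer
#' review); given the same records in the same order and the same
#' seed, the split is identical across runs and platforms. Record
#' order within each subset follows the input order.
#'
#' @param records A `record_set` with at least 3 records.
#' @param seed Integer seed; when `NULL` one is drawn and reported in
#'   the result (the "applied random seed").
#' @return A `split_result` with elements `development`, `validation`
#'   (both `record_set`s), `seed`, and `ratio = "2:1"`.
#' @export
split_records <- function(records, seed = NULL) {
  stopifnot(inherits(records, "record_set"))
  n <- n_records(records)
  if (n < 3L) stop("test set too small to split", call. = FALSE)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  seed <- as.integer(seed)
  n_dev <- as.integer(round_half_up(2 * n / 3))
  dev_idx <- sort(.split_rng(seed, sample.int(n, n_dev)))
  val_idx <- setdiff(seq_len(n), dev_idx)
  structure(
    list(
      development = new_record_set(records$records[dev_idx],
                                   records$source_dialect),
      validation = new_record_set(records$records[val_idx],
                                  records$source_dialect),
      seed = seed,
      ratio = "2:1"
    ),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf(
    "<split_result> development %d / validation %d (ratio %s), applied random seed %d\n",
    n_records(x$development), n_records(x$validation), x$ratio, x$seed))
  invisible(x)
}

#' PMID list in OVID search syntax
#'
#' Renders the record ids as an Ovid MEDLINE unique-identifier search,
#' `"(id1 or id2 or ...).ui."`, suitable for pasting into the Ovid
#' search box to re-retrieve the set. Non-numeric ids cannot be PMIDs
#' and are skipped with a warning.
#'
#' @param records A `record_set`.
#' @return A single search string.
#' @export
pmids_to_ovid <- function(records) {
  stopifnot(inherits(records, "record_set"))
  ids <- vapply(records$records, `[[`, character(1), "record_id")
  numeric_ok <- grepl("^[0-9]+$", ids)
  if (any(!numeric_ok)) {
    warning(sprintf("skipping non-numeric id(s): %s",
                    paste(ids[!numeric_ok], collapse = ", ")),
            call. = FALSE)
  }
  ids <- ids[numeric_ok]
  if (!length(ids)) stop("no numeric record ids", call. = FALSE)
  sprintf("(%s).ui.", paste(ids, collapse = " or "))
}
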