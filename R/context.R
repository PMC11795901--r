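# Keyword-in-context concordance and the 2-word skip-gram table.

#' Keyword-in-context (KWIC) concordance
#'
#' Shows every occurrence of a query term in its immediate context.
#' The query is tokenized with the same term definition as the
#' analysis, so multi-word and hyphenated queries work alike
#' ("decision-making" matches the token sequence "decision making").
#' Title and abstract token streams are scanned independently; a hit
#' reports up to `window` tokens of context on each side, truncated at
#' field boundaries.
#'
#' @param records A `record_set` (by default the whole uploaded set;
#'   pass a split's `development` to restrict).
#' @param query Query string; must tokenize to at least one term.
#' @param window Context width in words on each side (default 2).
#' @return A tibble with columns `record_id`, `field`, `left`, `match`,
#'   `right` (space-joined token strings), one row per occurrence, with
#'   attributes `n_matching_records` and `n_occurrences`.
#' @export
kwic <- function(records, query, window = 2L) {
  stopifnot(inherits(records, "record_set"), window >= 1)
  qtoks <- tokenize_freetext(query)
  if (!length(qtoks)) {
    stop("query has no searchable tokens", call. = FALSE)
  }
  k <- length(qtoks)
  hits <- list()
  for (r in records$records) {
    for (field in c("title", "abstract")) {
      toks <- tokenize_freetext(r[[field]])
      L <- length(toks)
      if (L < k) next
      for (i in seq_len(L - k + 1L)) {
        if (all(toks[i:(i + k - 1L)] == qtoks)) {
          lo <- max(1L, i - window)
          hi <- min(L, i + k - 1L + window)
          hits[[length(hits) + 1L]] <- tibble::tibble(
            record_id = r$record_id,
            field = field,
            left = paste(toks[seq2(lo, i - 1L)], collapse = " "),
            match = paste(qtoks, collapse = " "),
            right = paste(toks[seq2(i + k, hi)], collapse = " ")
          )
        }
      }
    }
  }
  out <- if (length(hits)) {
    do.call(rbind, hits)
  } else {
    tibble::tibble(record_id = character(), field = character(),
                   left = character(), match = character(),
                   right = character())
  }
  attr(out, "n_matching_records") <- length(unique(out$record_id))
  attr(out, "n_occurrences") <- nrow(out)
  out
}

# seq that is empty when from > to (base seq() would count backwards)
seq2 <- function(from, to) {
  if (from > to) integer() else seq.int(from, to)
}

#' Display text of a record's title or abstract
#'
#' Blank titles and abstracts are rendered as the placeholders
#' `"NO_TITLE"` and `"NO_ABSTRACT"`.
#'
#' @param record A single record from a `record_set`.
#' @param field `"title"` or `"abstract"`.
#' @return The field text or its placeholder.
#' @export
record_display_text <- function(record, field = c("title", "abstract")) {
  field <- match.arg(field)
  x <- record[[field]]
  if (!is.null(x) && nzchar(trimws(x))) {
    x
  } else if (field == "title") {
    "NO_TITLE"
  } else {
    "NO_ABSTRACT"
  }
}

#' 2-word skip-gram frequency table
#'
#' For every record and for title and abstract independently, every
#' ordered token pair separated by at most `max_skip` intervening
#' words contributes one occurrence at its skip distance; pairs never
#' span the title/abstract boundary. In "shared decision making",
#' ("shared", "making") is a skip-1 gram. Direction is preserved.
#'
#' @param records A `record_set`.
#' @param max_skip Maximum skip distance (default 2: skips 0, 1, 2).
#' @return A tibble with columns `first`, `second`, one `skip_<k>`
#'   count column per distance, and `total`; sorted by `total`
#'   descending, ties alphabetical by (`first`, `second`).
#' @export
skipgram_table <- function(records, max_skip = 2L) {
  stopifnot(inherits(records, "record_set"), max_skip >= 0)
  max_skip <- as.integer(max_skip)
  sep <- "\x1f"
  keys <- list()
  for (r in records$records) {
    for (field in c("title", "abstract")) {
      toks <- tokenize_freetext(r[[field]])
      L <- length(toks)
      if (L < 2L) next
      for (k in 0:max_skip) {
        if (L < k + 2L) next
        first <- toks[seq_len(L - k - 1L)]
        second <- toks[seq_len(L - k - 1L) + k + 1L]
        keys[[length(keys) + 1L]] <- paste(first, second, k, sep = sep)
      }
    }
  }
  keys <- unlist(keys)
  skip_cols <- paste0("skip_", 0:max_skip)
  if (!length(keys)) {
    out <- tibble::tibble(first = character(), second = character())
    for (col in skip_cols) out[[col]] <- integer()
    out$total <- integer()
    return(out)
  }
  tab <- table(keys)
  parts <- do.call(rbind, strsplit(names(tab), sep, fixed = TRUE))
  long <- data.frame(first = parts[, 1], second = parts[, 2],
                     k = as.integer(parts[, 3]),
                     count = as.integer(tab),
                     stringsAsFactors = FALSE)
  pair_key <- paste(long$first, long$second, sep = sep)
  pairs <- !duplicated(pair_key)
  out <- tibble::tibble(first = long$first[pairs],
                        second = long$second[pairs])
  out_key <- pair_key[pairs]
  for (k in 0:max_skip) {
    cnt <- integer(nrow(out))
    rows <- long$k == k
    cnt[match(pair_key[rows], out_key)] <- long$count[rows]
    out[[paste0("skip_", k)]] <- cnt
  }
  out$total <- as.integer(rowSums(as.matrix(out[, skip_cols])))
  ord <- order(-out$total, out$first, out$second, method = "radix")
  out[ord, ]
}
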