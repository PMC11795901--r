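# RIS reading and writing for the two dialects commonly produced by
# PubMed ("Send to > Citation manager") and EndNote exports.  Only the
# tags the analysis uses are retained: TY, AN, AU/A1, TI/T1, AB/N1,
# PY/Y1, KW/DE, ER.

.ris_tags_pubmed  <- c(author = "AU", title = "TI", abstract = "AB",
                       year = "PY", keyword = "KW")
.ris_tags_endnote <- c(author = "A1", title = "T1", abstract = "N1",
                       year = "Y1", keyword = "DE")
.ris_known_tags <- c("TY", "AN", "AU", "A1", "TI", "T1", "AB", "N1",
                     "PY", "Y1", "KW", "DE", "ER")

new_ris_record <- function(record_id = "", ref_type = "",
                           authors = character(), title = "",
                           abstract = "", year = "",
                           keywords = character()) {
  structure(
    list(record_id = record_id, ref_type = ref_type, authors = authors,
         title = title, abstract = abstract, year = year,
         keywords = keywords),
    class = "ris_record"
  )
}

new_record_set <- function(records, source_dialect = "pubmed") {
  stopifnot(source_dialect %in% c("pubmed", "endnote"))
  structure(list(records = records, source_dialect = source_dialect),
            class = "record_set")
}

#' Number of records in a record set
#' @param x A `record_set`.
#' @return Integer count of records.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "record_set"))
  length(x$records)
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set> %d records (%s dialect)\n",
              n_records(x), x$source_dialect))
  invisible(x)
}

#' Summarise a record set as a tibble
#'
#' One row per record with the fields shown in the upload overview:
#' id, publication year, first author, and title.
#'
#' @param x A `record_set`.
#' @param ... Unused.
#' @return A tibble with columns `record_id`, `year`, `author`, `title`.
#' @export
as_tibble.record_set <- function(x, ...) {
  tibble::tibble(
    record_id = vapply(x$records, `[[`, character(1), "record_id"),
    year      = vapply(x$records, `[[`, character(1), "year"),
    author    = vapply(x$records, function(r) {
      if (length(r$authors)) r$authors[[1]] else ""
    }, character(1)),
    title     = vapply(x$records, `[[`, character(1), "title")
  )
}

#' Parse bibliographic records from RIS text
#'
#' Accepts the RIS-like PubMed export and the standard EndNote RIS
#' export. Records are delimited by `ER` lines; tag lines have the form
#' `XX  - value`; physical lines that do not start a new tag are treated
#' as continuations of the previous tag and joined with a single space.
#' Tags other than TY, AN, AU/A1, TI/T1, AB/N1, PY/Y1 and KW/DE are
#' ignored without error.
#'
#' @param text RIS content as a single string or a character vector of
#'   lines (CRLF and LF line endings are both accepted).
#' @param dialect `"pubmed"`, `"endnote"`, or `"auto"`. In auto mode a
#'   file whose records carry A1/T1/N1/Y1 is classified as EndNote;
#'   AU/TI/AB/PY (with AN) as PubMed; ambiguous files fall back to
#'   PubMed with a warning.
#' @return A `record_set`: an ordered list of records plus the detected
#'   source dialect. Record ids come from the AN tag; records without AN
#'   get a synthesized `REC<n>` id with a warning. Duplicate ids are an
#'   error.
#' @export
parse_ris <- function(text, dialect = c("auto", "pubmed", "endnote")) {
  dialect <- match.arg(dialect)
  lines <- if (length(text) == 1L) {
    strsplit(text, "\r\n|\n|\r")[[1]]
  } else {
    # pre-split input: still strip any stray CR
    sub("\r$", "", text)
  }

  tag_re    <- "^([A-Z][A-Z0-9])  - ?(.*)$"
  sloppy_re <- paste0("^(", paste(.ris_known_tags, collapse = "|"),
                      ")\\s*-\\s")

  records <- list()
  fields <- list()      # accumulating tag -> character vector
  cur_tag <- NA_character_
  seen_any_tag <- FALSE
  tags_seen <- character()

  flush_record <- function(fields) {
    get1 <- function(tags) {
      for (t in tags) if (!is.null(fields[[t]])) {
        return(paste(fields[[t]], collapse = " "))
      }
      ""
    }
    abstract <- if (!is.null(fields[["AB"]])) {
      if (!is.null(fields[["N1"]])) {
        warning("record has both AB and N1; keeping AB", call. = FALSE)
      }
      paste(fields[["AB"]], collapse = " ")
    } else {
      get1("N1")
    }
    year_raw <- get1(c("PY", "Y1"))
    year <- stringr::str_extract(year_raw, "\\d{4}")
    as_chr <- function(x) if (is.null(x)) character() else as.character(x)
    new_ris_record(
      record_id = get1("AN"),
      ref_type  = get1("TY"),
      authors   = as_chr(c(fields[["AU"]], fields[["A1"]])),
      title     = get1(c("TI", "T1")),
      abstract  = abstract,
      year      = if (is.na(year)) "" else year,
      keywords  = as_chr(c(fields[["KW"]], fields[["DE"]]))
    )
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    m <- regmatches(line, regexec(tag_re, line))[[1]]
    if (length(m)) {
      tag <- m[[2]]
      value <- m[[3]]
      tags_seen <- c(tags_seen, tag)
      if (tag == "ER") {
        records[[length(records) + 1L]] <- flush_record(fields)
        fields <- list()
        cur_tag <- NA_character_
        next
      }
      cur_tag <- tag
      seen_any_tag <- TRUE
      if (tag %in% .ris_known_tags) {
        fields[[tag]] <- c(fields[[tag]], value)
      } else {
        fields[[tag]] <- NULL
      }
      next
    }
    if (!nzchar(trimws(line))) {
      cur_tag <- NA_character_
      next
    }
    if (is.na(cur_tag)) {
      if (grepl(sloppy_re, line)) {
        stop(sprintf("malformed RIS tag line %d: %s", i, line),
             call. = FALSE)
      }
      stop(sprintf("unexpected content outside any tag at line %d: %s",
                   i, line), call. = FALSE)
    }
    # continuation of the previous tag, joined by a single space
    if (cur_tag %in% .ris_known_tags) {
      v <- fields[[cur_tag]]
      v[length(v)] <- paste(v[length(v)], trimws(line))
      fields[[cur_tag]] <- v
    }
  }

  if (!length(records)) stop("empty record set", call. = FALSE)

  # synthesize ids, then enforce uniqueness
  ids <- vapply(records, `[[`, character(1), "record_id")
  missing <- !nzchar(ids)
  if (any(missing)) {
    warning(sprintf("%d record(s) lack an AN tag; synthesized ids",
                    sum(missing)), call. = FALSE)
    ids[missing] <- paste0("REC", which(missing))
    for (j in which(missing)) records[[j]]$record_id <- ids[[j]]
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }

  if (dialect == "auto") {
    endnoteish <- any(tags_seen %in% c("A1", "T1", "N1", "Y1"))
    pubmedish  <- any(tags_seen %in% c("AU", "TI", "AB", "PY"))
    dialect <- if (endnoteish && !pubmedish) {
      "endnote"
    } else if (pubmedish && !endnoteish) {
      "pubmed"
    } else {
      warning("ambiguous RIS dialect; assuming pubmed", call. = FALSE)
      "pubmed"
    }
  }
  new_record_set(records, source_dialect = dialect)
}

#' Read a RIS file
#' @param path Path to a UTF-8 RIS file.
#' @inheritParams parse_ris
#' @return A `record_set`, see [parse_ris()].
#' @export
read_ris <- function(path, dialect = c("auto", "pubmed", "endnote")) {
  txt <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parse_ris(txt, dialect = match.arg(dialect))
}

#' Serialise a record set back to RIS text
#'
#' The output uses the tag names of the set's source dialect (AU/TI/AB/
#' PY/KW for PubMed, A1/T1/N1/Y1/DE for EndNote), so a parse/write round
#' trip preserves every retained field. Empty fields are omitted rather
#' than written as blank tags; lines end with LF.
#'
#' @param records A `record_set`.
#' @return A single string of RIS text.
#' @export
write_ris <- function(records) {
  stopifnot(inherits(records, "record_set"))
  if (!n_records(records)) stop("empty record set", call. = FALSE)
  tags <- if (records$source_dialect == "endnote") {
    .ris_tags_endnote
  } else {
    .ris_tags_pubmed
  }
  fmt <- function(tag, values) {
    values <- values[nzchar(values)]
    if (!length(values)) return(character())
    sprintf("%s  - %s", tag, values)
  }
  blocks <- vapply(records$records, function(r) {
    paste(c(
      fmt("TY", r$ref_type),
      fmt("AN", r$record_id),
      fmt(tags[["author"]], r$authors),
      fmt(tags[["title"]], r$title),
      fmt(tags[["abstract"]], r$abstract),
      fmt(tags[["year"]], r$year),
      fmt(tags[["keyword"]], r$keywords),
      "ER  - "
    ), collapse = "\n")
  }, character(1))
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

#' Write a record set to a RIS file
#' @param records A `record_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ris_file <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(write_ris(records), con, sep = "", useBytes = TRUE)
  invisible(path)
}
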