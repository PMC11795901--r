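# CSV export of the frequency tables in two locale dialects.

#' CSV export dialect
#'
#' The western dialect matches the Western European CSV convention:
#' semicolon value separator, comma decimal separator, CRLF line
#' endings — the format spreadsheet software in a German/French locale
#' opens correctly by double-click. The standard dialect uses comma
#' separators with `.` decimals and LF.
#'
#' @param name `"western"` or `"standard"`.
#' @return A `csv_dialect` list with `field_separator`,
#'   `decimal_separator`, and `newline`.
#' @export
csv_dialect <- function(name = c("western", "standard")) {
  name <- match.arg(name)
  if (name == "western") {
    structure(list(name = name, field_separator = ";",
                   decimal_separator = ",", newline = "\r\n"),
              class = "csv_dialect")
  } else {
    structure(list(name = name, field_separator = ",",
                   decimal_separator = ".", newline = "\n"),
              class = "csv_dialect")
  }
}

# on-screen column names for export headers
.export_headers <- c(
  term = "Candidate terms",
  documents = "Documents",
  documents_pct = "Documents in %",
  z = "Z-Score",
  term_frequency = "Term frequency",
  keyword = "Keyword",
  frequency = "Frequency",
  record_id = "Record",
  field = "Field",
  left = "Left context",
  match = "Match",
  right = "Right context",
  first = "First word",
  second = "Second word",
  total = "Total"
)

format_cell <- function(x, dialect, digits = 4) {
  if (is.numeric(x) && !is.integer(x)) {
    # sentinels and whole numbers print without decimals; other reals
    # get fixed 4-decimal rendering in the dialect's decimal separator
    out <- ifelse(
      x == round(x),
      sprintf("%.0f", x),
      formatC(round(x, digits), format = "f", digits = digits,
              decimal.mark = dialect$decimal_separator)
    )
  } else if (is.logical(x)) {
    out <- ifelse(x, "TRUE", "FALSE")
  } else {
    out <- as.character(x)
  }
  needs_quote <- grepl(dialect$field_separator, out, fixed = TRUE) |
    grepl("\"", out, fixed = TRUE) | grepl("\n", out, fixed = TRUE)
  out[needs_quote] <- paste0(
    "\"", gsub("\"", "\"\"", out[needs_quote], fixed = TRUE), "\"")
  out
}

#' Export a frequency table as CSV
#'
#' Headers use the on-screen column names ("Candidate terms",
#' "Documents", "Documents in %", "Z-Score", "Term frequency", ...).
#' Real numbers are rendered with 4 decimal places in the dialect's
#' decimal separator; the 10000 sentinel prints as a plain integer.
#' Cells containing the field separator or quotes are quoted. The
#' `is_candidate` flag is a screen affordance and is not exported.
#'
#' @param rows A nonempty table from the analysis functions.
#' @param path Output path, or `""` to return the CSV text invisibly
#'   and print it to stdout.
#' @param dialect A [csv_dialect()].
#' @return The CSV text, invisibly.
#' @export
export_table <- function(rows, path = "",
                         dialect = csv_dialect("western")) {
  stopifnot(inherits(dialect, "csv_dialect"))
  if (!nrow(rows)) stop("refusing to export an empty table",
                        call. = FALSE)
  cols <- setdiff(names(rows), "is_candidate")
  headers <- vapply(cols, function(cl) {
    if (cl %in% names(.export_headers)) {
      .export_headers[[cl]]
    } else if (grepl("^skip_", cl)) {
      paste("Skip", sub("^skip_", "", cl))
    } else {
      cl
    }
  }, character(1))
  cells <- lapply(cols, function(cl) format_cell(rows[[cl]], dialect))
  body <- do.call(paste, c(cells, sep = dialect$field_separator))
  txt <- paste0(
    paste(c(paste(format_cell(headers, dialect),
                  collapse = dialect$field_separator), body),
          collapse = dialect$newline),
    dialect$newline)
  if (nzchar(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "", useBytes = TRUE)
  } else {
    cat(txt)
  }
  invisible(txt)
}

#' Re-read an exported CSV table
#'
#' Inverse of [export_table()] at the export precision (4 decimals):
#' re-parses the file under the same dialect with the internal column
#' names restored.
#'
#' @param path Path to a CSV written by [export_table()].
#' @param dialect The [csv_dialect()] it was written with.
#' @return A tibble.
#' @export
read_exported_table <- function(path, dialect = csv_dialect("western")) {
  df <- utils::read.table(
    path, header = TRUE, sep = dialect$field_separator,
    dec = dialect$decimal_separator, quote = "\"",
    check.names = FALSE, stringsAsFactors = FALSE,
    encoding = "UTF-8"
  )
  rev_map <- stats::setNames(names(.export_headers),
                             unname(.export_headers))
  nm <- names(df)
  known <- nm %in% names(rev_map)
  nm[known] <- rev_map[nm[known]]
  nm <- sub("^Skip ", "skip_", nm)
  names(df) <- nm
  tibble::as_tibble(df)
}
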