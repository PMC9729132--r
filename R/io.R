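#' Read a participant-by-item response matrix from CSV/TSV
#'
#' Reads a delimited file with a header row. The delimiter is sniffed from
#' the header line (tab wins over comma when present) unless given. A
#' non-numeric first column becomes the row identifier; otherwise rows are
#' identified by their 1-based index. Missing or non-numeric cells are
#' errors, reported with their row and column.
#'
#' @param path file path.
#' @param delimiter `","`, `"\t"` or `NULL` (sniff).
#' @return tibble whose first column `row_id` is character and whose
#'   remaining columns are numeric item responses.
#' @export
read_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  df <- readr::read_delim(
    path, delim = delimiter, col_types = readr::cols(.default = readr::col_guess()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(df) == 0L || nrow(df) == 0L) abort("Empty input file.")
  if (!is.numeric(df[[1L]])) {
    row_id <- as.character(df[[1L]])
    body <- df[-1L]
  } else {
    row_id <- as.character(seq_len(nrow(df)))
    body <- df
  }
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        abort(sprintf("Non-numeric cell at row %d, column '%s'.",
                      bad[1L], names(body)[j]))
      }
      body[[j]] <- num
    }
    if (anyNA(body[[j]])) {
      abort(sprintf("Missing value at row %d, column '%s'; missing data are not supported.",
                    which(is.na(body[[j]]))[1L], names(body)[j]))
    }
  }
  dplyr::bind_cols(tibble(row_id = row_id), body)
}

#' Write a split assignment to CSV
#'
#' Writes one line per participant with columns `row_id, subsample`
#' (1-based labels), preserving the input row order. With
#' `augmented = TRUE` and the original data supplied, the assignment column
#' is prepended to the item responses instead.
#'
#' @param split a `split_assignment`.
#' @param path output CSV path.
#' @param data optional original data for `augmented` output.
#' @param augmented prepend the assignment to the original columns.
#' @return the written tibble, invisibly.
#' @export
write_assignment <- function(split, path, data = NULL, augmented = FALSE) {
  if (!all(c("row_id", "subsample") %in% names(split))) {
    abort("`split` must have columns `row_id` and `subsample`.")
  }
  out <- tibble(row_id = as.character(split$row_id),
                subsample = as.integer(split$subsample))
  if (isTRUE(augmented)) {
    if (is.null(data)) abort("`augmented = TRUE` needs the original `data`.")
    rm_ <- as_response_matrix(data)
    if (nrow(rm_$values) != nrow(out)) {
      abort("`data` and `split` have different numbers of rows.")
    }
    out <- dplyr::bind_cols(out, as_tibble(as.data.frame(rm_$values)))
  }
  readr::write_csv(out, path)
  invisible(out)
}

#' Write an adequacy report as JSON
#'
#' @param report an `adequacy_report` from [assess_split()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_adequacy_report <- function(report, path) {
  if (!inherits(report, "adequacy_report")) {
    abort("`report` must be an adequacy_report.")
  }
  jsonlite::write_json(
    list(kmo_total = report$kmo_total, kmo_1 = report$kmo_1,
         kmo_2 = report$kmo_2, s = report$s,
         n_1 = report$n_1, n_2 = report$n_2, m = report$m),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
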