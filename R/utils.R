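# Internal coercion and validation shared by the splitters and adequacy code.
#
# User-facing functions accept a data frame (tibble) of item responses, an
# optional identifier column, or a bare numeric matrix.  Internally everything
# runs on a numeric matrix with a parallel vector of row identifiers.

#' Coerce participant-by-item input to a numeric matrix with row ids
#'
#' @param data data frame or numeric matrix, rows = participants, columns =
#'   items. A non-numeric first column of a data frame is taken as the row
#'   identifier; otherwise identifiers default to the 1-based row index.
#' @param min_rows minimal number of rows required.
#' @return list with `values` (numeric matrix) and `row_ids` (character).
#' @keywords internal
#' @noRd
as_response_matrix <- function(data, min_rows = 1L) {
  if (is.matrix(data)) {
    if (!is.numeric(data)) {
      abort("`data` matrix must be numeric.")
    }
    values <- data
    row_ids <- rownames(data) %||% as.character(seq_len(nrow(data)))
  } else if (is.data.frame(data)) {
    if (ncol(data) == 0L) abort("`data` has no columns.")
    first <- data[[1L]]
    if (!is.numeric(first)) {
      row_ids <- as.character(first)
      body <- data[-1L]
    } else {
      row_ids <- as.character(seq_len(nrow(data)))
      body <- data
    }
    bad <- names(body)[!vapply(body, is.numeric, logical(1))]
    if (length(bad)) {
      abort(paste0(
        "All item columns must be numeric; offending column(s): ",
        paste(bad, collapse = ", "), "."
      ))
    }
    if (anyNA(body)) {
      abort("Missing values are not supported; remove or impute them first.")
    }
    values <- as.matrix(body)
  } else {
    abort("`data` must be a data frame or a numeric matrix.")
  }
  if (anyNA(values)) {
    abort("Missing values are not supported; remove or impute them first.")
  }
  if (nrow(values) < min_rows) {
    abort(sprintf("`data` needs at least %d rows; got %d.", min_rows, nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  list(values = values, row_ids = row_ids)
}

# Error (naming columns) if any column is constant.
check_nonzero_variance <- function(values) {
  v <- apply(values, 2L, stats::var)
  bad <- colnames(values)[v <= 0 | !is.finite(v)]
  if (length(bad)) {
    abort(paste0(
      "Zero-variance column(s): ", paste(bad, collapse = ", "),
      "; correlations are undefined."
    ))
  }
  invisible(TRUE)
}

check_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer.", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %d.", name, min))
  as.integer(x)
}
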