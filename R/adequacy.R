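#' Pearson correlation matrix of item responses
#'
#' Computes the product-moment correlation between all pairs of item columns.
#' This is the matrix factor analysis operates on in the linear factor model,
#' and the input to [kmo()].
#'
#' @param data data frame or numeric matrix of item responses (rows =
#'   participants). A non-numeric first column is treated as a row identifier.
#' @return symmetric numeric matrix with unit diagonal.
#' @examples
#' x <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = c(2, 1, 4, 3, 6, 5))
#' pearson_correlation(x)
#' @export
pearson_correlation <- function(data) {
  rm_ <- as_response_matrix(data, min_rows = 3L)
  if (ncol(rm_$values) < 2L) abort("Need at least 2 item columns.")
  check_nonzero_variance(rm_$values)
  r <- stats::cor(rm_$values)
  # guard against fp drift outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' The overall KMO statistic compares the squared correlations between items
#' with the squared anti-image partial correlations (each pair partialled on
#' all remaining items):
#' \deqn{KMO = \frac{\sum_{j \ne k} r_{jk}^2}{\sum_{j \ne k} r_{jk}^2 +
#'   \sum_{j \ne k} p_{jk}^2}}
#' where \eqn{p_{jk} = -q_{jk} / \sqrt{q_{jj} q_{kk}}} and \eqn{Q = R^{-1}}.
#' Values near 1 indicate abundant common variance (a matrix worth factor
#' analyzing); values near 0 indicate that partial correlations dominate.
#'
#' Near-singular correlation matrices (possible when the number of rows is
#' close to the number of items) are stabilized with a ridge of
#' `1e-10 * trace(R)` on the diagonal before inversion, with a warning; if the
#' condition number still exceeds `1e12` an error is raised.
#'
#' @param x correlation matrix, or raw response data (data frame / numeric
#'   matrix), in which case the Pearson correlation is computed first.
#' @return a single number in `[0, 1]`.
#' @examples
#' r <- matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3, 3)
#' kmo(r) # 0.6923 for the 3x3 equicorrelated matrix with rho = .5
#' @export
kmo <- function(x) {
  r <- as_correlation(x)
  m <- ncol(r)
  off <- upper.tri(r)
  ssr <- sum(r[off]^2)
  if (ssr == 0) {
    abort("KMO is undefined for an identity correlation matrix (no correlations).")
  }
  q <- invert_correlation(r)
  d <- sqrt(diag(q))
  p <- -q / tcrossprod(d)
  ssp <- sum(p[off]^2)
  ssr / (ssr + ssp)
}

# Accept either a correlation matrix or raw data.
as_correlation <- function(x) {
  if (is.matrix(x) && nrow(x) == ncol(x) &&
      all(abs(diag(x) - 1) < 1e-8) && max(abs(x - t(x))) < 1e-8 &&
      all(abs(x) <= 1 + 1e-8)) {
    if (ncol(x) < 2L) abort("Correlation matrix must be at least 2x2.")
    return((x + t(x)) / 2)
  }
  pearson_correlation(x)
}

# Ridge-stabilized inverse; errors if hopelessly singular.
invert_correlation <- function(r) {
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  cond <- ev[1L] / max(ev[length(ev)], .Machine$double.eps)
  if (ev[length(ev)] <= 0 || cond > 1e12) {
    ridge <- 1e-10 * sum(diag(r))
    r <- r + diag(ridge, ncol(r))
    warn(sprintf(
      "Correlation matrix is near-singular; ridge %.3g added before inversion.",
      ridge
    ))
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    cond <- ev[1L] / max(ev[length(ev)], .Machine$double.eps)
    if (ev[length(ev)] <= 0 || cond > 1e12) {
      abort("Correlation matrix is singular beyond ridge tolerance; cannot compute KMO.")
    }
  }
  solve(r)
}

#' Communality Ratio between two subsamples
#'
#' The Communality Ratio S scores how equivalent two subsamples are in terms
#' of common variance, as the ratio of their KMO sampling-adequacy values:
#' \deqn{S = \min(KMO_1, KMO_2) / \max(KMO_1, KMO_2)}
#' S is 1 when the subsamples are equivalent and approaches 0 when one
#' subsample carries only error variance.
#'
#' @param kmo_1,kmo_2 KMO values of the two subsamples, each in `[0, 1]`.
#' @return a single number in `(0, 1]`.
#' @examples
#' communality_ratio(0.8594, 0.8615) # 0.9975...
#' @export
communality_ratio <- function(kmo_1, kmo_2) {
  if (!is.numeric(kmo_1) || !is.numeric(kmo_2) ||
      length(kmo_1) != 1L || length(kmo_2) != 1L) {
    abort("`kmo_1` and `kmo_2` must be single numbers.")
  }
  if (is.na(kmo_1) || is.na(kmo_2) ||
      kmo_1 < 0 || kmo_1 > 1 || kmo_2 < 0 || kmo_2 > 1) {
    abort("KMO values must lie in [0, 1].")
  }
  hi <- max(kmo_1, kmo_2)
  if (hi == 0) abort("Both KMO values are zero; the ratio is undefined.")
  min(kmo_1, kmo_2) / hi
}

#' Assess the equivalence of a two-way split
#'
#' Computes the Pearson correlation matrix and KMO within each of the two
#' subsamples defined by `split`, then the Communality Ratio S between them.
#'
#' @param data the full response data the split was computed on.
#' @param split a two-way split: an object returned by [solomon_split()],
#'   [duplex_split()], [random_split()] or [stratified_split()], or any data
#'   frame with columns `row_id` and `subsample`, or a plain integer vector of
#'   labels in `{1, 2}` aligned with the rows of `data`.
#' @return an object of class `adequacy_report`: a list with elements
#'   `kmo_total`, `kmo_1`, `kmo_2`, `s`, `n_1`, `n_2`, `m`. Use [tidy()] /
#'   [glance()] for tibble views; `s` is reported at full precision and
#'   printed to 4 decimals.
#' @examples
#' set.seed(1)
#' x <- as.data.frame(matrix(rnorm(100 * 6), 100, 6))
#' sp <- solomon_split(x)
#' assess_split(x, sp)
#' @export
assess_split <- function(data, split) {
  rm_ <- as_response_matrix(data, min_rows = 6L)
  labels <- split_labels(split, nrow(rm_$values))
  if (!setequal(unique(labels), c(1L, 2L))) {
    abort("`split` must be a two-way partition with labels 1 and 2.")
  }
  n1 <- sum(labels == 1L)
  n2 <- sum(labels == 2L)
  m <- ncol(rm_$values)
  if (min(n1, n2) < 3L) {
    abort("Each subsample needs at least 3 rows to compute correlations.")
  }
  if (min(n1, n2) <= m) {
    warn(sprintf(
      "A subsample has n = %d <= m = %d items; KMO may be unstable.",
      min(n1, n2), m
    ))
  }
  k1 <- kmo(pearson_correlation(rm_$values[labels == 1L, , drop = FALSE]))
  k2 <- kmo(pearson_correlation(rm_$values[labels == 2L, , drop = FALSE]))
  structure(
    list(
      kmo_total = kmo(pearson_correlation(rm_$values)),
      kmo_1 = k1,
      kmo_2 = k2,
      s = communality_ratio(k1, k2),
      n_1 = n1,
      n_2 = n2,
      m = m
    ),
    class = "adequacy_report"
  )
}

# Extract integer labels from the accepted split representations.
split_labels <- function(split, n) {
  if (inherits(split, "split_assignment") || is.data.frame(split)) {
    if (!all(c("row_id", "subsample") %in% names(split))) {
      abort("A split data frame needs columns `row_id` and `subsample`.")
    }
    labels <- as.integer(split$subsample)
  } else if (is.numeric(split)) {
    labels <- as.integer(split)
  } else {
    abort("`split` must be a split_assignment, a data frame, or an integer vector.")
  }
  if (length(labels) != n) {
    abort(sprintf("Split has %d labels but `data` has %d rows.", length(labels), n))
  }
  labels
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat("Split adequacy report\n")
  cat(sprintf("  subsample sizes : %d / %d (m = %d items)\n", x$n_1, x$n_2, x$m))
  cat(sprintf("  KMO total       : %.4f\n", x$kmo_total))
  cat(sprintf("  KMO subsamples  : %.4f / %.4f\n", x$kmo_1, x$kmo_2))
  cat(sprintf("  Communality S   : %.4f\n", x$s))
  invisible(x)
}

#' @rdname assess_split
#' @param x an `adequacy_report`.
#' @param ... unused.
#' @method tidy adequacy_report
#' @export
tidy.adequacy_report <- function(x, ...) {
  tibble(
    subsample = c(1L, 2L),
    n = c(x$n_1, x$n_2),
    kmo = c(x$kmo_1, x$kmo_2)
  )
}

#' @rdname assess_split
#' @method glance adequacy_report
#' @export
glance.adequacy_report <- function(x, ...) {
  tibble(
    kmo_total = x$kmo_total, kmo_1 = x$kmo_1, kmo_2 = x$kmo_2,
    s = x$s, n_1 = x$n_1, n_2 = x$n_2, m = x$m
  )
}
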