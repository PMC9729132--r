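#' Dimensionality bound from Kaiser's eigenvalue rule
#'
#' Counts the eigenvalues of the correlation matrix that exceed 1 (Kaiser's
#' rule), then clamps the count to the interval `[2, m - 1]`. The rule is
#' known to overestimate the number of interpretable factors, which is exactly
#' why it works as a conservative upper bound on the dimensionality used to
#' order participants before splitting: it keeps every source of common
#' variance without using all m item dimensions. At least two dimensions are
#' always retained so that the ordering never collapses onto a single axis.
#'
#' @param x correlation matrix, or raw response data.
#' @return integer Q with `2 <= Q <= m - 1`.
#' @examples
#' kaiser_dimensionality(diag(5)) # floor of 2 applies
#' @export
kaiser_dimensionality <- function(x) {
  r <- as_correlation(x)
  m <- ncol(r)
  if (m < 3L) {
    abort("Need at least 3 items for a dimensionality in [2, m - 1].")
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  q <- max(2L, sum(ev > 1))
  as.integer(min(q, m - 1L))
}

#' Principal-component projections of participants
#'
#' Standardizes each item column to z-scores, eigendecomposes the Pearson
#' correlation matrix, and projects every participant onto the first `q` unit
#' eigenvectors: `c_ij = z_i . v_j`. The projection on component j has
#' variance equal to the j-th eigenvalue; the weight `w_j = lambda_j / m` is
#' the proportion of total variance the component accounts for.
#'
#' Eigenvector signs are indeterminate in any eigendecomposition; they are
#' fixed deterministically so that each eigenvector's largest-magnitude
#' loading is positive (ties resolved toward the lowest item index), making
#' projections reproducible across linear-algebra backends.
#'
#' @param data data frame or numeric matrix of item responses.
#' @param q number of components to retain (`2 <= q <= m - 1`), or `"auto"`
#'   to use [kaiser_dimensionality()].
#' @return object of class `component_model`: list with `eigenvalues` (all m,
#'   descending), `eigenvectors` (m x m, sign-fixed unit columns), `q`,
#'   `weights` (`lambda/m` for the q retained components), `scores`
#'   (n x q projection matrix) and `row_ids`.
#' @examples
#' set.seed(42)
#' x <- as.data.frame(matrix(rnorm(50 * 4), 50, 4))
#' cm <- component_scores(x, q = 2)
#' head(cm$scores)
#' @export
component_scores <- function(data, q = "auto") {
  rm_ <- as_response_matrix(data, min_rows = 3L)
  check_nonzero_variance(rm_$values)
  m <- ncol(rm_$values)
  r <- pearson_correlation(rm_$values)
  if (identical(q, "auto")) {
    q <- kaiser_dimensionality(r)
  } else {
    q <- check_scalar_int(q, "q", min = 2L)
    if (q > m - 1L) abort(sprintf("`q` must be <= m - 1 = %d.", m - 1L))
  }
  eg <- eigen(r, symmetric = TRUE)
  vecs <- fix_eigenvector_signs(eg$vectors)
  z <- scale(rm_$values, center = TRUE, scale = TRUE)
  scores <- z %*% vecs[, seq_len(q), drop = FALSE]
  structure(
    list(
      eigenvalues = eg$values,
      eigenvectors = vecs,
      q = q,
      weights = eg$values[seq_len(q)] / m,
      scores = unname(scores),
      row_ids = rm_$row_ids
    ),
    class = "component_model"
  )
}

# Flip each column so its largest-|loading| entry is positive; ties go to the
# lowest row index.
fix_eigenvector_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf(
    "Principal-component model: %d of %d components retained\n",
    x$q, length(x$eigenvalues)
  ))
  cat("  eigenvalues :", paste(sprintf("%.3f", head(x$eigenvalues, 6L)),
                               collapse = " "),
      if (length(x$eigenvalues) > 6L) "..." else "", "\n")
  cat("  weights     :", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @rdname component_scores
#' @param x a `component_model`.
#' @param ... unused.
#' @method tidy component_model
#' @export
tidy.component_model <- function(x, ...) {
  m <- length(x$eigenvalues)
  tibble(
    component = seq_len(m),
    eigenvalue = x$eigenvalues,
    prop_variance = x$eigenvalues / m,
    retained = seq_len(m) <= x$q
  )
}

#' @rdname component_scores
#' @method glance component_model
#' @export
glance.component_model <- function(x, ...) {
  tibble(
    m = length(x$eigenvalues),
    q = x$q,
    variance_retained = sum(x$weights)
  )
}

#' Variance-weighted composite of component projections
#'
#' Collapses a participant's q component projections into the single ordering
#' value \eqn{d_i = \sum_{j=1}^{Q} w_j c_{ij}}, where `w_j` is the proportion
#' of variance accounted for by component j. The composite describes each
#' participant's position in the reduced component space with one number;
#' participants far apart in the sorted list of d are far apart in the cloud.
#'
#' @param scores n x q matrix (or data frame) of component projections, or a
#'   `component_model`, in which case its scores and weights are used.
#' @param weights length-q positive weights; ignored when `scores` is a
#'   `component_model`.
#' @return numeric vector of length n.
#' @examples
#' composite(rbind(c(2.617, 1.140), c(2.065, 1.094)), c(0.411, 0.175))
#' @export
composite <- function(scores, weights = NULL) {
  if (inherits(scores, "component_model")) {
    weights <- weights %||% scores$weights
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) abort("`scores` must be numeric.")
  if (is.null(weights)) abort("`weights` is required when `scores` is a matrix.")
  if (length(weights) != ncol(scores)) {
    abort(sprintf(
      "Dimension mismatch: %d weights for %d score columns.",
      length(weights), ncol(scores)
    ))
  }
  if (any(weights <= 0)) abort("`weights` must be strictly positive.")
  drop(scores %*% weights)
}
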