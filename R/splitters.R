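# Splitters: Solomon, Duplex, random, and the stratified wrapper.
#
# Every splitter returns a `split_assignment`: a tibble with one row per
# participant (columns `row_id`, `subsample`), in the input row order, plus
# attributes recording how the split was produced.

new_split_assignment <- function(row_ids, labels, method, k, extra = list()) {
  out <- tibble(row_id = row_ids, subsample = as.integer(labels))
  attr(out, "method") <- method
  attr(out, "k") <- as.integer(k)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("split_assignment", class(out))
  out
}

#' @method tidy split_assignment
#' @export
tidy.split_assignment <- function(x, ...) {
  new_tibble(as.data.frame(x))
}

#' @method glance split_assignment
#' @export
glance.split_assignment <- function(x, ...) {
  sizes <- tabulate(x$subsample, nbins = attr(x, "k"))
  tibble(
    method = attr(x, "method"),
    k = attr(x, "k"),
    n = nrow(x),
    size_min = min(sizes),
    size_max = max(sizes)
  )
}

#' @method autoplot split_assignment
#' @export
autoplot.split_assignment <- function(object, ...) {
  d <- attr(object, "d")
  if (!is.null(d)) {
    df <- tibble(
      rank = rank(-d, ties.method = "first"),
      d = d,
      subsample = factor(object$subsample)
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$d,
                                     colour = .data$subsample)) +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "rank by composite d", y = "weighted composite d",
        colour = "subsample",
        title = "Alternating assignment along the composite ordering"
      )
  } else {
    df <- dplyr::count(as_tibble(object), .data$subsample)
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$subsample), y = .data$n)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "subsample", y = "participants",
                    title = paste(attr(object, "method"), "split sizes"))
  }
}

#' Solomon split: equivalent subsamples via a component-score ordering
#'
#' Orders participants by the variance-weighted composite `d` of their
#' principal-component projections (see [component_scores()] and
#' [composite()]) and deals them out cyclically: with `k = 2`, the 1st,
#' 3rd, 5th, ... participants in the ordering go to subsample 1 and the rest
#' to subsample 2. Because neighbours in the ordering are the most similar
#' participants, each subsample receives the same spread of response
#' patterns and the two correlation matrices carry near-identical common
#' variance. The procedure is fully deterministic: no randomness is involved,
#' and ties in `d` are broken by the original row order.
#'
#' With odd `n` the leftover participant (an odd position in the ordering)
#' goes to subsample 1. For `k > 2`: an odd `k` deals consecutive k-tuples of
#' the ordering across the k subsamples; an even `k` splits in half and then
#' splits each half again, recursively.
#'
#' @param data data frame or numeric matrix of item responses. A non-numeric
#'   first column is used as the row identifier.
#' @param q number of components for the ordering, or `"auto"` (default) for
#'   Kaiser's eigenvalue-greater-than-one count, clamped to `[2, m - 1]`.
#' @param k number of subsamples (default 2).
#' @return a `split_assignment` tibble (`row_id`, `subsample`) with the
#'   composite `d` attached as attribute `"d"`.
#' @examples
#' set.seed(7)
#' x <- as.data.frame(matrix(rnorm(60 * 5), 60, 5))
#' sp <- solomon_split(x)
#' table(sp$subsample)
#' @export
solomon_split <- function(data, q = "auto", k = 2L) {
  k <- check_scalar_int(k, "k", min = 2L)
  rm_ <- as_response_matrix(data, min_rows = 2L * k)
  cm <- component_scores(rm_$values, q = q)
  d <- composite(cm)
  labels <- solomon_assign(d, k = k)
  new_split_assignment(
    rm_$row_ids, labels, "solomon", k,
    extra = list(d = d, q = cm$q, weights = cm$weights,
                 eigenvalues = cm$eigenvalues)
  )
}

#' Alternating assignment along a composite ordering
#'
#' The assignment stage of the Solomon method, usable on its own when the
#' composite values `d` are already available: sorts `d` in descending order
#' (ties broken by original position) and assigns sorted positions
#' 1, 2, ..., k, 1, 2, ... cyclically for `k = 2` or odd `k`; even `k > 2`
#' is handled by recursive halving.
#'
#' @param d numeric vector of composite ordering values.
#' @param k number of subsamples.
#' @return integer vector of labels in `{1..k}`, aligned with `d`.
#' @examples
#' solomon_assign(c(1.276, 1.041, 0.869, 0.616, -0.043, -0.260, -0.823))
#' @export
solomon_assign <- function(d, k = 2L) {
  k <- check_scalar_int(k, "k", min = 2L)
  n <- length(d)
  if (n < 2L * k) abort(sprintf("Need at least 2k = %d observations.", 2L * k))
  ord <- order(-d, seq_along(d)) # descending d, stable in original order
  labels <- integer(n)
  if (k == 2L || k %% 2L == 1L) {
    labels[ord] <- rep_len(seq_len(k), n)
  } else {
    # even k > 2: halve, then split each half again
    half <- integer(n)
    half[ord] <- rep_len(1:2, n)
    for (h in 1:2) {
      idx <- which(half == h)
      sub <- solomon_assign(d[idx], k = k %/% 2L)
      labels[idx] <- sub + (h - 1L) * (k %/% 2L)
    }
  }
  labels
}

#' Duplex split: max-min Euclidean distance subset selection
#'
#' The Duplex method (Snee's refinement of Kennard-Stone selection) builds
#' two subsamples that each cover the full m-dimensional response space.
#' The two participants farthest apart (Euclidean distance over the raw item
#' responses) seed subsample 1; the farthest pair among the remainder seeds
#' subsample 2; thereafter the subsamples alternate, each receiving the
#' unassigned participant whose minimum distance to that subsample's current
#' members is largest. With odd `n` the final participant joins whichever
#' subsample's turn is next.
#'
#' All ties (frequent with discrete Likert responses) are broken
#' deterministically in favour of the lowest row index, and a degeneracy
#' warning is emitted when ties occurred, so the method always completes.
#'
#' @param data data frame or numeric matrix of item responses.
#' @param scale if `TRUE`, z-score the items before computing distances
#'   (default `FALSE`: raw responses, the conventional choice).
#' @return a `split_assignment` tibble (`row_id`, `subsample`).
#' @examples
#' x <- data.frame(v = c(0, 1, 2, 3))
#' duplex_split(x)$subsample # farthest pair {0, 3} seeds subsample 1
#' @export
duplex_split <- function(data, scale = FALSE) {
  rm_ <- as_response_matrix(data, min_rows = 4L)
  x <- rm_$values
  if (isTRUE(scale)) x <- base::scale(x)
  n <- nrow(x)
  dm <- as.matrix(stats::dist(x))
  ties <- 0L

  pick_pair <- function(active) {
    sub <- dm[active, active, drop = FALSE]
    mask <- upper.tri(sub)
    mx <- max(sub[mask])
    hits <- which(mask & sub == mx, arr.ind = TRUE)
    # lowest row index first, then lowest column index
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    if (nrow(hits) > 1L) ties <<- ties + 1L
    active[hits[1L, ]]
  }

  assigned <- integer(n)
  remaining <- seq_len(n)
  p1 <- pick_pair(remaining)
  assigned[p1] <- 1L
  remaining <- setdiff(remaining, p1)
  p2 <- pick_pair(remaining)
  assigned[p2] <- 2L
  remaining <- setdiff(remaining, p2)

  # min distance from every point to each subsample's current members
  mind <- list(
    pmin(dm[, p1[1L]], dm[, p1[2L]]),
    pmin(dm[, p2[1L]], dm[, p2[2L]])
  )
  turn <- 1L
  while (length(remaining)) {
    cand <- mind[[turn]][remaining]
    best <- remaining[which.max(cand)] # first max = lowest row index
    if (sum(cand == max(cand)) > 1L) ties <- ties + 1L
    assigned[best] <- turn
    remaining <- remaining[remaining != best]
    mind[[turn]] <- pmin(mind[[turn]], dm[, best])
    turn <- 3L - turn
  }
  if (ties > 0L) {
    warn(sprintf(
      "Duplex encountered %d exact distance tie(s); resolved by lowest row index.",
      ties
    ))
  }
  new_split_assignment(rm_$row_ids, assigned, "duplex", 2L)
}

#' Random split
#'
#' Splits the sample by a uniform random permutation: the first
#' `ceiling(n/2)` rows of the shuffled order form subsample 1. The baseline
#' every representative splitter is compared against.
#'
#' @param data data frame or numeric matrix of item responses.
#' @param seed integer seed for reproducibility; `NULL` uses the session RNG
#'   state.
#' @return a `split_assignment` tibble (`row_id`, `subsample`).
#' @examples
#' random_split(data.frame(v = 1:11), seed = 1)
#' @export
random_split <- function(data, seed = NULL) {
  rm_ <- as_response_matrix(data, min_rows = 2L)
  n <- nrow(rm_$values)
  perm <- if (is.null(seed)) {
    sample.int(n)
  } else {
    withr::with_seed(as.integer(seed), sample.int(n))
  }
  labels <- integer(n)
  labels[perm] <- rep(c(1L, 2L), c(ceiling(n / 2), floor(n / 2)))
  new_split_assignment(rm_$row_ids, labels, "random", 2L)
}

#' Stratified split: balance a covariate across subsamples
#'
#' Applies a splitter within each stratum of a categorical covariate (e.g.
#' gender) and merges the per-stratum subsamples, so that the covariate's
#' proportions are preserved in both halves: stratum-level subsample 1's are
#' pooled into global subsample 1, and likewise for subsample 2.
#'
#' @param data data frame or numeric matrix of item responses. The stratum
#'   column itself must not be among the item columns; pass it via `strata`.
#' @param strata per-row category labels (vector of length `nrow(data)`), or
#'   the name of a column of `data` holding them (that column is then dropped
#'   from the items).
#' @param method `"solomon"`, `"duplex"` or `"random"`, or a function
#'   `f(data, ...)` returning a `split_assignment`.
#' @param ... passed to the splitter (e.g. `q`, `seed`).
#' @return a `split_assignment` tibble (`row_id`, `subsample`) in the input
#'   row order.
#' @examples
#' set.seed(3)
#' x <- as.data.frame(matrix(rnorm(36 * 4), 36, 4))
#' g <- rep(c("F", "M"), c(20, 16))
#' sp <- stratified_split(x, g, method = "solomon")
#' table(g, sp$subsample) # halved within each stratum
#' @export
stratified_split <- function(data, strata, method = "solomon", ...) {
  if (is.character(strata) && length(strata) == 1L && is.data.frame(data) &&
      strata %in% names(data)) {
    strata_values <- data[[strata]]
    data <- data[setdiff(names(data), strata)]
  } else {
    strata_values <- strata
  }
  rm_ <- as_response_matrix(data, min_rows = 4L)
  n <- nrow(rm_$values)
  if (length(strata_values) != n) {
    abort(sprintf("`strata` has %d values but `data` has %d rows.",
                  length(strata_values), n))
  }
  splitter <- if (is.function(method)) {
    method
  } else {
    switch(match.arg(method, c("solomon", "duplex", "random")),
      solomon = solomon_split, duplex = duplex_split, random = random_split
    )
  }
  labels <- integer(n)
  for (s in unique(strata_values)) {
    idx <- which(strata_values == s)
    if (length(idx) < 2L) {
      abort(sprintf("Stratum '%s' has fewer than 2 rows; cannot split it.", s))
    }
    sub <- splitter(rm_$values[idx, , drop = FALSE], ...)
    labels[idx] <- sub$subsample
  }
  new_split_assignment(rm_$row_ids, labels, "stratified", 2L,
                       extra = list(strata = strata_values))
}
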