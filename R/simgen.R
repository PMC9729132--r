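# Monte-Carlo generators: orthogonal-factor population models, multivariate
# normal samples with a target correlation structure, and 5-point
# categorization with configurable response-style thresholds.

#' Categorization thresholds for the two response styles
#'
#' Cumulative proportions (converted to standard-normal quantiles at
#' categorization time) defining the 5-point response formats used in the
#' simulations: `normal` spreads responses symmetrically
#' (expected category frequencies .05/.21/.48/.21/.05), `extreme`
#' concentrates about 75% of responses in the top category, mimicking the
#' skewed item distributions of extreme responders.
#' @format named list of two length-4 numeric vectors.
#' @export
response_thresholds <- list(
  normal  = c(0.05, 0.26, 0.74, 0.95),
  extreme = c(0.05, 0.10, 0.15, 0.25)
)

# Clip negative eigenvalues to 1e-10, reconstruct, rescale to unit diagonal.
# Records the largest entrywise change as attribute "repair_delta".
repair_correlation <- function(sigma) {
  eg <- eigen(sigma, symmetric = TRUE)
  if (min(eg$values) >= 1e-10) {
    attr(sigma, "repair_delta") <- 0
    return(sigma)
  }
  ev <- pmax(eg$values, 1e-10)
  rep_ <- eg$vectors %*% (ev * t(eg$vectors))
  d <- sqrt(diag(rep_))
  rep_ <- rep_ / tcrossprod(d)
  diag(rep_) <- 1
  attr(rep_, "repair_delta") <- max(abs(rep_ - sigma))
  rep_
}

new_population_model <- function(loadings, thresholds = NULL) {
  pop_corr <- tcrossprod(loadings)
  diag(pop_corr) <- 1
  pop_corr <- repair_correlation(pop_corr)
  structure(
    list(
      loadings = loadings,
      pop_corr = pop_corr,
      thresholds = thresholds,
      r = ncol(loadings),
      m = nrow(loadings)
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "Orthogonal factor population model: %d variables, %d factors\n", x$m, x$r
  ))
  cat(sprintf("  salient loadings in [%.2f, %.2f]\n",
              min(abs(x$loadings)[abs(x$loadings) > 0.15]),
              max(abs(x$loadings))))
  if (!is.null(x$thresholds)) {
    cat("  categorization thresholds:", paste(x$thresholds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Population model for the large sample-size sweep
#'
#' Builds an orthogonal 5-factor population loading matrix with 20 variables
#' per factor (100 variables): each variable loads on its own factor with a
#' salient loading drawn uniformly from `[.40, .45]` and on every other
#' factor with a non-salient loading drawn uniformly from `[-.10, .10]`.
#' The implied population correlation is the loading cross-product with unit
#' diagonal (repaired to positive semidefinite if needed).
#'
#' @param seed integer seed; the model is fully reproducible from it.
#' @return a `population_model` (loadings, `pop_corr`, factor/variable
#'   counts).
#' @examples
#' m <- make_loadings_study1(seed = 1)
#' dim(m$loadings)
#' @export
make_loadings_study1 <- function(seed) {
  seed <- check_scalar_int(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    r <- 5L
    per <- 20L
    m <- r * per
    lambda <- matrix(stats::runif(m * r, -0.10, 0.10), m, r)
    for (f in seq_len(r)) {
      rows <- ((f - 1L) * per + 1L):(f * per)
      lambda[rows, f] <- stats::runif(per, 0.40, 0.45)
    }
    new_population_model(lambda)
  })
}

#' Simulation condition for the factorial method-comparison study
#'
#' Validates and bundles one cell of the factorial design crossing
#' communality level, number of factors, variables per factor, sample size
#' and response style. The design is deliberately not fully crossed:
#' conditions with `n = 100` and 60 or 90 variables are rejected because a
#' 50-participant subsample with that many items is unrealistic in applied
#' factor analysis.
#'
#' @param communality `"large"` (salient loadings U\[.55, .88\]) or `"wide"`
#'   (U\[.20, .88\]).
#' @param r number of factors: 1, 2 or 3.
#' @param vars_per_factor variables per factor: 10, 20 or 30.
#' @param n sample size: 100, 200, 400, 800 or 1600.
#' @param response_style `"normal"` or `"extreme"` (see
#'   [response_thresholds]).
#' @return a `sim_condition` list.
#' @examples
#' sim_condition("large", r = 2, vars_per_factor = 10, n = 400, "normal")
#' @export
sim_condition <- function(communality = c("large", "wide"),
                          r, vars_per_factor, n,
                          response_style = c("normal", "extreme")) {
  communality <- match.arg(communality)
  response_style <- match.arg(response_style)
  r <- check_scalar_int(r, "r", min = 1L)
  vars_per_factor <- check_scalar_int(vars_per_factor, "vars_per_factor", min = 2L)
  n <- check_scalar_int(n, "n", min = 4L)
  if (!r %in% 1:3) abort("`r` must be 1, 2 or 3.")
  if (!vars_per_factor %in% c(10L, 20L, 30L)) {
    abort("`vars_per_factor` must be 10, 20 or 30.")
  }
  if (!n %in% c(100L, 200L, 400L, 800L, 1600L)) {
    abort("`n` must be one of 100, 200, 400, 800, 1600.")
  }
  m <- r * vars_per_factor
  if (n == 100L && m >= 60L) {
    abort(sprintf(
      "Excluded design cell: n = 100 with m = %d variables (subsamples of 50 participants would have fewer rows than items).",
      m
    ))
  }
  structure(
    list(communality = communality, r = r, vars_per_factor = vars_per_factor,
         m = m, n = n, response_style = response_style),
    class = "sim_condition"
  )
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf(
    "Condition: communality %s, r = %d, m/r = %d (m = %d), n = %d, %s responding\n",
    x$communality, x$r, x$vars_per_factor, x$m, x$n, x$response_style
  ))
  invisible(x)
}

#' All non-excluded cells of the factorial design
#'
#' @return list of `sim_condition` objects (168 cells).
#' @export
all_sim_conditions <- function() {
  grid <- expand.grid(
    communality = c("large", "wide"), r = 1:3,
    vars_per_factor = c(10L, 20L, 30L),
    n = c(100L, 200L, 400L, 800L, 1600L),
    response_style = c("normal", "extreme"),
    stringsAsFactors = FALSE
  )
  keep <- !(grid$n == 100L & grid$r * grid$vars_per_factor >= 60L)
  grid <- grid[keep, , drop = FALSE]
  purrr::pmap(grid, sim_condition)
}

#' Population model for one factorial design cell
#'
#' Builds a simple-structure loading matrix for the condition: each variable
#' loads on exactly one factor, with the salient loading drawn uniformly from
#' the condition's communality range (`large`: `[.55, .88]`; `wide`:
#' `[.20, .88]`); loadings on all other factors are zero. The implied
#' communality of each variable is its squared salient loading.
#'
#' @param cond a [sim_condition()].
#' @param seed integer seed.
#' @return a `population_model` with the condition's categorization
#'   thresholds attached.
#' @export
make_loadings_study2 <- function(cond, seed) {
  if (!inherits(cond, "sim_condition")) abort("`cond` must be a sim_condition.")
  seed <- check_scalar_int(seed, "seed", min = 0L)
  range_ <- switch(cond$communality, large = c(0.55, 0.88), wide = c(0.20, 0.88))
  withr::with_seed(seed, {
    lambda <- matrix(0, cond$m, cond$r)
    for (f in seq_len(cond$r)) {
      rows <- ((f - 1L) * cond$vars_per_factor + 1L):(f * cond$vars_per_factor)
      lambda[rows, f] <- stats::runif(cond$vars_per_factor, range_[1L], range_[2L])
    }
    new_population_model(lambda, thresholds = response_thresholds[[cond$response_style]])
  })
}

#' Draw a multivariate-normal sample with the model's correlation structure
#'
#' Samples `n` rows from a zero-mean multivariate normal whose covariance is
#' the model's population correlation matrix (factorized through a symmetric
#' eigendecomposition). Marginals are standard normal.
#'
#' @param model a `population_model`.
#' @param n number of rows.
#' @param seed integer seed.
#' @return tibble with `n` rows and columns `V1..Vm`.
#' @examples
#' m <- make_loadings_study1(seed = 2)
#' x <- sample_continuous(m, n = 10, seed = 3)
#' dim(x)
#' @export
sample_continuous <- function(model, n, seed) {
  if (!inherits(model, "population_model")) {
    abort("`model` must be a population_model.")
  }
  n <- check_scalar_int(n, "n", min = 1L)
  seed <- check_scalar_int(seed, "seed", min = 0L)
  x <- withr::with_seed(seed, MASS::mvrnorm(n, mu = rep(0, model$m),
                                            Sigma = model$pop_corr))
  x <- matrix(x, nrow = n, ncol = model$m) # mvrnorm drops dims at n = 1
  colnames(x) <- paste0("V", seq_len(model$m))
  as_tibble(as.data.frame(x))
}

#' Categorize continuous responses to a 5-point scale
#'
#' Maps each continuous value to a category 1-5 by comparing it against the
#' standard-normal quantiles of four cumulative proportions. Under the
#' `normal` thresholds `(.05, .26, .74, .95)` a standard-normal item yields
#' expected frequencies `(.05, .21, .48, .21, .05)`; under the `extreme`
#' thresholds `(.05, .10, .15, .25)` about 75% of responses land in the top
#' category.
#'
#' @param data data frame or numeric matrix of continuous responses (assumed
#'   standard-normal marginals).
#' @param thresholds four strictly increasing cumulative proportions in
#'   `(0, 1)`, or `"normal"` / `"extreme"` for the built-in styles.
#' @return data of the same shape with integer categories 1-5 (tibble).
#' @examples
#' categorize(data.frame(v = c(-10, 0, 10)), "normal")
#' @export
categorize <- function(data, thresholds = "normal") {
  if (is.character(thresholds) && length(thresholds) == 1L) {
    thresholds <- response_thresholds[[match.arg(thresholds,
                                                 names(response_thresholds))]]
  }
  if (length(thresholds) != 4L || any(!is.finite(thresholds)) ||
      any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be 4 strictly increasing proportions in (0, 1).")
  }
  rm_ <- as_response_matrix(data, min_rows = 1L)
  cuts <- stats::qnorm(thresholds)
  cat_ <- matrix(
    findInterval(rm_$values, cuts) + 1L,
    nrow = nrow(rm_$values), ncol = ncol(rm_$values),
    dimnames = dimnames(rm_$values)
  )
  as_tibble(as.data.frame(cat_))
}

#' Draw a sample without replacement from a finite population
#'
#' Uniformly selects `n` distinct rows from a previously generated
#' population of responses, the sampling scheme used when comparing
#' splitters across sample sizes against one fixed population.
#'
#' @param population data frame or matrix of population responses.
#' @param n rows to draw (`n <=` population size).
#' @param seed integer seed.
#' @return tibble of `n` rows.
#' @export
draw_from_population <- function(population, n, seed) {
  rm_ <- as_response_matrix(population, min_rows = 1L)
  n <- check_scalar_int(n, "n", min = 1L)
  seed <- check_scalar_int(seed, "seed", min = 0L)
  np <- nrow(rm_$values)
  if (n > np) {
    abort(sprintf("Cannot draw %d rows from a population of %d.", n, np))
  }
  idx <- withr::with_seed(seed, sample.int(np, size = n, replace = FALSE))
  out <- rm_$values[idx, , drop = FALSE]
  as_tibble(as.data.frame(out))
}
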