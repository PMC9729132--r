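# Monte-Carlo experiment drivers comparing splitters by the Communality
# Ratio S across sample sizes (sweep study) and across a factorial design of
# population factor models (factorial study).

SPLIT_METHODS <- c("solomon", "duplex", "random")

# Seeds for every stochastic step, derived reproducibly from the master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Split one sample with one method and score the split; errors are captured,
# not raised, so a sweep never aborts.
split_and_score <- function(x, method, seed = NULL) {
  n_warn <- 0L
  res <- tryCatch(
    withCallingHandlers(
      {
        sp <- switch(method,
          solomon = solomon_split(x),
          duplex = duplex_split(x),
          random = random_split(x, seed = seed),
          abort(sprintf("Unknown method '%s'.", method))
        )
        k1 <- kmo(pearson_correlation(x[sp$subsample == 1L, , drop = FALSE]))
        k2 <- kmo(pearson_correlation(x[sp$subsample == 2L, , drop = FALSE]))
        communality_ratio(k1, k2)
      },
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NA_real_
  )
  list(s = res, warnings = n_warn)
}

new_sim_summary <- function(study, replication_log) {
  summary <- replication_log |>
    dplyr::group_by(dplyr::across(-c("replication", "s", "warnings"))) |>
    dplyr::summarise(
      mean_s = mean(.data$s, na.rm = TRUE),
      sd_s = if (sum(!is.na(.data$s)) > 1L) stats::sd(.data$s, na.rm = TRUE) else 0,
      replications = dplyr::n(),
      failures = sum(is.na(.data$s)),
      .groups = "drop"
    )
  structure(
    list(study = study, summary = summary, replications = replication_log),
    class = "sim_summary"
  )
}

#' Sample-size sweep: Solomon vs Duplex on a 5-factor population
#'
#' For each sample size and replication, generates a fresh 100-variable,
#' 5-factor population model ([make_loadings_study1()]), draws a
#' multivariate-normal sample of that size, splits it with each requested
#' method, and scores the split by the Communality Ratio S of the two
#' subsample KMO values. Results are aggregated to the mean and standard
#' deviation of S per (sample size, method) cell; splitter or adequacy
#' errors are counted as failures, never aborting the sweep.
#'
#' @param sizes sample sizes to sweep (default the full `500..7500` grid;
#'   desk-scale runs typically use a short prefix such as `c(500, 1000)`).
#' @param replications replications per size (default 30; the full design
#'   used 100).
#' @param methods subset of `c("solomon", "duplex", "random")`.
#' @param seed master seed; every population, sample and random split seed
#'   is derived from it, so the sweep is bit-reproducible.
#' @return a `sim_summary`: list with `summary` (one row per cell:
#'   `n`, `method`, `mean_s`, `sd_s`, `replications`, `failures`) and
#'   `replications` (the per-replication log). Methods: [tidy()] (log),
#'   [glance()] (cells), [autoplot()] (mean S vs N).
#' @examples
#' \donttest{
#' sweep <- run_study1(sizes = 500, replications = 5,
#'                     methods = "solomon", seed = 1)
#' sweep$summary
#' }
#' @export
run_study1 <- function(sizes = seq(500L, 7500L, by = 500L),
                       replications = 30L,
                       methods = c("solomon", "duplex"),
                       seed = 1L) {
  replications <- check_scalar_int(replications, "replications", min = 1L)
  methods <- match.arg(methods, SPLIT_METHODS, several.ok = TRUE)
  sizes <- vapply(sizes, check_scalar_int, integer(1), name = "sizes", min = 12L)
  seeds <- matrix(
    derive_seeds(seed, 3L * length(sizes) * replications),
    ncol = 3L
  )
  rows <- list()
  cell <- 0L
  for (n in sizes) {
    for (rep_ in seq_len(replications)) {
      cell <- cell + 1L
      model <- make_loadings_study1(seeds[cell, 1L])
      x <- as.matrix(sample_continuous(model, n, seeds[cell, 2L]))
      for (method in methods) {
        sc <- split_and_score(x, method, seed = seeds[cell, 3L])
        rows[[length(rows) + 1L]] <- tibble(
          n = n, method = method, replication = rep_,
          s = sc$s, warnings = sc$warnings
        )
      }
    }
  }
  log <- dplyr::bind_rows(rows)
  new_sim_summary("sweep", log)
}

#' Factorial study: splitter equivalence across factor-model conditions
#'
#' For each design cell ([sim_condition()]): builds the condition's
#' population model, simulates a finite population of `population_size`
#' continuous response vectors, categorizes them to a 5-point scale with the
#' condition's response-style thresholds, and then repeatedly draws samples
#' of the condition's size without replacement, splits each with every
#' requested method, and scores the Communality Ratio S.
#'
#' @param conditions list of [sim_condition()] objects (default all 168
#'   non-excluded cells).
#' @param replications samples drawn per condition (default 50; the full
#'   design used 1000).
#' @param methods subset of `c("solomon", "duplex", "random")`.
#' @param seed master seed.
#' @param population_size rows in each condition's finite population
#'   (default 10000).
#' @return a `sim_summary` whose `summary` has one row per
#'   (condition, method) and whose `replications` log carries the condition
#'   factors, so marginal means per factor level can be recomputed with
#'   [marginal_means()].
#' @examples
#' \donttest{
#' conds <- list(sim_condition("large", 1, 10, 200, "normal"))
#' res <- run_study2(conds, replications = 5, methods = "random", seed = 1)
#' res$summary
#' }
#' @export
run_study2 <- function(conditions = all_sim_conditions(),
                       replications = 50L,
                       methods = c("solomon", "duplex", "random"),
                       seed = 1L,
                       population_size = 10000L) {
  replications <- check_scalar_int(replications, "replications", min = 1L)
  population_size <- check_scalar_int(population_size, "population_size", min = 10L)
  methods <- match.arg(methods, SPLIT_METHODS, several.ok = TRUE)
  if (inherits(conditions, "sim_condition")) conditions <- list(conditions)
  ok <- vapply(conditions, inherits, logical(1), what = "sim_condition")
  if (!all(ok)) abort("`conditions` must be a list of sim_condition objects.")
  seeds <- matrix(
    derive_seeds(seed, length(conditions) * (2L + 2L * replications)),
    nrow = length(conditions)
  )
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    model <- make_loadings_study2(cond, seeds[ci, 1L])
    pop <- as.matrix(categorize(
      sample_continuous(model, population_size, seeds[ci, 2L]),
      model$thresholds
    ))
    for (rep_ in seq_len(replications)) {
      x <- as.matrix(draw_from_population(pop, cond$n, seeds[ci, 2L + rep_]))
      for (method in methods) {
        sc <- split_and_score(x, method,
                              seed = seeds[ci, 2L + replications + rep_])
        rows[[length(rows) + 1L]] <- tibble(
          communality = cond$communality, r = cond$r,
          vars_per_factor = cond$vars_per_factor, n = cond$n,
          response_style = cond$response_style,
          method = method, replication = rep_,
          s = sc$s, warnings = sc$warnings
        )
      }
    }
  }
  log <- dplyr::bind_rows(rows)
  new_sim_summary("factorial", log)
}

#' Marginal mean S per level of one design factor
#'
#' Averages the per-replication S values over all non-excluded cells at each
#' level of one factor (or overall), per method — the summary layout used to
#' compare splitters across a factorial design.
#'
#' @param x a `sim_summary` from [run_study2()].
#' @param margin one of `"overall"`, `"communality"`, `"r"`,
#'   `"vars_per_factor"`, `"n"`, `"response_style"`.
#' @return tibble with the margin level, `method`, `mean_s`, `sd_s`.
#' @export
marginal_means <- function(x, margin = "overall") {
  if (!inherits(x, "sim_summary")) abort("`x` must be a sim_summary.")
  margin <- match.arg(margin, c("overall", "communality", "r",
                                "vars_per_factor", "n", "response_style"))
  log <- x$replications
  keys <- if (margin == "overall") "method" else c(margin, "method")
  log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_s = mean(.data$s, na.rm = TRUE),
      sd_s = stats::sd(.data$s, na.rm = TRUE),
      replications = dplyr::n(),
      failures = sum(is.na(.data$s)),
      .groups = "drop"
    )
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("Simulation summary (%s study)\n", x$study))
  print(x$summary, n = 20)
  invisible(x)
}

#' @rdname run_study1
#' @param x a `sim_summary`.
#' @param ... unused.
#' @method tidy sim_summary
#' @export
tidy.sim_summary <- function(x, ...) {
  x$replications
}

#' @rdname run_study1
#' @method glance sim_summary
#' @export
glance.sim_summary <- function(x, ...) {
  x$summary
}

#' @rdname run_study1
#' @param object a `sim_summary`.
#' @method autoplot sim_summary
#' @export
autoplot.sim_summary <- function(object, ...) {
  if (object$study == "sweep") {
    ggplot2::ggplot(object$summary,
                    ggplot2::aes(x = .data$n, y = .data$mean_s,
                                 colour = .data$method)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$mean_s - .data$sd_s,
                     ymax = .data$mean_s + .data$sd_s),
        width = 0
      ) +
      ggplot2::labs(x = "sample size N", y = "mean Communality Ratio S",
                    colour = "method")
  } else {
    ggplot2::ggplot(object$summary,
                    ggplot2::aes(x = factor(.data$n), y = .data$mean_s,
                                 colour = .data$method)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "sample size N", y = "mean Communality Ratio S",
                    colour = "method")
  }
}

#' Write a simulation summary to CSV
#'
#' Writes one row per (condition, method) cell with fixed column order
#' `condition, method, mean_S, sd_S, replications, failures`; S values are
#' formatted to 4 decimals. The full-precision per-replication log is
#' available via [tidy()] and lets every summary cell be re-derived.
#'
#' @param x a `sim_summary`.
#' @param path output CSV path.
#' @return the written tibble, invisibly.
#' @export
write_sim_summary <- function(x, path) {
  if (!inherits(x, "sim_summary")) abort("`x` must be a sim_summary.")
  if (nrow(x$summary) == 0L) abort("Empty summary; nothing to write.")
  s <- x$summary
  cond_cols <- setdiff(names(s), c("method", "mean_s", "sd_s",
                                   "replications", "failures"))
  out <- tibble(
    condition = do.call(paste, c(lapply(cond_cols, function(cc) {
      paste0(cc, "=", s[[cc]])
    }), sep = ";")),
    method = s$method,
    mean_S = sprintf("%.4f", s$mean_s),
    sd_S = sprintf("%.4f", s$sd_s),
    replications = s$replications,
    failures = s$failures
  )
  readr::write_csv(out, path)
  invisible(out)
}
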