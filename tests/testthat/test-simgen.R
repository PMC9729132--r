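test_that("make_loadings_study1 builds the 100x5 block model with the stated loading ranges", {
  m <- make_loadings_study1(seed = 1)
  expect_equal(dim(m$loadings), c(100L, 5L))
  expect_equal(dim(m$pop_corr), c(100L, 100L))
  expect_equal(unname(diag(m$pop_corr)), rep(1, 100))
  for (f in 1:5) {
    rows <- (f - 1) * 20 + 1:20
    sal <- m$loadings[rows, f]
    expect_true(all(sal >= 0.40 & sal <= 0.45))
    non <- m$loadings[rows, -f]
    expect_true(all(abs(non) <= 0.10))
  }
  # reproducible from the seed
  expect_identical(make_loadings_study1(1)$loadings, m$loadings)
  expect_false(identical(make_loadings_study1(2)$loadings, m$loadings))
})

test_that("population correlation is PSD with bounded repair and matches a large-sample draw", {
  m <- make_loadings_study1(seed = 3)
  ev <- eigen(m$pop_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_lt(attr(m$pop_corr, "repair_delta"), 0.01)
  # law of large numbers: empirical correlation of a big draw approaches
  # the population matrix entrywise
  x <- as.matrix(sample_continuous(m, n = 20000, seed = 4))
  expect_lt(max(abs(cor(x) - m$pop_corr)), 0.04)
})

test_that("sim_condition validates levels and rejects the excluded design cells", {
  c1 <- sim_condition("large", r = 2, vars_per_factor = 10, n = 400, "normal")
  expect_equal(c1$m, 20L)
  expect_error(sim_condition("large", 3, 30, 100, "normal"), "Excluded")
  expect_error(sim_condition("large", 2, 30, 100, "extreme"), "Excluded")
  expect_error(sim_condition("large", 1, 15, 100, "normal"), "vars_per_factor")
  expect_error(sim_condition("large", 4, 10, 100, "normal"), "r")
  expect_error(sim_condition("large", 1, 10, 300, "normal"), "one of")
  # the non-excluded design has 180 - 12 cells
  expect_length(all_sim_conditions(), 168L)
})

test_that("make_loadings_study2 builds simple structure with range-bound salient loadings", {
  cond <- sim_condition("large", r = 3, vars_per_factor = 10, n = 400, "normal")
  m <- make_loadings_study2(cond, seed = 5)
  expect_equal(dim(m$loadings), c(30L, 3L))
  sal <- m$loadings[m$loadings != 0]
  expect_length(sal, 30L)
  expect_true(all(sal >= 0.55 & sal <= 0.88))
  # simple structure: communality equals the squared salient loading
  expect_equal(rowSums(m$loadings^2), apply(m$loadings, 1, max)^2)

  wide <- make_loadings_study2(
    sim_condition("wide", 1, 10, 200, "extreme"), seed = 6
  )
  sal_w <- wide$loadings[wide$loadings != 0]
  expect_true(all(sal_w >= 0.20 & sal_w <= 0.88))
  expect_equal(wide$thresholds, c(0.05, 0.10, 0.15, 0.25))
})

test_that("sample_continuous is seeded, shaped, and centered as the CLT predicts", {
  m <- make_loadings_study1(seed = 7)
  x1 <- sample_continuous(m, n = 1000, seed = 8)
  x2 <- sample_continuous(m, n = 1000, seed = 8)
  expect_identical(x1, x2)
  expect_equal(dim(x1), c(1000L, 100L))
  expect_true(all(abs(colMeans(as.matrix(x1))) < 3 / sqrt(1000)))
  xs <- sample_continuous(m, n = 1, seed = 9)
  expect_equal(dim(xs), c(1L, 100L))
})

test_that("categorize maps tails to the end categories and respects the threshold frequencies", {
  expect_equal(categorize(data.frame(v = c(-10, 10)), "normal")$v, c(1L, 5L))
  set.seed(901)
  z <- data.frame(v = rnorm(40000))
  freq_n <- tabulate(categorize(z, "normal")$v, 5) / 40000
  expect_equal(freq_n, c(.05, .21, .48, .21, .05), tolerance = 0.02)
  freq_e <- tabulate(categorize(z, "extreme")$v, 5) / 40000
  expect_equal(freq_e[5], 0.75, tolerance = 0.02)
  # monotone: larger continuous values never map to smaller categories
  v <- sort(rnorm(500))
  cats <- categorize(data.frame(v = v), "extreme")$v
  expect_true(all(diff(cats) >= 0))
  expect_error(categorize(z, c(.3, .2, .5, .9)), "increasing")
  expect_error(categorize(z, c(.1, .5, .9)), "increasing|4")
})

test_that("draw_from_population subsets without replacement, seeded", {
  pop <- tibble::tibble(a = 1:50, b = 51:100)
  d1 <- draw_from_population(pop, 20, seed = 10)
  d2 <- draw_from_population(pop, 20, seed = 10)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 20L)
  # distinct rows, all from the population
  expect_equal(anyDuplicated(d1$a), 0L)
  expect_true(all(d1$a %in% pop$a))
  # exhaustive draw is a permutation
  all_ <- draw_from_population(pop, 50, seed = 11)
  expect_setequal(all_$a, pop$a)
  expect_error(draw_from_population(pop, 51, seed = 1), "Cannot draw")
  # different seeds give different draws
  expect_false(identical(draw_from_population(pop, 20, 12),
                         draw_from_population(pop, 20, 13)))
})

test_that("the full generative chain is reproducible from (condition, seed)", {
  cond <- sim_condition("wide", 2, 10, 200, "extreme")
  gen <- function() {
    m <- make_loadings_study2(cond, seed = 21)
    pop <- categorize(sample_continuous(m, 500, seed = 22), m$thresholds)
    draw_from_population(pop, 100, seed = 23)
  }
  expect_identical(gen(), gen())
})
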