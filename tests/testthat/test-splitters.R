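# Shared property: a splitter output is an exhaustive disjoint partition with
# near-equal sizes.
expect_valid_partition <- function(split, n, k = 2L) {
  expect_s3_class(split, "split_assignment")
  expect_equal(nrow(split), n)
  expect_true(all(split$subsample %in% seq_len(k)))
  sizes <- tabulate(split$subsample, nbins = k)
  expect_equal(sum(sizes), n)
  expect_lte(max(sizes) - min(sizes), 1L)
}

test_that("solomon_assign deals the descending-d ordering alternately, leftovers to subsample 1", {
  d <- c(10, 9, 8, 7, 6, 5, 4)
  expect_equal(solomon_assign(d), c(1L, 2L, 1L, 2L, 1L, 2L, 1L))
  # unsorted input: assignment follows the d-ordering, not the row order
  d2 <- c(5, 10, 7, 9, 6, 8, 4)
  lab <- solomon_assign(d2)
  expect_equal(lab[order(-d2)], c(1L, 2L, 1L, 2L, 1L, 2L, 1L))
  # ties broken by original row order
  expect_equal(solomon_assign(c(1, 1, 1, 1)), c(1L, 2L, 1L, 2L))
})

test_that("solomon_assign supports k-way assignment: odd k tuples, even k recursive halving", {
  d <- 12:1
  lab3 <- solomon_assign(d, k = 3)
  # consecutive triplets of the ordering each cover all three subsamples
  expect_equal(lab3, rep(c(1L, 2L, 3L), 4))
  lab4 <- solomon_assign(d, k = 4)
  expect_equal(sort(tabulate(lab4, 4)), rep(3L, 4))
  # recursive halving: first halving alternates, then halves alternate again
  expect_equal(lab4[1:4], c(1L, 3L, 2L, 4L))
  expect_error(solomon_assign(1:3, k = 2), "at least")
})

test_that("solomon_split is deterministic, RNG-free, and permutation-invariant", {
  set.seed(601)
  x <- as.data.frame(matrix(rnorm(41 * 5), 41, 5))
  x <- cbind(id = sprintf("p%02d", 1:41), x)
  s1 <- solomon_split(x)
  s2 <- solomon_split(x)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_valid_partition(s1, 41)
  # odd n: the extra row lands in subsample 1
  expect_equal(sum(s1$subsample == 1L), 21L)

  # permuting rows permutes labels but preserves the partition of row ids
  perm <- sample(41)
  sp <- solomon_split(x[perm, ])
  for (g in 1:2) {
    expect_setequal(sp$row_id[sp$subsample == g], s1$row_id[s1$subsample == g])
  }
})

test_that("solomon_split at n = 2k gives one tuple per subsample and carries diagnostics", {
  set.seed(602)
  x <- matrix(rnorm(4 * 5), 4, 5)
  s <- solomon_split(x)
  expect_equal(sort(tabulate(s$subsample, 2)), c(2L, 2L))
  expect_length(attr(s, "d"), 4)
  expect_gte(attr(s, "q"), 2L)
})

test_that("duplex_split seeds with the two farthest pairs", {
  s <- duplex_split(data.frame(v = c(0, 1, 2, 3)))
  expect_equal(s$subsample, c(1L, 2L, 2L, 1L))
})

test_that("duplex_split matches the exhaustive greedy oracle on random instances", {
  set.seed(603)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    got <- duplex_split(x)
    expect_equal(got$subsample, duplex_oracle(x), info = paste("instance", i))
  }
})

test_that("duplex_split completes on degenerate all-tied data with a warning", {
  x <- matrix(1, 4, 3)
  expect_warning(s <- duplex_split(x), "tie")
  expect_valid_partition(s, 4)
  expect_equal(s$subsample, c(1L, 1L, 2L, 2L))
  expect_error(duplex_split(matrix(1, 3, 2)), "at least 4")
})

test_that("random_split is seeded, reproducible, and balanced", {
  x <- data.frame(v = rnorm(11))
  s1 <- random_split(x, seed = 9)
  s2 <- random_split(x, seed = 9)
  expect_identical(s1$subsample, s2$subsample)
  expect_valid_partition(s1, 11)
  expect_equal(tabulate(s1$subsample, 2), c(6L, 5L))
  expect_equal(tabulate(random_split(data.frame(v = rnorm(10)), 1)$subsample, 2),
               c(5L, 5L))
  # different seeds eventually differ
  labs <- vapply(1:5, function(sd) paste(random_split(x, sd)$subsample, collapse = ""),
                 character(1))
  expect_gt(length(unique(labs)), 1L)
})

test_that("stratified_split halves every stratum and merges by stratum-level label", {
  set.seed(604)
  x <- as.data.frame(matrix(rnorm(18 * 4), 18, 4))
  g <- rep(c("a", "b"), c(10, 8))
  s <- stratified_split(x, g, method = "solomon")
  expect_valid_partition(s, 18)
  for (st in unique(g)) {
    counts <- tabulate(s$subsample[g == st], 2)
    expect_lte(abs(diff(counts)), 1L)
  }
  # random strata property check
  for (i in 1:5) {
    g2 <- sample(c("u", "v", "w"), 18, replace = TRUE)
    while (min(table(g2)) < 4) g2 <- sample(c("u", "v", "w"), 18, replace = TRUE)
    s2 <- stratified_split(x, g2, method = "random", seed = i)
    for (st in unique(g2)) {
      expect_lte(abs(diff(tabulate(s2$subsample[g2 == st], 2))), 1L)
    }
  }
})

test_that("stratified_split with a single stratum matches the unstratified call", {
  set.seed(605)
  x <- as.data.frame(matrix(rnorm(20 * 4), 20, 4))
  s_strat <- stratified_split(x, rep("all", 20), method = "solomon")
  s_plain <- solomon_split(x)
  expect_equal(s_strat$subsample, s_plain$subsample)
})

test_that("stratified_split accepts a stratum column by name and rejects tiny strata", {
  set.seed(606)
  x <- as.data.frame(matrix(rnorm(16 * 4), 16, 4))
  x$sex <- rep(c("f", "m"), 8)
  s <- stratified_split(x, "sex", method = "random", seed = 2)
  expect_valid_partition(s, 16)
  g_bad <- c(rep("big", 15), "tiny")
  expect_error(stratified_split(x[, 1:4], g_bad, method = "random"), "tiny")
})

test_that("split_assignment tidiers and plots work", {
  set.seed(607)
  x <- as.data.frame(matrix(rnorm(30 * 4), 30, 4))
  s <- solomon_split(x)
  gl <- glance(s)
  expect_equal(gl$method, "solomon")
  expect_equal(gl$n, 30L)
  td <- tidy(s)
  expect_named(td, c("row_id", "subsample"))
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(random_split(x, 1))
  expect_s3_class(p2, "ggplot")
})
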