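# Independent oracles used across the suite. Each re-derives a quantity by a
# different route than the implementation (explicit loops, regression
# residuals, textbook sum formulas) so agreement is informative.

# Two-pass product-moment correlation from the textbook sum formula.
cor_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# Overall KMO from raw data via regression-residual partial correlations:
# for each pair (j, k), residualize both on all remaining variables with lm()
# and correlate the residuals.
kmo_oracle <- function(x) {
  x <- as.matrix(x)
  m <- ncol(x)
  r <- stats::cor(x)
  ssr <- 0
  ssp <- 0
  for (j in 1:(m - 1)) {
    for (k in (j + 1):m) {
      rest <- setdiff(1:m, c(j, k))
      if (length(rest)) {
        ej <- stats::resid(stats::lm(x[, j] ~ x[, rest, drop = FALSE]))
        ek <- stats::resid(stats::lm(x[, k] ~ x[, rest, drop = FALSE]))
        p <- stats::cor(ej, ek)
      } else {
        p <- r[j, k]
      }
      ssr <- ssr + 2 * r[j, k]^2
      ssp <- ssp + 2 * p^2
    }
  }
  ssr / (ssr + ssp)
}

# Exhaustive greedy Duplex oracle: plain loops, scanning all candidates at
# every step, ties to the lowest row index. Mirrors the stated selection
# rules, not the implementation's incremental data structures.
duplex_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  farthest_pair <- function(active) {
    best <- c(NA, NA)
    bestd <- -1
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        dd <- d(active[a], active[b])
        if (dd > bestd + 1e-12) {
          bestd <- dd
          best <- c(active[a], active[b])
        }
      }
    }
    best
  }
  labels <- integer(n)
  remaining <- 1:n
  p1 <- farthest_pair(remaining)
  labels[p1] <- 1L
  remaining <- setdiff(remaining, p1)
  p2 <- farthest_pair(remaining)
  labels[p2] <- 2L
  remaining <- setdiff(remaining, p2)
  turn <- 1L
  while (length(remaining)) {
    members <- which(labels == turn)
    bestd <- -1
    best <- NA
    for (cand in remaining) {
      mind <- min(vapply(members, function(mm) d(cand, mm), numeric(1)))
      if (mind > bestd + 1e-12) {
        bestd <- mind
        best <- cand
      }
    }
    labels[best] <- turn
    remaining <- setdiff(remaining, best)
    turn <- 3L - turn
  }
  labels
}

# Random PSD correlation matrix via a random Gram matrix.
random_correlation <- function(m, n = 50L) {
  z <- matrix(stats::rnorm(n * m), n, m)
  stats::cor(z)
}

# The seven-participant worked example: responses, printed component
# projections, and printed composites.
table1_fixture <- function() {
  tibble::tibble(
    participant = c("Teresa", "Daniel", "Gabriel", "David",
                    "Laura", "Maria", "Carlota"),
    c1 = c(2.617, 2.065, 2.540, 2.062, -0.429, -0.937, -1.630),
    c2 = c(1.140, 1.094, -1.002, -1.324, 0.759, 0.714, -0.875),
    d_printed = c(1.276, 1.041, 0.869, 0.616, -0.043, -0.260, -0.823)
  )
}
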