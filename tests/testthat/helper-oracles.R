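# Independent brute-force oracles used to verify the implementation.
# These deliberately avoid the code paths (and, for ranks, even the base
# helpers) used by the package itself.

rand_gray8 <- function(seed, nr = 64, nc = 64, channel_tag = "other") {
  withr::with_seed(seed,
    gray8(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc),
          channel_tag = channel_tag))
}

# Half-open interval mask by explicit pixel loop.
bf_interval_mask <- function(img, lo, hi) {
  m <- matrix(FALSE, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      v <- img[i, j]
      m[i, j] <- v >= lo && v < hi
    }
  }
  m
}

# Mid-ranks computed by explicit counting, not base rank().
bf_ranks <- function(values) {
  vapply(values, function(v) {
    sum(values < v) + (sum(values == v) + 1) / 2
  }, numeric(1))
}

# Tie-corrected Kruskal-Wallis H through the rank-variance form
# H = (N - 1) * SSbetween / SStotal of the ranks (equivalent to the
# tie-corrected classical formula, but an algebraically different route).
bf_kw_H <- function(groups) {
  values <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- bf_ranks(values)
  N <- length(values)
  rbar <- mean(r)
  ss_between <- sum(vapply(seq_along(groups), function(i) {
    ri <- r[g == i]
    length(ri) * (mean(ri) - rbar)^2
  }, numeric(1)))
  ss_total <- sum((r - rbar)^2)
  if (ss_total == 0) 0 else (N - 1) * ss_between / ss_total
}

# Dunn z statistics from the definition, with manually counted ranks.
bf_dunn_z <- function(groups) {
  values <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- bf_ranks(values)
  N <- length(values)
  tie_sum <- sum(vapply(unique(values), function(v) {
    t <- sum(values == v); t^3 - t
  }, numeric(1)))
  var_term <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  k <- length(groups)
  out <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ri <- mean(r[g == i]); rj <- mean(r[g == j])
      ni <- sum(g == i); nj <- sum(g == j)
      out <- c(out, (ri - rj) / sqrt(var_term * (1 / ni + 1 / nj)))
    }
  }
  out
}

# Small, fast phantom spec for tests.
test_spec <- function(seed = 1, ...) {
  args <- list(width = 96L, height = 80L, seed = as.integer(seed))
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

# Expression map with a single expressing compartment.
single_expression <- function(channel = "green", compartment = "epithelium",
                              mean = 200, span = 0) {
  e <- list()
  e[[channel]] <- structure(
    list(list(mean = mean, gradient_direction = 0, gradient_span = span)),
    names = compartment)
  e
}
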