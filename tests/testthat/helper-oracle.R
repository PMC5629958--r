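# Independent, loop-based transcription of the entropy-weight model
# equations, kept deliberately naive (scalar loops, no shared code with the
# package implementation) to serve as the oracle for ew_evaluate().
ew_oracle <- function(values, directions, subjective = NULL,
                      entropy_on = "raw") {
  m <- nrow(values)
  n <- ncol(values)
  if (is.null(subjective)) subjective <- rep(1 / n, n)
  subjective <- subjective / sum(subjective)

  d <- matrix(0, m, n)
  for (j in 1:n) {
    for (i in 1:m) {
      d[i, j] <- if (directions[j] == "benefit") {
        values[i, j] / max(values[, j])
      } else {
        min(values[, j]) / values[i, j]
      }
    }
  }
  base <- if (entropy_on == "raw") values else d
  p <- matrix(0, m, n)
  E <- numeric(n)
  for (j in 1:n) {
    s <- 0
    for (i in 1:m) s <- s + base[i, j]
    for (i in 1:m) p[i, j] <- base[i, j] / s
    acc <- 0
    for (i in 1:m) if (p[i, j] > 0) acc <- acc - p[i, j] * log(p[i, j])
    E[j] <- acc
  }
  e <- E / log(m)
  info <- 1 - e
  theta <- info / sum(info)
  prod <- theta * subjective
  alpha <- prod / sum(prod)
  lambda <- numeric(m)
  for (i in 1:m) {
    for (j in 1:n) lambda[i] <- lambda[i] + alpha[j] * d[i, j]
  }
  list(shares = p, entropy = E, normalized_entropy = e, theta = theta,
       alpha = alpha, d = d, lambda = lambda)
}

# random positive decision matrix with random directions
random_matrix_case <- function(m = sample(2:4, 1), n = sample(1:4, 1),
                               integer_entries = FALSE) {
  vals <- if (integer_entries) {
    matrix(sample(1:9, m * n, replace = TRUE), m, n)
  } else {
    matrix(stats::runif(m * n, 0.1, 10), m, n)
  }
  # avoid the all-columns-constant degenerate case
  if (all(apply(vals, 2, function(x) diff(range(x)) == 0))) {
    vals[1, 1] <- vals[1, 1] + 1
  }
  list(values = vals,
       directions = sample(c("benefit", "cost"), n, replace = TRUE))
}

expect_valid_evaluation <- function(res) {
  expect_true(all(abs(colSums(res$shares) - 1) < 1e-9))
  expect_true(all(res$normalized_entropy >= 0 - 1e-12 &
                    res$normalized_entropy <= 1 + 1e-12))
  expect_equal(sum(res$weights$objective), 1, tolerance = 1e-9)
  expect_equal(sum(res$weights$comprehensive), 1, tolerance = 1e-9)
  expect_true(all(res$lambda > 0 & res$lambda <= 1 + 1e-12))
}
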