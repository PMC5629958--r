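test_that("column shares rescale each indicator to a unit-sum distribution", {
  expect_equal(column_shares(cbind(c(2, 2, 2, 2))), cbind(rep(0.25, 4)))
  expect_equal(column_shares(cbind(c(1, 3))), cbind(c(0.25, 0.75)))
  # hand summation on a 3x2 matrix
  m <- cbind(a = c(1, 2, 5), b = c(4, 4, 8))
  expect_equal(unname(column_shares(m)),
               cbind(c(0.125, 0.25, 0.625), c(0.25, 0.25, 0.5)))
  expect_error(column_shares(cbind(c(1, 0))), "must be positive")
})

test_that("information entropy follows the Shannon formula with 0 ln 0 = 0", {
  expect_equal(information_entropy(cbind(rep(0.25, 4))), log(4))
  expect_equal(information_entropy(cbind(c(1, 0))), 0)
  expect_equal(information_entropy(cbind(c(0.25, 0.75))), 0.562335144619,
               tolerance = 1e-9)
  expect_error(information_entropy(cbind(c(0.5, 0.4))), "unit column sums")
})

test_that("normalized entropy rescales by ln m onto [0, 1]", {
  expect_equal(normalized_entropy(log(7), 7), 1)
  expect_equal(normalized_entropy(0, 4), 0)
  expect_equal(normalized_entropy(1, 4), 0.721347520444, tolerance = 1e-9)
  expect_error(normalized_entropy(1, 1), "at least 2 schemes")
})

test_that("objective weights grow with discriminating information", {
  expect_equal(objective_weights(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(objective_weights(c(1.0, 0.8)), c(0, 1))
  expect_error(objective_weights(c(1, 1, 1)), "no discriminating")
})

test_that("weight fusion is the normalized product and renormalizes input", {
  theta <- c(0.325, 0.159, 0.192, 0.137, 0.071, 0.075, 0.040)
  w <- c(0.200, 0.200, 0.200, 0.200, 0.067, 0.067, 0.067)
  expect_message(alpha <- combine_weights(theta, w), "rescaling")
  expect_equal(sum(alpha), 1, tolerance = 1e-12)
  expect_equal(alpha, theta * w / sum(theta * w), tolerance = 1e-12)

  # uniform subjective weights leave the objective weights unchanged
  expect_equal(combine_weights(theta, rep(1 / 7, 7)), theta / sum(theta),
               tolerance = 1e-12)
  expect_equal(combine_weights(c(1, 0), c(0.5, 0.5)), c(1, 0))
  expect_error(combine_weights(c(1, 0), c(0, 1)), "product is zero")
  expect_error(combine_weights(c(1, 0), c(0.2, 0.3, 0.5)), "length")
})

test_that("normalization scores the best scheme 1 in each direction", {
  x <- scheme_matrix(cbind(b = c(50, 100), c = c(2, 4)),
                     directions = c("benefit", "cost"))
  expect_equal(unname(normalize_matrix(x)), cbind(c(0.5, 1), c(1, 0.5)))

  # hand application of both branches on a 3x2 matrix; ties all score 1
  y <- scheme_matrix(cbind(c(2, 8, 8), c(3, 6, 2)),
                     directions = c("benefit", "cost"))
  expect_equal(unname(normalize_matrix(y)),
               cbind(c(0.25, 1, 1), c(2 / 3, 1 / 3, 1)))
})

test_that("evaluation values are the alpha-weighted normalized scores", {
  d <- cbind(c(1, 0.25), c(1, 0.5))
  expect_equal(evaluation_values(d, c(0.5, 0.5)), c(1, 0.375))
  expect_equal(evaluation_values(d, c(1, 0)), d[, 1])
  expect_error(evaluation_values(d, c(1, 0, 0)), "does not match")
})

test_that("ranking is descending with stable, flagged ties", {
  r <- rank_schemes(c(a = 0.3, b = 0.9, c = 0.5))
  expect_equal(as.character(r), c("b", "c", "a"))
  expect_false(attr(r, "ties"))
  r2 <- rank_schemes(c(x = 0.5, y = 0.5, z = 0.5))
  expect_equal(as.character(r2), c("x", "y", "z"))
  expect_true(attr(r2, "ties"))
})

test_that("ew_evaluate reproduces the hand-computed canonical fixture", {
  # 2x2 matrix ((4,2),(1,1)), both benefit, uniform subjective weights;
  # all expected values computed by hand from the model equations
  x <- scheme_matrix(rbind(A = c(4, 2), B = c(1, 1)),
                     directions = c("benefit", "benefit"))
  res <- ew_evaluate(x)
  expect_equal(unname(res$shares), cbind(c(0.8, 0.2), c(2 / 3, 1 / 3)),
               tolerance = 1e-12)
  expect_equal(unname(res$entropy), c(0.500402423538, 0.636514168295),
               tolerance = 1e-9)
  expect_equal(unname(res$normalized_entropy),
               c(0.721928094887, 0.918295834054), tolerance = 1e-9)
  expect_equal(unname(res$weights$objective),
               c(0.772902723338, 0.227097276662), tolerance = 1e-9)
  expect_equal(unname(res$weights$comprehensive),
               unname(res$weights$objective), tolerance = 1e-12)
  expect_equal(unname(res$normalized_matrix),
               cbind(c(1, 0.25), c(1, 0.5)))
  expect_equal(unname(res$lambda), c(1, 0.306774319166), tolerance = 1e-9)
  expect_equal(res$ranking, c("A", "B"))
})

test_that("a scheme dominant in every indicator gets lambda exactly 1", {
  x <- scheme_matrix(rbind(best = c(9, 1), mid = c(5, 3), worst = c(2, 7)),
                     directions = c("benefit", "cost"))
  res <- ew_evaluate(x)
  expect_equal(res$ranking[1], "best")
  expect_equal(unname(res$lambda["best"]), 1)
  expect_true(all(res$lambda[c("mid", "worst")] < 1))
})

test_that("the normalized-entropy variant takes shares of the scores", {
  x <- scheme_matrix(rbind(A = c(4, 2), B = c(1, 6), C = c(2, 3)),
                     directions = c("benefit", "cost"))
  res <- ew_evaluate(x, entropy_on = "normalized")
  orc <- ew_oracle(x$values, x$directions, entropy_on = "normalized")
  expect_equal(unname(res$weights$objective), orc$theta, tolerance = 1e-12)
  expect_equal(unname(res$lambda), orc$lambda, tolerance = 1e-12)
  # the two variants genuinely differ on this matrix
  raw <- ew_evaluate(x)
  expect_gt(max(abs(raw$weights$objective - res$weights$objective)), 1e-4)
})

test_that("degenerate matrices are rejected with informative errors", {
  expect_error(scheme_matrix(cbind(c(1, 0.5, -2)), "benefit"),
               "positive.*S3.*X1")
  expect_error(scheme_matrix(rbind(c(1, 2)), c("benefit", "benefit")),
               "at least 2 schemes")
  expect_error(scheme_matrix(rbind(c(1, 2), c(2, 1)), "benefit"),
               "one direction per indicator")
  con <- scheme_matrix(rbind(c(2, 2), c(2, 2)), c("benefit", "cost"))
  expect_error(ew_evaluate(con), "no discriminating")
})

test_that("matrix, directions and weights round-trip through CSV/JSON", {
  x <- benchmark_matrix()
  td <- withr::local_tempdir()
  mcsv <- file.path(td, "matrix.csv")
  dcsv <- file.path(td, "directions.csv")
  wcsv <- file.path(td, "weights.csv")
  utils::write.csv(data.frame(scheme = rownames(x$values), x$values,
                              check.names = FALSE), mcsv, row.names = FALSE)
  utils::write.csv(data.frame(indicator = names(x$directions),
                              direction = unname(x$directions)), dcsv,
                   row.names = FALSE)
  utils::write.csv(data.frame(indicator = names(x$directions),
                              weight = c(0.2, 0.2, 0.2, 0.2, 0.067, 0.067,
                                         0.067)), wcsv, row.names = FALSE)
  back <- read_scheme_matrix(mcsv, dcsv)
  expect_equal(back$values, x$values)
  expect_equal(back$directions, x$directions)
  w <- read_subjective_weights(wcsv, colnames(x$values))
  suppressMessages(res <- ew_evaluate(back, subjective = w))

  jpath <- file.path(td, "res.json")
  write_evaluation_json(res, jpath)
  parsed <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(unlist(parsed$lambda), res$lambda, tolerance = 1e-12)
  expect_equal(parsed$ranking, res$ranking)
  expect_equal(parsed$options$entropy_on, "raw")
})
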