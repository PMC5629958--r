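# Two-factor ANOVA and Duncan letter grouping.

# balanced two-way layout generator: y[i, j, r]
balanced_layout <- function(cell_means, reps, sd = 1) {
  a <- nrow(cell_means)
  b <- ncol(cell_means)
  data.frame(
    scheme = paste0("I", rep(rep(seq_len(a), each = b), each = reps),
                    "F", rep(rep(seq_len(b), times = a), each = reps)),
    y = stats::rnorm(a * b * reps,
                     mean = rep(c(t(cell_means)), each = reps), sd = sd)
  )
}

test_that("two-way ANOVA matches hand-computed sums of squares", {
  # 2x2 with 3 replicates; classical balanced formulas computed explicitly
  set.seed(11)
  dat <- balanced_layout(rbind(c(10, 12), c(11, 16)), reps = 3, sd = 1.5)
  res <- two_way_anova(dat, "y")

  fac <- scheme_factors(dat$scheme)
  A <- factor(fac$irrigation)
  B <- factor(fac$fertilizer)
  y <- dat$y
  r <- 3
  gm <- mean(y)
  ssa <- r * nlevels(B) * sum((tapply(y, A, mean) - gm)^2)
  ssb <- r * nlevels(A) * sum((tapply(y, B, mean) - gm)^2)
  cellm <- tapply(y, list(A, B), mean)
  sscells <- r * sum((cellm - gm)^2)
  ssab <- sscells - ssa - ssb
  sse <- sum((y - cellm[cbind(A, B)])^2)
  dfe <- nlevels(A) * nlevels(B) * (r - 1)
  f_hand <- c(ssa / 1, ssb / 1, ssab / 1) / (sse / dfe)

  expect_equal(res$F, f_hand, tolerance = 1e-8)
  expect_equal(res$df, c(1, 1, 1))
  expect_equal(attr(res, "df_error"), dfe)
  expect_equal(attr(res, "mse"), sse / dfe, tolerance = 1e-8)
  expect_equal(res$signif, significance_class_ref(res$p))
})


test_that("ANOVA is invariant to adding a constant to every observation", {
  set.seed(12)
  dat <- balanced_layout(matrix(5, 3, 3), reps = 3)
  res1 <- two_way_anova(dat, "y")
  dat$y <- dat$y + 42
  res2 <- two_way_anova(dat, "y")
  expect_equal(res1$F, res2$F, tolerance = 1e-9)
  expect_equal(res1$p, res2$p, tolerance = 1e-9)
})

test_that("control arms are excluded and broken designs rejected", {
  set.seed(13)
  dat <- balanced_layout(matrix(5, 3, 3), reps = 3)
  with_ck <- rbind(dat, data.frame(scheme = "CK", y = rnorm(3, 9)))
  res <- two_way_anova(with_ck, "y")
  expect_equal(sum(res$df) + attr(res, "df_error"), nrow(dat) - 1)

  expect_error(two_way_anova(dat[dat$scheme != "I2F2", ], "y"),
               "incomplete factorial")
  expect_error(two_way_anova(dat[-seq(1, 2), ], "y"), "at least 2 replicates")
  expect_error(two_way_anova(dat, "nope"), "no column")
  expect_error(two_way_anova(data.frame(scheme = "CK", y = 1), "y"),
               "no factorial schemes")
})

test_that("null-model p values are uniform (KS on simulated interactions)", {
  set.seed(14)
  p <- replicate(400, {
    dat <- balanced_layout(matrix(10, 3, 3), reps = 3, sd = 2)
    two_way_anova(dat, "y")$p[3]
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("Duncan critical ranges use protected studentized-range levels", {
  rng <- duncan_ranges(2:5, df_error = 15, mse = 2.25, n = 4)
  # independent: q((1-a)^(k-1), k, df) * sqrt(mse/n), evaluated term by term
  expect_equal(rng[1], stats::qtukey(0.95, 2, 15) * 0.75, tolerance = 1e-10)
  expect_equal(rng[3], stats::qtukey(0.95^3, 4, 15) * 0.75,
               tolerance = 1e-10)
  # non-decreasing in span
  expect_true(all(diff(rng) >= 0))
  rng2 <- duncan_ranges(2:8, df_error = 30, mse = 5, n = 3, alpha = 0.01)
  expect_true(all(diff(rng2) >= 0))
  expect_error(duncan_ranges(2, 0, 1, 3), "degrees of freedom")
  expect_error(duncan_ranges(2, 10, -1, 3), "mean square")
})

test_that("letter grouping matches the cross-checked reference fixtures", {
  # frozen letter strings verified once against an independent
  # studentized-range implementation of the stepwise procedure
  l1 <- duncan_letters(c(A = 24.2, B = 22.1, C = 21.9, D = 19.5, E = 18.3),
                       mse = 2.25, df_error = 15, n = 4)
  expect_equal(l1$scheme, c("A", "B", "C", "D", "E"))
  expect_equal(l1$letters, c("a", "a", "a", "b", "b"))

  l2 <- duncan_letters(c(A = 28.8, B = 24.0, C = 22.2, D = 19.6, E = 14.2),
                       mse = 11, df_error = 20, n = 5)
  expect_equal(l2$letters, c("a", "b", "b", "b", "c"))

  l3 <- duncan_letters(c(A = 25.0, B = 22.0, C = 20.5, D = 17.0),
                       mse = 9, df_error = 12, n = 4)
  expect_equal(l3$letters, c("a", "a", "ab", "b"))
})

test_that("letter grouping handles degenerate spreads and input order", {
  all_same <- duncan_letters(c(a = 5, b = 5, c = 5), mse = 1,
                             df_error = 10, n = 3)
  expect_equal(all_same$letters, c("a", "a", "a"))

  far <- duncan_letters(c(lo = 0, hi = 100), mse = 1, df_error = 10, n = 3)
  expect_equal(far$letters[far$scheme == "hi"], "a")
  expect_equal(far$letters[far$scheme == "lo"], "b")

  # invariant to the order the means arrive in
  m <- c(A = 24.2, B = 22.1, C = 21.9, D = 19.5, E = 18.3)
  shuffled <- duncan_letters(m[c(3, 5, 1, 4, 2)], mse = 2.25,
                             df_error = 15, n = 4)
  orig <- duncan_letters(m, mse = 2.25, df_error = 15, n = 4)
  expect_equal(shuffled, orig)
  expect_error(duncan_letters(m, 2.25, df_error = 0, n = 4),
               "degrees of freedom")
  expect_error(duncan_letters(m, 2.25, 15, n = 1), "at least 2 replicates")
})

test_that("scheme_letters runs the one-way fit across all arms", {
  set.seed(15)
  dat <- balanced_layout(rbind(c(10, 10, 10), c(10, 10, 10),
                               c(10, 10, 30)), reps = 3, sd = 1)
  dat <- rbind(dat, data.frame(scheme = "CK", y = rnorm(3, 10)))
  l <- scheme_letters(dat, "y")
  expect_setequal(l$scheme, c(unique(dat$scheme)))
  # the one outlying arm is alone in its letter group
  expect_equal(l$scheme[1], "I3F3")
  expect_false(l$letters[1] %in% l$letters[-1])
})
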