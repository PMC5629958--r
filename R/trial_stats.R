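## Two-factor fixed-effects ANOVA and Duncan's multiple range letters for
## replicated factorial trials. The control arm is not a factorial cell and
## is excluded from the factorial fit; it enters the letter display only.

#' Split scheme labels into factor levels
#'
#' Parses labels of the form `I<i>F<j>` (e.g. `I2F3`) into irrigation and
#' fertilizer level indices; any other label (such as the control `CK`) maps
#' to `NA` in both factors.
#'
#' @param scheme Character vector of scheme labels.
#' @return Data frame with columns `irrigation` and `fertilizer` (integer,
#'   `NA` for non-factorial schemes).
#' @export
scheme_factors <- function(scheme) {
  m <- regmatches(scheme, regexec("^I([0-9]+)F([0-9]+)$", scheme))
  irr <- vapply(m, function(g) if (length(g) == 3) as.integer(g[2])
                else NA_integer_, integer(1))
  fert <- vapply(m, function(g) if (length(g) == 3) as.integer(g[3])
                 else NA_integer_, integer(1))
  data.frame(irrigation = irr, fertilizer = fert)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Classical balanced two-factor ANOVA of one response over a complete
#' factorial (irrigation x fertilizer), with the control arm excluded.
#' Significance classes follow the usual field-trial convention:
#' `**` for p < 0.01, `*` for 0.01 <= p < 0.05, `ns` otherwise.
#'
#' @param records Plot-level data frame carrying a `scheme` column with
#'   `I<i>F<j>` labels (see [scheme_factors()]) plus the response column.
#' @param response Name of the response column, e.g. `"marketable_yield"`.
#' @return An object of class `wf_anova`: a data frame with one row per
#'   effect (`I`, `F`, `I:F`) and columns `df`, `F`, `p`, `signif`, plus
#'   attributes `df_error`, `mse` and `n_per_cell`.
#' @examples
#' trial <- generate_trial(trial_design(), seed = 1)
#' two_way_anova(derive_indicators(trial), "marketable_yield")
#' @export
two_way_anova <- function(records, response) {
  records <- as.data.frame(records)
  if (!response %in% names(records)) {
    stop("no column '", response, "' in records", call. = FALSE)
  }
  fac <- scheme_factors(records$scheme)
  keep <- !is.na(fac$irrigation)
  dat <- data.frame(
    y = records[[response]][keep],
    irrigation = factor(fac$irrigation[keep]),
    fertilizer = factor(fac$fertilizer[keep])
  )
  if (nrow(dat) == 0) stop("no factorial schemes in records", call. = FALSE)
  cells <- table(dat$irrigation, dat$fertilizer)
  if (any(cells == 0)) {
    stop("incomplete factorial: empty cell(s) ",
         paste(which(cells == 0, arr.ind = TRUE)[, 1], collapse = ", "),
         "; unbalanced designs are not supported", call. = FALSE)
  }
  if (any(cells < 2)) {
    stop("need at least 2 replicates per cell to estimate the error term",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ irrigation * fertilizer, data = dat)
  tab <- summary(fit)[[1]]
  eff <- c("I", "F", "I:F")
  out <- data.frame(
    effect = eff,
    df = tab[1:3, "Df"],
    F = tab[1:3, "F value"],
    p = tab[1:3, "Pr(>F)"],
    row.names = NULL
  )
  out$signif <- significance_class(out$p)
  structure(out, class = c("wf_anova", "data.frame"),
            response = response,
            df_error = tab[4, "Df"],
            mse = tab[4, "Mean Sq"],
            n_per_cell = unname(cells[1, 1]))
}

significance_class <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

#' @export
print.wf_anova <- function(x, ...) {
  cat("Two-way ANOVA of", attr(x, "response"), "\n")
  print.data.frame(cbind(x[1], round(x[c("df", "F")], 2),
                         p = signif(x$p, 3), signif = x$signif), ...)
  cat("Error df:", attr(x, "df_error"), " MSE:",
      signif(attr(x, "mse"), 4), "\n")
  invisible(x)
}

#' Duncan's multiple range critical values
#'
#' The critical range for a span of `k` ordered means is
#' `q(alpha_k, k, df) * sqrt(mse / n)` with the span-wise significance level
#' `alpha_k = 1 - (1 - alpha)^(k - 1)` taken on the studentized range
#' distribution (Duncan's protection levels).
#'
#' @param k Integer vector of spans (>= 2).
#' @param df_error Error degrees of freedom.
#' @param mse Residual mean square.
#' @param n Common (or harmonic-mean) group size.
#' @param alpha Base significance level.
#' @return Numeric vector of critical ranges, one per span.
#' @export
duncan_ranges <- function(k, df_error, mse, n, alpha = 0.05) {
  if (df_error <= 0) stop("error degrees of freedom must be positive",
                          call. = FALSE)
  if (mse <= 0) stop("residual mean square must be positive", call. = FALSE)
  q <- stats::qtukey((1 - alpha)^(k - 1), nmeans = k, df = df_error)
  q * sqrt(mse / n)
}

#' Duncan's multiple range test letter groups
#'
#' Stepwise range procedure over the group means: means sorted descending,
#' a pair spanning `k` sorted positions differs significantly when its
#' difference exceeds the span-`k` critical range (see [duncan_ranges()]);
#' letters are assigned by the standard overlapping-bar sweep, so two groups
#' share a letter exactly when they are not significantly different.
#'
#' @param means Named numeric vector of group means.
#' @param mse Residual mean square from the ANOVA.
#' @param df_error Error degrees of freedom.
#' @param n Replicates per group; a vector of unequal sizes is replaced by
#'   its harmonic mean.
#' @param alpha Significance level (default 0.05).
#' @return A data frame of class `duncan_letters` with columns `scheme`,
#'   `mean`, `letters`, in descending mean order.
#' @examples
#' duncan_letters(c(A = 24.2, B = 22.1, C = 21.9, D = 19.5, E = 18.3),
#'                mse = 2.25, df_error = 15, n = 4)
#' @export
duncan_letters <- function(means, mse, df_error, n, alpha = 0.05) {
  if (is.null(names(means))) names(means) <- paste0("G", seq_along(means))
  if (length(n) > 1) n <- length(n) / sum(1 / n)  # harmonic mean
  if (n < 2) stop("need at least 2 replicates per group", call. = FALSE)
  ord <- order(-means)
  v <- means[ord]
  g <- length(v)
  if (g == 1) {
    out <- data.frame(scheme = names(v), mean = unname(v), letters = "a")
    return(structure(out, class = c("duncan_letters", "data.frame")))
  }
  rng <- c(NA, duncan_ranges(2:g, df_error, mse, n, alpha))

  # maximal stretches of mutually non-significant means
  segs <- matrix(NA_integer_, nrow = 0, ncol = 2)
  for (i in seq_len(g)) {
    e <- i
    for (j in seq(i + 1, length.out = g - i)) {
      if (v[i] - v[j] <= rng[j - i + 1]) e <- j
    }
    segs <- rbind(segs, c(i, e))
  }
  segs <- unique(segs)
  contained <- vapply(seq_len(nrow(segs)), function(s) {
    any(segs[, 1] <= segs[s, 1] & segs[s, 2] <= segs[, 2] &
          (segs[, 1] != segs[s, 1] | segs[, 2] != segs[s, 2]))
  }, logical(1))
  segs <- segs[!contained, , drop = FALSE]
  segs <- segs[order(segs[, 1], segs[, 2]), , drop = FALSE]

  letters_out <- character(g)
  for (s in seq_len(nrow(segs))) {
    idx <- segs[s, 1]:segs[s, 2]
    letters_out[idx] <- paste0(letters_out[idx], letters[s])
  }
  out <- data.frame(scheme = names(v), mean = unname(v),
                    letters = letters_out, row.names = NULL)
  structure(out, class = c("duncan_letters", "data.frame"),
            alpha = alpha, ranges = rng[-1])
}

#' @export
print.duncan_letters <- function(x, ...) {
  cat("Duncan's multiple range test (alpha =", attr(x, "alpha"), ")\n")
  print.data.frame(cbind(x["scheme"], mean = round(x$mean, 3),
                         x["letters"]), row.names = FALSE, ...)
  invisible(x)
}

#' Letter groups for all schemes of a trial
#'
#' One-way ANOVA of the response over every scheme (control arm included),
#' followed by [duncan_letters()] on the scheme means with the one-way
#' residual mean square. This mirrors the usual field-trial display where
#' the control carries letters but no factorial effect row.
#'
#' @param records Plot-level data frame with `scheme` and the response.
#' @param response Name of the response column.
#' @param alpha Significance level.
#' @return A `duncan_letters` data frame over all schemes.
#' @export
scheme_letters <- function(records, response, alpha = 0.05) {
  records <- as.data.frame(records)
  if (!response %in% names(records)) {
    stop("no column '", response, "' in records", call. = FALSE)
  }
  dat <- data.frame(y = records[[response]],
                    scheme = factor(records$scheme))
  sizes <- table(dat$scheme)
  if (any(sizes < 2)) {
    stop("need at least 2 replicates per scheme for letter grouping",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ scheme, data = dat)
  tab <- summary(fit)[[1]]
  means <- tapply(dat$y, dat$scheme, mean)
  duncan_letters(means, mse = tab[2, "Mean Sq"], df_error = tab[2, "Df"],
                 n = as.numeric(sizes), alpha = alpha)
}
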