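## Entropy weight coefficient model.
##
## For an m-scheme by n-indicator decision matrix R = (r_ij) of positive
## values, each indicator's Shannon entropy across schemes
##   E_j = -sum_i p_ij ln p_ij,   p_ij = r_ij / sum_i r_ij,
## is scaled to e_j = E_j / ln m; low-entropy (discriminating) indicators
## receive high objective weight theta_j = (1 - e_j) / sum(1 - e_j).
## Comprehensive weights fuse theta with subjective weights w by normalized
## product, alpha_j = theta_j w_j / sum(theta_j w_j). Values are normalized
## per indicator direction (benefit: r/max, cost: min/r) and each scheme is
## scored by lambda_i = sum_j alpha_j d_ij; the highest lambda wins.

#' Construct a scheme-by-indicator decision matrix
#'
#' @param values Numeric matrix (or data frame) of strictly positive values,
#'   schemes in rows and indicators in columns. Positivity is required both
#'   by the entropy logarithm and by cost-direction normalization.
#' @param directions Character vector, one of `"benefit"` (larger is better)
#'   or `"cost"` (smaller is better) per indicator.
#' @param schemes,indicators Optional labels; default to the dimnames of
#'   `values` or generated labels.
#' @return An object of class `scheme_matrix`.
#' @examples
#' m <- scheme_matrix(rbind(A = c(4, 2), B = c(1, 1)),
#'                    directions = c("benefit", "benefit"))
#' @export
scheme_matrix <- function(values, directions,
                          schemes = rownames(values),
                          indicators = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values)
  n <- ncol(values)
  if (m < 2 || n < 1) {
    stop("need at least 2 schemes and 1 indicator", call. = FALSE)
  }
  if (is.null(schemes)) schemes <- paste0("S", seq_len(m))
  if (is.null(indicators)) indicators <- paste0("X", seq_len(n))
  dimnames(values) <- list(schemes, indicators)
  if (length(directions) != n) {
    stop("need exactly one direction per indicator", call. = FALSE)
  }
  directions <- match.arg(as.character(directions), c("benefit", "cost"),
                          several.ok = TRUE)
  if (length(directions) != n) {  # match.arg drops unmatched duplicates
    stop("directions must each be \"benefit\" or \"cost\"", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("decision matrix values must be positive; offending entry: scheme ",
         schemes[bad[1, 1]], ", indicator ", indicators[bad[1, 2]],
         call. = FALSE)
  }
  structure(list(values = values, directions = stats::setNames(directions,
                                                               indicators)),
            class = "scheme_matrix")
}

#' @export
print.scheme_matrix <- function(x, ...) {
  cat("Decision matrix:", nrow(x$values), "schemes x", ncol(x$values),
      "indicators\n")
  dir <- ifelse(x$directions == "benefit", "(+)", "(-)")
  hdr <- x$values
  colnames(hdr) <- paste(colnames(hdr), dir)
  print(round(hdr, 3), ...)
  invisible(x)
}

#' Column shares of a decision matrix
#'
#' `p_ij = r_ij / sum_i r_ij`: each indicator column rescaled to sum to one
#' over schemes, the distribution on which the indicator's entropy is taken.
#'
#' @param x A [scheme_matrix()] or a positive numeric matrix.
#' @return Matrix of shares with unit column sums.
#' @export
column_shares <- function(x) {
  v <- if (inherits(x, "scheme_matrix")) x$values else as.matrix(x)
  if (any(!is.finite(v) | v <= 0)) {
    bad <- which(!is.finite(v) | v <= 0, arr.ind = TRUE)[1, ]
    stop("matrix values must be positive (row ", bad[1], ", column ", bad[2],
         ")", call. = FALSE)
  }
  sweep(v, 2, colSums(v), "/")
}

#' Shannon entropy of each indicator column
#'
#' `E_j = -sum_i p_ij ln p_ij`, with the limit convention `0 * ln 0 = 0`.
#'
#' @param shares Matrix of column shares (columns sum to 1, entries in
#'   `[0, 1]`).
#' @return Numeric vector of entropies, one per column.
#' @export
information_entropy <- function(shares) {
  shares <- as.matrix(shares)
  if (any(shares < 0 | shares > 1) ||
        any(abs(colSums(shares) - 1) > 1e-8)) {
    stop("shares must lie in [0, 1] with unit column sums", call. = FALSE)
  }
  plogp <- ifelse(shares > 0, shares * log(shares), 0)
  -colSums(plogp)
}

#' Normalized entropy
#'
#' `e_j = E_j / ln m`, mapping each entropy onto `[0, 1]` (1 = the indicator
#' is uniform across schemes and carries no ranking information).
#'
#' @param entropies Numeric vector of column entropies.
#' @param m Number of schemes, at least 2.
#' @return Numeric vector of normalized entropies.
#' @export
normalized_entropy <- function(entropies, m) {
  if (length(m) != 1 || m < 2) {
    stop("need at least 2 schemes to normalize entropy", call. = FALSE)
  }
  entropies / log(m)
}

#' Objective indicator weights from normalized entropies
#'
#' `theta_j = (1 - e_j) / sum_j (1 - e_j)`: indicators that discriminate
#' between schemes (low entropy) weigh more.
#'
#' @param normalized_entropies Numeric vector of `e_j` values in `[0, 1]`.
#' @return Nonnegative weights summing to 1.
#' @export
objective_weights <- function(normalized_entropies) {
  info <- 1 - normalized_entropies
  if (all(abs(info) < 1e-12)) {
    stop("all indicators are constant across schemes: no discriminating ",
         "information to weight", call. = FALSE)
  }
  info / sum(info)
}

#' Fuse objective and subjective weights
#'
#' `alpha_j = theta_j * w_j / sum_j theta_j * w_j`, the normalized product of
#' the entropy-derived objective weights with the decision-maker's subjective
#' weights.
#'
#' @param objective Objective weight vector `theta`.
#' @param subjective Subjective weight vector `w`, same length; rescaled to
#'   sum to 1 on input (with a notice) if it does not already.
#' @return Comprehensive weights `alpha`, nonnegative and summing to 1.
#' @examples
#' combine_weights(objective  = c(0.325, 0.159, 0.192, 0.137,
#'                                0.071, 0.075, 0.040),
#'                 subjective = c(0.200, 0.200, 0.200, 0.200,
#'                                0.067, 0.067, 0.067))
#' @export
combine_weights <- function(objective, subjective) {
  if (length(objective) != length(subjective)) {
    stop("objective and subjective weights differ in length", call. = FALSE)
  }
  if (any(objective < 0) || any(subjective < 0)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  subjective <- normalize_subjective(subjective)
  prod <- objective * subjective
  if (sum(prod) <= 0) {
    stop("every objective x subjective product is zero; cannot fuse weights",
         call. = FALSE)
  }
  prod / sum(prod)
}

# Rescale a subjective weight vector to unit sum; printed weight tables are
# often rounded so their sum misses 1 by a few thousandths.
normalize_subjective <- function(subjective) {
  s <- sum(subjective)
  if (s <= 0) stop("subjective weights sum to zero", call. = FALSE)
  if (abs(s - 1) > 1e-9) {
    message("subjective weights sum to ", format(s),
            "; rescaling to unit sum")
    subjective <- subjective / s
  }
  subjective
}

#' Direction-aware normalization of the decision matrix
#'
#' For a benefit indicator `d_ij = r_ij / max_i r_ij`; for a cost indicator
#' `d_ij = min_i r_ij / r_ij`. The best scheme in each column scores exactly
#' 1 (all optima under ties), and all scores lie in `(0, 1]`.
#'
#' @param x A [scheme_matrix()].
#' @return Matrix of normalized scores `d_ij`.
#' @export
normalize_matrix <- function(x) {
  stopifnot(inherits(x, "scheme_matrix"))
  v <- x$values
  d <- v
  for (j in seq_len(ncol(v))) {
    if (x$directions[j] == "benefit") {
      d[, j] <- v[, j] / max(v[, j])
    } else {
      d[, j] <- min(v[, j]) / v[, j]
    }
  }
  d
}

#' Scheme evaluation values
#'
#' `lambda_i = sum_j alpha_j d_ij`: the comprehensive-weighted sum of a
#' scheme's normalized scores. `lambda_i = 1` exactly when scheme `i` is
#' best in every indicator.
#'
#' @param normalized Matrix of normalized scores from [normalize_matrix()].
#' @param comprehensive Comprehensive weight vector `alpha` (sums to 1).
#' @return Named numeric vector of evaluation values in `(0, 1]`.
#' @export
evaluation_values <- function(normalized, comprehensive) {
  normalized <- as.matrix(normalized)
  if (ncol(normalized) != length(comprehensive)) {
    stop("weight vector length does not match the number of indicators",
         call. = FALSE)
  }
  drop(normalized %*% comprehensive)
}

#' Rank schemes by evaluation value
#'
#' @param lambdas Named numeric vector of evaluation values.
#' @param tol Absolute tolerance below which two values count as tied
#'   (ties keep input order and set the `ties` attribute).
#' @return Character vector of scheme labels in descending `lambda` order,
#'   with attribute `ties` (logical flag).
#' @export
rank_schemes <- function(lambdas, tol = 1e-9) {
  if (is.null(names(lambdas))) {
    names(lambdas) <- paste0("S", seq_along(lambdas))
  }
  ord <- order(-lambdas)  # stable: ties keep input order
  sorted <- lambdas[ord]
  ties <- length(sorted) > 1 && any(abs(diff(sorted)) <= tol)
  structure(names(sorted), ties = ties)
}

#' Evaluate a decision matrix with the entropy weight coefficient model
#'
#' Runs the full chain: column shares, Shannon entropies, normalized
#' entropies, objective weights, weight fusion, direction-aware
#' normalization, evaluation values and ranking, returning every
#' intermediate.
#'
#' @param x A [scheme_matrix()].
#' @param subjective Subjective weight vector, one per indicator; defaults
#'   to uniform weights (so the comprehensive weights equal the objective
#'   ones). Rescaled to unit sum on input if needed.
#' @param entropy_on Distribution on which the entropies are taken:
#'   `"raw"` (default) uses shares of the raw values, the form the model
#'   equations state; `"normalized"` uses shares of the direction-normalized
#'   scores, a common textbook variant.
#' @return An object of class `ew_evaluation`: a list with elements
#'   `shares`, `entropy`, `normalized_entropy`, `weights` (subjective,
#'   objective, comprehensive), `normalized_matrix`, `lambda`, `ranking`,
#'   `ties` and `options`.
#' @examples
#' m <- scheme_matrix(rbind(A = c(4, 2), B = c(1, 1)),
#'                    directions = c("benefit", "benefit"))
#' ew_evaluate(m)
#' @export
ew_evaluate <- function(x, subjective = NULL,
                        entropy_on = c("raw", "normalized")) {
  stopifnot(inherits(x, "scheme_matrix"))
  entropy_on <- match.arg(entropy_on)
  n <- ncol(x$values)
  m <- nrow(x$values)
  if (is.null(subjective)) subjective <- rep(1 / n, n)
  if (length(subjective) != n) {
    stop("need one subjective weight per indicator", call. = FALSE)
  }
  subjective <- normalize_subjective(subjective)

  d <- normalize_matrix(x)
  shares <- if (entropy_on == "raw") column_shares(x) else column_shares(d)
  entropy <- information_entropy(shares)
  e <- normalized_entropy(entropy, m)
  theta <- objective_weights(e)
  alpha <- combine_weights(theta, subjective)
  lambda <- evaluation_values(d, alpha)
  ranking <- rank_schemes(lambda)

  structure(list(
    shares = shares,
    entropy = entropy,
    normalized_entropy = e,
    weights = list(subjective = stats::setNames(subjective, colnames(d)),
                   objective = stats::setNames(theta, colnames(d)),
                   comprehensive = stats::setNames(alpha, colnames(d))),
    normalized_matrix = d,
    lambda = lambda,
    ranking = as.character(ranking),
    ties = isTRUE(attr(ranking, "ties")),
    options = list(entropy_on = entropy_on)
  ), class = "ew_evaluation")
}

#' @export
print.ew_evaluation <- function(x, digits = 3, ...) {
  cat("Entropy-weight evaluation (", length(x$lambda), " schemes, ",
      length(x$entropy), " indicators; entropy on ", x$options$entropy_on,
      " values)\n\n", sep = "")
  w <- do.call(rbind, x$weights)
  cat("Weights:\n")
  print(round(w, digits))
  cat("\nEvaluation values (descending):\n")
  lam <- x$lambda[x$ranking]
  print(round(lam, digits))
  if (x$ties) cat("Note: ties broken by input order.\n")
  invisible(x)
}
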