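## CSV / JSON interfaces for the decision-matrix workflow.

#' Read a decision matrix and its indicator directions from CSV
#'
#' The matrix CSV has a first column `scheme` and one column per indicator;
#' the companion directions CSV has columns `indicator,direction` with
#' direction `benefit` or `cost`.
#'
#' @param matrix_csv Path to the scheme-by-indicator CSV.
#' @param directions_csv Path to the directions CSV.
#' @return A [scheme_matrix()].
#' @export
read_scheme_matrix <- function(matrix_csv, directions_csv) {
  for (p in c(matrix_csv, directions_csv)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  tab <- utils::read.csv(matrix_csv, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (names(tab)[1] != "scheme") {
    stop("matrix CSV must start with a 'scheme' column", call. = FALSE)
  }
  dirs <- utils::read.csv(directions_csv, stringsAsFactors = FALSE)
  if (!all(c("indicator", "direction") %in% names(dirs))) {
    stop("directions CSV needs columns 'indicator' and 'direction'",
         call. = FALSE)
  }
  vals <- as.matrix(tab[-1])
  rownames(vals) <- tab$scheme
  idx <- match(colnames(vals), dirs$indicator)
  if (anyNA(idx)) {
    stop("no direction given for indicator(s): ",
         paste(colnames(vals)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  scheme_matrix(vals, directions = dirs$direction[idx])
}

#' Read a subjective weight vector from CSV
#'
#' Expects columns `indicator,weight`. If `indicators` is given the weights
#' are reordered to match and every indicator must be present.
#'
#' @param path Path to the weights CSV.
#' @param indicators Optional character vector fixing the indicator order.
#' @return Named numeric weight vector (not yet rescaled to unit sum).
#' @export
read_subjective_weights <- function(path, indicators = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("indicator", "weight") %in% names(tab))) {
    stop("weights CSV needs columns 'indicator' and 'weight'", call. = FALSE)
  }
  w <- stats::setNames(tab$weight, tab$indicator)
  if (!is.null(indicators)) {
    idx <- match(indicators, names(w))
    if (anyNA(idx)) {
      stop("no subjective weight for indicator(s): ",
           paste(indicators[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    w <- w[idx]
  }
  w
}

#' Write an evaluation result to JSON
#'
#' Serializes every intermediate of an [ew_evaluate()] result at full double
#' precision (display rounding belongs to the report, not the archive).
#'
#' @param result An `ew_evaluation` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(result, path) {
  stopifnot(inherits(result, "ew_evaluation"))
  payload <- list(
    shares = result$shares,
    entropy = as.list(result$entropy),
    normalized_entropy = as.list(result$normalized_entropy),
    objective_weights = as.list(result$weights$objective),
    subjective_weights = as.list(result$weights$subjective),
    comprehensive_weights = as.list(result$weights$comprehensive),
    normalized_matrix = result$normalized_matrix,
    lambda = as.list(result$lambda),
    ranking = result$ranking,
    options = result$options
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
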