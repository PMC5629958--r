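## End-to-end pipeline: plot records -> indicators -> ANOVA + letters ->
## decision matrix -> entropy-weight evaluation -> report bundle.

evaluation_indicators <- c("marketable_yield", "sar", "iwue", "salinity",
                           "avail_n", "avail_p", "avail_k")

#' Build the decision matrix from scheme-level indicators
#'
#' Selects the seven evaluation indicators from an [aggregate_indicators()]
#' table and attaches their benefit/cost directions.
#'
#' @param indicators Scheme-level indicator data frame.
#' @param directions Named direction vector; defaults to
#'   [default_directions()].
#' @return A [scheme_matrix()].
#' @export
scheme_matrix_from_indicators <- function(indicators,
                                          directions = default_directions()) {
  missing_c <- setdiff(evaluation_indicators, names(indicators))
  if (length(missing_c) > 0) {
    stop("indicator table lacks column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(indicators[evaluation_indicators])
  rownames(vals) <- indicators$scheme
  scheme_matrix(vals, directions = directions[evaluation_indicators])
}

#' Run the full trial analysis
#'
#' One call from plot-level records to the report bundle: derives and
#' aggregates the indicators, attaches Duncan letter groups per indicator,
#' fits the two-way ANOVA per indicator over the factorial arms, evaluates
#' the scheme matrix with the entropy-weight model, and writes
#' `scheme_indicators.csv`, `anova.json`, `evaluation.json` and `report.md`
#' to `out_dir`. If any stage fails, partial outputs are removed and the
#' error names the stage.
#'
#' @param plots Plot-level records: a data frame or a path to a CSV in the
#'   [read_plot_records()] layout.
#' @param subjective Subjective weight vector over the seven evaluation
#'   indicators (default uniform).
#' @param alpha Significance level for the letter display.
#' @param entropy_on Passed to [ew_evaluate()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with elements `indicators`, `letters`,
#'   `anova`, `evaluation` and `paths`.
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_design(), seed = 1)
#' res <- run_full_analysis(trial, out_dir = tempfile("run"))
#' res$evaluation$ranking
#' }
#' @export
run_full_analysis <- function(plots, subjective = NULL, alpha = 0.05,
                              entropy_on = c("raw", "normalized"),
                              out_dir = "ewmtrial-output") {
  entropy_on <- match.arg(entropy_on)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(out_dir, recursive = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  records <- stage("read", {
    if (is.character(plots)) read_plot_records(plots)
    else validate_plot_records(plots)
  })
  ind <- stage("indicators", aggregate_indicators(records))
  derived <- derive_indicators(records)

  lett <- stage("letters", {
    out <- lapply(evaluation_indicators, function(v)
      scheme_letters(derived, v, alpha = alpha))
    names(out) <- evaluation_indicators
    out
  })
  anova_res <- stage("anova", {
    out <- lapply(evaluation_indicators, function(v)
      two_way_anova(derived, v))
    names(out) <- evaluation_indicators
    out
  })
  evaluation <- stage("evaluate", {
    mat <- scheme_matrix_from_indicators(ind)
    ew_evaluate(mat, subjective = subjective, entropy_on = entropy_on)
  })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    indicators = file.path(out_dir, "scheme_indicators.csv"),
    anova = file.path(out_dir, "anova.json"),
    evaluation = file.path(out_dir, "evaluation.json"),
    report = file.path(out_dir, "report.md")
  )
  stage("write", {
    ind_out <- ind
    for (v in evaluation_indicators) {
      l <- lett[[v]]
      ind_out[[paste0(v, "_letters")]] <-
        l$letters[match(ind_out$scheme, l$scheme)]
    }
    write_scheme_indicators(ind_out, paths$indicators)
    anova_payload <- lapply(anova_res, function(a) {
      list(effects = a[c("effect", "df", "F", "p", "signif")],
           df_error = attr(a, "df_error"), mse = attr(a, "mse"))
    })
    jsonlite::write_json(anova_payload, paths$anova, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    write_evaluation_json(evaluation, paths$evaluation)
    writeLines(render_report(ind, lett, anova_res, evaluation),
               paths$report)
  })
  invisible(list(indicators = ind, letters = lett, anova = anova_res,
                 evaluation = evaluation, paths = paths))
}

render_report <- function(ind, lett, anova_res, evaluation) {
  fmt3 <- function(x) formatC(x, format = "f", digits = 3)
  lines <- c("# Water-fertilizer scheme evaluation", "",
             "## Comprehensive ranking (entropy weight coefficient model)",
             "")
  lam <- evaluation$lambda[evaluation$ranking]
  lines <- c(lines, "| rank | scheme | evaluation value |",
             "|---|---|---|",
             sprintf("| %d | %s | %s |", seq_along(lam), names(lam),
                     fmt3(lam)), "")
  w <- evaluation$weights
  lines <- c(lines, "## Indicator weights", "",
             "| indicator | subjective | objective | comprehensive |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %s | %s |", names(w$objective),
                     fmt3(w$subjective), fmt3(w$objective),
                     fmt3(w$comprehensive)), "")
  lines <- c(lines, "## Factorial effects", "",
             "| indicator | I | F | I:F |", "|---|---|---|---|")
  for (v in names(anova_res)) {
    a <- anova_res[[v]]
    cell <- sprintf("%.1f%s", a$F, ifelse(a$signif == "ns", "ns", a$signif))
    lines <- c(lines, sprintf("| %s | %s | %s | %s |", v, cell[1], cell[2],
                              cell[3]))
  }
  lines <- c(lines, "", "## Duncan letter groups (scheme means)", "")
  for (v in names(lett)) {
    l <- lett[[v]]
    lines <- c(lines, paste0("- **", v, "**: ",
                             paste0(l$scheme, " ", fmt3(l$mean), " (",
                                    l$letters, ")", collapse = ", ")))
  }
  lines
}
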