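## Per-scheme agronomic indicators derived from plot-level measurements.
## Unit convention (fixed): yields t/ha, irrigation m3/ha per event, IWUE
## kg/m3; the t -> kg factor lives inside iwue() only.

#' Blossom-end rot incidence
#'
#' Share of the total fruit yield lost to blossom-end rot (BER), as a
#' percentage: `100 * ber_yield / total_yield`.
#'
#' @param total_yield Total fruit yield (t/ha), must be positive.
#' @param ber_yield BER-infected fruit yield (t/ha), in `[0, total_yield]`.
#' @param plot Optional plot labels used in error messages.
#' @return Numeric vector of incidences in percent, in `[0, 100]`.
#' @examples
#' ber_incidence(100, 10.3)
#' @export
ber_incidence <- function(total_yield, ber_yield, plot = NULL) {
  check_yields(total_yield, ber_yield, plot)
  100 * ber_yield / total_yield
}

#' Marketable yield
#'
#' Total yield minus the BER-infected yield (t/ha).
#'
#' @inheritParams ber_incidence
#' @return Numeric vector of marketable yields (t/ha), non-negative.
#' @examples
#' marketable_yield(131.9, 9.5)
#' @export
marketable_yield <- function(total_yield, ber_yield, plot = NULL) {
  check_yields(total_yield, ber_yield, plot)
  total_yield - ber_yield
}

check_yields <- function(total_yield, ber_yield, plot = NULL) {
  bad <- !is.finite(total_yield) | total_yield <= 0
  if (any(bad)) {
    stop("non-positive total yield", at_plots(bad, plot), call. = FALSE)
  }
  bad <- !is.finite(ber_yield) | ber_yield < 0 | ber_yield > total_yield
  if (any(bad)) {
    stop("BER yield must lie in [0, total yield]", at_plots(bad, plot),
         call. = FALSE)
  }
  invisible(TRUE)
}

at_plots <- function(bad, plot) {
  if (is.null(plot)) {
    paste0(" (element ", paste(which(bad), collapse = ", "), ")")
  } else {
    paste0(" (plot ", paste(unique(plot[bad]), collapse = ", "), ")")
  }
}

#' Fruit sugar/acid ratio
#'
#' Ratio of total sugar to total titratable acid content, a taste/quality
#' indicator. Both contents are percentages of fresh weight; the ratio is
#' dimensionless.
#'
#' @param sugar Total sugar content (percent), non-negative.
#' @param acid Total acid content (percent), strictly positive.
#' @param plot Optional plot labels used in error messages.
#' @return Numeric vector of ratios.
#' @seealso [sar_from_layers()] for the per-layer averaging used when fruit
#'   are sampled from more than one truss layer.
#' @examples
#' sugar_acid_ratio(4.5, 0.5)
#' @export
sugar_acid_ratio <- function(sugar, acid, plot = NULL) {
  if (any(!is.finite(acid) | acid <= 0)) {
    stop("acid content must be positive",
         at_plots(!is.finite(acid) | acid <= 0, plot), call. = FALSE)
  }
  if (any(!is.finite(sugar) | sugar < 0)) {
    stop("sugar content must be non-negative",
         at_plots(!is.finite(sugar) | sugar < 0, plot), call. = FALSE)
  }
  sugar / acid
}

#' Sugar/acid ratio averaged over fruit layers
#'
#' When fruit are sampled from several truss layers the scheme's ratio is the
#' mean of the per-layer ratios (mean of ratios, not ratio of means).
#'
#' @param sugar,acid Numeric vectors of per-layer contents (percent).
#' @return A single averaged sugar/acid ratio.
#' @examples
#' sar_from_layers(sugar = c(4.0, 4.2), acid = c(0.40, 0.50))
#' @export
sar_from_layers <- function(sugar, acid) {
  if (length(sugar) != length(acid)) {
    stop("sugar and acid must give one value per layer", call. = FALSE)
  }
  mean(sugar_acid_ratio(sugar, acid))
}

#' Irrigation water use efficiency
#'
#' Marketable yield produced per unit of irrigation water applied over the
#' season: `1000 * marketable_yield / (irrigation_quota * irrigation_events)`
#' in kg/m3, where the quota is the volume per hectare applied at each
#' irrigation event.
#'
#' @param marketable_yield Marketable yield (t/ha), non-negative.
#' @param irrigation_quota Water applied per event (m3/ha), positive.
#' @param irrigation_events Number of irrigation events over the season,
#'   at least 1.
#' @param plot Optional plot labels used in error messages.
#' @return Numeric vector of efficiencies (kg/m3).
#' @examples
#' iwue(122.4, 180, 21)
#' @export
iwue <- function(marketable_yield, irrigation_quota, irrigation_events,
                 plot = NULL) {
  bad <- !is.finite(irrigation_quota) | irrigation_quota <= 0 |
    !is.finite(irrigation_events) | irrigation_events < 1
  if (any(bad)) {
    stop("irrigation quota must be positive and events at least 1",
         at_plots(bad, plot), call. = FALSE)
  }
  if (any(marketable_yield < 0)) {
    stop("marketable yield must be non-negative",
         at_plots(marketable_yield < 0, plot), call. = FALSE)
  }
  1000 * marketable_yield / (irrigation_quota * irrigation_events)
}

#' Percent change relative to a control
#'
#' `100 * (value - control) / control`, used to express treatment gains over
#' the conventional-practice arm.
#'
#' @param value Treatment value.
#' @param control Control value, strictly positive.
#' @return Percent change (positive = above control).
#' @examples
#' percent_change(122.4, 95.6)
#' @export
percent_change <- function(value, control) {
  if (any(!is.finite(control) | control <= 0)) {
    stop("control value must be positive", call. = FALSE)
  }
  100 * (value - control) / control
}

plot_record_columns <- c(
  "scheme", "replicate", "total_yield", "ber_yield", "sugar", "acid",
  "irrigation_quota", "irrigation_events", "salinity",
  "avail_n", "avail_p", "avail_k"
)

#' Validate plot-level replicate records
#'
#' Checks that a data frame of plot records has the expected columns and
#' that every row satisfies the physical constraints of the measurements
#' (yields ordered, positive acid and irrigation, replicate counts integral).
#'
#' @param records Data frame of plot records; see [read_plot_records()] for
#'   the column layout.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_plot_records <- function(records) {
  records <- as.data.frame(records)
  missing <- setdiff(plot_record_columns, names(records))
  if (length(missing) > 0) {
    stop("plot records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("plot records are empty", call. = FALSE)
  lab <- paste0(records$scheme, "/r", records$replicate)
  check_yields(records$total_yield, records$ber_yield, lab)
  if (any(records$acid <= 0)) {
    stop("acid content must be positive", at_plots(records$acid <= 0, lab),
         call. = FALSE)
  }
  if (any(records$irrigation_quota <= 0 | records$irrigation_events < 1)) {
    stop("irrigation quota must be positive and events at least 1",
         at_plots(records$irrigation_quota <= 0 |
                    records$irrigation_events < 1, lab), call. = FALSE)
  }
  if (any(records$replicate != round(records$replicate) |
            records$replicate < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  records
}

#' Derive per-plot indicators
#'
#' Adds the derived indicator columns (`ber_incidence`, `marketable_yield`,
#' `sar`, `iwue`) to validated plot records; soil indicators (`salinity`,
#' `avail_n`, `avail_p`, `avail_k`) pass through unchanged.
#'
#' @inheritParams validate_plot_records
#' @return The records with one extra column per derived indicator.
#' @export
derive_indicators <- function(records) {
  records <- validate_plot_records(records)
  lab <- paste0(records$scheme, "/r", records$replicate)
  records$ber_incidence <- ber_incidence(records$total_yield,
                                         records$ber_yield, lab)
  records$marketable_yield <- marketable_yield(records$total_yield,
                                               records$ber_yield, lab)
  records$sar <- sugar_acid_ratio(records$sugar, records$acid, lab)
  records$iwue <- iwue(records$marketable_yield, records$irrigation_quota,
                       records$irrigation_events, lab)
  records
}

scheme_indicator_columns <- c(
  "ber_incidence", "marketable_yield", "sar", "iwue", "salinity",
  "avail_n", "avail_p", "avail_k"
)

#' Aggregate plot indicators to scheme level
#'
#' Averages the derived indicators over the replicates of each scheme. The
#' scheme means feed both the significance letters and the decision matrix,
#' so every scheme must carry at least one replicate and the full set of
#' indicators; missing values are a hard error, never imputed.
#'
#' @inheritParams validate_plot_records
#' @return A data frame with one row per scheme: `scheme`, `n_replicates`,
#'   and the mean of each indicator.
#' @examples
#' trial <- generate_trial(trial_design(), seed = 1)
#' head(aggregate_indicators(trial))
#' @export
aggregate_indicators <- function(records) {
  records <- derive_indicators(records)
  if (anyNA(records[scheme_indicator_columns])) {
    stop("missing indicator values; the decision matrix must be complete",
         call. = FALSE)
  }
  schemes <- unique(records$scheme)
  out <- do.call(rbind, lapply(schemes, function(s) {
    sub <- records[records$scheme == s, , drop = FALSE]
    row <- as.data.frame(lapply(sub[scheme_indicator_columns], mean))
    cbind(data.frame(scheme = s, n_replicates = nrow(sub)), row)
  }))
  rownames(out) <- NULL
  out
}

#' Read plot-level records from CSV
#'
#' Expects the header `scheme,replicate,total_yield,ber_yield,sugar,acid,`
#' `irrigation_quota,irrigation_events,salinity,avail_n,avail_p,avail_k`
#' (UTF-8, dot decimal separator).
#'
#' @param path Path to the CSV file.
#' @return A validated data frame of plot records.
#' @export
read_plot_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_plot_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write scheme-level indicators to CSV
#'
#' @param indicators Data frame from [aggregate_indicators()], optionally
#'   carrying extra columns such as significance letters.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scheme_indicators <- function(indicators, path) {
  utils::write.csv(indicators, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
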