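# Report rendering: model-selection tables and stratified summaries.

#' Model-selection report for a set of fits
#'
#' One row per model, in canonical order: unobserved-cell estimate X,
#' population estimate N, confidence interval, parameter count, G2,
#' BIC, AIC, and a flag on the selected (minimum-AIC) model. Estimates
#' stay real-valued here; rounding is left to the caller's rendering.
#'
#' @param fits list of `crc_fit` objects (e.g. [fit_all_models()]).
#' @return Data frame with columns `model`, `x000`, `n_hat`, `ci_low`,
#'   `ci_high`, `n_params`, `g2`, `bic`, `aic`, `selected`.
#' @export
crc_report <- function(fits) {
  selected <- select_model(fits)
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      model = f$model$label,
      x000 = f$x000_hat,
      n_hat = f$n_hat,
      ci_low = f$ci_n[["low"]],
      ci_high = f$ci_n[["high"]],
      n_params = f$n_params,
      g2 = f$g2,
      bic = f$bic,
      aic = f$aic,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out$selected <- out$model == selected$model$label
  out
}

#' Write a model-selection report as JSON and CSV
#'
#' @param report data frame from [crc_report()].
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_crc_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report, csv_path, row.names = FALSE)
  }
  invisible(report)
}

#' Stratified summary with completeness and per-1,000 rates
#'
#' Combines per-stratum fits with reported counts and denominator
#' populations. Strata with no population figure get `NA` rates with a
#' warning.
#'
#' @param fits named list of `crc_fit` objects from [stratified_fit()].
#' @param reported optional named vector of reported (observed) counts
#'   per stratum; defaults to each fit's `n_obs`.
#' @param population optional named vector of denominator populations.
#' @return Data frame with columns `stratum`, `reported`, `n_hat`,
#'   `ci_low`, `ci_high`, `completeness_pct`, `rate_per_1000`.
#' @export
stratified_report <- function(fits, reported = NULL, population = NULL) {
  strata <- names(fits)
  rep_n <- if (is.null(reported)) {
    vapply(fits, `[[`, numeric(1), "n_obs")
  } else {
    as.numeric(reported[strata])
  }
  nh <- vapply(fits, `[[`, numeric(1), "n_hat")
  rate <- rep(NA_real_, length(strata))
  if (!is.null(population)) {
    pop <- as.numeric(population[strata])
    has_pop <- !is.na(pop)
    if (any(!has_pop)) {
      warning("no population for strata: ",
              paste(strata[!has_pop], collapse = ", "),
              "; rate omitted")
    }
    rate[has_pop] <- rate_per_1000(nh[has_pop], pop[has_pop])
  }
  data.frame(
    stratum = strata,
    reported = rep_n,
    n_hat = nh,
    ci_low = vapply(fits, function(f) f$ci_n[["low"]], numeric(1)),
    ci_high = vapply(fits, function(f) f$ci_n[["high"]], numeric(1)),
    completeness_pct = completeness(rep_n, nh),
    rate_per_1000 = rate,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
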