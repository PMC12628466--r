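#' Declared dose grids for the exogenous challenges
#'
#' The glucose challenge uses 3.9, 5.6, 7.2 and 10 mM (70-180 mg/dL,
#' spanning resting glycemia to supplementation); the hydrogen peroxide
#' challenge uses 0, 5, 10, 20 and 40 uM on top of 10 mM glucose (plasma
#' levels in health are 1-5 uM, ~50 uM in inflammatory disease).
#'
#' @param challenge `"glucose"` or `"h2o2"`.
#' @return Numeric dose grid (mM for glucose, uM for hydrogen peroxide).
#' @export
dose_grid <- function(challenge = c("glucose", "h2o2")) {
  switch(match.arg(challenge),
         glucose = c(3.9, 5.6, 7.2, 10),
         h2o2 = c(0, 5, 10, 20, 40))
}

#' Summarize a flux table over the condition-by-timepoint design
#'
#' Aggregates per-sample flux estimates into cell means and dispersions and
#' derives fold changes of each cell mean against the same condition's
#' baseline and pre-exercise cells (fold changes on cell means, matching how
#' group percentages are reported). Empty design cells yield a row of `NA`
#' with a missing-cell warning rather than a failure.
#'
#' @param flux_tbl A tibble of flux estimates (e.g. from
#'   [estimate_fluxes()]) with at least the value column and the design
#'   label columns.
#' @param value Column with the flux value (tidy-eval), default `slope`.
#' @param condition,timepoint Column names (strings) of the design labels.
#' @param baseline,pre Timepoint labels used as fold-change references.
#' @param timepoint_levels Optional explicit timepoint ordering; cells
#'   listed here but absent from the data are reported as missing.
#' @return A tibble with one row per condition x timepoint: `n`, `mean_flux`,
#'   `sd_flux`, `se_flux`, `fold_vs_baseline`, `fold_vs_pre`,
#'   `pct_vs_pre`, and a `missing` flag.
#' @export
summarize_timecourse <- function(flux_tbl, value = slope,
                                 condition = "condition",
                                 timepoint = "timepoint",
                                 baseline = "baseline", pre = "pre",
                                 timepoint_levels = NULL) {
  flux_tbl <- as_tibble(flux_tbl)
  vals <- dplyr::pull(flux_tbl, {{ value }})
  d <- tibble(
    condition = as.character(flux_tbl[[condition]]),
    timepoint = as.character(flux_tbl[[timepoint]]),
    value = vals
  )
  tp_levels <- timepoint_levels %||% unique(d$timepoint)
  grid <- tidyr::expand_grid(condition = unique(d$condition),
                             timepoint = tp_levels)
  cells <- summarise(d, n = dplyr::n(),
                     mean_flux = mean(.data$value),
                     sd_flux = sd(.data$value),
                     .by = c("condition", "timepoint"))
  out <- left_join(grid, cells, by = c("condition", "timepoint"))
  out$n[is.na(out$n)] <- 0L
  out$missing <- out$n == 0L
  if (any(out$missing)) {
    warn(paste0("Empty design cell(s): ",
                paste(sprintf("%s/%s", out$condition[out$missing],
                              out$timepoint[out$missing]), collapse = ", ")),
         class = "erythroflux_missing_cell")
  }
  out <- mutate(out, se_flux = .data$sd_flux / sqrt(pmax(.data$n, 1)))
  ref <- function(tbl, label) {
    m <- setNames(tbl$mean_flux[tbl$timepoint == label], tbl$condition[tbl$timepoint == label])
    unname(m[tbl$condition])
  }
  out <- mutate(out,
                fold_vs_baseline = .data$mean_flux / ref(out, baseline),
                fold_vs_pre = .data$mean_flux / ref(out, pre),
                pct_vs_pre = 100 * (.data$fold_vs_pre - 1))
  out
}

#' Dose-response table for the glucose and hydrogen peroxide challenges
#'
#' Fits one flux estimate per (condition, dose) cell and reports a
#' monotonic-trend diagnostic per condition: the sign of the Spearman rank
#' correlation between dose and fitted flux.
#'
#' @inheritParams estimate_flux
#' @param data Long table of lactate series with a dose column.
#' @param challenge `"glucose"` or `"h2o2"`; fixes the admissible dose grid.
#' @param dose Column (tidy-eval) holding the dose label; every value must
#'   lie on [dose_grid()] for the chosen challenge.
#' @param condition Grouping column name (string); default `"condition"`.
#' @return A tibble with one row per (condition, dose) carrying the flux fit
#'   columns, plus attribute `trend`: a per-condition tibble with the
#'   Spearman rho and its sign (`-1`, `0`, `1`).
#' @export
dose_response <- function(data, challenge = c("glucose", "h2o2"),
                          dose = dose, time = incubation_min,
                          lactate = lactate_uM, condition = "condition") {
  challenge <- match.arg(challenge)
  grid <- dose_grid(challenge)
  data <- as_tibble(data)
  doses <- dplyr::pull(data, {{ dose }})
  off <- setdiff(unique(doses), grid)
  if (length(off)) {
    abort(sprintf("Dose(s) %s are not on the declared %s grid {%s}.",
                  paste(off, collapse = ", "), challenge,
                  paste(grid, collapse = ", ")),
          class = "erythroflux_off_grid_dose")
  }
  data$.dose <- doses
  tbl <- estimate_fluxes(data, {{ time }}, {{ lactate }},
                         .by = c(condition, ".dose"))
  tbl <- rename(tbl, dose = ".dose")
  trend <- summarise(
    tbl,
    rho = if (dplyr::n() < 2 || sd(.data$slope) == 0 || sd(.data$dose) == 0) 0
          else suppressWarnings(cor(.data$dose, .data$slope, method = "spearman")),
    .by = dplyr::all_of(condition)
  )
  trend$trend_sign <- sign(round(trend$rho, 10))
  attr(tbl, "trend") <- trend
  attr(tbl, "challenge") <- challenge
  tbl
}
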