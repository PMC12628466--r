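#' Estimate glycolytic flux from one lactate time course
#'
#' Ex vivo glycolytic flux is proxied by the rate of extracellular lactate
#' accumulation: the slope of the ordinary least-squares regression of
#' lactate concentration on incubation time, in micromolar per minute of the
#' 50%-hematocrit suspension. Series need at least 3 distinct incubation
#' times (the assay design uses 0/30/60/90 min).
#'
#' @param data Data frame holding one series.
#' @param time,lactate Columns (tidy-eval) with incubation time in minutes
#'   and lactate concentration in micromolar.
#' @param qc_r_squared Fits with R-squared below this threshold are flagged
#'   (`qc = "low_r_squared"`), never dropped. Default 0.9.
#'
#' @return An object of class `flux_fit` wrapping the [stats::lm()] fit,
#'   with elements `slope` (flux, uM/min), `intercept` (uM), `slope_se`,
#'   `r_squared`, `n_points` and `qc`. [tidy()] returns the coefficient
#'   table; [glance()] a one-row summary tibble.
#'
#' @examples
#' d <- data.frame(incubation_min = c(0, 30, 60, 90),
#'                 lactate_uM = c(0, 633, 1266, 1899))
#' glance(estimate_flux(d))$slope  # 21.1 uM/min
#' @export
estimate_flux <- function(data, time = incubation_min, lactate = lactate_uM,
                          qc_r_squared = 0.9) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ lactate }})
  check_series(t, y)
  fit <- lm(y ~ t)
  sm <- suppressWarnings(summary(fit)) # exact lines trip a perfect-fit warning
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-12) 1 else sm$r.squared
  out <- structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      slope_se = unname(sm$coefficients[2, 2]),
      r_squared = r2,
      n_points = length(y),
      qc = if (r2 < qc_r_squared) "low_r_squared" else "ok",
      fit = fit
    ),
    class = "flux_fit"
  )
  out
}

check_series <- function(t, y) {
  if (length(t) < 3 || length(unique(t)) < 3) {
    abort("A lactate series needs >= 3 points at >= 3 distinct incubation times.",
          class = "erythroflux_degenerate_input")
  }
  if (any(!is.finite(t)) || any(!is.finite(y)) || any(t < 0)) {
    abort("Incubation times must be non-negative and concentrations finite.",
          class = "erythroflux_degenerate_input")
  }
  invisible(TRUE)
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf(
    "<flux_fit> flux %.3f uM/min (SE %.3f), intercept %.1f uM, R2 %.4f, n %d%s\n",
    x$slope, x$slope_se, x$intercept, x$r_squared, x$n_points,
    if (x$qc != "ok") paste0(" [", x$qc, "]") else ""))
  invisible(x)
}

#' @describeIn estimate_flux Coefficient-level tidy table.
#' @param x A `flux_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.flux_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("intercept", "flux"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' @describeIn estimate_flux One-row fit summary.
#' @exportS3Method generics::glance
glance.flux_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, slope_se = x$slope_se,
         r_squared = x$r_squared, n_points = x$n_points, qc = x$qc)
}

# fast grouped OLS via lm.fit; same model as estimate_flux
flux_fit_row <- function(t, y, qc_r_squared = 0.9) {
  check_series(t, y)
  fit <- lm.fit(cbind(1, t), y)
  res <- fit$residuals
  n <- length(y)
  sigma2 <- sum(res^2) / (n - 2)
  sxx <- sum((t - mean(t))^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-12) 1 else 1 - sum(res^2) / ss_tot
  tibble(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    slope_se = sqrt(sigma2 / sxx),
    r_squared = r2,
    n_points = n,
    qc = if (r2 < qc_r_squared) "low_r_squared" else "ok"
  )
}

#' Estimate glycolytic flux for every series in a table
#'
#' Grouped version of [estimate_flux()]: fits one OLS slope per combination
#' of the `.by` columns and returns a tidy table of flux estimates.
#'
#' @inheritParams estimate_flux
#' @param .by Character vector of grouping columns identifying a series
#'   (e.g. participant/condition/timepoint, or dose labels).
#' @return A tibble with the `.by` columns plus `slope`, `intercept`,
#'   `slope_se`, `r_squared`, `n_points`, `qc`.
#' @export
estimate_fluxes <- function(data, time = incubation_min, lactate = lactate_uM,
                            .by = NULL, qc_r_squared = 0.9) {
  data <- as_tibble(data)
  if (is.null(.by)) {
    return(glance(estimate_flux(data, {{ time }}, {{ lactate }}, qc_r_squared)))
  }
  dplyr::reframe(data, flux_fit_row({{ time }}, {{ lactate }}, qc_r_squared),
                 .by = dplyr::all_of(.by))
}

#' Percent change between two flux estimates
#'
#' Reporting convention for flux responses: `100 * (comparison - reference)
#' / reference`. A rest-to-stress change of 21.1 to 29.3 uM/min is +38.9%.
#'
#' @param reference,comparison Flux values (uM/min) or `flux_fit` objects;
#'   `reference` must be > 0.
#' @return Percent change (may be negative).
#' @export
percent_change <- function(reference, comparison) {
  ref <- if (inherits(reference, "flux_fit")) reference$slope else reference
  cmp <- if (inherits(comparison, "flux_fit")) comparison$slope else comparison
  if (!is.numeric(ref) || !is.numeric(cmp) || any(!is.finite(ref)) || any(!is.finite(cmp))) {
    abort("Flux values must be finite numbers.", class = "erythroflux_invalid_parameter")
  }
  if (any(ref <= 0)) {
    abort("`reference` flux must be > 0 for a percent change.",
          class = "erythroflux_undefined_ratio")
  }
  100 * (cmp - ref) / ref
}
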