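test_that("flux is the OLS slope of lactate on incubation time", {
  d <- tibble::tibble(incubation_min = c(0, 30, 60, 90),
                      lactate_uM = c(0, 633, 1266, 1899))
  f <- estimate_flux(d)
  expect_equal(f$slope, 21.1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(f$n_points, 4)

  flat <- tibble::tibble(incubation_min = c(0, 30, 60, 90),
                         lactate_uM = rep(100, 4))
  f0 <- estimate_flux(flat)
  expect_equal(f0$slope, 0)
  expect_equal(f0$intercept, 100)
})

test_that("estimator agrees with the closed-form normal-equation solution", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    t <- sort(sample(0:200, n))
    y <- runif(1, 0, 50) + runif(1, 0, 40) * t + rnorm(n, 0, 25)
    d <- tibble::tibble(incubation_min = t, lactate_uM = y)
    f <- estimate_flux(d)
    o <- ols_oracle(t, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-9)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(f$slope_se, o$se, tolerance = 1e-9)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-9)
    # grouped fast path gives the same numbers
    g <- estimate_fluxes(dplyr::mutate(d, id = "a"), .by = "id")
    expect_equal(g$slope, o$slope, tolerance = 1e-9)
    expect_equal(g$slope_se, o$se, tolerance = 1e-9)
  }
})

test_that("slope estimate is scale-equivariant", {
  set.seed(7)
  t <- c(0, 30, 60, 90)
  y <- 10 + 21 * t + rnorm(4, 0, 30)
  f1 <- estimate_flux(tibble::tibble(incubation_min = t, lactate_uM = y))
  f2 <- estimate_flux(tibble::tibble(incubation_min = t, lactate_uM = 3.7 * y))
  expect_equal(f2$slope, 3.7 * f1$slope, tolerance = 1e-9)
})

test_that("degenerate series are rejected and noisy fits are QC-flagged", {
  expect_error(estimate_flux(tibble::tibble(incubation_min = c(0, 30),
                                            lactate_uM = c(1, 2))),
               class = "erythroflux_degenerate_input")
  expect_error(estimate_flux(tibble::tibble(incubation_min = c(0, 0, 0, 30),
                                            lactate_uM = 1:4)),
               class = "erythroflux_degenerate_input")
  wild <- tibble::tibble(incubation_min = c(0, 30, 60, 90),
                         lactate_uM = c(0, 900, 100, 950))
  expect_equal(estimate_flux(wild)$qc, "low_r_squared")
})

test_that("percent change follows the reporting convention", {
  expect_equal(percent_change(20, 30), 50)
  expect_equal(percent_change(21.1, 29.3), 100 * (29.3 - 21.1) / 21.1)
  expect_equal(round(percent_change(21.1, 29.3), 1), 38.9)
  expect_equal(round(percent_change(21.0, 57.7), 1), 174.8)
  expect_error(percent_change(0, 10), class = "erythroflux_undefined_ratio")
  expect_error(percent_change(-2, 10), class = "erythroflux_undefined_ratio")
})

test_that("timecourse summary: identical slopes give unit fold-changes", {
  tbl <- tidyr::expand_grid(condition = c("control", "oxidative_stress"),
                            timepoint = c("baseline", "pre", "post0"),
                            slope = 21)
  s <- summarize_timecourse(tbl)
  expect_true(all(s$fold_vs_baseline == 1))
  expect_true(all(s$fold_vs_pre == 1))
  expect_true(all(s$pct_vs_pre == 0))
})

test_that("timecourse summary flags missing cells without failing", {
  tbl <- tibble::tibble(condition = "control",
                        timepoint = c("baseline", "pre"),
                        slope = c(20, 25))
  expect_warning(
    s <- summarize_timecourse(tbl, timepoint_levels = c("baseline", "pre", "post0")),
    class = "erythroflux_missing_cell"
  )
  expect_equal(nrow(s), 3)
  expect_true(s$missing[s$timepoint == "post0"])
  expect_true(is.na(s$mean_flux[s$timepoint == "post0"]))
})

test_that("noiseless synthetic study recovers the generator multipliers exactly", {
  eff <- effect_sizes(lactate_noise_sd = 0, lactate_intercept_sd = 0,
                      lactate_intercept_mean = 150, baseline_flux_sd = 2)
  study <- generate_study(study_design(n_participants = 5, seed = 3), eff,
                          include_nirs = FALSE)
  est <- estimate_fluxes(study$lactate,
                         .by = c("participant", "condition", "timepoint"))
  joined <- dplyr::inner_join(est, study$truth$fluxes,
                              by = c("participant", "condition", "timepoint"))
  expect_equal(joined$slope, joined$true_flux, tolerance = 1e-9)
  s <- summarize_timecourse(est,
                            timepoint_levels = c("baseline", "pre", "post0", "post10", "post30"))
  os_pre <- s$mean_flux[s$condition == "oxidative_stress" & s$timepoint == "pre"]
  ctrl_pre <- s$mean_flux[s$condition == "control" & s$timepoint == "pre"]
  expect_equal(os_pre / ctrl_pre, eff$os_flux_multiplier, tolerance = 1e-9)
  expect_equal(s$fold_vs_pre[s$condition == "control" & s$timepoint == "post0"],
               eff$exercise_flux_multiplier_control, tolerance = 1e-9)
  expect_equal(s$fold_vs_pre[s$condition == "oxidative_stress" & s$timepoint == "post0"],
               eff$exercise_flux_multiplier_os, tolerance = 1e-9)
})

make_dose_data <- function(doses, fluxes, conditions = "control") {
  tidyr::expand_grid(condition = conditions, dose = doses) |>
    dplyr::mutate(series = purrr::map(dplyr::row_number(), function(i) {
      generate_lactate_series(fluxes[(i - 1) %% length(doses) + 1], noise_sd = 0)
    })) |>
    tidyr::unnest("series")
}

test_that("dose-response detects the trend sign and validates the grid", {
  doses <- dose_grid("h2o2")
  # flux halves by 40 uM peroxide: negative trend
  falling <- make_dose_data(doses, c(21, 19, 16, 13, 10.5))
  tbl <- dose_response(falling, "h2o2")
  expect_equal(nrow(tbl), 5)
  expect_equal(attr(tbl, "trend")$trend_sign, -1)
  expect_equal(tbl$slope, c(21, 19, 16, 13, 10.5), tolerance = 1e-9)

  flat <- make_dose_data(doses, rep(21, 5))
  expect_equal(attr(dose_response(flat, "h2o2"), "trend")$trend_sign, 0)

  expect_error(dose_response(make_dose_data(c(0, 5, 10, 20, 33), rep(21, 5)), "h2o2"),
               regexp = "33", class = "erythroflux_off_grid_dose")
})

test_that("glucose challenge table reproduces a generated fold-change", {
  doses <- dose_grid("glucose")
  fluxes <- c(18, 22, 18 * 1.49, 25) # +49% at 7.2 vs 3.9 mM
  tbl <- dose_response(make_dose_data(doses, fluxes), "glucose")
  f39 <- tbl$slope[tbl$dose == 3.9]
  f72 <- tbl$slope[tbl$dose == 7.2]
  expect_equal(percent_change(f39, f72), 49, tolerance = 1e-9)
})
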