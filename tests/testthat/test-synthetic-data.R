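test_that("noiseless lactate series lie exactly on the generating line", {
  s <- generate_lactate_series(21.1, noise_sd = 0)
  expect_equal(s$incubation_min, c(0, 30, 60, 90))
  expect_equal(s$lactate_uM, 21.1 * c(0, 30, 60, 90))

  flat <- generate_lactate_series(0, noise_sd = 0, intercept = 5)
  expect_equal(flat$lactate_uM, rep(5, 4))

  expect_error(generate_lactate_series(21, noise_sd = -1),
               class = "erythroflux_invalid_parameter")
  expect_error(generate_lactate_series(-1), class = "erythroflux_invalid_parameter")
})

test_that("lactate generator is seed-deterministic and never negative", {
  a <- generate_lactate_series(21.1, noise_sd = 50, seed = 42)
  b <- generate_lactate_series(21.1, noise_sd = 50, seed = 42)
  expect_identical(a, b)
  c <- generate_lactate_series(21.1, noise_sd = 50, seed = 43)
  expect_false(identical(a, c))
  # noise much larger than the signal: resampling keeps values >= 0
  for (seed in 1:20) {
    s <- generate_lactate_series(0.5, noise_sd = 100, seed = seed)
    expect_true(all(s$lactate_uM >= 0))
  }
})

test_that("replicate fitted slopes are unbiased for the generating flux", {
  # intercept well above the noise floor so the non-negativity constraint is
  # inactive and OLS sampling theory applies
  slopes <- vapply(1:1000, function(seed) {
    s <- generate_lactate_series(21.1, noise_sd = 50, intercept = 200, seed = seed)
    glance(estimate_flux(s))$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 21.1), 2 * se)

  # and near zero the truncation attenuates slopes, as documented
  low <- vapply(1:400, function(seed) {
    s <- generate_lactate_series(21.1, noise_sd = 50, intercept = 0, seed = seed)
    glance(estimate_flux(s))$slope
  }, numeric(1))
  expect_lt(mean(low), 21.1)
})

test_that("study tables have the full crossover cardinality", {
  design <- study_design(n_participants = 20, seed = 1)
  study <- generate_study(design, include_nirs = FALSE)
  expect_equal(nrow(study$truth$fluxes), 20 * 2 * 5)
  expect_equal(nrow(study$lactate), 20 * 2 * 5 * 4)
  counts <- dplyr::count(study$lactate, participant, condition, timepoint)
  expect_true(all(counts$n == 4))
  expect_equal(nrow(study$bloodgas), 20 * 2 * 5)
  expect_true(all(study$lactate$lactate_uM >= 0))
})

test_that("truth table encodes the multipliers exactly", {
  eff <- effect_sizes()
  study <- generate_study(study_design(n_participants = 12, seed = 5), eff,
                          include_nirs = FALSE)
  tr <- study$truth$fluxes
  cell <- function(cond, tp) mean(tr$true_flux[tr$condition == cond & tr$timepoint == tp])
  expect_equal(cell("oxidative_stress", "pre") / cell("control", "pre"),
               eff$os_flux_multiplier, tolerance = 1e-12)
  expect_equal(cell("control", "post0") / cell("control", "pre"),
               eff$exercise_flux_multiplier_control, tolerance = 1e-12)
  expect_equal(cell("oxidative_stress", "post0") / cell("oxidative_stress", "pre"),
               eff$exercise_flux_multiplier_os, tolerance = 1e-12)
  # post-10 sits at the geometric mean of pre and post-0; post-30 back at pre
  expect_equal(cell("control", "post10") / cell("control", "pre"),
               sqrt(eff$exercise_flux_multiplier_control), tolerance = 1e-12)
  expect_equal(cell("control", "post30"), cell("control", "pre"), tolerance = 1e-12)
})

test_that("blood-gas panel applies the stated pre -> post shifts", {
  eff <- effect_sizes()
  study <- generate_study(study_design(n_participants = 6, seed = 9),
                          include_nirs = FALSE)
  bg <- study$bloodgas
  pick <- function(cond, tp, col) unique(bg[[col]][bg$condition == cond & bg$timepoint == tp])
  expect_equal(pick("control", "pre", "ph"), eff$ph_baseline)
  expect_equal(pick("control", "post0", "ph"), eff$ph_baseline + eff$ph_delta)
  expect_equal(pick("control", "post0", "dpg"),
               eff$dpg_baseline * (1 + eff$dpg_fraction_control))
  expect_equal(pick("oxidative_stress", "post0", "dpg"),
               eff$dpg_baseline * (1 + eff$dpg_fraction_os))
  expect_equal(pick("control", "pre", "temp"), eff$temp_rest)
  expect_equal(pick("control", "post0", "temp"), eff$temp_exercise)
  expect_equal(pick("control", "post30", "dpg"), eff$dpg_baseline)
})

test_that("study generation is bit-reproducible under a fixed seed", {
  a <- generate_study(study_design(n_participants = 3, seed = 11), include_nirs = FALSE)
  b <- generate_study(study_design(n_participants = 3, seed = 11), include_nirs = FALSE)
  expect_identical(a$lactate, b$lactate)
  expect_identical(a$bloodgas, b$bloodgas)
  expect_identical(a$truth$fluxes, b$truth$fluxes)
  c <- generate_study(study_design(n_participants = 3, seed = 12), include_nirs = FALSE)
  expect_false(identical(a$lactate, c$lactate))
})

test_that("nirs traces are 10 Hz, phased, seeded, and validated", {
  tr <- generate_nirs_trace(120, "exercise",
                            nirs_kinetics(noise_sd = 0, n_optodes = 2,
                                          rest_s = 60, recovery_s = 60),
                            seed = 1)
  expect_equal(sort(unique(tr$phase)), c("exercise", "recovery", "rest"))
  one <- tr[tr$optode == 1, ]
  expect_equal(unique(round(diff(one$time_s), 10)), 0.1)
  expect_identical(tr, generate_nirs_trace(120, "exercise",
                                           nirs_kinetics(noise_sd = 0, n_optodes = 2,
                                                         rest_s = 60, recovery_s = 60),
                                           seed = 1))
  expect_error(generate_nirs_trace(120, "swimming"),
               class = "erythroflux_invalid_parameter")
  expect_error(generate_nirs_trace(30, "exercise"),
               class = "erythroflux_invalid_parameter")
})

test_that("flat noiseless kinetics put every decile bin at baseline", {
  k <- nirs_kinetics(o2hb_amp = 0, hhb_amp = 0, noise_sd = 0, n_optodes = 1)
  tr <- generate_nirs_trace(600, "exercise", k)
  avg <- optode_average(tr)
  base <- nirs_baseline(avg)
  bins <- nirs_decile_bins(avg)
  expect_equal(bins$O2Hb, rep(base$O2Hb, 10))
  expect_equal(bins$HHb, rep(base$HHb, 10))
})

test_that("exercise kinetics fall in O2Hb, rise in HHb, and recover", {
  k <- nirs_kinetics(noise_sd = 0, n_optodes = 1)
  tr <- generate_nirs_trace(600, "exercise", k)
  avg <- optode_average(tr)
  summ <- nirs_exercise_summary(avg)
  bins <- summ[grepl("^p", summ$point), ]
  expect_true(all(diff(bins$O2Hb) < 0))
  expect_true(all(diff(bins$HHb) > 0))
  base <- summ[summ$point == "baseline", ]
  last <- summ[summ$point == "p100", ]
  rec <- summ[summ$point == "rec120", ]
  # recovery: by 2 min the excursion has shrunk well below its peak
  expect_lt(abs(rec$HHb - base$HHb), 0.2 * abs(last$HHb - base$HHb))
})
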