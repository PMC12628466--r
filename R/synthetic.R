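# Seeded synthetic crossover-study generator. The defaults emulate the
# study conditions the analysis assumes: 20 participants, two conditions
# (control / oxidative stress) in crossover, five blood timepoints, lactate
# incubations at 0/30/60/90 min, resting glycolytic flux near 21 uM/min
# raised 1.4-fold by oxidative stress and 2.74-fold (control) / 1.67-fold
# (oxidative stress) by acute arm exercise with return to the pre level by
# 30 min, pre->post blood-gas shifts (pH fall, 2,3-BPG +14%/+22%,
# temperature 37 -> 38.5 degC), and NIRS exercise kinetics with variable
# exhaustion time.

#' Study design for the synthetic crossover dataset
#'
#' @param n_participants Number of participants (>= 2; default 20).
#' @param conditions Condition labels (default control / oxidative_stress).
#' @param timepoints Ordered blood-sampling timepoints.
#' @param incubation_times Lactate incubation times in minutes, strictly
#'   increasing and starting at 0.
#' @param seed Integer RNG seed driving every random draw downstream.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_participants = 20,
                         conditions = c("control", "oxidative_stress"),
                         timepoints = c("baseline", "pre", "post0", "post10", "post30"),
                         incubation_times = c(0, 30, 60, 90),
                         seed = 1) {
  check_number(n_participants, "n_participants", lower = 2)
  if (length(incubation_times) < 2 || incubation_times[1] != 0 ||
      any(diff(incubation_times) <= 0)) {
    abort("`incubation_times` must be strictly increasing and start at 0.",
          class = "erythroflux_invalid_parameter")
  }
  check_number(seed, "seed")
  structure(
    list(n_participants = as.integer(n_participants), conditions = conditions,
         timepoints = timepoints, incubation_times = incubation_times,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Effect-size profile for the synthetic generator
#'
#' The defaults are the study conditions themselves: resting flux 21.1
#' uM/min, a 1.4-fold oxidative-stress multiplier applied at the
#' pre-exercise timepoint, exercise multipliers 2.74 (control) and 1.67
#' (oxidative stress) at post-0 with the post-10 flux at the geometric mean
#' of pre and post-0 and full return to the pre level at post-30; redox
#' biomarker shifts (+22% F2-isoprostanes, +28% protein carbonyls, -20%
#' glutathione); and pre->post-0 blood-gas shifts (pH 7.40 -> 7.20, 2,3-BPG
#' +14% control / +22% oxidative stress from 4.65 mM, temperature 37 ->
#' 38.5 degC).
#'
#' @param baseline_flux_mean,baseline_flux_sd Between-participant mean and
#'   SD of resting glycolytic flux (uM/min).
#' @param os_flux_multiplier Multiplier on flux from systemic oxidative
#'   stress (applied from the pre timepoint onward).
#' @param exercise_flux_multiplier_control,exercise_flux_multiplier_os
#'   Multipliers applied at post-0 in each condition.
#' @param lactate_noise_sd Assay noise SD on each lactate point (uM).
#' @param lactate_intercept_mean,lactate_intercept_sd Mean and SD of the
#'   participant-level lactate intercept (uM): the residual extracellular
#'   lactate left in the washed 50%-hematocrit suspension at time zero.
#'   Keeping the mean several noise SDs above zero matters: concentrations
#'   cannot be negative, and an intercept near zero would truncate the
#'   assay-noise distribution at the first incubation point and attenuate
#'   fitted slopes (see [generate_lactate_series()]).
#' @param biomarker_effects Named fractional changes induced by oxidative
#'   stress at the pre timepoint.
#' @param ph_baseline,ph_delta Resting plasma pH and its pre->post-0 shift.
#' @param dpg_baseline Resting 2,3-BPG, mM.
#' @param dpg_fraction_control,dpg_fraction_os Fractional post-exercise
#'   2,3-BPG increase per condition.
#' @param temp_rest,temp_exercise Blood temperature at rest / exercise, degC.
#' @return A list of class `effect_sizes`.
#' @export
effect_sizes <- function(baseline_flux_mean = 21.1,
                         baseline_flux_sd = 3,
                         os_flux_multiplier = 1.4,
                         exercise_flux_multiplier_control = 2.74,
                         exercise_flux_multiplier_os = 1.67,
                         lactate_noise_sd = 50,
                         lactate_intercept_mean = 200,
                         lactate_intercept_sd = 20,
                         biomarker_effects = c(f2_isoprostanes = 0.22,
                                               protein_carbonyls = 0.28,
                                               glutathione = -0.20),
                         ph_baseline = 7.40, ph_delta = -0.20,
                         dpg_baseline = 4.65,
                         dpg_fraction_control = 0.14,
                         dpg_fraction_os = 0.22,
                         temp_rest = 37, temp_exercise = 38.5) {
  check_number(baseline_flux_mean, "baseline_flux_mean", lower = 0)
  check_number(baseline_flux_sd, "baseline_flux_sd", lower = 0)
  check_number(os_flux_multiplier, "os_flux_multiplier", lower = 1e-12)
  check_number(exercise_flux_multiplier_control, "exercise_flux_multiplier_control", lower = 1e-12)
  check_number(exercise_flux_multiplier_os, "exercise_flux_multiplier_os", lower = 1e-12)
  check_number(lactate_noise_sd, "lactate_noise_sd", lower = 0)
  check_number(lactate_intercept_mean, "lactate_intercept_mean", lower = 0)
  check_number(lactate_intercept_sd, "lactate_intercept_sd", lower = 0)
  if (temp_rest >= temp_exercise) {
    abort("`temp_rest` must be below `temp_exercise`.",
          class = "erythroflux_invalid_parameter")
  }
  structure(
    list(baseline_flux_mean = baseline_flux_mean,
         baseline_flux_sd = baseline_flux_sd,
         os_flux_multiplier = os_flux_multiplier,
         exercise_flux_multiplier_control = exercise_flux_multiplier_control,
         exercise_flux_multiplier_os = exercise_flux_multiplier_os,
         lactate_noise_sd = lactate_noise_sd,
         lactate_intercept_mean = lactate_intercept_mean,
         lactate_intercept_sd = lactate_intercept_sd,
         biomarker_effects = biomarker_effects,
         ph_baseline = ph_baseline, ph_delta = ph_delta,
         dpg_baseline = dpg_baseline,
         dpg_fraction_control = dpg_fraction_control,
         dpg_fraction_os = dpg_fraction_os,
         temp_rest = temp_rest, temp_exercise = temp_exercise),
    class = "effect_sizes"
  )
}

#' Simulate one ex vivo lactate incubation series
#'
#' Lactate grows linearly with incubation time at the true flux, with
#' independent Gaussian assay noise per point. Draws that would be negative
#' are resampled rather than clipped, so no probability mass piles up at
#' zero. Note the physical constraint this encodes: concentrations cannot
#' be negative, so when the expected value at a time point is within a few
#' noise SDs of zero the realized error distribution is necessarily
#' truncated and fitted slopes are attenuated. For the pure linear-model
#' regime keep `intercept` at least ~3 `noise_sd` (the study generator's
#' default intercept of ~200 uM residual lactate does this).
#'
#' @param true_flux True glycolytic flux, uM/min (>= 0).
#' @param times Incubation times in minutes (non-empty, increasing).
#' @param noise_sd Assay noise SD, uM (>= 0).
#' @param intercept Lactate at time 0, uM (>= 0).
#' @param seed Optional seed; fixed seed gives an identical series.
#' @return Tibble with `incubation_min` and `lactate_uM`.
#' @examples
#' generate_lactate_series(21.1, noise_sd = 0)  # exact line of slope 21.1
#' @export
generate_lactate_series <- function(true_flux, times = c(0, 30, 60, 90),
                                    noise_sd = 0, intercept = 0, seed = NULL) {
  check_number(true_flux, "true_flux", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(intercept, "intercept", lower = 0)
  if (!length(times) || any(diff(times) <= 0)) {
    abort("`times` must be non-empty and increasing.",
          class = "erythroflux_invalid_parameter")
  }
  with_seed(seed, {
    mu <- intercept + true_flux * times
    y <- mu + rnorm(length(times), 0, noise_sd)
    for (iter in seq_len(100)) {
      neg <- y < 0
      if (!any(neg)) break
      y[neg] <- mu[neg] + rnorm(sum(neg), 0, noise_sd)
    }
    y[y < 0] <- 0 # pathological noise regimes only
    tibble(incubation_min = as.numeric(times), lactate_uM = y)
  })
}

# per-participant true flux trajectories under the crossover design
truth_fluxes <- function(design, effects) {
  b <- rnorm(design$n_participants, effects$baseline_flux_mean,
             effects$baseline_flux_sd)
  for (iter in seq_len(100)) {
    bad <- b <= 0
    if (!any(bad)) break
    b[bad] <- rnorm(sum(bad), effects$baseline_flux_mean, effects$baseline_flux_sd)
  }
  tidyr::expand_grid(
    participant = seq_len(design$n_participants),
    condition = design$conditions,
    timepoint = design$timepoints
  ) |>
    mutate(
      base = b[.data$participant],
      pre_mult = ifelse(.data$condition == "oxidative_stress",
                        effects$os_flux_multiplier, 1),
      ex_mult = ifelse(.data$condition == "oxidative_stress",
                       effects$exercise_flux_multiplier_os,
                       effects$exercise_flux_multiplier_control),
      true_flux = .data$base * .data$pre_mult * dplyr::case_when(
        .data$timepoint == "baseline" ~ 1 / .data$pre_mult,
        .data$timepoint == "pre" ~ 1,
        .data$timepoint == "post0" ~ .data$ex_mult,
        .data$timepoint == "post10" ~ sqrt(.data$ex_mult),
        .data$timepoint == "post30" ~ 1,
        .default = 1
      )
    ) |>
    select("participant", "condition", "timepoint", "true_flux")
}

bloodgas_panel <- function(design, effects) {
  hct <- pmin(pmax(rnorm(design$n_participants, 0.45, 0.02), 0.35), 0.55)
  hb <- pmin(pmax(rnorm(design$n_participants, 15, 0.8), 12), 18)
  tidyr::expand_grid(
    participant = seq_len(design$n_participants),
    condition = design$conditions,
    timepoint = design$timepoints
  ) |>
    mutate(
      po2 = 100, pco2 = 40,
      ph = effects$ph_baseline + effects$ph_delta * dplyr::case_when(
        .data$timepoint == "post0" ~ 1,
        .data$timepoint == "post10" ~ 0.5,
        .default = 0
      ),
      dpg_frac = ifelse(.data$condition == "oxidative_stress",
                        effects$dpg_fraction_os, effects$dpg_fraction_control),
      dpg = effects$dpg_baseline * dplyr::case_when(
        .data$timepoint == "post0" ~ 1 + .data$dpg_frac,
        .data$timepoint == "post10" ~ 1 + .data$dpg_frac / 2,
        .default = 1
      ),
      temp = dplyr::case_when(
        .data$timepoint == "post0" ~ effects$temp_exercise,
        .data$timepoint == "post10" ~ (effects$temp_rest + effects$temp_exercise) / 2,
        .default = effects$temp_rest
      ),
      hct = hct[.data$participant],
      hb = hb[.data$participant],
      total_hb = 10 * .data$hb,                               # g/L
      plasma_hb = ifelse(.data$condition == "oxidative_stress" &
                           .data$timepoint != "baseline", 0.032, 0.020),
      methb = .data$total_hb *
        ifelse(.data$timepoint %in% c("post0", "post10"), 0.035, 0.029)
    ) |>
    select(-"dpg_frac")
}

#' Simulate a full synthetic crossover study
#'
#' Draws per-participant resting fluxes, applies the condition and
#' timepoint multipliers multiplicatively in the truth table, and generates
#' the observable tables: lactate incubation series ([generate_lactate_series()]
#' per participant-condition-timepoint), blood-gas/effector panels with the
#' pre->post shifts, redox biomarker summaries, and (optionally) 10 Hz
#' three-optode NIRS exercise traces with exhaustion times drawn uniformly
#' between 480 and 900 s. Fully reproducible from `design$seed`.
#'
#' @param design A [study_design()].
#' @param effects An [effect_sizes()] profile.
#' @param include_nirs Generate the NIRS table? (The trace table is large;
#'   Monte-Carlo loops that only use lactate can switch it off.)
#' @return A list of class `synthetic_study`: `lactate` (long table of
#'   series), `bloodgas`, `biomarkers`, `nirs` (or `NULL`), and `truth`
#'   (the effect profile plus the per-sample true-flux table and NIRS
#'   ground-truth parameters).
#' @examples
#' study <- generate_study(study_design(n_participants = 4, seed = 7),
#'                         include_nirs = FALSE)
#' dplyr::count(study$lactate, condition, timepoint)
#' @export
generate_study <- function(design = study_design(), effects = effect_sizes(),
                           include_nirs = TRUE) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_sizes"))
  with_seed(design$seed, {
    truth_tbl <- truth_fluxes(design, effects)
    intercepts <- pmax(rnorm(design$n_participants, effects$lactate_intercept_mean,
                             effects$lactate_intercept_sd), 0)
    lactate <- truth_tbl |>
      mutate(intercept = intercepts[.data$participant]) |>
      mutate(series = purrr::map2(.data$true_flux, .data$intercept, function(f, ic) {
        generate_lactate_series(f, design$incubation_times,
                                noise_sd = effects$lactate_noise_sd,
                                intercept = ic)
      })) |>
      select("participant", "condition", "timepoint", "series") |>
      tidyr::unnest("series")

    bloodgas <- bloodgas_panel(design, effects)

    eff <- effects$biomarker_effects
    biomarkers <- tidyr::expand_grid(
      participant = seq_len(design$n_participants),
      condition = design$conditions,
      biomarker = names(eff)
    ) |>
      mutate(
        baseline = 100 * exp(rnorm(dplyr::n(), 0, 0.05)),
        pre = .data$baseline *
          ifelse(.data$condition == "oxidative_stress",
                 1 + unname(eff[.data$biomarker]), 1) *
          exp(rnorm(dplyr::n(), 0, 0.02))
      )

    nirs <- NULL
    nirs_truth <- NULL
    if (include_nirs) {
      nirs_truth <- tidyr::expand_grid(
        participant = seq_len(design$n_participants),
        condition = design$conditions
      ) |>
        mutate(
          exhaustion_s = runif(dplyr::n(), 480, 900),
          hhb_amp = 12 * ifelse(.data$condition == "oxidative_stress", 1 - 0.074, 1),
          o2hb_amp = 10
        )
      nirs <- purrr::pmap_dfr(nirs_truth, function(participant, condition,
                                                   exhaustion_s, hhb_amp, o2hb_amp) {
        tr <- generate_nirs_trace(
          duration_s = exhaustion_s, phase = "exercise",
          kinetics = nirs_kinetics(o2hb_amp = o2hb_amp, hhb_amp = hhb_amp)
        )
        mutate(tr, participant = participant, condition = condition,
               limb = "arm", .before = 1)
      })
    }

    structure(
      list(lactate = lactate, bloodgas = bloodgas, biomarkers = biomarkers,
           nirs = nirs,
           truth = list(effects = effects, fluxes = truth_tbl,
                        nirs = nirs_truth, design = design)),
      class = "synthetic_study"
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  d <- x$truth$design
  cat(sprintf("<synthetic_study> %d participants x %d conditions x %d timepoints (seed %d)\n",
              d$n_participants, length(d$conditions), length(d$timepoints), d$seed))
  cat(sprintf("  lactate: %d rows | bloodgas: %d rows | nirs: %s\n",
              nrow(x$lactate), nrow(x$bloodgas),
              if (is.null(x$nirs)) "not generated" else paste(nrow(x$nirs), "rows")))
  invisible(x)
}

#' Kinetic parameter set for synthetic NIRS traces
#'
#' @param o2hb_baseline,hhb_baseline Resting signal levels, uM.
#' @param o2hb_amp Magnitude of the O2Hb fall over the exercise/occlusion
#'   phase, uM (O2Hb declines; HHb rises by `hhb_amp`).
#' @param hhb_amp Magnitude of the HHb rise, uM.
#' @param shape Power shaping the monotone exercise trend
#'   (`frac^shape`; 1 = linear ramp).
#' @param recovery_tau Exponential recovery time constant, s (signals
#'   return to baseline within ~3 min for the default 40 s).
#' @param noise_sd Per-sample, per-optode Gaussian noise SD, uM.
#' @param n_optodes Number of optodes (default 3).
#' @param rest_s,recovery_s Rest and recovery phase lengths, s.
#' @return A list of class `nirs_kinetics`.
#' @export
nirs_kinetics <- function(o2hb_baseline = 25, hhb_baseline = 15,
                          o2hb_amp = 10, hhb_amp = 12, shape = 1,
                          recovery_tau = 40, noise_sd = 0.5, n_optodes = 3,
                          rest_s = 300, recovery_s = 180) {
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_optodes, "n_optodes", lower = 1)
  check_number(recovery_tau, "recovery_tau", lower = 1e-9)
  structure(
    list(o2hb_baseline = o2hb_baseline, hhb_baseline = hhb_baseline,
         o2hb_amp = o2hb_amp, hhb_amp = hhb_amp, shape = shape,
         recovery_tau = recovery_tau, noise_sd = noise_sd,
         n_optodes = as.integer(n_optodes), rest_s = rest_s,
         recovery_s = recovery_s),
    class = "nirs_kinetics"
  )
}

#' Simulate a 10 Hz three-optode NIRS trace
#'
#' Exercise mode: flat rest, then a monotone O2Hb decline and HHb rise over
#' the exercise phase (shape `frac^shape`), then exponential recovery toward
#' baseline. Occlusion mode: flat rest, linear drift during occlusion (O2Hb
#' down, HHb up), exponential recovery; pair with the 5/5/3-min protocol by
#' using `duration_s = 300` and the default rest/recovery lengths via
#' `nirs_kinetics(rest_s = 300, recovery_s = 180)`.
#'
#' @param duration_s Length of the exercise/occlusion phase, s (> 60).
#' @param phase `"exercise"` or `"occlusion"` (the middle-phase label).
#' @param kinetics A [nirs_kinetics()] parameter set.
#' @param seed Optional seed; fixed seed gives an identical trace.
#' @return Tidy trace tibble: `time_s`, `phase`, `optode`, `O2Hb`, `HHb`.
#' @export
generate_nirs_trace <- function(duration_s, phase = c("exercise", "occlusion"),
                                kinetics = nirs_kinetics(), seed = NULL) {
  if (!is.character(phase) || !all(phase %in% c("exercise", "occlusion"))) {
    abort("`phase` must be \"exercise\" or \"occlusion\".",
          class = "erythroflux_invalid_parameter")
  }
  phase <- match.arg(phase)
  check_number(duration_s, "duration_s", lower = 60 + 1e-9)
  k <- kinetics
  stopifnot(inherits(k, "nirs_kinetics"))
  with_seed(seed, {
    t_all <- seq(0, k$rest_s + duration_s + k$recovery_s - 0.1, by = 0.1)
    ph <- ifelse(t_all < k$rest_s, "rest",
                 ifelse(t_all < k$rest_s + duration_s, phase, "recovery"))
    frac <- pmin(pmax((t_all - k$rest_s) / duration_s, 0), 1)
    trend <- if (phase == "exercise") frac^k$shape else frac # occlusion: linear
    o2 <- k$o2hb_baseline - k$o2hb_amp * trend
    hh <- k$hhb_baseline + k$hhb_amp * trend
    rec <- ph == "recovery"
    dt_rec <- t_all[rec] - (k$rest_s + duration_s)
    decay <- exp(-dt_rec / k$recovery_tau)
    o2[rec] <- k$o2hb_baseline - k$o2hb_amp * decay
    hh[rec] <- k$hhb_baseline + k$hhb_amp * decay
    purrr::map_dfr(seq_len(k$n_optodes), function(op) {
      tibble(time_s = t_all, phase = ph, optode = op,
             O2Hb = o2 + rnorm(length(t_all), 0, k$noise_sd),
             HHb = hh + rnorm(length(t_all), 0, k$noise_sd))
    })
  })
}
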