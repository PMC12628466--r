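#' Functional (cell-bound) hemoglobin after hemolysis
#'
#' Hemolysis releases hemoglobin into plasma where it no longer carries
#' oxygen; functional hemoglobin is the total minus the plasma fraction
#' (e.g. 150 g/L total minus 0.02 g/L plasma = 149.98 g/L). Units are
#' caller-declared; both arguments must share them.
#'
#' @param total_hb Total hemoglobin (vectorized, >= 0).
#' @param plasma_hb Plasma (free) hemoglobin, same units, `0 <= plasma_hb <=
#'   total_hb`.
#' @return `total_hb - plasma_hb`.
#' @export
functional_hb <- function(total_hb, plasma_hb) {
  if (!is.numeric(total_hb) || !is.numeric(plasma_hb) ||
      any(!is.finite(total_hb)) || any(!is.finite(plasma_hb)) ||
      any(total_hb < 0) || any(plasma_hb < 0)) {
    abort("Hemoglobin values must be finite and >= 0.",
          class = "erythroflux_invalid_panel")
  }
  if (any(plasma_hb > total_hb)) {
    abort("`plasma_hb` cannot exceed `total_hb`.",
          class = "erythroflux_invalid_panel")
  }
  total_hb - plasma_hb
}

#' Methemoglobin as a percentage of total hemoglobin
#'
#' Methemoglobin (Fe3+) cannot bind oxygen; the physiologically relevant
#' metric is its share of total hemoglobin. Scale-invariant as long as both
#' arguments share units.
#'
#' @param methb Methemoglobin (vectorized, >= 0, same units as `total_hb`).
#' @param total_hb Total hemoglobin (> 0).
#' @return `100 * methb / total_hb` (percent).
#' @export
methb_percent <- function(methb, total_hb) {
  if (!is.numeric(methb) || !is.numeric(total_hb) ||
      any(!is.finite(methb)) || any(!is.finite(total_hb)) || any(methb < 0)) {
    abort("Hemoglobin values must be finite and >= 0.",
          class = "erythroflux_invalid_panel")
  }
  if (any(total_hb <= 0)) {
    abort("`total_hb` must be > 0.", class = "erythroflux_undefined_ratio")
  }
  100 * methb / total_hb
}

run_stage <- function(name, expr) {
  tryCatch(list(status = "ok", result = expr),
           error = function(e) list(status = "failed",
                                    error = conditionMessage(e)))
}

#' Run the full analysis pipeline on a (simulated) study
#'
#' Orchestrates every stage over one dataset: flux estimation and
#' timecourse summary, the three stoichiometric scenario presets, p50 per
#' blood-gas panel with the pre vs post-0 shift, NIRS exercise summaries,
#' and the hemoglobin audits. Stages run independently: a failing stage is
#' marked `"failed"` in the report and the rest still run.
#'
#' @param study A `synthetic_study` from [generate_study()], or `NULL` to
#'   simulate one here.
#' @param design,effects Used only when `study` is `NULL`.
#' @param seed Convenience override of `design$seed` when simulating.
#' @return A list of class `pipeline_report` with one block per stage plus
#'   `meta` (package version, seed, design sizes, timestamp). Serialize
#'   with [write_report()]; reports from the same seed are identical apart
#'   from the timestamp.
#' @examples
#' rep <- run_pipeline(seed = 1)
#' rep$stoichiometry$result$control
#' @export
run_pipeline <- function(study = NULL, design = study_design(),
                         effects = effect_sizes(), seed = NULL) {
  if (is.null(study)) {
    if (!is.null(seed)) design$seed <- as.integer(seed)
    study <- generate_study(design, effects)
  }
  meta <- list(
    package = "erythroflux",
    version = as.character(utils::packageVersion("erythroflux")),
    seed = study$truth$design$seed,
    n_participants = study$truth$design$n_participants,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  flux <- run_stage("flux", {
    est <- estimate_fluxes(study$lactate,
                           .by = c("participant", "condition", "timepoint"))
    list(estimates = est,
         timecourse = summarize_timecourse(
           est, timepoint_levels = study$truth$design$timepoints))
  })

  stoich <- run_stage("stoichiometry", {
    purrr::map(setNames(nm = c("control", "oxidative_stress", "exercise")),
               function(p) {
                 y <- compute_yields(scenario_preset(p))
                 out <- as.list(glance(y))
                 out$carbon_residual <- carbon_balance(y)$residual
                 if (!is.null(attr(y, "discrepancy"))) {
                   out$note <- attr(y, "discrepancy")
                 }
                 out
               })
  })

  odc <- run_stage("odc", {
    tbl <- add_p50(study$bloodgas)
    cells <- summarise(tbl, p50 = mean(.data$p50),
                       .by = c("condition", "timepoint"))
    shift <- tidyr::pivot_wider(
      filter(cells, .data$timepoint %in% c("pre", "post0")),
      names_from = "timepoint", values_from = "p50")
    shift <- mutate(shift, delta_p50 = .data$post0 - .data$pre,
                    shift = ifelse(.data$delta_p50 > 0, "right shift",
                                   ifelse(.data$delta_p50 < 0, "left shift", "no shift")))
    list(p50_cells = cells, pre_post_shift = shift)
  })

  nirs <- run_stage("nirs", {
    if (is.null(study$nirs)) {
      abort("Study carries no NIRS table (generated with include_nirs = FALSE).")
    }
    study$nirs |>
      tidyr::nest(trace = -c("participant", "condition", "limb")) |>
      mutate(summary = purrr::map(.data$trace, function(tr) {
        nirs_exercise_summary(optode_average(tr))
      })) |>
      select(-"trace") |>
      tidyr::unnest("summary") |>
      summarise(O2Hb = mean(.data$O2Hb), HHb = mean(.data$HHb),
                tHb = mean(.data$tHb), .by = c("condition", "point"))
  })

  hb <- run_stage("hb", {
    mutate(
      select(study$bloodgas, "participant", "condition", "timepoint",
             "total_hb", "plasma_hb", "methb"),
      functional_hb = functional_hb(.data$total_hb, .data$plasma_hb),
      methb_pct = methb_percent(.data$methb, .data$total_hb)
    ) |>
      summarise(functional_hb = mean(.data$functional_hb),
                methb_pct = mean(.data$methb_pct),
                .by = c("condition", "timepoint"))
  })

  structure(
    list(meta = meta, flux = flux, stoichiometry = stoich, odc = odc,
         nirs = nirs, hb = hb),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %s, %s participants\n",
              x$meta$seed, x$meta$n_participants))
  for (stage in setdiff(names(x), "meta")) {
    cat(sprintf("  %-14s %s\n", stage, x[[stage]]$status))
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' One machine-readable document with one block per stage; tibbles become
#' arrays of records. Two runs under the same seed produce byte-identical
#' files apart from the `meta$timestamp` field.
#'
#' @param report A `pipeline_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
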