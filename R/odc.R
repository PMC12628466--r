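# Revised hemoglobin-O2 dissociation model (Dash-Bassingthwaighte family,
# 2016 parameterization): p50 is the standard constant plus additive
# polynomial corrections in pH, pCO2, 2,3-BPG and temperature; saturation is
# a Hill curve with a pO2-dependent exponent.
.odc_const <- list(
  p50_std = 26.8,    # mmHg at the standard state
  ph_std = 7.40,     # plasma pH
  pco2_std = 40,     # mmHg
  dpg_std = 4.65e-3, # mol/L (4.65 mM)
  temp_std = 37,     # degC
  hill_alpha = 2.82,
  hill_beta = 1.20,
  hill_gamma = 29.25, # mmHg
  # validity box; states outside get a warning, not an error
  range = list(ph = c(6.8, 7.8), pco2 = c(5, 120), dpg = c(1, 10), temp = c(30, 43))
)

#' Blood-gas and effector state for the oxygen dissociation curve
#'
#' Bundles one participant-condition-timepoint effector panel. Defaults are
#' the model's standard state (arterial pO2 100 mmHg, pCO2 40 mmHg, plasma
#' pH 7.40, 2,3-BPG 4.65 mM, 37 degC).
#'
#' @param po2 Partial pressure of oxygen, mmHg (>= 0).
#' @param pco2 Partial pressure of carbon dioxide, mmHg (>= 0).
#' @param ph Plasma pH (6.5-8.0).
#' @param dpg 2,3-bisphosphoglycerate concentration, mM (>= 0). Callers
#'   assaying 2,3-BPG in other units must convert to mM first.
#' @param temp Blood temperature, degC (30-44).
#' @param hct Hematocrit fraction in (0, 1).
#' @param hb Hemoglobin concentration, g/dL.
#' @return A list of class `blood_gas_state`.
#' @export
blood_gas_state <- function(po2 = 100, pco2 = 40, ph = 7.40, dpg = 4.65,
                            temp = 37, hct = 0.45, hb = 15) {
  check_number(po2, "po2", lower = 0)
  check_number(pco2, "pco2", lower = 0)
  check_number(ph, "ph", lower = 6.5, upper = 8.0)
  check_number(dpg, "dpg", lower = 0)
  check_number(temp, "temp", lower = 30, upper = 44)
  check_number(hct, "hct", lower = 1e-6, upper = 1 - 1e-6)
  check_number(hb, "hb", lower = 0)
  structure(list(po2 = po2, pco2 = pco2, ph = ph, dpg = dpg,
                 temp = temp, hct = hct, hb = hb),
            class = "blood_gas_state")
}

#' @export
print.blood_gas_state <- function(x, ...) {
  cat(sprintf(
    "<blood_gas_state> pO2 %g mmHg | pCO2 %g mmHg | pH %g | 2,3-BPG %g mM | %g degC\n",
    x$po2, x$pco2, x$ph, x$dpg, x$temp))
  invisible(x)
}

# vectorized core: p50 (mmHg) from effectors; dpg in mM
p50_from_effectors <- function(ph, pco2, dpg, temp) {
  k <- .odc_const
  dph <- ph - k$ph_std
  dco2 <- pco2 - k$pco2_std
  ddpg <- dpg * 1e-3 - k$dpg_std # to mol/L
  dt <- temp - k$temp_std
  k$p50_std +
    (-25.535 * dph + 10.646 * dph^2 - 1.764 * dph^3) +
    (1.273e-1 * dco2 + 1.083e-4 * dco2^2) +
    (795.633533 * ddpg - 19660.8947 * ddpg^2) +
    (1.435 * dt + 4.163e-2 * dt^2 + 6.86e-4 * dt^3)
}

#' p50 adjusted for pH, pCO2, 2,3-BPG and temperature
#'
#' Computes the oxygen half-saturation pressure from the closed-form
#' correction polynomials of the revised dissociation-curve model: the
#' standard p50 of 26.8 mmHg plus additive terms in the deviations of plasma
#' pH (from 7.40), pCO2 (from 40 mmHg), 2,3-BPG (from 4.65 mM) and
#' temperature (from 37 degC). Lower pH, and higher pCO2, 2,3-BPG or
#' temperature, all raise p50 (right-shift the curve).
#'
#' States outside the model's validity box (pH 6.8-7.8, pCO2 5-120 mmHg,
#' 2,3-BPG 1-10 mM, 30-43 degC) return a value with an `out_of_range`
#' attribute and a warning, since post-exercise states sit near the edge.
#'
#' @param state A [blood_gas_state()].
#' @return p50 in mmHg.
#' @examples
#' p50_adjusted(blood_gas_state())                    # 26.8 at standard state
#' p50_adjusted(blood_gas_state(temp = 38.5))         # right shift with fever/exercise
#' @export
p50_adjusted <- function(state) {
  stopifnot(inherits(state, "blood_gas_state"))
  p50 <- p50_from_effectors(state$ph, state$pco2, state$dpg, state$temp)
  rg <- .odc_const$range
  oor <- character(0)
  if (state$ph < rg$ph[1] || state$ph > rg$ph[2]) oor <- c(oor, "ph")
  if (state$pco2 < rg$pco2[1] || state$pco2 > rg$pco2[2]) oor <- c(oor, "pco2")
  if (state$dpg < rg$dpg[1] || state$dpg > rg$dpg[2]) oor <- c(oor, "dpg")
  if (state$temp < rg$temp[1] || state$temp > rg$temp[2]) oor <- c(oor, "temp")
  if (length(oor)) {
    warn(paste0("Blood-gas state outside the model's validity range for: ",
                paste(oor, collapse = ", "), ". p50 is an extrapolation."),
         class = "erythroflux_out_of_range")
    attr(p50, "out_of_range") <- oor
  }
  p50
}

#' Hemoglobin oxygen saturation at a given pO2
#'
#' Hill-type saturation anchored at the state's adjusted p50, with the
#' model's pO2-dependent cooperativity exponent
#' `n(pO2) = 2.82 - 1.20 * 10^(-pO2 / 29.25)`. By construction
#' `hb_saturation(p50_adjusted(state), state) == 0.5`, saturation at 0 mmHg
#' is 0, and the curve rises monotonically toward 1.
#'
#' @param po2 Partial pressure of oxygen, mmHg (vectorized, >= 0).
#' @param state A [blood_gas_state()].
#' @return Fractional saturation in `[0, 1]`.
#' @export
hb_saturation <- function(po2, state) {
  stopifnot(inherits(state, "blood_gas_state"))
  if (!is.numeric(po2) || any(!is.finite(po2)) || any(po2 < 0)) {
    abort("`po2` must be finite and >= 0.", class = "erythroflux_invalid_parameter")
  }
  p50 <- suppressWarnings(p50_adjusted(state))
  k <- .odc_const
  n <- k$hill_alpha - k$hill_beta * 10^(-po2 / k$hill_gamma)
  x <- (po2 / p50)^n
  x / (1 + x)
}

#' Oxygen dissociation curve over a pO2 grid
#'
#' @param state A [blood_gas_state()].
#' @param po2_grid Increasing vector of pO2 values, mmHg; default 0-150.
#' @return A tibble of class `odc_curve` with columns `po2` and
#'   `saturation`, and attributes `p50` and `state`.
#' @examples
#' curve <- build_odc_curve(blood_gas_state())
#' attr(curve, "p50")
#' @export
build_odc_curve <- function(state, po2_grid = seq(0, 150, by = 0.5)) {
  stopifnot(inherits(state, "blood_gas_state"))
  if (length(po2_grid) == 0) {
    abort("`po2_grid` must be non-empty.", class = "erythroflux_invalid_parameter")
  }
  if (is.unsorted(po2_grid, strictly = FALSE)) {
    abort("`po2_grid` must be increasing.", class = "erythroflux_invalid_parameter")
  }
  out <- tibble(po2 = as.numeric(po2_grid),
                saturation = hb_saturation(po2_grid, state))
  attr(out, "p50") <- suppressWarnings(p50_adjusted(state))
  attr(out, "state") <- state
  class(out) <- c("odc_curve", class(out))
  out
}

#' p50 difference between two blood-gas states
#'
#' @param state_a,state_b [blood_gas_state()] objects; the difference is
#'   `p50(state_b) - p50(state_a)`, so a positive value means `state_b` is
#'   right-shifted (lower oxygen affinity) relative to `state_a`.
#' @return A one-row tibble with `p50_a`, `p50_b`, `delta_p50` (mmHg) and a
#'   `shift` label (`"right shift"`, `"left shift"`, `"no shift"`).
#' @export
delta_p50 <- function(state_a, state_b) {
  pa <- suppressWarnings(p50_adjusted(state_a))
  pb <- suppressWarnings(p50_adjusted(state_b))
  d <- as.numeric(pb) - as.numeric(pa)
  tibble(
    p50_a = as.numeric(pa), p50_b = as.numeric(pb), delta_p50 = d,
    shift = if (d > 0) "right shift" else if (d < 0) "left shift" else "no shift"
  )
}

#' Add adjusted p50 to a blood-gas table
#'
#' Data-frame interface to [p50_adjusted()]: expects columns `ph`, `pco2`,
#' `dpg` (mM) and `temp` and appends a `p50` column.
#'
#' @param data A data frame of blood-gas panels.
#' @return `data` as a tibble with a `p50` column (mmHg).
#' @export
add_p50 <- function(data) {
  need <- c("ph", "pco2", "dpg", "temp")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "erythroflux_invalid_parameter")
  }
  mutate(as_tibble(data),
         p50 = p50_from_effectors(.data$ph, .data$pco2, .data$dpg, .data$temp))
}
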