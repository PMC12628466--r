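# Independent oracles, deliberately written without reusing package internals.

# closed-form simple-regression solution from the normal equations
ols_oracle <- function(t, y) {
  n <- length(t)
  st <- sum(t); sy <- sum(y); stt <- sum(t * t); sty <- sum(t * y)
  slope <- (n * sty - st * sy) / (n * stt - st * st)
  intercept <- (sy - slope * st) / n
  res <- y - intercept - slope * t
  sse <- sum(res^2)
  sxx <- stt - st^2 / n
  se <- sqrt(sse / (n - 2) / sxx)
  sst <- sum((y - sy / n)^2)
  r2 <- if (sst < 1e-12) 1 else 1 - sse / sst
  list(slope = slope, intercept = intercept, se = se, r2 = r2)
}

# second transcription of the revised p50 correction polynomials
# (standard state: pH 7.40, pCO2 40 mmHg, DPG 4.65 mM, 37 degC; p50 26.8)
p50_oracle <- function(ph, pco2, dpg_mM, temp) {
  x <- ph - 7.40
  term_ph <- (-25.535) * x + 10.646 * x * x + (-1.764) * x * x * x
  z <- pco2 - 40
  term_co2 <- 0.1273 * z + 0.0001083 * z * z
  w <- dpg_mM / 1000 - 0.00465
  term_dpg <- 795.633533 * w + (-19660.8947) * w * w
  u <- temp - 37
  term_t <- 1.435 * u + 0.04163 * u * u + 0.000686 * u * u * u
  26.8 + term_ph + term_co2 + term_dpg + term_t
}

sat_oracle <- function(po2, p50) {
  nh <- 2.82 - 1.20 * 10^(-po2 / 29.25)
  r <- (po2 / p50)^nh
  r / (1 + r)
}

# brute-force mean over samples falling in a window; explicit loop
window_mean_oracle <- function(time_s, x, lo, hi, include_lo = FALSE) {
  tot <- 0; cnt <- 0
  for (i in seq_along(time_s)) {
    inside <- if (include_lo) {
      time_s[i] >= lo - 1e-6 && time_s[i] <= hi + 1e-6
    } else {
      time_s[i] > lo + 1e-6 && time_s[i] <= hi + 1e-6
    }
    if (inside) {
      tot <- tot + x[i]
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

# assemble a single-signal trace tibble from per-phase sample values
make_trace <- function(rest_s = 300, mid_s = 600, rec_s = 180,
                       mid_label = "exercise",
                       o2hb = function(t) rep(0, length(t)),
                       hhb = function(t) rep(0, length(t))) {
  t <- seq(0, rest_s + mid_s + rec_s - 0.1, by = 0.1)
  phase <- ifelse(t < rest_s, "rest",
                  ifelse(t < rest_s + mid_s, mid_label, "recovery"))
  tibble::tibble(time_s = t, phase = phase, O2Hb = o2hb(t), HHb = hhb(t))
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
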