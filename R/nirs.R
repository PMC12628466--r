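# NIRS traces are tidy tibbles sampled at 10 Hz with columns:
#   time_s, phase ("rest", "exercise" or "occlusion", "recovery"),
#   optode (optional, before averaging), O2Hb, HHb  [uM]
# All reductions are window means; the window convention throughout is a
# trailing 30 s window ending at the reporting point, mirroring the
# last-30-s baseline rule.

nirs_window_s <- 30

check_trace <- function(trace, need_optode = FALSE) {
  trace <- as_tibble(trace)
  need <- c("time_s", "phase", "O2Hb", "HHb")
  if (need_optode) need <- c(need, "optode")
  missing_cols <- setdiff(need, names(trace))
  if (length(missing_cols)) {
    abort(paste0("NIRS trace lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "erythroflux_invalid_parameter")
  }
  trace
}

phase_span <- function(trace, phase) {
  t <- trace$time_s[trace$phase == phase]
  if (!length(t)) return(NULL)
  c(min(t), max(t))
}

# mean of a signal over samples in the half-open window (t_end - 30, t_end]
# (300 samples at 10 Hz); when the window would reach before `floor_s` (the
# phase start) it is clipped to [floor_s, t_end]
trailing_mean <- function(time_s, x, t_end, floor_s = -Inf) {
  lo <- t_end - nirs_window_s
  eps <- 1e-6
  sel <- if (lo < floor_s) time_s >= floor_s - eps else time_s > lo + eps
  sel <- sel & time_s <= t_end + eps
  mean(x[sel])
}

#' Average a multi-optode NIRS trace into one signal per chromophore
#'
#' The device carries three optode sources at different interoptode
#' distances; analyses use their pointwise arithmetic mean.
#'
#' @param trace Tidy trace with columns `time_s`, `phase`, `optode`,
#'   `O2Hb`, `HHb` (plus any metadata columns, which are kept).
#' @return The trace collapsed over `optode` (one row per sample).
#' @export
optode_average <- function(trace) {
  trace <- check_trace(trace, need_optode = TRUE)
  counts <- summarise(trace, n = dplyr::n(), .by = "optode")
  if (length(unique(counts$n)) != 1L) {
    abort("Optodes have mismatched lengths; cannot align samples.",
          class = "erythroflux_alignment_error")
  }
  meta <- setdiff(names(trace), c("optode", "O2Hb", "HHb"))
  summarise(trace, O2Hb = mean(.data$O2Hb), HHb = mean(.data$HHb),
            .by = dplyr::all_of(meta))
}

#' Baseline value from the final 30 s of rest
#'
#' @param trace Single-signal trace (see [optode_average()]).
#' @return One-row tibble with `O2Hb`, `HHb` and `tHb = O2Hb + HHb` (uM).
#' @export
nirs_baseline <- function(trace) {
  trace <- check_trace(trace)
  span <- phase_span(trace, "rest")
  if (is.null(span) || diff(span) < nirs_window_s - 1e-9) {
    abort("Rest phase shorter than 30 s; cannot extract a baseline.",
          class = "erythroflux_insufficient_baseline")
  }
  rest <- trace[trace$phase == "rest", ]
  o2 <- trailing_mean(rest$time_s, rest$O2Hb, span[2], floor_s = span[1])
  hh <- trailing_mean(rest$time_s, rest$HHb, span[2], floor_s = span[1])
  tibble(O2Hb = o2, HHb = hh, tHb = o2 + hh)
}

#' Decile bins over the exercise phase
#'
#' Because exhaustion times differ between participants, the exercise phase
#' is normalized to ten 10%-of-duration reporting points; the value at the
#' k-th point is the mean over the 30 s window ending at `start + k/10 *
#' duration` (clipped at the exercise start; the final bin ends at the last
#' exercise sample).
#'
#' @param trace Single-signal trace.
#' @param windows `"trailing"` (default; window ends at the decile point) or
#'   `"centered"` (window centered on it, clipped to the phase).
#' @return Tibble with 10 rows: `bin` (1-10), `pct_duration`, `t_end`,
#'   `O2Hb`, `HHb`, `tHb`.
#' @export
nirs_decile_bins <- function(trace, windows = c("trailing", "centered")) {
  windows <- match.arg(windows)
  trace <- check_trace(trace)
  span <- phase_span(trace, "exercise")
  if (is.null(span) || diff(span) < 60) {
    abort("Exercise phase shorter than 60 s; decile binning is infeasible.",
          class = "erythroflux_infeasible_binning")
  }
  ex <- trace[trace$phase == "exercise", ]
  dur <- span[2] - span[1]
  ends <- span[1] + (1:10) / 10 * dur
  purrr::map_dfr(1:10, function(k) {
    t_end <- ends[k]
    if (windows == "trailing") {
      o2 <- trailing_mean(ex$time_s, ex$O2Hb, t_end, floor_s = span[1])
      hh <- trailing_mean(ex$time_s, ex$HHb, t_end, floor_s = span[1])
    } else {
      lo <- max(t_end - nirs_window_s / 2, span[1])
      hi <- min(t_end + nirs_window_s / 2, span[2])
      sel <- ex$time_s >= lo - 1e-9 & ex$time_s <= hi + 1e-9
      o2 <- mean(ex$O2Hb[sel]); hh <- mean(ex$HHb[sel])
    }
    tibble(bin = k, pct_duration = 10 * k, t_end = t_end,
           O2Hb = o2, HHb = hh, tHb = o2 + hh)
  })
}

nirs_recovery_points <- function(trace, mid_phase) {
  span_mid <- phase_span(trace, mid_phase)
  rec <- trace[trace$phase == "recovery", ]
  if (!nrow(rec)) {
    abort("Trace has no recovery phase.", class = "erythroflux_invalid_parameter")
  }
  t0 <- span_mid[2] # release / exhaustion
  purrr::map_dfr(c(60, 90, 120), function(s) {
    o2 <- trailing_mean(rec$time_s, rec$O2Hb, t0 + s, floor_s = min(rec$time_s))
    hh <- trailing_mean(rec$time_s, rec$HHb, t0 + s, floor_s = min(rec$time_s))
    tibble(recovery_s = s, O2Hb = o2, HHb = hh, tHb = o2 + hh)
  })
}

#' Full reduction of an incremental-exercise NIRS trace
#'
#' Combines [nirs_baseline()], [nirs_decile_bins()] and recovery values at
#' 60/90/120 s after exhaustion (30 s trailing-window means measured from
#' the end of exercise) into one long summary.
#'
#' @inheritParams nirs_decile_bins
#' @return Tibble of class `nirs_summary` with columns `point`
#'   (`"baseline"`, `"p10"`..`"p100"`, `"rec60"`, `"rec90"`, `"rec120"`),
#'   `O2Hb`, `HHb`, `tHb`.
#' @export
nirs_exercise_summary <- function(trace, windows = c("trailing", "centered")) {
  trace <- check_trace(trace)
  base <- nirs_baseline(trace)
  bins <- nirs_decile_bins(trace, windows)
  rec <- nirs_recovery_points(trace, "exercise")
  out <- bind_rows(
    tibble(point = "baseline", O2Hb = base$O2Hb, HHb = base$HHb, tHb = base$tHb),
    tibble(point = paste0("p", bins$pct_duration), O2Hb = bins$O2Hb,
           HHb = bins$HHb, tHb = bins$tHb),
    tibble(point = paste0("rec", rec$recovery_s), O2Hb = rec$O2Hb,
           HHb = rec$HHb, tHb = rec$tHb)
  )
  class(out) <- c("nirs_summary", class(out))
  attr(out, "mode") <- "exercise"
  out
}

#' Reduction of a vascular-occlusion NIRS trace
#'
#' The occlusion protocol is 5 min rest, 5 min arterial occlusion, 3 min
#' recovery. Reported values: baseline (last 30 s of rest), minute-wise
#' occlusion values (30 s windows ending at minutes 1-5 of occlusion) and
#' recovery at 60/90/120 s after cuff release.
#'
#' @param trace Single-signal trace whose middle phase is labelled
#'   `"occlusion"`.
#' @param tolerance Fractional tolerance on the 5/5/3 min phase lengths
#'   (default 0.05); a mismatch beyond it is a protocol error.
#' @return Tibble of class `nirs_summary` with `point` values `"baseline"`,
#'   `"occ1"`..`"occ5"`, `"rec60"`, `"rec90"`, `"rec120"`.
#' @export
nirs_occlusion_summary <- function(trace, tolerance = 0.05) {
  trace <- check_trace(trace)
  expected <- c(rest = 300, occlusion = 300, recovery = 180)
  for (ph in names(expected)) {
    span <- phase_span(trace, ph)
    if (is.null(span)) {
      abort(sprintf("Occlusion trace lacks a '%s' phase.", ph),
            class = "erythroflux_protocol_error")
    }
    len <- diff(span)
    if (abs(len - expected[[ph]]) > tolerance * expected[[ph]]) {
      abort(sprintf("Phase '%s' lasts %.1f s; protocol expects %.0f s (tolerance %.0f%%).",
                    ph, len, expected[[ph]], 100 * tolerance),
            class = "erythroflux_protocol_error")
    }
  }
  base <- nirs_baseline(trace)
  occ <- trace[trace$phase == "occlusion", ]
  occ_span <- phase_span(trace, "occlusion")
  mins <- purrr::map_dfr(1:5, function(m) {
    t_end <- occ_span[1] + 60 * m
    o2 <- trailing_mean(occ$time_s, occ$O2Hb, t_end, floor_s = occ_span[1])
    hh <- trailing_mean(occ$time_s, occ$HHb, t_end, floor_s = occ_span[1])
    tibble(minute = m, O2Hb = o2, HHb = hh, tHb = o2 + hh)
  })
  rec <- nirs_recovery_points(trace, "occlusion")
  out <- bind_rows(
    tibble(point = "baseline", O2Hb = base$O2Hb, HHb = base$HHb, tHb = base$tHb),
    tibble(point = paste0("occ", mins$minute), O2Hb = mins$O2Hb,
           HHb = mins$HHb, tHb = mins$tHb),
    tibble(point = paste0("rec", rec$recovery_s), O2Hb = rec$O2Hb,
           HHb = rec$HHb, tHb = rec$tHb)
  )
  class(out) <- c("nirs_summary", class(out))
  attr(out, "mode") <- "occlusion"
  out
}
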