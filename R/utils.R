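# internal validation helpers

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "erythroflux_invalid_parameter")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(lower), format(upper)),
          class = "erythroflux_invalid_parameter")
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name),
          class = "erythroflux_invalid_parameter")
  }
  invisible(x)
}

# local, restorable RNG: functions taking a `seed` argument never disturb the
# caller's .Random.seed
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_number(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
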