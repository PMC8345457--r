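#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("half-up") rounding, as used when echoing derived dose-response
#' coefficients at a fixed printed precision. Base [round()] rounds half to
#' even, which differs exactly at the midpoints that matter here (e.g. 0.03125
#' at four decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.03125, 4) # 0.0313
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config("%s must lie in [0, 1], got %s", what,
                paste(format(x), collapse = ", "))
  invisible(x)
}

# Deterministic 31-bit sub-stream seed for (run seed, nest id). Keeps nests
# independent: adding a nest never perturbs the draws of the others.
nest_seed <- function(seed, nest_id) {
  h <- 0
  for (k in utf8ToInt(as.character(nest_id))) h <- (h * 131 + k) %% 1013904223
  as.integer((abs(seed) %% 2147480000 + h * 7919) %% 2147483629)
}

# Calendar month (1..12) of a 0-based 30-day month block for a simulation
# starting in `start_month`.
month_of_year <- function(month_block, start_month) {
  ((start_month - 1 + month_block) %% 12) + 1
}
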