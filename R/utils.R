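# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding with ties going upward (0.5 -> 1), the convention used
#' in the rendered report tables.  Base [round()] uses round-half-even,
#' which prints e.g. 24.5 as 24.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a share of a total as a percentage
#'
#' @param n Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places kept.
#' @param rounding `"half_up"` rounds ties upward; `"down"` truncates
#'   toward zero.  Published flow figures mix both conventions, so the
#'   choice is explicit.
#' @return Numeric percentage on the 0-100 scale.
#' @export
flow_percent <- function(n, total, digits = 1,
                         rounding = c("half_up", "down")) {
  rounding <- match.arg(rounding)
  if (total <= 0) stop("flow_percent(): 'total' must be positive")
  pct <- n / total * 100
  if (rounding == "half_up") {
    round_half_up(pct, digits)
  } else {
    trunc(pct * 10^digits) / 10^digits
  }
}

# Deterministic sub-seed for a named generation stage.  Labels partition the
# RNG so that adding a stage never perturbs draws of earlier stages.  Plain
# polynomial string hash folded into the 31-bit seed range.
stage_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

# Consistent "named field failed validation" error.
check_fraction <- function(x, field, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    stop(sprintf("invalid scenario parameter '%s': must be a fraction in [0,1%s)",
                 field, if (allow_one) "]" else ""), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !is.finite(x)) {
    stop(sprintf("invalid scenario parameter '%s': must be finite and >= 0", field),
         call. = FALSE)
  }
  invisible(x)
}
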