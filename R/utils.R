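# internal helpers shared across modules

# round-half-up at `digits` decimals; base round() uses banker's rounding,
# which does not reproduce printed table percentages
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Kish effective sample size
#'
#' `(sum w)^2 / sum(w^2)`: the number of equally-weighted observations that
#' would carry the same information as the weighted sample. Used to report
#' pseudo-population sizes after inverse-probability weighting.
#'
#' @param w nonnegative numeric weights.
#' @return A single number in `[0, length(w)]`.
#' @export
kish_ess <- function(w) {
  stopifnot(is.numeric(w), all(w >= 0))
  w <- w[w > 0]
  if (length(w) == 0) return(0)
  sum(w)^2 / sum(w^2)
}

# weighted mean / variance, frequency-weight convention:
# var = sum(w (x - m)^2) / (sum(w) - 1)
wtd_mean <- function(x, w) sum(w * x) / sum(w)

wtd_var <- function(x, w) {
  sw <- sum(w)
  if (sw <= 1) stop("sum of weights must exceed 1 for the variance to be defined")
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / (sw - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
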