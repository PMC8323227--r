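## Binary-outcome MR power and minimum-detectable-OR inversion (the mRnd
## non-centrality-parameter approach).

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Implements the mRnd binary-outcome approximation. With case fraction
#' `K = n_cases/N` and true odds ratio `OR`, the attenuated mean shift is
#' `b = K * (OR/(1 + K*(OR - 1)) - 1)`, the estimator variance is
#' `v = (K*(1 - K) - b^2)/(N * R2)` where `R2` is the exposure variance
#' explained by the instruments, and the power is the upper-tail
#' probability of a chi-square(1, ncp = b^2/v) beyond the central
#' chi-square (1 - alpha) quantile. At `OR = 1` the power equals `alpha`
#' exactly.
#'
#' @param or_true true odds ratio per 1-SD exposure increase (> 0).
#' @param n_cases,n_controls design case and control counts.
#' @param r2 instrument variance explained on the exposure.
#' @param alpha significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @examples
#' mrPowerBinary(1.45, n_cases = 2120, n_controls = 454228, r2 = 0.0187)
#' @export
mrPowerBinary <- function(or_true, n_cases, n_controls, r2, alpha = 0.05) {
  stopifnot(or_true > 0, n_cases > 0, n_controls > 0,
            r2 > 0, r2 < 1, alpha > 0, alpha < 1)
  n <- n_cases + n_controls
  k <- n_cases / n
  b <- k * (or_true / (1 + k * (or_true - 1)) - 1)
  if (b^2 >= k * (1 - k))
    stop("degenerate variance: b^2 >= K(1-K) for OR = ", or_true)
  v <- (k * (1 - k) - b^2) / (n * r2)
  ncp <- b^2 / v
  stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1, ncp = ncp,
                lower.tail = FALSE)
}

#' Power of a two-sample MR analysis with a continuous outcome
#'
#' Normal-approximation power for an effect of `beta` SD of the outcome per
#' SD of the exposure, used for the reverse-direction design where the
#' outcome (e.g. circulating vitamin C) is continuous.
#'
#' @param beta true effect in SD units.
#' @param n outcome sample size.
#' @param r2 instrument variance explained on the exposure.
#' @param alpha significance level.
#' @return Power in `[0, 1]`.
#' @export
mrPowerContinuous <- function(beta, n, r2, alpha = 0.05) {
  stopifnot(n > 0, r2 > 0, r2 < 1, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  se <- 1 / sqrt(n * r2)
  stats::pnorm(abs(beta) / se - z) + stats::pnorm(-abs(beta) / se - z)
}

#' Minimum detectable odds ratios at a target power
#'
#' Inverts [mrPowerBinary()] on a fixed OR grid: `orUpper` is the smallest
#' OR on `{1 + grid_step, 1 + 2*grid_step, ...}` whose power reaches
#' `power_target`, and `orLower` the largest OR below 1 on the mirrored grid
#' doing the same. By construction the bracketing invariant holds: power at
#' each bound is >= the target while one grid step closer to 1 it is not.
#'
#' @inheritParams mrPowerBinary
#' @param power_target target power (default 0.80).
#' @param grid_step OR grid resolution (default 0.01).
#' @return A [MinDetectableOR-class].
#' @examples
#' minDetectableOR(n_cases = 2120, n_controls = 454228, r2 = 0.0187)
#' @export
minDetectableOR <- function(n_cases, n_controls, r2 = 0.0187, alpha = 0.05,
                            power_target = 0.80, grid_step = 0.01) {
  stopifnot(grid_step > 0, power_target > 0, power_target < 1)
  pw <- function(or) mrPowerBinary(or, n_cases, n_controls, r2, alpha)
  or_up <- 1
  repeat {
    or_up <- or_up + grid_step
    if (or_up > 10)
      stop("target power unreachable below OR = 10 for this design")
    if (pw(or_up) >= power_target) break
  }
  or_lo <- 1
  repeat {
    or_lo <- or_lo - grid_step
    if (or_lo < 0.1)
      stop("target power unreachable above OR = 0.1 for this design")
    if (pw(or_lo) >= power_target) break
  }
  new("MinDetectableOR", orLower = or_lo, orUpper = or_up,
      gridStep = grid_step, powerLower = pw(or_lo), powerUpper = pw(or_up))
}
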