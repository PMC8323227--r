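## Random-effects meta-analysis (DerSimonian-Laird) and Egger's
## publication-bias test, used both to combine MR odds ratios across
## datasets and to pool published highest-vs-lowest relative risks.

.META_Z <- 1.959964  # z multiplier used for CI <-> SE conversion

#' Build meta-analysis inputs from published ratio CIs
#'
#' Converts published `point (ci_low - ci_high)` ratio estimates (OR or RR)
#' to the log scale with `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param label study labels.
#' @param point,ci_low,ci_high ratio estimates and 95% CI bounds
#'   (`ci_low < point < ci_high`).
#' @return data.frame with columns `label`, `effect` (log scale), `se`.
#' @examples
#' metaFromCI(c("UKB", "BCAC"), c(1.34, 1.05), c(1.14, 0.94), c(1.57, 1.17))
#' @export
metaFromCI <- function(label, point, ci_low, ci_high) {
  stopifnot(all(ci_low < point), all(point < ci_high), all(ci_low > 0))
  data.frame(label = as.character(label), effect = log(point),
             se = (log(ci_high) - log(ci_low)) / (2 * .META_Z),
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects meta-analysis on the log scale: fixed-effect
#' weights `w = 1/se^2` give Cochran's Q about the fixed-effect mean;
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`; studies are then
#' re-weighted by `1/(se^2 + tau2)` and pooled with a normal 95% CI.
#'
#' @param effect study effects on the log scale (log OR / log RR), or a
#'   data.frame as returned by [metaFromCI()].
#' @param se study standard errors (ignored when `effect` is a data.frame).
#' @return A [MetaResult-class].
#' @examples
#' dlRandomEffects(metaFromCI(c("UKB", "BCAC"), c(1.34, 1.05),
#'                            c(1.14, 0.94), c(1.57, 1.17)))
#' @export
dlRandomEffects <- function(effect, se = NULL) {
  if (is.data.frame(effect)) {
    se <- effect$se
    effect <- effect$effect
  }
  k <- length(effect)
  if (k < 2) stop("meta-analysis needs at least 2 studies")
  stopifnot(length(se) == k, all(se > 0))
  w <- 1 / se^2
  mu_fe <- sum(w * effect) / sum(w)
  q <- sum(w * (effect - mu_fe)^2)
  df <- k - 1L
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * effect) / sum(wr)
  se_p <- sqrt(1 / sum(wr))
  new("MetaResult", pooled = pooled, se = se_p,
      ciLow = pooled - .META_Z * se_p, ciHigh = pooled + .META_Z * se_p,
      tau2 = tau2, q = q, qDf = df, i2 = max(0, (q - df) / q),
      nStudies = as.integer(k))
}

#' Egger's test for funnel-plot asymmetry (publication bias)
#'
#' Regresses the standardized effect `effect/se` on the precision `1/se`;
#' a nonzero intercept indicates small-study (funnel) asymmetry such as
#' one-sided suppression of small null studies.
#'
#' @inheritParams dlRandomEffects
#' @return `list(intercept, se, p)` with a two-sided t-test p-value on
#'   k - 2 df.
#' @export
eggerAsymmetry <- function(effect, se = NULL) {
  if (is.data.frame(effect)) {
    se <- effect$se
    effect <- effect$effect
  }
  k <- length(effect)
  if (k < 3) stop("Egger's test needs at least 3 studies")
  stopifnot(length(se) == k, all(se > 0))
  z <- effect / se
  prec <- 1 / se
  fit <- stats::lm(z ~ prec)
  sm <- summary(fit)
  int <- sm$coefficients["(Intercept)", "Estimate"]
  se_int <- sm$coefficients["(Intercept)", "Std. Error"]
  list(intercept = int, se = se_int,
       p = 2 * stats::pt(-abs(int / se_int), df = k - 2))
}

#' Read meta-analysis inputs from a delimited file
#'
#' Accepts either the CI form (columns `label, point, ci_low, ci_high`) or
#' the log form (columns `label, log_effect, se`).
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame with columns `label`, `effect`, `se`.
#' @export
readMetaInputs <- function(path, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (all(c("label", "point", "ci_low", "ci_high") %in% names(raw)))
    return(metaFromCI(raw$label, raw$point, raw$ci_low, raw$ci_high))
  if (all(c("label", "log_effect", "se") %in% names(raw)))
    return(data.frame(label = raw$label, effect = raw$log_effect,
                      se = raw$se, stringsAsFactors = FALSE))
  stop("meta input needs columns (label, point, ci_low, ci_high) or ",
       "(label, log_effect, se)")
}
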