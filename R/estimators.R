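## The MR estimator battery: random-effects IVW (primary), MR-Egger,
## weighted median, mode-based estimation, MR-PRESSO, robust MM regression,
## and robust adjusted profile score, plus Cochran's Q and multivariable IVW.
##
## Notation: gamma_j / se_exp are the SNP-exposure effects, Gamma_j / se_out
## the SNP-outcome effects of a HarmonizedSet. All per-SNP (Wald) ratio SEs
## are first order (se_out/|gamma|), appropriate for strong instruments.

.Z95 <- stats::qnorm(0.975)

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.mk_est <- function(method, beta, se, n, ...) {
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - .Z95 * se, ciHigh = beta + .Z95 * se,
      pvalue = 2 * stats::pnorm(-abs(beta / se)), nSnps = as.integer(n), ...)
}

.inst <- function(hset) {
  stopifnot(is(hset, "HarmonizedSet"))
  df <- hset@instruments
  if (!nrow(df)) stop("empty harmonized set: nothing to estimate")
  if (any(df$beta_exp == 0))
    stop("undefined Wald ratio: zero SNP-exposure effect for ",
         paste(df$snp_id[df$beta_exp == 0], collapse = ", "))
  df
}

## Per-SNP ratio estimates, first-order SEs, and IVW weights.
.ratios <- function(hset) {
  df <- .inst(hset)
  se_ratio <- df$se_out / abs(df$beta_exp)
  list(snp_id = df$snp_id, ratio = df$beta_out / df$beta_exp,
       se = se_ratio, w = 1 / se_ratio^2)
}

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate `Gamma/gamma` with first-order SE
#' `se_out/|gamma|`.
#'
#' @param hset a [HarmonizedSet-class].
#' @param snp which instrument to use; may be omitted when the set holds
#'   exactly one.
#' @return An [MREstimate-class] with method `"wald"`.
#' @export
waldRatio <- function(hset, snp = NULL) {
  df <- .inst(hset)
  if (!is.null(snp)) df <- df[df$snp_id == snp, , drop = FALSE]
  if (nrow(df) != 1)
    stop("waldRatio needs exactly one instrument (use snp= to pick one)")
  .mk_est("wald", df$beta_out / df$beta_exp, df$se_out / abs(df$beta_exp), 1L)
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of per-SNP ratio estimates about
#' `center`, chi-square distributed on J-1 df under homogeneity.
#'
#' @param ratio per-SNP ratio estimates.
#' @param se their standard errors.
#' @param center the pooled estimate the deviations are taken about.
#' @return `list(q, df, p)`.
#' @export
cochranQ <- function(ratio, se, center) {
  if (length(ratio) < 2) stop("Cochran's Q needs at least 2 estimates")
  stopifnot(length(ratio) == length(se), all(se > 0))
  q <- sum((ratio - center)^2 / se^2)
  df <- length(ratio) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Random-effects inverse-variance-weighted estimate (primary method)
#'
#' IVW combination of Wald ratios with weights `gamma^2/se_out^2`,
#' equivalent to weighted regression of Gamma on gamma through the origin.
#' The random-effects flavor inflates the fixed-effect SE multiplicatively
#' by `sqrt(max(1, Q/(J-1)))`, so heterogeneity widens the CI but
#' homogeneous sets are not rewarded with a shrunken one. With a single
#' instrument this reduces exactly to the Wald ratio.
#'
#' @param hset a [HarmonizedSet-class].
#' @return An [MREstimate-class] with method `"ivw_re"` carrying Q, its df
#'   and p-value (J >= 2).
#' @export
ivwRandomEffects <- function(hset) {
  r <- .ratios(hset)
  J <- length(r$ratio)
  beta <- sum(r$w * r$ratio) / sum(r$w)
  se_fixed <- sqrt(1 / sum(r$w))
  if (J == 1)
    return(.mk_est("ivw_re", beta, se_fixed, 1L))
  qq <- cochranQ(r$ratio, r$se, beta)
  se <- se_fixed * sqrt(max(1, qq$q / qq$df))
  .mk_est("ivw_re", beta, se, J, q = qq$q, qDf = as.numeric(qq$df),
          qP = qq$p)
}

#' MR-Egger regression
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept (weights `1/se_out^2`), after orienting
#' every instrument to a positive exposure effect (the InSiDE convention).
#' The slope is the causal estimate; the intercept estimates the average
#' directional pleiotropy and its test is the Egger pleiotropy test.
#' SEs carry the same multiplicative overdispersion as IVW, on J-2 df.
#'
#' @param hset a [HarmonizedSet-class] with at least 3 instruments.
#' @return An [MREstimate-class] with method `"egger"` and the intercept
#'   slots filled.
#' @export
mrEgger <- function(hset) {
  df <- .inst(hset)
  J <- nrow(df)
  if (J < 3) stop("MR-Egger needs at least 3 instruments")
  s <- sign(df$beta_exp)
  g <- df$beta_exp * s
  G <- df$beta_out * s
  if (stats::var(g) == 0)
    stop("collinear instruments: no spread in exposure effects after orientation")
  w <- 1 / df$se_out^2
  fit <- stats::lm(G ~ g, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  infl <- max(1, sigma)
  slope <- sm$coefficients["g", "Estimate"]
  se_slope <- sm$coefficients["g", "Std. Error"] / sigma * infl
  int <- sm$coefficients["(Intercept)", "Estimate"]
  se_int <- sm$coefficients["(Intercept)", "Std. Error"] / sigma * infl
  q <- sum(w * stats::residuals(fit)^2)
  .mk_est("egger", slope, se_slope, J,
          q = q, qDf = J - 2, qP = stats::pchisq(q, J - 2, lower.tail = FALSE),
          eggerIntercept = int, eggerInterceptSE = se_int,
          eggerInterceptP = 2 * stats::pnorm(-abs(int / se_int)))
}

## Weighted 50th percentile: sort by ratio, take mid-point cumulative
## weights, interpolate linearly at 0.5.
.weighted_median <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(b[1])
  if (0.5 >= cw[length(b)]) return(b[length(b)])
  stats::approx(cw, b, xout = 0.5, ties = "ordered")$y
}

.boot_draws <- function(df, n_boot) {
  J <- nrow(df)
  list(g = matrix(stats::rnorm(n_boot * J, rep(df$beta_exp, each = n_boot),
                               rep(df$se_exp, each = n_boot)), n_boot, J),
       G = matrix(stats::rnorm(n_boot * J, rep(df$beta_out, each = n_boot),
                               rep(df$se_out, each = n_boot)), n_boot, J),
       sy = matrix(rep(df$se_out, each = n_boot), n_boot, J))
}

#' Weighted median estimate
#'
#' The inverse-variance-weighted 50th percentile of the per-SNP ratio
#' estimates; consistent when at least half of the weight comes from valid
#' instruments. The SE is a parametric bootstrap: instrument effects are
#' redrawn from their sampling distributions and the weighted median
#' recomputed.
#'
#' @param hset a [HarmonizedSet-class] with at least 3 instruments.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed RNG seed for the bootstrap (the caller's RNG state is left
#'   untouched).
#' @return An [MREstimate-class] with method `"weighted_median"`.
#' @export
weightedMedian <- function(hset, n_boot = 1000, seed = 1L) {
  if (n_boot < 100) stop("configuration error: n_boot must be >= 100")
  df <- .inst(hset)
  if (nrow(df) < 3) stop("weighted median needs at least 3 instruments")
  r <- .ratios(hset)
  est <- .weighted_median(r$ratio, r$w)
  boot <- .with_seed(seed, {
    d <- .boot_draws(df, n_boot)
    ratio <- d$G / d$g
    w <- d$g^2 / d$sy^2
    vapply(seq_len(n_boot),
           function(i) .weighted_median(ratio[i, ], w[i, ]), numeric(1))
  })
  .mk_est("weighted_median", est, stats::sd(boot), nrow(df))
}

## Mode of the inverse-variance-weighted Gaussian KDE of the ratios.
## Bandwidth: phi x modified Silverman 0.9 * min(sd, mad) * J^(-1/5).
.mbe_point <- function(b, w, phi, grid_n = 512L) {
  if (length(unique(b)) == 1) return(b[1])
  cand <- c(stats::sd(b), stats::mad(b))
  cand <- cand[cand > 0]
  h <- phi * 0.9 * min(cand) * length(b)^(-1 / 5)
  wn <- w / sum(w)
  grid <- seq(min(b) - 2 * h, max(b) + 2 * h, length.out = grid_n)
  dens <- colSums(wn * stats::dnorm(outer(b, grid, "-") / h)) / h
  grid[which.max(dens)]
}

#' Mode-based estimate (MBE)
#'
#' The maximizer of an inverse-variance-weighted Gaussian kernel density
#' over the per-SNP ratio estimates, evaluated on a fine grid spanning the
#' ratio range. Robust to a minority of outlying (pleiotropic) ratios:
#' the estimate tracks the largest cluster of agreeing instruments.
#'
#' @param hset a [HarmonizedSet-class] with at least 3 instruments.
#' @param phi bandwidth multiplier on the modified Silverman rule
#'   `0.9 * min(sd, mad) * J^(-1/5)` (default 1).
#' @param n_boot parametric-bootstrap replicates for the SE.
#' @param seed RNG seed for the bootstrap.
#' @return An [MREstimate-class] with method `"mbe"`.
#' @export
modeBasedEstimate <- function(hset, phi = 1, n_boot = 1000, seed = 1L) {
  if (phi <= 0) stop("phi must be > 0")
  if (n_boot < 100) stop("configuration error: n_boot must be >= 100")
  df <- .inst(hset)
  if (nrow(df) < 3) stop("mode-based estimation needs at least 3 instruments")
  r <- .ratios(hset)
  est <- .mbe_point(r$ratio, r$w, phi)
  boot <- .with_seed(seed, {
    d <- .boot_draws(df, n_boot)
    ratio <- d$G / d$g
    w <- d$g^2 / d$sy^2
    vapply(seq_len(n_boot),
           function(i) .mbe_point(ratio[i, ], w[i, ], phi, grid_n = 256L),
           numeric(1))
  })
  .mk_est("mbe", est, stats::sd(boot), nrow(df))
}

## Leave-one-out IVW estimates from ratio/weight vectors.
.loo_ivw <- function(ratio, w) {
  (sum(w * ratio) - w * ratio) / (sum(w) - w)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global horizontal-pleiotropy test with per-SNP outlier detection.
#' The observed statistic is the weighted residual sum of squares of each
#' SNP-outcome effect about its leave-one-out IVW prediction,
#' `RSS = sum_j (Gamma_j - beta_(-j) gamma_j)^2 / se_out_j^2`. Its null
#' distribution comes from a parametric bootstrap that redraws both effect
#' estimates around their no-pleiotropy expected values; the global p is the
#' fraction of replicates exceeding the observed RSS. Per-SNP outlier
#' p-values are the analogous single-term comparisons, Bonferroni-adjusted;
#' flagged outliers (adjusted p < 0.05) are removed and the outlier-corrected
#' IVW reported, together with a distortion test comparing the correction to
#' removals of random subsets of the same size.
#'
#' @param hset a [HarmonizedSet-class] with at least 4 instruments.
#' @param n_sim parametric-bootstrap replicates (>= 1000).
#' @param seed RNG seed.
#' @param global_alpha significance level attached to the global test in
#'   downstream reporting (default 0.01).
#' @return An [MREstimate-class] with method `"presso"`: the raw IVW when no
#'   outlier is flagged, otherwise the outlier-corrected IVW, with
#'   `pressoGlobalP`, `outliers` and `distortionP` filled.
#' @export
mrPresso <- function(hset, n_sim = 5000, seed = 1L, global_alpha = 0.01) {
  if (n_sim < 1000) stop("configuration error: n_sim must be >= 1000")
  df <- .inst(hset)
  J <- nrow(df)
  if (J < 4) stop("MR-PRESSO needs at least 4 instruments")
  g <- df$beta_exp; G <- df$beta_out
  sx <- df$se_exp; sy <- df$se_out
  ratio <- G / g
  w <- g^2 / sy^2
  b_loo <- .loo_ivw(ratio, w)
  e_obs2 <- (G - b_loo * g)^2 / sy^2
  rss_obs <- sum(e_obs2)

  sim <- .with_seed(seed, {
    gs <- matrix(stats::rnorm(n_sim * J, rep(g, each = n_sim),
                              rep(sx, each = n_sim)), n_sim, J)
    Gs <- matrix(stats::rnorm(n_sim * J, rep(b_loo * g, each = n_sim),
                              rep(sy, each = n_sim)), n_sim, J)
    sym <- matrix(rep(sy, each = n_sim), n_sim, J)
    ws <- gs^2 / sym^2
    rs <- Gs / gs
    t1 <- rowSums(ws * rs); t0 <- rowSums(ws)
    bl <- (t1 - ws * rs) / (t0 - ws)       # leave-one-out IVW per replicate
    es2 <- (Gs - bl * gs)^2 / sym^2
    list(rss = rowSums(es2), e2 = es2)
  })
  global_p <- mean(sim$rss > rss_obs)
  p_out <- colMeans(sim$e2 > matrix(e_obs2, n_sim, J, byrow = TRUE))
  p_adj <- pmin(1, p_out * J)
  outliers <- df$snp_id[p_adj < 0.05]

  if (length(outliers) && J - length(outliers) >= 2) {
    keep <- !(df$snp_id %in% outliers)
    sub <- hset
    sub@instruments <- df[keep, , drop = FALSE]
    corrected <- ivwRandomEffects(sub)
    beta_raw <- sum(w * ratio) / sum(w)
    d_obs <- corrected@beta - beta_raw
    n_dist <- 1000L
    d_rand <- .with_seed(seed + 1L, {
      vapply(seq_len(n_dist), function(i) {
        drop <- sample.int(J, length(outliers))
        sum((w * ratio)[-drop]) / sum(w[-drop]) - beta_raw
      }, numeric(1))
    })
    distortion_p <- mean(abs(d_rand) >= abs(d_obs))
    return(.mk_est("presso", corrected@beta, corrected@se,
                   J - length(outliers),
                   q = corrected@q, qDf = corrected@qDf, qP = corrected@qP,
                   pressoGlobalP = global_p, outliers = outliers,
                   distortionP = distortion_p))
  }
  raw <- ivwRandomEffects(hset)
  .mk_est("presso", raw@beta, raw@se, J, q = raw@q, qDf = raw@qDf,
          qP = raw@qP, pressoGlobalP = global_p, outliers = outliers)
}

#' Robust MM regression estimate (MR-Robust)
#'
#' Robust linear regression of the SNP-outcome on the SNP-exposure effects
#' through the origin with inverse-variance weights, using MM-estimation
#' with the Tukey biweight at 95% Gaussian efficiency (tuning constant
#' 4.685); outlying instruments are smoothly down-weighted rather than
#' removed. When the weighted least-squares fit is already exact (noiseless
#' collinear data, where the robust scale degenerates to zero) the IVW
#' solution is returned unchanged.
#'
#' @param hset a [HarmonizedSet-class] with at least 3 instruments.
#' @return An [MREstimate-class] with method `"robust"`.
#' @export
mrRobust <- function(hset) {
  df <- .inst(hset)
  J <- nrow(df)
  if (J < 3) stop("MR-Robust needs at least 3 instruments")
  w <- 1 / df$se_out^2
  ls <- stats::lm(df$beta_out ~ df$beta_exp - 1, weights = w)
  if (max(abs(stats::residuals(ls))) < 1e-12 * max(abs(df$beta_out))) {
    ivw <- ivwRandomEffects(hset)
    return(.mk_est("robust", ivw@beta, ivw@se, J))
  }
  maxit <- 200L
  fit <- .with_seed(90210L, tryCatch(
    MASS::rlm(df$beta_out ~ df$beta_exp - 1, weights = w,
              wt.method = "inv.var", method = "MM", c = 4.685,
              maxit = maxit, acc = 1e-10),
    error = function(e) stop("robust regression failed: ",
                             conditionMessage(e))))
  if (!fit$converged)
    stop("robust regression did not converge in ", maxit, " iterations")
  sm <- summary(fit)
  .mk_est("robust", sm$coefficients[1, "Value"],
          sm$coefficients[1, "Std. Error"], J)
}

## Huber settings for the robust adjusted profile score.
.RAPS_C <- 1.345
.RAPS_DELTA <- 2 * stats::pnorm(1.345) - 1   # E[psi(Z) Z] = E[psi'(Z)]
## E[psi_c(Z)^2] for standard normal Z (closed form)
.RAPS_C1 <- .RAPS_DELTA - 2 * .RAPS_C * stats::dnorm(.RAPS_C) +
  .RAPS_C^2 * 2 * stats::pnorm(.RAPS_C, lower.tail = FALSE)

.raps_psi <- function(t) pmax(-.RAPS_C, pmin(.RAPS_C, t))

#' Robust adjusted profile score estimate (MR-RAPS)
#'
#' Profile-score estimation that models measurement error in both effect
#' estimates and a random-effects (overdispersed) distribution of
#' pleiotropic effects. Standardized residuals
#' `t_j = (Gamma_j - beta*gamma_j)/sqrt(se_out_j^2 + beta^2 se_exp_j^2 + tau2)`
#' are scored through the Huber psi (tuning constant 1.345); the estimate
#' solves the adjusted score equations
#' `sum psi(t_j) gamma_j/sqrt(v_j) = 0` (causal effect) and
#' `sum psi(t_j) t_j = J * (2 Phi(1.345) - 1)` (overdispersion `tau2 >= 0`,
#' the right-hand side being `E[psi(Z) Z]` so the equation is unbiased under
#' the model). Deterministic given the inputs; the SE is the
#' expected-information (model-based) one,
#' `sqrt(E[psi^2] / E[psi']^2 / sum(gamma_j^2 / v_j))`, which is stable at
#' the small instrument counts typical of MR (an empirical sandwich estimate
#' is far noisier there).
#'
#' @param hset a [HarmonizedSet-class] with at least 3 instruments.
#' @return An [MREstimate-class] with method `"raps"`; the fitted `tau2` is
#'   attached as attribute `"tau2"`.
#' @export
mrRaps <- function(hset) {
  df <- .inst(hset)
  J <- nrow(df)
  if (J < 3) stop("MR-RAPS needs at least 3 instruments")
  g <- df$beta_exp; G <- df$beta_out
  sx2 <- df$se_exp^2; sy2 <- df$se_out^2

  tfun <- function(beta, tau2) (G - beta * g) / sqrt(sy2 + beta^2 * sx2 + tau2)
  s_beta <- function(beta, tau2) {
    v <- sy2 + beta^2 * sx2 + tau2
    sum(.raps_psi(tfun(beta, tau2)) * g / sqrt(v))
  }
  s_tau <- function(beta, tau2) {
    t <- tfun(beta, tau2)
    sum(.raps_psi(t) * t) - J * .RAPS_DELTA
  }
  solve_beta <- function(tau2, start) {
    half <- max(10 * sqrt(1 / sum(g^2 / sy2)), 1e-3)
    lo <- start - half; hi <- start + half
    for (k in 1:60) {
      if (s_beta(lo, tau2) * s_beta(hi, tau2) <= 0) break
      lo <- lo - half; hi <- hi + half; half <- 2 * half
      if (k == 60) stop("MR-RAPS optimizer failure: cannot bracket the causal effect")
    }
    stats::uniroot(s_beta, c(lo, hi), tau2 = tau2, tol = 1e-12)$root
  }
  solve_tau <- function(beta) {
    if (s_tau(beta, 0) <= 0) return(0)   # boundary: no overdispersion
    hi <- stats::median(sy2)
    while (s_tau(beta, hi) > 0) {
      hi <- hi * 4
      if (hi > 1e6 * max(sy2)) stop("MR-RAPS optimizer failure: tau2 diverges")
    }
    stats::uniroot(function(x) s_tau(beta, x), c(0, hi), tol = 1e-14)$root
  }

  r <- .ratios(hset)
  beta <- sum(r$w * r$ratio) / sum(r$w)
  tau2 <- 0
  for (it in 1:200) {
    beta_new <- solve_beta(tau2, beta)
    tau2_new <- solve_tau(beta_new)
    done <- abs(beta_new - beta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
    beta <- beta_new; tau2 <- tau2_new
    if (done) break
    if (it == 200) stop("MR-RAPS did not converge in 200 iterations")
  }

  ## Expected-information SE: Var = E[psi^2] / E[psi']^2 / sum(g^2/v).
  ## The empirical sandwich sum(psi(t)^2 g^2/v) is far too noisy at small J
  ## (chi-square-type numerator on ~J df), so the model-based expectation
  ## under t ~ N(0,1) is used instead.
  v <- sy2 + beta^2 * sx2 + tau2
  se <- sqrt(.RAPS_C1 / .RAPS_DELTA^2 / sum(g^2 / v))
  out <- .mk_est("raps", beta, se, J)
  attr(out, "tau2") <- tau2
  out
}

#' Multivariable IVW
#'
#' Weighted multiple regression of the SNP-outcome effects on several
#' exposures' SNP effects jointly, without intercept and with weights
#' `1/se_out^2`; each coefficient is the direct effect of that exposure
#' conditional on the others (e.g. vitamin C adjusted for smoking). SEs
#' carry multiplicative overdispersion on J-K df.
#'
#' @param beta_exp J x K matrix of SNP effects on the K exposures (one
#'   column per exposure); column names label the exposures.
#' @param beta_out,se_out SNP-outcome effects and SEs (length J).
#' @param se_exp optional J x K matrix of exposure-side SEs (not used by the
#'   point estimator; accepted for interface completeness).
#' @return Named list of [MREstimate-class], method `"mv_ivw"`, one per
#'   exposure.
#' @export
multivariableIVW <- function(beta_exp, beta_out, se_out, se_exp = NULL) {
  X <- as.matrix(beta_exp)
  J <- nrow(X); K <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(K))
  stopifnot(length(beta_out) == J, length(se_out) == J, all(se_out > 0))
  if (J < K + 1)
    stop("multivariable IVW needs at least ", K + 1, " instruments for ",
         K, " exposures")
  if (qr(X)$rank < K)
    stop("collinear exposure-effect matrix: rank ", qr(X)$rank, " < ", K)
  w <- 1 / se_out^2
  fit <- stats::lm(beta_out ~ X - 1, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  infl <- max(1, sigma)
  out <- lapply(seq_len(K), function(k) {
    .mk_est("mv_ivw", sm$coefficients[k, "Estimate"],
            sm$coefficients[k, "Std. Error"] / sigma * infl, J)
  })
  names(out) <- colnames(X)
  out
}

.SUITE_METHODS <- c("ivw_re", "egger", "weighted_median", "mbe", "presso",
                    "robust", "raps")

#' Configuration for the estimator suite
#'
#' @param n_boot bootstrap replicates for weighted median and MBE SEs.
#' @param seed RNG seed for all stochastic members.
#' @param phi MBE bandwidth multiplier.
#' @param presso_n_sim MR-PRESSO bootstrap replicates.
#' @param presso_global_alpha global-test significance threshold used by
#'   reporting rules (default 0.01).
#' @return A named list.
#' @export
suiteConfig <- function(n_boot = 1000, seed = 1L, phi = 1,
                        presso_n_sim = 5000, presso_global_alpha = 0.01) {
  list(n_boot = n_boot, seed = as.integer(seed), phi = phi,
       presso_n_sim = presso_n_sim,
       presso_global_alpha = presso_global_alpha)
}

#' Run the full estimator battery on a harmonized set
#'
#' Applies, in a fixed order, the primary random-effects IVW and the six
#' sensitivity methods (MR-Egger, weighted median, mode-based, MR-PRESSO,
#' robust MM, MR-RAPS). A method whose preconditions fail (e.g. too few
#' instruments) is recorded as a failure with its message; the suite never
#' aborts. A single-instrument set yields the IVW (= Wald ratio) alone,
#' the others marked not applicable.
#'
#' @param hset a [HarmonizedSet-class].
#' @param config see [suiteConfig()].
#' @return A list with `estimates` (named list of [MREstimate-class] or
#'   `NULL` for failed methods) and `table`, a data.frame with one row per
#'   method and the fixed column schema `method, status, n_snps, beta, se,
#'   or, ci_low, ci_high, or_ci_low, or_ci_high, p, q, q_p,
#'   egger_intercept, egger_intercept_p, presso_global_p, outliers`.
#' @export
runEstimatorSuite <- function(hset, config = suiteConfig()) {
  df <- .inst(hset)
  J <- nrow(df)
  run1 <- function(method) {
    if (J == 1 && method != "ivw_re")
      return(list(est = NULL, status = "not_applicable"))
    res <- tryCatch(switch(method,
      ivw_re = ivwRandomEffects(hset),
      egger = mrEgger(hset),
      weighted_median = weightedMedian(hset, n_boot = config$n_boot,
                                       seed = config$seed),
      mbe = modeBasedEstimate(hset, phi = config$phi,
                              n_boot = config$n_boot, seed = config$seed),
      presso = mrPresso(hset, n_sim = config$presso_n_sim,
                        seed = config$seed,
                        global_alpha = config$presso_global_alpha),
      robust = mrRobust(hset),
      raps = mrRaps(hset)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) list(est = NULL, status = paste0("error: ", res))
    else list(est = res, status = "ok")
  }
  runs <- lapply(.SUITE_METHODS, run1)
  names(runs) <- .SUITE_METHODS
  rows <- lapply(.SUITE_METHODS, function(m) {
    r <- runs[[m]]
    if (is.null(r$est))
      return(data.frame(method = m, status = r$status, n_snps = NA_integer_,
                        beta = NA_real_, se = NA_real_, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        or_ci_low = NA_real_, or_ci_high = NA_real_,
                        p = NA_real_, q = NA_real_, q_p = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_p = NA_real_,
                        presso_global_p = NA_real_, outliers = "",
                        stringsAsFactors = FALSE))
    e <- r$est
    data.frame(method = m, status = "ok", n_snps = e@nSnps, beta = e@beta,
               se = e@se, or = exp(e@beta), ci_low = e@ciLow,
               ci_high = e@ciHigh, or_ci_low = exp(e@ciLow),
               or_ci_high = exp(e@ciHigh), p = e@pvalue, q = e@q,
               q_p = e@qP, egger_intercept = e@eggerIntercept,
               egger_intercept_p = e@eggerInterceptP,
               presso_global_p = e@pressoGlobalP,
               outliers = paste(e@outliers, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(estimates = lapply(runs, `[[`, "est"), table = tab)
}
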